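#' Assemble the coincidence network
#'
#' Nodes are the gene families appearing in at least one significant pair,
#' annotated with their D value; edges are the significant pairs, annotated
#' with the raw p-value. Connected components are numbered from 0 in
#' decreasing size order (ties broken by smallest member identifier) and
#' each receives a colour from a deterministic categorical palette shared
#' with the heatmap output.
#'
#' @param pairs A `pair_statistics` data frame; only rows with
#'   `significant == TRUE` are used.
#' @param d_results Data frame from [score_coincident_genes()] covering
#'   every family appearing in the significant pairs.
#' @return An object of class `coincidence_network`: a list with `nodes`
#'   (family, D, component, colour), `edges` (family_i, family_j, p_raw)
#'   and `components` (component, size, members).
#' @export
build_network <- function(pairs, d_results) {
  sig <- pairs[pairs$significant, , drop = FALSE]
  empty_nodes <- data.frame(family = character(0), D = numeric(0),
                            component = integer(0), colour = character(0),
                            stringsAsFactors = FALSE)
  empty_edges <- data.frame(family_i = character(0), family_j = character(0),
                            p_raw = numeric(0), stringsAsFactors = FALSE)
  empty_comp <- data.frame(component = integer(0), size = integer(0),
                           members = character(0), stringsAsFactors = FALSE)
  if (nrow(sig) == 0) {
    return(structure(list(nodes = empty_nodes, edges = empty_edges,
                          components = empty_comp),
                     class = "coincidence_network"))
  }
  node_ids <- sort(unique(c(sig$family_i, sig$family_j)))
  missing <- setdiff(node_ids, d_results$family)
  if (length(missing) > 0) {
    stop(sprintf("internal error: no D result for %s",
                 paste(utils::head(missing, 3), collapse = ", ")))
  }
  g <- igraph::graph_from_data_frame(
    sig[, c("family_i", "family_j")], directed = FALSE,
    vertices = data.frame(name = node_ids))
  memb <- igraph::components(g)$membership[node_ids]
  # order components by decreasing size, ties by smallest member id
  sizes <- table(memb)
  smallest <- tapply(node_ids, memb, min)
  comp_order <- names(sizes)[order(-as.integer(sizes), smallest)]
  comp_id <- setNames(seq_along(comp_order) - 1L, comp_order)
  node_comp <- comp_id[as.character(memb)]
  pal <- component_palette(length(comp_order))
  nodes <- data.frame(
    family = node_ids,
    D = d_results$D[match(node_ids, d_results$family)],
    component = as.integer(node_comp),
    colour = pal[node_comp + 1L],
    stringsAsFactors = FALSE)
  edges <- data.frame(family_i = sig$family_i, family_j = sig$family_j,
                      p_raw = sig$p_raw, stringsAsFactors = FALSE)
  members <- vapply(seq_along(comp_order) - 1L, function(cid) {
    paste(sort(nodes$family[nodes$component == cid]), collapse = ",")
  }, character(1))
  comps <- data.frame(component = seq_along(comp_order) - 1L,
                      size = as.integer(sizes[comp_order]),
                      members = members, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, components = comps),
            class = "coincidence_network")
}

#' @export
print.coincidence_network <- function(x, ...) {
  cat(sprintf("coincidence network: %d genes, %d edges, %d components\n",
              nrow(x$nodes), nrow(x$edges), nrow(x$components)))
  invisible(x)
}

#' Deterministic categorical palette for components
#'
#' Evenly spaced HCL hues, identical across runs, shared between the GEXF
#' export and the heatmaps.
#'
#' @param n Number of colours.
#' @return Character vector of hex colours.
#' @export
component_palette <- function(n) {
  if (n == 0) return(character(0))
  hues <- seq(15, 375, length.out = n + 1)[seq_len(n)]
  grDevices::hcl(h = hues, c = 100, l = 60)
}

# Edge thickness: monotone in -log10(p) so the most significant edges are
# the thickest; p is floored at 1e-300 before the log.
edge_thickness <- function(p, width_range = c(0.5, 5), raw_p = FALSE) {
  if (length(p) == 0) return(numeric(0))
  s <- if (raw_p) p else -log10(pmax(p, 1e-300))
  if (diff(range(s)) < .Machine$double.eps) {
    return(rep(mean(width_range), length(p)))
  }
  width_range[1] + (s - min(s)) / (max(s) - min(s)) * diff(width_range)
}

# Node size: affine map of D onto [min, max] over the observed D range;
# undefined D renders at the minimum size.
node_size <- function(D, size_range = c(5, 20)) {
  if (length(D) == 0) return(numeric(0))
  out <- rep(mean(size_range), length(D))
  ok <- !is.na(D)
  if (sum(ok) > 0 && diff(range(D[ok])) > .Machine$double.eps) {
    out[ok] <- size_range[1] +
      (D[ok] - min(D[ok])) / (max(D[ok]) - min(D[ok])) * diff(size_range)
  }
  out[!ok] <- size_range[1]
  out
}

#' Write a coincidence network as GEXF v1.2
#'
#' Emits Graph Exchange XML Format 1.2 with the viz extension: nodes are
#' coloured by connected component, sized by an affine map of the D value
#' over its observed range (constant when all D are equal), and labelled by
#' family identifier; edges carry a thickness monotone in -log10(p) (set
#' `edge_width_raw_p = TRUE` for thickness literally proportional to p). D
#' and p are also stored as typed attribute values.
#'
#' @param network A [build_network()] result.
#' @param path Output file path.
#' @param size_range,width_range Node-size and edge-thickness ranges.
#' @param edge_width_raw_p Use raw p instead of -log10(p) for thickness.
#' @return `path`, invisibly.
#' @export
write_gexf <- function(network, path, size_range = c(5, 20),
                       width_range = c(0.5, 5), edge_width_raw_p = FALSE) {
  stopifnot(inherits(network, "coincidence_network"))
  doc <- xml2::xml_new_root(
    "gexf",
    xmlns = "http://www.gexf.net/1.2draft",
    "xmlns:viz" = "http://www.gexf.net/1.2draft/viz",
    version = "1.2")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected",
                               mode = "static")
  attrs <- xml2::xml_add_child(graph, "attributes", class = "node")
  xml2::xml_add_child(attrs, "attribute", id = "d", title = "D",
                      type = "double")
  eattrs <- xml2::xml_add_child(graph, "attributes", class = "edge")
  xml2::xml_add_child(eattrs, "attribute", id = "p", title = "p",
                      type = "double")
  nodes_el <- xml2::xml_add_child(graph, "nodes")
  sizes <- node_size(network$nodes$D, size_range)
  for (k in seq_len(nrow(network$nodes))) {
    nd <- xml2::xml_add_child(nodes_el, "node",
                              id = network$nodes$family[k],
                              label = network$nodes$family[k])
    rgb <- grDevices::col2rgb(network$nodes$colour[k])
    xml2::xml_add_child(nd, "viz:color", r = as.character(rgb[1]),
                        g = as.character(rgb[2]), b = as.character(rgb[3]))
    xml2::xml_add_child(nd, "viz:size",
                        value = format(sizes[k], digits = 8))
    av <- xml2::xml_add_child(nd, "attvalues")
    xml2::xml_add_child(av, "attvalue", `for` = "d",
                        value = format(network$nodes$D[k], digits = 10))
  }
  edges_el <- xml2::xml_add_child(graph, "edges")
  thick <- edge_thickness(network$edges$p_raw, width_range, edge_width_raw_p)
  for (k in seq_len(nrow(network$edges))) {
    ed <- xml2::xml_add_child(edges_el, "edge",
                              id = as.character(k - 1L),
                              source = network$edges$family_i[k],
                              target = network$edges$family_j[k],
                              weight = format(thick[k], digits = 8))
    xml2::xml_add_child(ed, "viz:thickness",
                        value = format(thick[k], digits = 8))
    av <- xml2::xml_add_child(ed, "attvalues")
    xml2::xml_add_child(av, "attvalue", `for` = "p",
                        value = format(network$edges$p_raw[k], digits = 10))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read back a GEXF file written by [write_gexf()]
#'
#' Generic enough for round-trip checks: returns node identifiers with
#' colour, size and D, and edges with endpoints, thickness and p.
#'
#' @param path GEXF file path.
#' @return A list with `nodes` and `edges` data frames.
#' @export
read_gexf <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(g = "http://www.gexf.net/1.2draft",
          viz = "http://www.gexf.net/1.2draft/viz")
  node_els <- xml2::xml_find_all(doc, ".//g:nodes/g:node", ns)
  get_attr <- function(el, xp, at) {
    child <- xml2::xml_find_first(el, xp, ns)
    if (inherits(child, "xml_missing")) NA_character_
    else xml2::xml_attr(child, at)
  }
  nodes <- data.frame(
    id = xml2::xml_attr(node_els, "id"),
    label = xml2::xml_attr(node_els, "label"),
    r = as.integer(vapply(node_els, get_attr, "", "./viz:color", "r")),
    g = as.integer(vapply(node_els, get_attr, "", "./viz:color", "g")),
    b = as.integer(vapply(node_els, get_attr, "", "./viz:color", "b")),
    size = as.numeric(vapply(node_els, get_attr, "", "./viz:size", "value")),
    D = as.numeric(vapply(node_els, get_attr, "",
                          "./g:attvalues/g:attvalue[@for='d']", "value")),
    stringsAsFactors = FALSE)
  edge_els <- xml2::xml_find_all(doc, ".//g:edges/g:edge", ns)
  edges <- data.frame(
    source = xml2::xml_attr(edge_els, "source"),
    target = xml2::xml_attr(edge_els, "target"),
    thickness = as.numeric(vapply(edge_els, get_attr, "",
                                  "./viz:thickness", "value")),
    p = as.numeric(vapply(edge_els, get_attr, "",
                          "./g:attvalues/g:attvalue[@for='p']", "value")),
    stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges)
}
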