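#' Layout specification for coincident-gene heatmaps
#'
#' Determines, without rendering anything, how the heatmaps will be drawn:
#' gene columns ordered by D value from most lineage-independent (largest
#' D) to least, undefined D last, ties broken by identifier; column colours
#' taken from the network's component palette; genome rows in the tip order
#' of the ladderized tree as it is drawn; and the split of gene columns
#' into panels of at most `panel_size`.
#'
#' @param x A [pam()] object (the filtered matrix).
#' @param tree The reconciled `phylo` tree.
#' @param network A [build_network()] result.
#' @param panel_size Maximum gene columns per output file (default 100).
#' @return A list of class `heatmap_spec`: `gene_order`, `gene_colour`,
#'   `genome_order`, `panels` (list of column-index vectors).
#' @export
heatmap_spec <- function(x, tree, network, panel_size = 100) {
  stopifnot(inherits(x, "pam"), inherits(tree, "phylo"),
            inherits(network, "coincidence_network"))
  if (panel_size < 1) config_error("panel_size must be >= 1")
  nd <- network$nodes
  # D descending, NA last, ties lexicographic by family id
  o <- order(is.na(nd$D), -ifelse(is.na(nd$D), 0, nd$D), nd$family)
  gene_order <- nd$family[o]
  gene_colour <- setNames(nd$colour[o], gene_order)
  genome_order <- ladderized_tip_order(tree)
  n_genes <- length(gene_order)
  panels <- if (n_genes == 0) list() else
    split(seq_len(n_genes), ceiling(seq_len(n_genes) / panel_size))
  structure(list(gene_order = gene_order, gene_colour = gene_colour,
                 genome_order = genome_order, panels = unname(panels)),
            class = "heatmap_spec")
}

# Tip order (bottom to top) of the ladderized tree as plot.phylo draws it:
# ladderize with increasing clade sizes ("right = TRUE", ape's default).
ladderized_tip_order <- function(tree) {
  lt <- ape::ladderize(tree, right = TRUE)
  is_tip <- lt$edge[, 2] <= length(lt$tip.label)
  lt$tip.label[lt$edge[is_tip, 2]]
}

#' Render presence/absence heatmaps next to the phylogeny
#'
#' Writes `<prefix>heatmap0.pdf`, `<prefix>heatmap1.pdf`, ... each showing
#' the ladderized phylogeny on the left and up to `panel_size` gene columns
#' on the right; a filled cell marks presence, coloured by the gene's
#' connected component (matching the GEXF palette). The number of files is
#' `ceiling(n_genes / panel_size)`. An empty network produces no files.
#'
#' @inheritParams heatmap_spec
#' @param prefix Output path prefix.
#' @return Character vector of written paths (with the computed
#'   `heatmap_spec` as attribute `"spec"`), invisibly.
#' @export
render_heatmaps <- function(x, tree, network, prefix = "coincident_",
                            panel_size = 100) {
  spec <- heatmap_spec(x, tree, network, panel_size)
  if (length(spec$gene_order) == 0) {
    message("render_heatmaps: empty network, nothing to draw")
    return(invisible(structure(character(0), spec = spec)))
  }
  lt <- ape::ladderize(tree, right = TRUE)
  m <- x$presence[spec$genome_order, spec$gene_order, drop = FALSE]
  paths <- character(length(spec$panels))
  for (pn in seq_along(spec$panels)) {
    cols <- spec$panels[[pn]]
    path <- sprintf("%sheatmap%d.pdf", prefix, pn - 1L)
    grDevices::pdf(path, width = 10, height = 7)
    graphics::layout(matrix(1:2, nrow = 1), widths = c(1, 2.2))
    op <- graphics::par(mar = c(4, 0.5, 2, 0))
    ape::plot.phylo(lt, show.tip.label = FALSE, no.margin = FALSE)
    graphics::par(mar = c(4, 0.2, 2, 1))
    graphics::plot(NA, xlim = c(0.5, length(cols) + 0.5),
                   ylim = c(0.5, nrow(m) + 0.5), xlab = "gene families",
                   ylab = "", axes = FALSE,
                   main = sprintf("coincident genes %d-%d (by D, descending)",
                                  cols[1], cols[length(cols)]))
    for (ci in seq_along(cols)) {
      fam <- spec$gene_order[cols[ci]]
      rows <- which(m[, cols[ci]] == 1L)
      if (length(rows) > 0) {
        graphics::rect(ci - 0.5, rows - 0.5, ci + 0.5, rows + 0.5,
                       col = spec$gene_colour[[fam]], border = NA)
      }
    }
    graphics::box()
    graphics::par(op)
    grDevices::dev.off()
    paths[pn] <- path
  }
  invisible(structure(paths, spec = spec))
}
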