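#' Read a Roary gene_presence_absence.csv file
#'
#' Parses the standard pangenome pipeline output: an RFC-4180 CSV with a
#' header row, 14 metadata columns (the first of which names the gene
#' family) and one column per genome from column 15 onward. A family is
#' scored present in a genome when that genome's cell is non-empty after
#' whitespace trimming; multiple locus tags within one cell still count as a
#' single presence, because all downstream statistics are presence/absence
#' only.
#'
#' @param path Path to the CSV file.
#' @return A [pam()] object.
#' @export
read_roary_csv <- function(path) {
  if (!file.exists(path)) format_error("input file not found: %s", path)
  df <- tryCatch(
    utils::read.csv(path, header = TRUE, check.names = FALSE,
                    colClasses = "character", na.strings = NULL),
    error = function(e) format_error("cannot parse CSV %s: %s", path,
                                     conditionMessage(e)))
  if (ncol(df) < 15) {
    format_error("Roary CSV %s has %d columns; need 14 metadata columns plus at least one genome column",
                 path, ncol(df))
  }
  if (nrow(df) == 0) format_error("Roary CSV %s has a header but no gene rows", path)
  fams <- trimws(df[[1]])
  gens <- trimws(colnames(df)[15:ncol(df)])
  if (anyDuplicated(fams)) {
    format_error("duplicate gene family name in %s at row %d: %s",
                 path, which(duplicated(fams))[1], fams[duplicated(fams)][1])
  }
  if (anyDuplicated(gens)) {
    format_error("duplicate genome column in %s: %s",
                 path, gens[duplicated(gens)][1])
  }
  cells <- as.matrix(df[, 15:ncol(df), drop = FALSE])
  m <- matrix(as.integer(nzchar(trimws(cells))), nrow = nrow(cells))
  m <- t(m)  # genomes x families
  dimnames(m) <- list(gens, fams)
  pam(m)
}

#' Read a two-column gene membership list
#'
#' Each non-empty line holds one (gene family, genome) membership as two
#' tab-separated fields, family first. Duplicate lines collapse to a single
#' presence. Line order is irrelevant.
#'
#' @param path Path to the TSV file.
#' @return A [pam()] object.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) format_error("input file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) format_error("gene list %s contains no memberships", path)
  lines <- lines[keep]
  lineno <- which(keep)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2)) {
    bad <- which(nf != 2)[1]
    format_error("gene list %s line %d: expected 2 tab-separated fields, found %d",
                 path, lineno[bad], nf[bad])
  }
  fam <- trimws(vapply(parts, `[[`, "", 1L))
  gen <- trimws(vapply(parts, `[[`, "", 2L))
  if (any(!nzchar(fam)) || any(!nzchar(gen))) {
    bad <- which(!nzchar(fam) | !nzchar(gen))[1]
    format_error("gene list %s line %d: empty identifier", path, lineno[bad])
  }
  fams <- sort(unique(fam))
  gens <- sort(unique(gen))
  m <- matrix(0L, nrow = length(gens), ncol = length(fams),
              dimnames = list(gens, fams))
  m[cbind(match(gen, gens), match(fam, fams))] <- 1L
  pam(m)
}

#' Write a presence/absence matrix as a gene membership list
#'
#' Inverse of [read_gene_list()]: one `family<TAB>genome` line per presence,
#' ordered by family then genome.
#'
#' @param x A [pam()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(x, path) {
  stopifnot(inherits(x, "pam"))
  idx <- which(x$presence == 1L, arr.ind = TRUE)
  fam <- families(x)[idx[, 2]]
  gen <- genomes(x)[idx[, 1]]
  o <- order(fam, gen)
  writeLines(paste(fam[o], gen[o], sep = "\t"), path)
  invisible(path)
}

#' Write a presence/absence matrix in the Roary CSV dialect
#'
#' Emits a minimal but standards-shaped gene_presence_absence.csv: the 14
#' metadata columns (with a real "No. isolates" count; the other metadata
#' fields carry placeholders) followed by one column per genome holding a
#' synthetic locus tag where the family is present. Useful for exercising
#' [read_roary_csv()] end-to-end on generated data.
#'
#' @param x A [pam()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roary_csv <- function(x, path) {
  stopifnot(inherits(x, "pam"))
  meta_names <- c("Gene", "Non-unique Gene name", "Annotation", "No. isolates",
                  "No. sequences", "Avg sequences per isolate", "Genome Fragment",
                  "Order within Fragment", "Accessory Fragment",
                  "Accessory Order with Fragment", "QC",
                  "Min group size nuc", "Max group size nuc", "Avg group size nuc")
  fams <- families(x)
  gens <- genomes(x)
  ni <- family_counts(x)
  quote_csv <- function(v) paste0('"', gsub('"', '""', v), '"')
  header <- paste(quote_csv(c(meta_names, gens)), collapse = ",")
  rows <- vapply(seq_along(fams), function(j) {
    tags <- ifelse(x$presence[, j] == 1L,
                   paste0(gens, "_", sprintf("%05d", j)), "")
    meta <- c(fams[j], "", "hypothetical protein", ni[j], ni[j], "1", "", "",
              "", "", "", "", "", "")
    paste(quote_csv(c(meta, tags)), collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a Newick phylogeny
#'
#' Reads exactly one Newick tree. Tip labels (the genome identifiers) must
#' be unique; quoted labels are unquoted; internal node labels are tolerated
#' and never used for identity. Branch lengths, when present, must be
#' non-negative.
#'
#' @param path Path to a Newick file containing a single tree.
#' @return An \pkg{ape} `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) format_error("tree file not found: %s", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!nzchar(trimws(txt))) format_error("tree file %s is empty", path)
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) format_error("cannot parse Newick %s: %s",
                                                  path, conditionMessage(e)))
  if (inherits(tr, "multiPhylo")) {
    format_error("tree file %s contains %d trees; exactly one expected",
                 path, length(tr))
  }
  if (is.null(tr) || !inherits(tr, "phylo") || length(tr$tip.label) == 0) {
    format_error("cannot parse Newick %s: no valid tree found", path)
  }
  tr$tip.label <- gsub("^['\"]|['\"]$", "", tr$tip.label)
  if (anyDuplicated(tr$tip.label)) {
    format_error("duplicate tip label in %s: %s", path,
                 tr$tip.label[duplicated(tr$tip.label)][1])
  }
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0)) {
    format_error("negative branch length in %s", path)
  }
  tr
}

# One provenance header comment per output TSV, echoing the run parameters.
# The worker count is an execution detail, not a parameter of the analysis,
# and is omitted so results stay byte-identical across worker counts.
provenance_lines <- function(config) {
  if (is.null(config)) return(character(0))
  config <- config[setdiff(names(config), "workers")]
  paste0("# ", paste(names(config), unlist(lapply(config, format)), sep = "=",
                     collapse = " "))
}

write_tsv_with_header <- function(df, path, config = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_lines(config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write the tabular output suite of a coincidence run
#'
#' Writes four TSV files: `<prefix>pairs.tsv` (significant pairs with
#' observed and expected rates and raw p-value), `<prefix>nodes.tsv` (each
#' coincident gene with its D value), `<prefix>edges.tsv` (significant
#' pairs with p-value) and `<prefix>components.tsv` (connected components
#' with comma-separated member genes). Each file begins with a `#`
#' provenance comment echoing the run parameters, followed by a header row.
#' With zero significant pairs all four files are still written, headers
#' only.
#'
#' @param result A `coincidence_result` from [coincidence_analysis()].
#' @param prefix Output path prefix; default `"coincident_"`.
#' @return Named character vector of the four paths, invisibly.
#' @export
write_tables <- function(result, prefix = "coincident_") {
  stopifnot(inherits(result, "coincidence_result"))
  cfg <- result$config
  net <- result$network
  sig <- result$significant
  pairs_df <- data.frame(gene_i = sig$family_i, gene_j = sig$family_j,
                         observed = sig$observed, expected = sig$expected,
                         p = sig$p_raw, stringsAsFactors = FALSE)
  nodes_df <- data.frame(gene = net$nodes$family, D = net$nodes$D,
                         stringsAsFactors = FALSE)
  edges_df <- data.frame(gene_i = net$edges$family_i,
                         gene_j = net$edges$family_j,
                         p = net$edges$p_raw, stringsAsFactors = FALSE)
  comp_df <- data.frame(component = net$components$component,
                        members = net$components$members,
                        stringsAsFactors = FALSE)
  paths <- c(pairs = paste0(prefix, "pairs.tsv"),
             nodes = paste0(prefix, "nodes.tsv"),
             edges = paste0(prefix, "edges.tsv"),
             components = paste0(prefix, "components.tsv"))
  write_tsv_with_header(pairs_df, paths[["pairs"]], cfg)
  write_tsv_with_header(nodes_df, paths[["nodes"]], cfg)
  write_tsv_with_header(edges_df, paths[["edges"]], cfg)
  write_tsv_with_header(comp_df, paths[["components"]], cfg)
  invisible(paths)
}
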