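#' Presence/absence matrix of gene families across genomes
#'
#' Constructs the central container of the package: a strictly binary
#' genomes-by-gene-families incidence matrix. Rows are genomes, columns are
#' gene families; cell (g, f) is 1 when family f has at least one member in
#' genome g.
#'
#' @param presence A numeric or logical matrix with genome identifiers as row
#'   names and gene family identifiers as column names. All values must be
#'   0/1 (or FALSE/TRUE).
#' @return An object of class `pam`.
#' @examples
#' m <- matrix(c(1, 1, 0, 0, 1, 1), nrow = 3,
#'             dimnames = list(c("gA", "gB", "gC"), c("fam1", "fam2")))
#' p <- pam(m)
#' family_counts(p)
#' @export
pam <- function(presence) {
  if (!is.matrix(presence)) format_error("presence must be a matrix")
  g <- rownames(presence)
  f <- colnames(presence)
  if (is.null(g) || is.null(f)) {
    format_error("presence matrix must carry genome row names and family column names")
  }
  check_identifiers(g, "genome")
  check_identifiers(f, "gene family")
  storage.mode(presence) <- "integer"
  if (anyNA(presence) || !all(presence %in% c(0L, 1L))) {
    format_error("presence matrix must be strictly binary (0/1)")
  }
  structure(list(presence = presence), class = "pam")
}

# Identifiers must be unique, non-empty after trimming, and free of tabs so
# that every downstream TSV stays well-formed.
check_identifiers <- function(ids, what) {
  ids <- trimws(ids)
  if (any(!nzchar(ids))) format_error("empty %s identifier", what)
  if (any(grepl("\t", ids, fixed = TRUE))) {
    format_error("%s identifier contains a tab character: %s", what,
                 ids[grepl("\t", ids, fixed = TRUE)][1])
  }
  if (anyDuplicated(ids)) {
    format_error("duplicate %s identifier: %s", what, ids[duplicated(ids)][1])
  }
  invisible(ids)
}

#' @export
print.pam <- function(x, ...) {
  cat(sprintf("presence/absence matrix: %d genomes x %d gene families\n",
              n_genomes(x), length(families(x))))
  invisible(x)
}

#' Accessors for presence/absence matrices
#'
#' @param x A [pam()] object.
#' @return `genomes()` and `families()` return character vectors of
#'   identifiers; `n_genomes()` the genome count N; `family_counts()` the
#'   named per-family occurrence counts N_i (column sums); `presence_matrix()`
#'   the underlying binary integer matrix.
#' @export
genomes <- function(x) rownames(x$presence)

#' @rdname genomes
#' @export
families <- function(x) colnames(x$presence)

#' @rdname genomes
#' @export
n_genomes <- function(x) nrow(x$presence)

#' @rdname genomes
#' @export
family_counts <- function(x) colSums(x$presence)

#' @rdname genomes
#' @export
presence_matrix <- function(x) x$presence

#' Reconcile a presence/absence matrix with a phylogeny
#'
#' Restricts the matrix and the tree to their common set of genome
#' identifiers. All downstream statistics (pairwise tests and the D
#' statistic) are computed over this shared genome set, so reconciliation
#' runs before the abundance filter.
#'
#' @param x A [pam()] object.
#' @param tree A rooted `phylo` tree whose tip labels are genome identifiers.
#' @return A list with elements `pam` (restricted matrix), `tree` (restricted
#'   tree), `dropped_genomes` (matrix genomes absent from the tree) and
#'   `dropped_tips` (tree tips absent from the matrix).
#' @export
reconcile <- function(x, tree) {
  stopifnot(inherits(x, "pam"), inherits(tree, "phylo"))
  shared <- intersect(genomes(x), tree$tip.label)
  if (length(shared) == 0) {
    config_error(paste0(
      "no genome identifiers shared between matrix and tree ",
      "(matrix e.g. %s; tree e.g. %s)"),
      paste(utils::head(genomes(x), 3), collapse = ", "),
      paste(utils::head(tree$tip.label, 3), collapse = ", "))
  }
  if (length(shared) < 3) {
    config_error("only %d genome(s) shared between matrix and tree; need >= 3",
                 length(shared))
  }
  dropped_g <- setdiff(genomes(x), shared)
  dropped_t <- setdiff(tree$tip.label, shared)
  if (length(dropped_g) > 0) {
    message(sprintf("reconcile: dropping %d matrix genome(s) absent from the tree",
                    length(dropped_g)))
  }
  if (length(dropped_t) > 0) {
    message(sprintf("reconcile: dropping %d tree tip(s) absent from the matrix",
                    length(dropped_t)))
    tree <- ape::drop.tip(tree, dropped_t)
  }
  # keep matrix row order aligned to the (pruned) tree's tip labels
  x2 <- pam(x$presence[tree$tip.label, , drop = FALSE])
  list(pam = x2, tree = tree, dropped_genomes = dropped_g, dropped_tips = dropped_t)
}

#' Cull core and rare gene families
#'
#' Core families (present in every genome) cannot associate or dissociate
#' with anything, so they are removed. Rare families, whose prevalence
#' fraction N_i/N is strictly below `cutoff_fraction`, are removed because
#' they cannot reach significance; a family exactly at the cutoff is
#' retained. Families absent from every genome are always dropped as rare.
#'
#' @param x A [pam()] object (already reconciled with the tree if one is
#'   used).
#' @param cutoff_fraction Minimum prevalence fraction in `[0, 1)`; default
#'   0.05, i.e. families in less than 5% of genomes are removed.
#' @return A list with `pam` (the filtered matrix) and `report`, a
#'   `pam_filter_report` partitioning the input families into
#'   `removed_core`, `removed_rare` and `retained`.
#' @export
filter_families <- function(x, cutoff_fraction = 0.05) {
  stopifnot(inherits(x, "pam"))
  if (!is.numeric(cutoff_fraction) || length(cutoff_fraction) != 1 ||
      cutoff_fraction < 0 || cutoff_fraction >= 1) {
    config_error("cutoff_fraction must be a single number in [0, 1)")
  }
  n <- n_genomes(x)
  ni <- family_counts(x)
  core <- ni == n
  rare <- !core & (ni == 0L | ni / n < cutoff_fraction)
  keep <- !core & !rare
  report <- structure(list(
    removed_core = names(ni)[core],
    removed_rare = names(ni)[rare],
    retained = names(ni)[keep],
    cutoff_fraction = cutoff_fraction,
    n_genomes = n
  ), class = "pam_filter_report")
  list(pam = pam(x$presence[, keep, drop = FALSE]), report = report)
}

#' @export
print.pam_filter_report <- function(x, ...) {
  cat(sprintf(
    "family filter (N = %d genomes, cutoff %.3f): %d core removed, %d rare removed, %d retained\n",
    x$n_genomes, x$cutoff_fraction, length(x$removed_core),
    length(x$removed_rare), length(x$retained)))
  invisible(x)
}
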