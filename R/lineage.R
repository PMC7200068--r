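#' Observed dispersion of a binary trait on a phylogeny
#'
#' The building block of the D statistic. Each internal node is assigned a
#' nodal value equal to the unweighted mean of its children's values
#' (polytomies average over all children), computed tips-to-root; branch
#' lengths play no role in this estimate. The returned quantity is the sum,
#' over every parent-child edge, of the absolute difference between the
#' child's and the parent's nodal values. Clade-confined traits yield small
#' sums; checkerboard-dispersed traits yield large ones.
#'
#' @param tree A rooted `phylo` tree (polytomies allowed).
#' @param trait Binary 0/1 vector over tips. If named, names must match the
#'   tip labels; if unnamed, values are taken in `tree$tip.label` order.
#' @return The observed sum of nodal-value changes, a non-negative real.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' d_observed(tr, c(A = 1, B = 1, C = 0, D = 0))  # 1.0, clade-confined
#' d_observed(tr, c(A = 1, B = 0, C = 1, D = 0))  # 2.0, checkerboard
#' @export
d_observed <- function(tree, trait) {
  trait <- align_trait(tree, trait)
  if (all(trait == 0) || all(trait == 1)) {
    config_error("D undefined for invariant trait")
  }
  as.numeric(d_stat_matrix(tree, matrix(trait, ncol = 1)))
}

# map a (possibly named) 0/1 trait vector onto tree tip order
align_trait <- function(tree, trait) {
  stopifnot(inherits(tree, "phylo"))
  nt <- length(tree$tip.label)
  if (!is.null(names(trait))) {
    if (!setequal(names(trait), tree$tip.label)) {
      config_error("trait names do not match the tree's tip labels")
    }
    trait <- trait[tree$tip.label]
  } else if (length(trait) != nt) {
    config_error("unnamed trait must have one value per tip")
  }
  trait <- as.numeric(trait)
  if (anyNA(trait) || !all(trait %in% c(0, 1))) {
    config_error("trait must be strictly binary (0/1)")
  }
  trait
}

# Vectorised dispersion sum for a matrix of traits (tips x replicates), each
# column one trait in tree tip order. One postorder sweep estimates all nodal
# values; the edge-wise |child - parent| sums come from a single matrix op.
d_stat_matrix <- function(tree, traits) {
  nt <- length(tree$tip.label)
  tr <- stats::reorder(tree, "postorder")
  edge <- tr$edge
  tot <- nt + tr$Nnode
  reps <- ncol(traits)
  vals <- matrix(0, tot, reps)
  vals[seq_len(nt), ] <- traits
  acc <- matrix(0, tot, reps)
  cnt <- integer(tot)
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1]; ch <- edge[e, 2]
    if (ch > nt && cnt[ch] > 0) {
      vals[ch, ] <- acc[ch, ] / cnt[ch]
    }
    acc[par, ] <- acc[par, ] + vals[ch, ]
    cnt[par] <- cnt[par] + 1L
  }
  root <- edge[nrow(edge), 1]
  vals[root, ] <- acc[root, ] / cnt[root]
  colSums(abs(vals[edge[, 2], , drop = FALSE] - vals[edge[, 1], , drop = FALSE]))
}

#' Null distributions of the dispersion sum
#'
#' `null_random()` shuffles the trait values across tips uniformly at
#' random, preserving prevalence — the "no phylogenetic signal" null that
#' anchors D = 1. `null_brownian()` simulates a continuous character along
#' the tree under Brownian motion (independent normal increments per edge
#' with variance equal to branch length; unit lengths are substituted when
#' the tree carries none) and thresholds the tip values so that exactly
#' `sum(trait)` tips score 1 — the threshold-model null that anchors D = 0.
#' Both preserve the observed prevalence in every replicate.
#'
#' @param tree A rooted `phylo` tree.
#' @param trait Binary trait as in [d_observed()].
#' @param n_perm Number of replicates (default 1000, minimum 100).
#' @param seed Integer seed; replicates are reproducible per seed.
#' @return Numeric vector of `n_perm` dispersion sums.
#' @name d_nulls
NULL

#' @rdname d_nulls
#' @export
null_random <- function(tree, trait, n_perm = 1000, seed = 1L) {
  trait <- align_trait(tree, trait)
  if (n_perm < 100) config_error("n_perm must be >= 100")
  nt <- length(trait)
  set.seed(seed)
  perms <- vapply(seq_len(n_perm), function(r) trait[sample.int(nt)],
                  numeric(nt))
  d_stat_matrix(tree, perms)
}

#' @rdname d_nulls
#' @export
null_brownian <- function(tree, trait, n_perm = 1000, seed = 1L) {
  trait <- align_trait(tree, trait)
  if (n_perm < 100) config_error("n_perm must be >= 100")
  prev <- sum(trait)
  set.seed(seed)
  tips <- brownian_tips(tree, n_perm)
  bin <- apply(tips, 2, function(xcol) {
    out <- numeric(length(xcol))
    out[order(xcol, stats::runif(length(xcol)), decreasing = TRUE)[seq_len(prev)]] <- 1
    out
  })
  d_stat_matrix(tree, bin)
}

# Brownian tip values: root value 0, preorder accumulation of N(0, len)
# increments; returns tips x reps. Uses the ambient RNG stream.
brownian_tips <- function(tree, reps) {
  nt <- length(tree$tip.label)
  tr <- stats::reorder(tree, "cladewise")
  edge <- tr$edge
  len <- tr$edge.length
  if (is.null(len)) len <- rep(1, nrow(edge))
  len <- pmax(len, 0)
  tot <- nt + tr$Nnode
  vals <- matrix(0, tot, reps)
  for (e in seq_len(nrow(edge))) {
    vals[edge[e, 2], ] <- vals[edge[e, 1], ] +
      stats::rnorm(reps, 0, sqrt(len[e]))
  }
  vals[seq_len(nt), , drop = FALSE]
}

#' Scale an observed dispersion sum into the D statistic
#'
#' `D = (d_obs - mean(brownian)) / (mean(random) - mean(brownian))`: 1 for a
#' phylogenetically random (lineage-independent) trait, 0 for a trait as
#' clumped as Brownian evolution predicts, below 0 for extreme clumping and
#' above 1 for overdispersion. When the two null means are closer than 1e-9
#' the statistic is undefined and reported as `NA` with a warning.
#'
#' @param d_obs Observed dispersion sum from [d_observed()].
#' @param d_random_sample Replicates from [null_random()].
#' @param d_brownian_sample Replicates from [null_brownian()].
#' @return A list with `d_obs`, `mean_d_random`, `mean_d_brownian` and `D`.
#' @export
compute_D <- function(d_obs, d_random_sample, d_brownian_sample) {
  stopifnot(length(d_random_sample) > 0, length(d_brownian_sample) > 0)
  mr <- mean(d_random_sample)
  mb <- mean(d_brownian_sample)
  denom <- mr - mb
  if (abs(denom) < 1e-9) {
    warning("D undefined: null means coincide")
    D <- NA_real_
  } else {
    D <- (d_obs - mb) / denom
  }
  list(d_obs = d_obs, mean_d_random = mr, mean_d_brownian = mb, D = D)
}

#' D statistic for one binary trait
#'
#' Convenience wrapper running [d_observed()], both nulls and [compute_D()].
#'
#' @inheritParams d_nulls
#' @return A one-row data frame: `d_obs`, `mean_d_random`,
#'   `mean_d_brownian`, `D`, `n_perm`, `seed`.
#' @export
phylo_signal_d <- function(tree, trait, n_perm = 1000, seed = 1L) {
  d <- d_observed(tree, trait)
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, 2)
  dr <- null_random(tree, trait, n_perm, sub[1])
  db <- null_brownian(tree, trait, n_perm, sub[2])
  res <- compute_D(d, dr, db)
  data.frame(d_obs = res$d_obs, mean_d_random = res$mean_d_random,
             mean_d_brownian = res$mean_d_brownian, D = res$D,
             n_perm = n_perm, seed = seed)
}

#' Score the lineage independence of a set of gene families
#'
#' Computes the D statistic for each requested family's presence/absence
#' pattern over the phylogeny. In the pipeline this runs only for genes
#' that appear in significant coincident pairs, which is where the bulk of
#' the runtime lives. Per-family sub-seeds are derived from the master seed
#' over the sorted family list, so results are identical for any worker
#' count.
#'
#' @param tree A rooted `phylo` tree reconciled with the matrix.
#' @param x A [pam()] object whose genomes are the tree's tips.
#' @param families Character vector of family identifiers to score.
#' @param n_perm Replicates per null (default 1000).
#' @param seed Master seed.
#' @param workers Parallel workers (forked; ignored on platforms without
#'   fork).
#' @return A data frame with one row per family: `family`, `d_obs`,
#'   `mean_d_random`, `mean_d_brownian`, `D`, `n_perm`, `seed`.
#' @export
score_coincident_genes <- function(tree, x, families, n_perm = 1000,
                                   seed = 1L, workers = 1L) {
  stopifnot(inherits(x, "pam"))
  families <- sort(unique(as.character(families)))
  empty <- data.frame(family = character(0), d_obs = numeric(0),
                      mean_d_random = numeric(0), mean_d_brownian = numeric(0),
                      D = numeric(0), n_perm = integer(0), seed = integer(0),
                      stringsAsFactors = FALSE)
  if (length(families) == 0) return(empty)
  missing <- setdiff(families, families(x))
  if (length(missing) > 0) {
    config_error("families not present in the matrix: %s",
                 paste(utils::head(missing, 3), collapse = ", "))
  }
  set.seed(seed)
  fam_seeds <- sample.int(.Machine$integer.max - 1L, length(families))
  score_one <- function(k) {
    fam <- families[k]
    trait <- x$presence[tree$tip.label, fam]
    names(trait) <- tree$tip.label
    r <- phylo_signal_d(tree, trait, n_perm = n_perm, seed = fam_seeds[k])
    cbind(data.frame(family = fam, stringsAsFactors = FALSE), r)
  }
  rows <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_along(families), score_one, mc.cores = workers)
  } else {
    lapply(seq_along(families), score_one)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
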