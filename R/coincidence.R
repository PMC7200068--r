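#' Observed and expected coincidence rates
#'
#' The statistical core works on per-family occurrence counts. With N
#' genomes, `N_i` genomes holding family i and `P_i = N_i / N`:
#'
#' * observed association `O_A = N_ij`, the number of genomes holding both
#'   families;
#' * expected association `E_A = P_i * P_j * N`;
#' * observed dissociation `O_D = N_i + N_j - 2 N_ij`, the number of genomes
#'   holding exactly one of the two;
#' * expected dissociation `E_D = [P_i (1 - P_j) + P_j (1 - P_i)] * N`.
#'
#' @param x A [pam()] object.
#' @param i,j Gene family identifiers.
#' @param n_i,n_j Occurrence counts of the two families.
#' @param n_ij Co-occurrence count.
#' @param n Total genome count N.
#' @return A count (observed rates) or a real number (expected rates).
#' @name coincidence_rates
NULL

#' @rdname coincidence_rates
#' @export
observed_association <- function(x, i, j) {
  stopifnot(inherits(x, "pam"))
  fams <- families(x)
  if (!(i %in% fams)) config_error("unknown gene family: %s", i)
  if (!(j %in% fams)) config_error("unknown gene family: %s", j)
  sum(x$presence[, i] & x$presence[, j])
}

#' @rdname coincidence_rates
#' @export
expected_association <- function(n_i, n_j, n) {
  stopifnot(n > 0, all(n_i >= 0), all(n_j >= 0), all(n_i <= n), all(n_j <= n))
  (n_i / n) * (n_j / n) * n
}

#' @rdname coincidence_rates
#' @export
observed_dissociation <- function(n_i, n_j, n_ij) {
  stopifnot(all(n_ij <= pmin(n_i, n_j)))
  n_i + n_j - 2L * n_ij
}

#' @rdname coincidence_rates
#' @export
expected_dissociation <- function(n_i, n_j, n) {
  stopifnot(n > 0, all(n_i >= 0), all(n_j >= 0), all(n_i <= n), all(n_j <= n))
  pi_ <- n_i / n
  pj_ <- n_j / n
  (pi_ * (1 - pj_) + pj_ * (1 - pi_)) * n
}

#' One-sided upper-tail binomial exact p-value
#'
#' Computes `P(X >= observed)` for `X ~ Binomial(size, rate)` by exact tail
#' summation. Terms are accumulated in log space, shifted by the largest
#' term, so the result is accurate over the full double range. Vectorised
#' over all three arguments.
#'
#' In association mode the pipeline calls this with `rate = P_i * P_j` and
#' `observed = N_ij`; in dissociation mode with
#' `rate = P_i (1 - P_j) + P_j (1 - P_i)` and `observed = O_D`. Both modes
#' use the upper tail: the question is always "more often than expected".
#'
#' @param observed Observed success count(s), `0 <= observed <= size`.
#' @param size Number of trials (the genome count N).
#' @param rate Expected per-trial success probability in `[0, 1]`.
#' @return p-value(s) in `[0, 1]`.
#' @examples
#' binomial_exact_p(5, 10, 0.25)   # ~0.0781
#' @export
binomial_exact_p <- function(observed, size, rate) {
  len <- max(length(observed), length(size), length(rate))
  observed <- rep_len(as.integer(round(observed)), len)
  size <- rep_len(as.integer(round(size)), len)
  rate <- rep_len(as.numeric(rate), len)
  stopifnot(all(observed >= 0L), all(observed <= size),
            all(rate >= -1e-12), all(rate <= 1 + 1e-12))
  rate <- pmin(pmax(rate, 0), 1)
  p <- rep(NA_real_, len)
  p[observed == 0L] <- 1            # P(X >= 0) = 1
  p[is.na(p) & rate == 0] <- 0      # observed > 0 impossible at rate 0
  p[is.na(p) & rate == 1] <- 1      # X = size >= observed surely
  todo <- which(is.na(p))
  # chunk the expanded k-grid to bound peak memory on large runs
  chunk_terms <- 4e6
  while (length(todo) > 0) {
    lens_all <- size[todo] - observed[todo] + 1L
    take <- which(cumsum(as.numeric(lens_all)) <= chunk_terms)
    if (length(take) == 0) take <- 1L
    idx <- todo[take]
    todo <- todo[-take]
    obs <- observed[idx]; sz <- size[idx]; r <- rate[idx]
    lens <- sz - obs + 1L
    grp <- rep(seq_along(idx), lens)
    k <- sequence(lens) - 1L + rep(obs, lens)
    szr <- rep(sz, lens); rr <- rep(r, lens)
    lp <- lchoose(szr, k) + k * log(rr) + (szr - k) * log1p(-rr)
    # largest tail term sits at max(observed, distribution mode)
    kmax <- pmin(pmax(obs, floor((sz + 1) * r)), sz)
    lm <- lchoose(sz, kmax) + kmax * log(r) + (sz - kmax) * log1p(-r)
    s <- rowsum(exp(lp - rep(lm, lens)), grp, reorder = FALSE)[, 1]
    p[idx] <- pmin(exp(lm + log(s)), 1)
  }
  p
}

#' Test every gene-family pair for coincidence
#'
#' Evaluates each unordered pair of retained families exactly once, in
#' either association or dissociation mode, with the one-sided binomial
#' exact test, and applies a Bonferroni correction whose denominator is the
#' number of pairs actually tested. The input should already be reconciled
#' with the tree and filtered with [filter_families()].
#'
#' Results are deterministic: pairs are enumerated lexicographically by
#' family identifier and the output is sorted by ascending raw p-value, then
#' by family identifiers, regardless of `workers`.
#'
#' @param x A filtered [pam()] object.
#' @param mode `"association"` or `"dissociation"`.
#' @param alpha Family-wise error target for the Bonferroni correction
#'   (default 0.05).
#' @param workers Number of parallel workers for the p-value computation.
#' @return A data frame of class `pair_statistics` with one row per pair:
#'   `family_i`, `family_j`, `N`, `N_i`, `N_j`, `N_ij`, `observed`,
#'   `expected`, `p_raw`, `significant`. Attributes `n_tests`, `alpha`,
#'   `threshold` and `mode` describe the correction.
#' @export
run_pairwise <- function(x, mode = c("association", "dissociation"),
                         alpha = 0.05, workers = 1L) {
  stopifnot(inherits(x, "pam"))
  mode <- match.arg(mode)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    config_error("alpha must be in (0, 1)")
  }
  n <- n_genomes(x)
  fams <- sort(families(x))
  empty <- data.frame(family_i = character(0), family_j = character(0),
                      N = integer(0), N_i = integer(0), N_j = integer(0),
                      N_ij = integer(0), observed = integer(0),
                      expected = numeric(0), p_raw = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
  if (length(fams) < 2) {
    message("run_pairwise: fewer than two retained families; zero tests")
    return(structure(empty, n_tests = 0L, alpha = alpha, threshold = NA_real_,
                     mode = mode, class = c("pair_statistics", "data.frame")))
  }
  m <- x$presence[, fams, drop = FALSE]
  co <- crossprod(m)                      # N_ij for every ordered pair
  ni <- colSums(m)
  ut <- which(upper.tri(co), arr.ind = TRUE)  # i < j in lexicographic order
  i <- ut[, 1]; j <- ut[, 2]
  n_i <- ni[i]; n_j <- ni[j]; n_ij <- co[ut]
  if (mode == "association") {
    observed <- as.integer(n_ij)
    rate <- (n_i / n) * (n_j / n)
    expected <- rate * n
  } else {
    observed <- as.integer(observed_dissociation(n_i, n_j, n_ij))
    rate <- (n_i / n) * (1 - n_j / n) + (n_j / n) * (1 - n_i / n)
    expected <- rate * n
  }
  p_raw <- if (workers > 1L && .Platform$OS.type == "unix") {
    splits <- parallel::splitIndices(length(observed), workers)
    unlist(parallel::mclapply(splits, function(sel) {
      binomial_exact_p(observed[sel], n, rate[sel])
    }, mc.cores = workers), use.names = FALSE)
  } else {
    binomial_exact_p(observed, n, rate)
  }
  n_tests <- length(p_raw)
  threshold <- alpha / n_tests
  res <- data.frame(family_i = fams[i], family_j = fams[j], N = n,
                    N_i = as.integer(n_i), N_j = as.integer(n_j),
                    N_ij = as.integer(n_ij), observed = observed,
                    expected = expected, p_raw = p_raw,
                    significant = p_raw <= threshold,
                    stringsAsFactors = FALSE)
  res <- res[order(res$p_raw, res$family_i, res$family_j), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, n_tests = n_tests, alpha = alpha, threshold = threshold,
            mode = mode, class = c("pair_statistics", "data.frame"))
}
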