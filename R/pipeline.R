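#' Full coincident-gene analysis
#'
#' Runs the complete pipeline on a presence/absence matrix and a phylogeny:
#' reconcile genome sets, cull core and rare families, test every retained
#' pair with the Bonferroni-corrected one-sided binomial exact test, score
#' the lineage independence (D) of each gene appearing in a significant
#' pair, and assemble the coincidence network. The association/dissociation
#' statistics and the D statistic are computed independently of one
#' another; D annotates the output and is never used as a filter.
#'
#' @param x A [pam()] object.
#' @param tree A rooted `phylo` tree whose tips are genome identifiers.
#' @param mode `"association"` (genes found together more often than
#'   expected) or `"dissociation"` (found apart more often than expected).
#' @param alpha Family-wise error target (default 0.05).
#' @param cutoff_fraction Rare-gene cull threshold (default 0.05; see
#'   [filter_families()]).
#' @param n_perm Replicates per D null (default 1000).
#' @param seed Master seed for the D permutations/simulations.
#' @param workers Parallel workers for pairwise tests and D scoring.
#' @param d_all Score D for every retained family rather than only those in
#'   significant pairs.
#' @return An object of class `coincidence_result`: a list with `pairs`
#'   (all tested pairs), `significant` (the significant subset), `d`
#'   (D results), `network`, `filter` (the cull report), `pam` (filtered
#'   matrix), `tree` (reconciled tree) and `config` (the run parameters).
#' @examples
#' tree <- random_tree(80, seed = 7)
#' sim <- simulate_matrix(tree, sim_config(n_background = 30,
#'                                         n_assoc_pairs = 2,
#'                                         epsilon = 0), seed = 7)
#' res <- coincidence_analysis(sim$pam, tree, n_perm = 100, seed = 7)
#' res
#' @export
coincidence_analysis <- function(x, tree, mode = c("association", "dissociation"),
                                 alpha = 0.05, cutoff_fraction = 0.05,
                                 n_perm = 1000, seed = 1L, workers = 1L,
                                 d_all = FALSE) {
  mode <- match.arg(mode)
  rec <- reconcile(x, tree)
  flt <- filter_families(rec$pam, cutoff_fraction)
  message(sprintf("N = %d genomes; %d families retained (%d core, %d rare removed)",
                  n_genomes(flt$pam), length(flt$report$retained),
                  length(flt$report$removed_core), length(flt$report$removed_rare)))
  pairs <- run_pairwise(flt$pam, mode = mode, alpha = alpha, workers = workers)
  sig <- pairs[pairs$significant, , drop = FALSE]
  message(sprintf("%d pairwise tests; %d significant at Bonferroni threshold %s",
                  attr(pairs, "n_tests"), nrow(sig),
                  format(attr(pairs, "threshold"), digits = 4)))
  to_score <- if (d_all) families(flt$pam) else
    unique(c(sig$family_i, sig$family_j))
  d <- score_coincident_genes(rec$tree, flt$pam, to_score, n_perm = n_perm,
                              seed = seed, workers = workers)
  net <- build_network(sig, d)
  message(sprintf("network: %d genes in %d connected components",
                  nrow(net$nodes), nrow(net$components)))
  config <- list(mode = mode, alpha = alpha,
                 cutoff_fraction = cutoff_fraction, n_perm = n_perm,
                 seed = seed, workers = workers, d_all = d_all,
                 n_genomes = n_genomes(flt$pam),
                 n_retained = length(flt$report$retained),
                 n_tests = attr(pairs, "n_tests"),
                 bonferroni_threshold = attr(pairs, "threshold"))
  structure(list(pairs = pairs, significant = sig, d = d, network = net,
                 filter = flt$report, pam = flt$pam, tree = rec$tree,
                 config = config),
            class = "coincidence_result")
}

#' @export
print.coincidence_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("coincident gene analysis (%s mode)\n", cfg$mode))
  cat(sprintf("  genomes:            %d\n", cfg$n_genomes))
  cat(sprintf("  retained families:  %d\n", cfg$n_retained))
  cat(sprintf("  pairwise tests:     %d\n", cfg$n_tests))
  cat(sprintf("  significant pairs:  %d (p <= %s)\n", nrow(x$significant),
              format(cfg$bonferroni_threshold, digits = 4)))
  cat(sprintf("  coincident genes:   %d in %d components\n",
              nrow(x$network$nodes), nrow(x$network$components)))
  invisible(x)
}

#' Write the complete output suite
#'
#' Writes the four tabular outputs ([write_tables()]), the GEXF network
#' (`<prefix>network.gexf`) and the heatmap PDFs ([render_heatmaps()]).
#'
#' @param result A `coincidence_result`.
#' @param prefix Output path prefix (default `"coincident_"`).
#' @param panel_size Gene columns per heatmap file.
#' @return Character vector of all written paths, invisibly.
#' @export
write_outputs <- function(result, prefix = "coincident_", panel_size = 100) {
  tabs <- write_tables(result, prefix)
  gexf <- paste0(prefix, "network.gexf")
  write_gexf(result$network, gexf)
  maps <- render_heatmaps(result$pam, result$tree, result$network,
                          prefix = prefix, panel_size = panel_size)
  invisible(c(tabs, network = gexf, maps))
}
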