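#' Simulation settings for synthetic pangenomes
#'
#' Collects the parameters of the synthetic presence/absence generator:
#' background gene families (independent of one another), planted
#' associating pairs (partner copies the anchor's presence vector) and
#' planted dissociating pairs (partner complements it), with a symmetric
#' per-genome flip probability `epsilon` decoupling each planted partner
#' from its anchor. Background and anchor genes are drawn either i.i.d.
#' Bernoulli across genomes (`clumping = "iid"`, lineage-independent) or by
#' thresholding a Brownian character simulated on the tree
#' (`clumping = "brownian"`, lineage-dependent).
#'
#' @param n_background Number of background gene families (default 500).
#' @param bg_prob Per-genome presence probability of background genes
#'   (default 0.5).
#' @param n_assoc_pairs,n_dissoc_pairs Planted pair counts (default 0).
#' @param epsilon Flip probability decoupling partner from anchor (default
#'   0.05).
#' @param anchor_prob Per-genome presence probability of planted anchors
#'   (default 0.5).
#' @param clumping `"iid"` or `"brownian"`, applied to background and
#'   anchor genes alike.
#' @param retry_cap Resampling attempts when a planted gene comes out
#'   invariant (default 50).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_background = 500, bg_prob = 0.5,
                       n_assoc_pairs = 0, n_dissoc_pairs = 0,
                       epsilon = 0.05, anchor_prob = 0.5,
                       clumping = c("iid", "brownian"), retry_cap = 50) {
  clumping <- match.arg(clumping)
  stopifnot(n_background >= 0, n_assoc_pairs >= 0, n_dissoc_pairs >= 0,
            bg_prob >= 0, bg_prob <= 1, epsilon >= 0, epsilon <= 1,
            anchor_prob > 0, anchor_prob < 1, retry_cap >= 1)
  structure(list(n_background = as.integer(n_background), bg_prob = bg_prob,
                 n_assoc_pairs = as.integer(n_assoc_pairs),
                 n_dissoc_pairs = as.integer(n_dissoc_pairs),
                 epsilon = epsilon, anchor_prob = anchor_prob,
                 clumping = clumping, retry_cap = as.integer(retry_cap)),
            class = "sim_config")
}

#' Random genome phylogeny
#'
#' A random rooted bifurcating tree built by coalescent-style joins with
#' exponential waiting times, tips labelled `g0001`, `g0002`, ...
#' Deterministic per seed.
#'
#' @param n_tips Number of genomes (at least 3).
#' @param seed Integer seed.
#' @return A `phylo` tree.
#' @export
random_tree <- function(n_tips, seed = 1L) {
  if (n_tips < 3) config_error("random_tree needs n_tips >= 3")
  set.seed(seed)
  ape::rcoal(n_tips, tip.label = sprintf("g%04d", seq_len(n_tips)))
}

# draw one gene's presence vector over the tree's tips, in tip-label order
draw_gene <- function(tree, prob, clumping) {
  nt <- length(tree$tip.label)
  if (clumping == "iid") {
    stats::rbinom(nt, 1L, prob)
  } else {
    prev <- max(1L, min(nt - 1L, round(prob * nt)))
    x <- brownian_tips(tree, 1)[, 1]
    out <- integer(nt)
    out[order(x, stats::runif(nt), decreasing = TRUE)[seq_len(prev)]] <- 1L
    out
  }
}

#' Simulate a presence/absence matrix with planted coincident pairs
#'
#' Generates `config$n_background` background genes plus the planted
#' associating and dissociating pairs described in [sim_config()], over the
#' tips of `tree`. All randomness flows from `seed` through named
#' substreams (background, association planting, dissociation planting), so
#' each block is reproducible independently. A planted gene whose presence
#' vector comes out invariant (all 0 or all 1) is resampled up to
#' `config$retry_cap` times, then an error is raised.
#'
#' @param tree A `phylo` tree whose tips are the genomes.
#' @param config A [sim_config()].
#' @param seed Master seed.
#' @return A list with `pam` (the simulated matrix), `truth` (data frame of
#'   planted pairs: `anchor`, `partner`, `type`, `epsilon`) and `modes`
#'   (data frame mapping every gene to its generating mode).
#' @export
simulate_matrix <- function(tree, config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"), inherits(tree, "phylo"))
  nt <- length(tree$tip.label)
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, 3)

  cols <- list()
  modes <- list()

  # background substream
  set.seed(sub[1])
  if (config$n_background > 0) {
    bg_names <- sprintf("bg%04d", seq_len(config$n_background))
    for (k in seq_len(config$n_background)) {
      cols[[bg_names[k]]] <- draw_gene(tree, config$bg_prob, config$clumping)
    }
    modes$bg <- data.frame(gene = bg_names,
                           mode = paste0("background_", config$clumping),
                           stringsAsFactors = FALSE)
  }

  plant <- function(n_pairs, type, prefix, stream_seed) {
    if (n_pairs == 0) return(NULL)
    set.seed(stream_seed)
    rows <- vector("list", n_pairs)
    for (k in seq_len(n_pairs)) {
      a_name <- sprintf("%sA%03d", prefix, k)
      b_name <- sprintf("%sB%03d", prefix, k)
      ok <- FALSE
      for (attempt in seq_len(config$retry_cap)) {
        anchor <- draw_gene(tree, config$anchor_prob, config$clumping)
        base <- if (type == "association") anchor else 1L - anchor
        flips <- stats::rbinom(nt, 1L, config$epsilon)
        partner <- as.integer(xor(base, flips))
        if (sum(anchor) > 0 && sum(anchor) < nt &&
            sum(partner) > 0 && sum(partner) < nt) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        config_error("planted %s pair %d invariant after %d attempts",
                     type, k, config$retry_cap)
      }
      cols[[a_name]] <<- anchor
      cols[[b_name]] <<- partner
      rows[[k]] <- data.frame(anchor = a_name, partner = b_name, type = type,
                              epsilon = config$epsilon,
                              stringsAsFactors = FALSE)
    }
    mode_df <- data.frame(
      gene = c(sprintf("%sA%03d", prefix, seq_len(n_pairs)),
               sprintf("%sB%03d", prefix, seq_len(n_pairs))),
      mode = c(rep(paste0("anchor_", config$clumping), n_pairs),
               rep(paste0("planted_", type), n_pairs)),
      stringsAsFactors = FALSE)
    list(truth = do.call(rbind, rows), modes = mode_df)
  }

  assoc <- plant(config$n_assoc_pairs, "association", "assoc", sub[2])
  dissoc <- plant(config$n_dissoc_pairs, "dissociation", "dissoc", sub[3])

  m <- do.call(cbind, cols)
  rownames(m) <- tree$tip.label
  truth <- rbind(if (!is.null(assoc)) assoc$truth,
                 if (!is.null(dissoc)) dissoc$truth)
  if (is.null(truth)) {
    truth <- data.frame(anchor = character(0), partner = character(0),
                        type = character(0), epsilon = numeric(0),
                        stringsAsFactors = FALSE)
  }
  mode_df <- rbind(modes$bg, if (!is.null(assoc)) assoc$modes,
                   if (!is.null(dissoc)) dissoc$modes)
  list(pam = pam(m), truth = truth, modes = mode_df)
}

#' Write a synthetic dataset in both input dialects
#'
#' Emits the simulated matrix as a Roary-style CSV and a gene-membership
#' TSV, plus the tree as Newick, exercising every reader end-to-end.
#'
#' @param sim A [simulate_matrix()] result.
#' @param tree The tree it was simulated on.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_fixture_set <- function(sim, tree, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(roary = file.path(dir, "gene_presence_absence.csv"),
             gene_list = file.path(dir, "gene_list.tsv"),
             tree = file.path(dir, "tree.nwk"))
  write_roary_csv(sim$pam, paths[["roary"]])
  write_gene_list(sim$pam, paths[["gene_list"]])
  ape::write.tree(tree, paths[["tree"]])
  invisible(paths)
}
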