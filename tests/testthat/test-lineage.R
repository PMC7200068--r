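test_that("observed dispersion matches the hand traversal on the quartet", {
  tr <- quartet_tree()
  # clade-confined: anc(A,B)=1, anc(C,D)=0, root=0.5 -> sum = 1.0
  expect_equal(d_observed(tr, c(A = 1, B = 1, C = 0, D = 0)), 1.0)
  # checkerboard: both ancestors 0.5, root 0.5 -> four tip edges of 0.5
  expect_equal(d_observed(tr, c(A = 1, B = 0, C = 1, D = 0)), 2.0)
  # clumped strictly below checkerboard at equal prevalence
  expect_lt(d_observed(tr, c(A = 1, B = 1, C = 0, D = 0)),
            d_observed(tr, c(A = 1, B = 0, C = 1, D = 0)))
})

test_that("dispersion is invariant to tree rotation and ignores branch lengths", {
  trait <- c(A = 1, B = 1, C = 0, D = 1)
  rotated <- ape::read.tree(text = "((D:9,C:2):4,(B:1,A:7):1);")
  expect_equal(d_observed(quartet_tree(), trait),
               d_observed(rotated, trait))
  # polytomies average over all children
  star <- ape::read.tree(text = "(A,B,C,D);")
  expect_equal(d_observed(star, c(A = 1, B = 1, C = 0, D = 0)), 2.0)
})

test_that("invariant traits are rejected", {
  tr <- quartet_tree()
  expect_error(d_observed(tr, c(A = 1, B = 1, C = 1, D = 1)),
               "invariant", class = "copresence_config_error")
  expect_error(d_observed(tr, c(A = 0, B = 0, C = 0, D = 0)),
               "invariant", class = "copresence_config_error")
})

test_that("tip-shuffle null matches exact enumeration on the quartet", {
  tr <- quartet_tree()
  trait <- c(A = 1, B = 1, C = 0, D = 0)
  # exact support: all C(4,2)=6 arrangements of prevalence 2
  combos <- combn(4, 2)
  support <- apply(combos, 2, function(sel) {
    v <- c(A = 0, B = 0, C = 0, D = 0)
    v[sel] <- 1
    d_observed(tr, v)
  })
  dr <- null_random(tr, trait, n_perm = 2000, seed = 9)
  expect_true(all(dr %in% support))
  se <- sd(support) / sqrt(2000)
  expect_lt(abs(mean(dr) - mean(support)), 4 * se)
})

test_that("Brownian-threshold null preserves prevalence exactly", {
  tr <- quartet_tree()
  trait <- c(A = 1, B = 0, C = 0, D = 0)
  # with prevalence 1 the only reachable d values are those of the four
  # single-presence arrangements
  support <- sapply(c("A", "B", "C", "D"), function(tip) {
    v <- c(A = 0, B = 0, C = 0, D = 0)
    v[tip] <- 1
    d_observed(tr, v)
  })
  db <- null_brownian(tr, trait, n_perm = 500, seed = 21)
  expect_true(all(db %in% support))
})

test_that("on a star tree the two nulls coincide in distribution", {
  star <- ape::stree(8, type = "star")
  star$tip.label <- sprintf("t%d", 1:8)
  trait <- setNames(rep(c(1, 0), each = 4), star$tip.label)
  dr <- null_random(star, trait, n_perm = 2000, seed = 31)
  db <- null_brownian(star, trait, n_perm = 2000, seed = 32)
  # on a star tree d depends on tip values only through the prevalence, so
  # both null distributions may be degenerate and exactly equal
  se <- sqrt(var(dr) / 2000 + var(db) / 2000)
  expect_lte(abs(mean(dr) - mean(db)), 3 * se + 1e-12)
})

test_that("D scales between the tip-shuffle and Brownian anchors", {
  dr <- c(4, 5, 6)
  db <- c(1, 2, 3)
  expect_equal(compute_D(mean(dr), dr, db)$D, 1)
  expect_equal(compute_D(mean(db), dr, db)$D, 0)
  expect_lt(compute_D(1.5, dr, db)$D, 0)
  expect_gt(compute_D(8, dr, db)$D, 1)
  expect_warning(res <- compute_D(2, c(2, 2), c(2, 2)), "undefined")
  expect_true(is.na(res$D))
})

test_that("D computation is reproducible and worker-invariant", {
  tree <- random_tree(40, seed = 3)
  sim <- simulate_matrix(tree, sim_config(n_background = 6), seed = 3)
  fams <- families(sim$pam)[1:4]
  r1 <- score_coincident_genes(tree, sim$pam, fams, n_perm = 200, seed = 99,
                               workers = 1)
  r4 <- score_coincident_genes(tree, sim$pam, fams, n_perm = 200, seed = 99,
                               workers = 4)
  expect_identical(r1, r4)
  r1b <- score_coincident_genes(tree, sim$pam, fams, n_perm = 200, seed = 99)
  expect_identical(r1, r1b)
  # empty request -> empty result
  expect_equal(nrow(score_coincident_genes(tree, sim$pam, character(0))), 0L)
  # one row per requested family
  expect_equal(r1$family, sort(fams))
})

test_that("scoring runs only on the requested families", {
  tree <- random_tree(30, seed = 8)
  sim <- simulate_matrix(tree, sim_config(n_background = 10), seed = 8)
  res <- score_coincident_genes(tree, sim$pam, families(sim$pam)[c(3, 1)],
                                n_perm = 100, seed = 1)
  expect_equal(nrow(res), 2L)
  expect_error(
    score_coincident_genes(tree, sim$pam, "missing_family", n_perm = 100),
    class = "copresence_config_error")
})
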