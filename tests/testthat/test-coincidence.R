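test_that("observed and expected rates follow the defining formulas", {
  x <- toy_pam()  # fam1 = {A,B}, fam2 = {B,C,D}, fam3 = {A,D}
  expect_equal(observed_association(x, "fam1", "fam2"), 1L)
  expect_equal(observed_association(x, "fam1", "fam3"), 1L)
  expect_equal(observed_association(x, "fam1", "fam1"), 2L)
  expect_error(observed_association(x, "fam1", "nope"),
               class = "copresence_config_error")

  expect_equal(expected_association(5, 5, 10), 2.5)
  expect_equal(expected_association(0, 5, 10), 0)
  expect_equal(expected_association(10, 7, 10), 7)  # P_i = 1

  expect_equal(observed_dissociation(5, 5, 0), 10L)
  expect_equal(observed_dissociation(5, 5, 5), 0L)
  expect_equal(observed_dissociation(3, 7, 2), 6L)

  expect_equal(expected_dissociation(5, 5, 10), 5.0)
  expect_equal(expected_dissociation(0, 4, 10), 4.0)
  expect_equal(expected_dissociation(10, 10, 10), 0)
})

test_that("binomial upper tail matches direct enumeration and handles edges", {
  expect_equal(binomial_exact_p(0, 10, 0.25), 1)
  expect_equal(binomial_exact_p(10, 10, 1), 1)
  expect_equal(binomial_exact_p(3, 10, 0), 0)
  # enumeration oracle: sum_{k=5..10} C(10,k) 0.25^k 0.75^(10-k)
  oracle <- sum(choose(10, 5:10) * 0.25^(5:10) * 0.75^(10 - (5:10)))
  expect_equal(binomial_exact_p(5, 10, 0.25), oracle, tolerance = 1e-14)
  expect_equal(round(oracle, 4), 0.0781)

  # cross-check against the independent distribution-function route
  set.seed(7)
  for (rep in 1:200) {
    n <- sample(1:300, 1)
    obs <- sample(0:n, 1)
    rate <- runif(1)
    ref <- pbinom(obs - 1, n, rate, lower.tail = FALSE)
    expect_equal(binomial_exact_p(obs, n, rate), ref, tolerance = 1e-10)
  }

  # vectorised call agrees with scalar calls
  obs <- c(0L, 3L, 17L, 40L)
  p_vec <- binomial_exact_p(obs, 40, 0.3)
  expect_equal(p_vec, vapply(obs, binomial_exact_p, 0, size = 40, rate = 0.3))

  # monotone: with trials and rate fixed, p is non-increasing in observed
  p_seq <- binomial_exact_p(0:50, 50, 0.37)
  expect_true(all(diff(p_seq) <= 0))
})

test_that("pairwise testing enumerates each unordered pair once with Bonferroni", {
  m <- matrix(0L, 60, 3, dimnames = list(sprintf("g%02d", 1:60),
                                         c("fa", "fb", "fc")))
  m[1:30, "fa"] <- 1L
  m[1:30, "fb"] <- 1L  # identical to fa: strong association
  m[seq(1, 60, 2), "fc"] <- 1L
  res <- run_pairwise(pam(m), "association")
  expect_equal(nrow(res), 3L)  # C(3,2)
  expect_equal(attr(res, "n_tests"), 3L)
  expect_equal(attr(res, "threshold"), 0.05 / 3)

  ab <- res[res$family_i == "fa" & res$family_j == "fb", ]
  expect_equal(ab$N_ij, 30L)
  expect_equal(ab$expected, 0.5 * 0.5 * 60)
  # identical vectors over half of 60 genomes clear the Bonferroni bar
  expect_true(ab$significant)
  # oracle: exact binomial tail at observed = N_i, rate = P_i^2
  expect_equal(ab$p_raw, pbinom(29, 60, 0.25, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("association and dissociation counts are conserved and consistent", {
  set.seed(11)
  tree <- random_tree(40, seed = 11)
  sim <- simulate_matrix(tree, sim_config(n_background = 30), seed = 11)
  x <- sim$pam
  asc <- run_pairwise(x, "association")
  dsc <- run_pairwise(x, "dissociation")
  key <- function(df) pair_keys(df$family_i, df$family_j)
  expect_setequal(key(asc), key(dsc))
  d_by_key <- setNames(dsc$observed, key(dsc))
  # O_D = N_i + N_j - 2 N_ij for every pair, and partition of N holds
  expect_equal(unname(d_by_key[key(asc)]), asc$N_i + asc$N_j - 2L * asc$N_ij)
  neither <- asc$N - asc$N_ij - (asc$N_i + asc$N_j - 2L * asc$N_ij)
  expect_true(all(neither >= 0))
  # monotonicity of p in N_ij at fixed margins
  p_var <- binomial_exact_p(0:20, 40, (20 / 40)^2)
  expect_true(all(diff(p_var) <= 0))
})

test_that("pairwise results are identical for any worker count", {
  tree <- random_tree(50, seed = 13)
  sim <- simulate_matrix(tree, sim_config(n_background = 40, n_assoc_pairs = 3),
                         seed = 13)
  r1 <- run_pairwise(sim$pam, "association", workers = 1)
  r4 <- run_pairwise(sim$pam, "association", workers = 4)
  expect_identical(r1, r4)
})

test_that("raw p-values are calibrated on an independent-presence null", {
  tree <- random_tree(100, seed = 17)
  sim <- simulate_matrix(tree, sim_config(n_background = 200), seed = 17)
  res <- run_pairwise(sim$pam, "association")
  t_pairs <- attr(res, "n_tests")
  frac <- mean(res$p_raw <= 0.05)
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 / t_pairs))
})

test_that("degenerate inputs yield zero tests, not failures", {
  m <- matrix(c(1L, 0L, 1L), 3, 1, dimnames = list(c("a", "b", "c"), "solo"))
  expect_message(res <- run_pairwise(pam(m), "association"), "fewer than two")
  expect_equal(nrow(res), 0L)
  expect_equal(attr(res, "n_tests"), 0L)
})
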