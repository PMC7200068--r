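test_that("network assembly groups genes into ordered components", {
  sig <- fake_sig_pairs(c("a", "b", "d"), c("b", "c", "e"))
  net <- build_network(sig, fake_d_results(letters[1:5]))
  expect_equal(nrow(net$nodes), 5L)
  expect_equal(nrow(net$edges), 3L)
  expect_equal(net$components$component, c(0L, 1L))
  expect_equal(net$components$members, c("a,b,c", "d,e"))
  expect_equal(net$components$size, c(3L, 2L))
  # every component holds at least two genes and they partition the nodes
  expect_true(all(net$components$size >= 2))
  all_members <- unlist(strsplit(net$components$members, ","))
  expect_setequal(all_members, net$nodes$family)

  # no significant pairs -> empty network
  none <- build_network(fake_sig_pairs(character(0), character(0)),
                        fake_d_results(character(0)))
  expect_equal(nrow(none$nodes), 0L)
  expect_equal(nrow(none$components), 0L)

  # a 6-clique stays one component with C(6,2)=15 edges
  cl <- t(combn(sprintf("ntp%d", 1:6), 2))
  net6 <- build_network(fake_sig_pairs(cl[, 1], cl[, 2]),
                        fake_d_results(sprintf("ntp%d", 1:6)))
  expect_equal(nrow(net6$components), 1L)
  expect_equal(nrow(net6$edges), 15L)
  expect_equal(net6$components$size, 6L)
})

test_that("a missing D result for a network node is an internal error", {
  sig <- fake_sig_pairs("a", "b")
  expect_error(build_network(sig, fake_d_results("a")), "no D result")
})

test_that("components agree with a transitive-closure oracle on random graphs", {
  set.seed(123)
  for (rep in 1:3) {
    n <- 200
    ids <- sprintf("v%03d", 1:n)
    n_edges <- sample(80:220, 1)
    e <- cbind(sample(n, n_edges, replace = TRUE),
               sample(n, n_edges, replace = TRUE))
    e <- e[e[, 1] != e[, 2], , drop = FALSE]
    sig <- fake_sig_pairs(ids[e[, 1]], ids[e[, 2]])
    touched <- sort(unique(c(e)))
    net <- build_network(sig, fake_d_results(ids[touched]))
    # oracle: boolean transitive closure by repeated squaring
    adj <- diag(n) > 0
    adj[e] <- TRUE
    adj[e[, c(2, 1), drop = FALSE]] <- TRUE
    repeat {
      nxt <- (adj %*% adj) > 0
      if (identical(nxt, adj)) break
      adj <- nxt
    }
    oracle_comp <- apply(adj[touched, touched, drop = FALSE], 1,
                         function(row) paste(sort(ids[touched][row]),
                                             collapse = ","))
    expect_setequal(net$components$members, unique(unname(oracle_comp)))
  }
})

test_that("GEXF export round-trips topology, colours and attributes", {
  sig <- fake_sig_pairs(c("a", "b", "d"), c("b", "c", "e"),
                        p = c(1e-12, 1e-6, 1e-3))
  net <- build_network(sig, fake_d_results(letters[1:5], c(-0.2, 0.4, 1.3, 0.9, 0.1)))
  path <- withr::local_tempfile(fileext = ".gexf")
  write_gexf(net, path)
  back <- read_gexf(path)
  expect_setequal(back$nodes$id, net$nodes$family)
  expect_equal(pair_keys(back$edges$source, back$edges$target),
               pair_keys(net$edges$family_i, net$edges$family_j))
  expect_equal(back$edges$p[order(back$edges$source)],
               net$edges$p_raw[order(net$edges$family_i)], tolerance = 1e-9)
  ord <- match(net$nodes$family, back$nodes$id)
  expect_equal(back$nodes$D[ord], net$nodes$D, tolerance = 1e-9)
  # colours encode the component partition
  rgb_back <- grDevices::rgb(back$nodes$r, back$nodes$g, back$nodes$b,
                             maxColorValue = 255)
  expect_equal(rgb_back[ord], net$nodes$colour)
  expect_equal(length(unique(rgb_back)), nrow(net$components))
  # node size is an affine map of D: extremes at the range ends
  expect_equal(back$nodes$size[ord][which.max(net$nodes$D)], 20)
  expect_equal(back$nodes$size[ord][which.min(net$nodes$D)], 5)
})

test_that("smaller p never gets a thinner edge", {
  p <- c(1e-20, 1e-9, 1e-9, 0.04, 1e-300, 0)
  th <- copresence:::edge_thickness(p)
  o <- order(p)
  expect_true(all(diff(th[o]) <= 1e-12))
  # raw-p mode restores literal proportionality direction
  thr <- copresence:::edge_thickness(c(0.01, 0.02, 0.05), raw_p = TRUE)
  expect_true(all(diff(thr) > 0))
})

test_that("an empty network still yields well-formed GEXF", {
  net <- build_network(fake_sig_pairs(character(0), character(0)),
                       fake_d_results(character(0)))
  path <- withr::local_tempfile(fileext = ".gexf")
  write_gexf(net, path)
  back <- read_gexf(path)
  expect_equal(nrow(back$nodes), 0L)
  expect_equal(nrow(back$edges), 0L)
})
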