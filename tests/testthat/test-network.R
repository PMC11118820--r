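lay3 <- channel_layout(c("a", "b", "c"),
                       c(a = "frontal", b = "central", c = "occipital"))

fc3 <- function(ab, ac, bc, metric = "wPLI") {
  m <- matrix(0, 3, 3, dimnames = list(lay3$labels, lay3$labels))
  m["a", "b"] <- m["b", "a"] <- ab
  m["a", "c"] <- m["c", "a"] <- ac
  m["b", "c"] <- m["c", "b"] <- bc
  eegfbn:::new_fc_matrix(m, metric, lay3)
}

test_that("averaging connectivity matrices is the elementwise mean", {
  m1 <- fc3(0.2, 0.5, 0.8)
  avg_same <- average_fc(list(m1, m1, m1))
  expect_equal(avg_same$values, m1$values)
  expect_equal(avg_same$n_windows_averaged, 3L)

  compl <- fc3(0.8, 0.5, 0.2)
  expect_equal(average_fc(list(m1, compl))$values["a", "b"], 0.5)

  m2 <- fc3(0.4, 0, 0); m3 <- fc3(0.9, 0, 0)
  expect_equal(average_fc(list(m1, m2, m3))$values["a", "b"], 0.5)

  expect_error(average_fc(list()), "empty")
  expect_error(average_fc(list(m1, fc3(0.1, 0.1, 0.1, metric = "PLV"))),
               "mixed metrics")
})

test_that("density binarization keeps the top-weight edges", {
  g <- binarize(fc3(0.9, 0.5, 0.1), rule = "density", d = 2 / 3)
  expect_equal(g$edge_rule$n_edges, 2)
  expect_true(g$adjacency["a", "b"] && g$adjacency["a", "c"])
  expect_false(g$adjacency["b", "c"])
  expect_equal(g$degrees, c(a = 2L, b = 1L, c = 1L))
  # degree sum = 2 x edge count
  expect_equal(sum(g$degrees), 2 * g$edge_rule$n_edges)
  # exactly one edge kept
  g1 <- binarize(fc3(0.9, 0.5, 0.1), rule = "density", d = 1 / 3)
  expect_equal(sort(unname(g1$degrees)), c(0L, 1L, 1L))
})

test_that("absolute binarization at tau = 0 yields the complete graph", {
  g <- binarize(fc3(0.9, 0.5, 0.1), rule = "absolute", tau = 0)
  expect_true(all(g$adjacency[upper.tri(g$adjacency)]))
  expect_equal(unname(g$degrees), rep(2L, 3))
  expect_false(any(diag(g$adjacency)))
})

test_that("density rule yields round(d * n_pairs) edges on 19 channels", {
  set.seed(6)
  lay <- channel_layout()
  w <- matrix(0, 19, 19, dimnames = list(lay$labels, lay$labels))
  w[upper.tri(w)] <- runif(171)
  w <- w + t(w)
  fc <- eegfbn:::new_fc_matrix(w, "wPLI", lay)
  for (d in c(0.1, 0.33, 0.8)) {
    g <- binarize(fc, d = d)
    expect_equal(g$edge_rule$n_edges, round(d * 171))
    expect_equal(sum(g$degrees), 2 * g$edge_rule$n_edges)
  }
  # ties broken deterministically
  w2 <- matrix(0.5, 19, 19); diag(w2) <- 0
  dimnames(w2) <- dimnames(w)
  fc2 <- eegfbn:::new_fc_matrix(w2, "wPLI", lay)
  g_a <- binarize(fc2, d = 0.33)
  g_b <- binarize(fc2, d = 0.33)
  expect_identical(g_a$adjacency, g_b$adjacency)
  expect_equal(g_a$edge_rule$n_edges, 56)
})

test_that("region degree statistics are per-region mean and sd", {
  lay <- channel_layout()
  # complete graph: every degree 18, sd 0
  w <- matrix(1, 19, 19, dimnames = list(lay$labels, lay$labels))
  diag(w) <- 0
  g <- binarize(eegfbn:::new_fc_matrix(w, "wPLI", lay), rule = "absolute",
                tau = 0.5)
  s <- g$region_degree_stats
  expect_equal(s$mean, rep(18, 3))
  expect_equal(s$sd, rep(0, 3))
  expect_equal(s$n_channels, c(7, 5, 7))
  # empty graph: all means zero
  g0 <- binarize(eegfbn:::new_fc_matrix(w * 0, "wPLI", lay),
                 rule = "absolute", tau = 0.5)
  expect_equal(g0$region_degree_stats$mean, rep(0, 3))
  # hand-set frontal degrees {4,5,6,7,8,6,6} -> mean 6
  gm <- g
  gm$degrees[region_channels(lay, "frontal")] <- c(4L, 5L, 6L, 7L, 8L, 6L, 6L)
  expect_equal(region_degree_stats(gm, lay)$mean[1], 6)
})

test_that("paired region test matches the closed-form t statistic", {
  b <- c(s1 = 5, s2 = 6, s3 = 4, s4 = 7, s5 = 5)
  a <- b + c(2, -1, 3, 0, 1)
  cmp <- paired_region_test(a, b)
  d <- c(2, -1, 3, 0, 1)
  t_manual <- mean(d) / (stats::sd(d) / sqrt(5))
  expect_equal(cmp$t_statistic, t_manual, tolerance = 1e-12)
  expect_equal(cmp$paired_n, 5L)
  expect_equal(cmp$p_value,
               2 * stats::pt(-abs(t_manual), df = 4), tolerance = 1e-12)
})

test_that("paired test edge cases follow the documented conventions", {
  a <- c(s1 = 5, s2 = 6, s3 = 4)
  cmp0 <- paired_region_test(a, a)
  expect_equal(cmp0$t_statistic, 0)
  expect_equal(cmp0$p_value, 1)
  # zero-variance nonzero differences
  cmp_inf <- paired_region_test(a + 1, a)
  expect_equal(cmp_inf$t_statistic, Inf)
  expect_equal(cmp_inf$p_value, 0)
  # unpaired subjects dropped with warning; < 2 pairs rejected
  expect_warning(paired_region_test(c(s1 = 1, s2 = 2, s9 = 3),
                                    c(s1 = 2, s2 = 1, s8 = 3)), "unpaired")
  expect_error(suppressWarnings(
    paired_region_test(c(s1 = 1, s9 = 3), c(s1 = 2, s8 = 3))), "at least 2")
})
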