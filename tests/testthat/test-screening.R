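lay19 <- channel_layout()

# small analytic window set with a known locked window
locked_window_set <- function() {
  fs <- 250
  n <- 50
  nch <- 19
  set.seed(9)
  mk_window <- function(locked) {
    phi <- t(apply(matrix(rnorm(nch * n, 1, 0.4), nch), 1, cumsum))
    if (locked) {
      iFz <- match("Fz", lay19$labels)
      phi[match("Cz", lay19$labels), ] <- phi[iFz, ] - pi / 2
      phi[match("Pz", lay19$labels), ] <- phi[iFz, ] - pi / 3
    }
    exp(1i * phi)
  }
  wins <- list(mk_window(TRUE), mk_window(FALSE), mk_window(FALSE))
  ws <- structure(list(windows = wins, window_s = n / fs,
                       source_indices = c(1L, 51L, 101L),
                       fs = fs, layout = lay19),
                  class = "eeg_windows")
  attr(ws, "analytic") <- TRUE
  ws
}

test_that("window scores are the mean core-pair PLV", {
  ws <- locked_window_set()
  sc <- score_windows(ws)
  expect_length(sc, 3)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_equal(sc[1], 1, tolerance = 1e-9)  # both core pairs locked
  expect_gt(sc[1], max(sc[2:3]))
  # mean combination: one pair locked, other scrambled -> about half
  sc_min <- score_windows(ws, combine = "min")
  sc_max <- score_windows(ws, combine = "max")
  expect_true(all(sc_min <= sc & sc <= sc_max))
  expect_error(score_windows(ws, core_pairs = list()), "empty")
  expect_error(score_windows(ws, core_pairs = list(c("Fz", "XX"))), "XX")
})

test_that("quantile and absolute selection rules behave as specified", {
  sr <- select_windows(c(0.9, 0.5, 0.1), q = 1 / 3)
  expect_identical(sr$selected, c(TRUE, FALSE, FALSE))

  sr2 <- select_windows(c(0.2, 0.4, 0.6, 0.8), q = 0.5)
  expect_identical(sr2$selected, c(FALSE, FALSE, TRUE, TRUE))

  sr3 <- select_windows(c(0.3, 0.6, 0.9), rule = "absolute", tau = 0)
  expect_true(all(sr3$selected))

  # at least the best window is always kept
  sr4 <- select_windows(c(0.1, 0.5, 0.2), rule = "absolute", tau = 0.99)
  expect_identical(sr4$selected, c(FALSE, TRUE, FALSE))

  expect_error(select_windows(c(0.5, 0.6), q = 0), "q > 0")
  expect_error(select_windows(rep(NaN, 3)), "no finite")
  # selected windows' mean score >= unselected windows' mean score
  set.seed(1)
  sc <- runif(50)
  sr5 <- select_windows(sc, q = 0.4)
  expect_gte(mean(sc[sr5$selected]), mean(sc[!sr5$selected]))
})

test_that("recombine keeps selected windows with their provenance", {
  ws <- locked_window_set()
  sr <- select_windows(c(0.9, 0.2, 0.8), rule = "absolute", tau = 0.5)
  out <- recombine(ws, sr)
  expect_length(out$windows, 2)
  expect_equal(out$source_indices, c(1L, 101L))
  # all-true mask reproduces the set
  sr_all <- select_windows(c(0.9, 0.2, 0.8), rule = "absolute", tau = 0)
  expect_equal(recombine(ws, sr_all)$windows, ws$windows)
  sr_bad <- sr; sr_bad$selected <- c(TRUE, FALSE)
  expect_error(recombine(ws, sr_bad), "mask length")
})

test_that("screening is idempotent under the absolute rule", {
  ws <- locked_window_set()
  sc <- score_windows(ws)
  sr <- select_windows(sc, rule = "absolute", tau = 0.6)
  kept <- recombine(ws, sr)
  sc2 <- score_windows(kept)
  sr2 <- select_windows(sc2, rule = "absolute", tau = 0.6)
  expect_true(all(sr2$selected))
})

test_that("post-screening core-pair synchrony exceeds pre-screening", {
  sim <- planted_screening_sim(seed = 5)
  a <- analytic_signal(gamma_band(sim$recording))
  ws <- segment(a, 0.2)
  sc <- score_windows(ws)
  sr <- select_windows(sc, q = 0.2)
  kept <- recombine(ws, sr)
  expect_gt(mean(score_windows(kept)), mean(sc))
})

test_that("recovery report handles the degenerate labelings", {
  ws <- locked_window_set()
  gt <- structure(list(events = list(
    coupling_event(0, 0.2, list(c("Fz", "Cz")), pi / 2, 1))),
    class = "eeg_ground_truth")
  # perfect selection of exactly the event window
  sr <- select_windows(c(1, 0.1, 0.1), rule = "absolute", tau = 0.5,
                       core_pairs = core_pairs())
  rep1 <- screening_recovery_report(sr, gt, ws)
  expect_equal(rep1$sensitivity, 1)
  expect_equal(rep1$specificity, 1)
  # selecting everything: sensitivity 1, specificity 0
  sr_all <- select_windows(c(1, 0.9, 0.9), rule = "absolute", tau = 0)
  rep2 <- screening_recovery_report(sr_all, gt, ws)
  expect_equal(rep2$sensitivity, 1)
  expect_equal(rep2$specificity, 0)
  # no events on core pairs -> sensitivity undefined
  gt0 <- structure(list(events = list(
    coupling_event(0, 0.2, list(c("O1", "O2")), pi / 2, 1))),
    class = "eeg_ground_truth")
  rep3 <- screening_recovery_report(sr, gt0, ws)
  expect_true(is.na(rep3$sensitivity))
})

test_that("planted events are recovered with high sensitivity", {
  sim <- planted_screening_sim(seed = 1)
  a <- analytic_signal(gamma_band(sim$recording))
  ws <- segment(a, 0.2)
  sr <- select_windows(score_windows(ws), q = 0.2)
  rep <- screening_recovery_report(sr, sim$ground_truth, ws)
  expect_gte(rep$sensitivity, 0.8)
  expect_gte(rep$specificity, 0.9)
})
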