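wrapi <- eegfbn:::wrap_pi

test_that("analytic signal of a cosine is the unit phasor", {
  fs <- 1000
  t <- seq_len(1000) / fs
  a <- analytic_signal(cos(2 * pi * 40 * t), fs = fs)
  i <- 101:900
  expect_lt(sqrt(mean((a$amplitude[1, i] - 1)^2)), 0.01)
  perr <- wrapi(a$phase[1, i] - wrapi(2 * pi * 40 * t[i]))
  expect_lt(sqrt(mean(perr^2)), 0.01)
  # phase advances 2*pi*40/fs per interior sample
  expect_equal(median(diff(a$phase[1, i]) %% (2 * pi)), 2 * pi * 40 / fs,
               tolerance = 1e-6)
})

test_that("analytic signal of a sine is the cosine's shifted by -pi/2", {
  fs <- 1000
  t <- seq_len(1000) / fs
  a_sin <- analytic_signal(sin(2 * pi * 40 * t), fs = fs)
  a_cos <- analytic_signal(cos(2 * pi * 40 * t), fs = fs)
  i <- 101:900
  expect_lt(sqrt(mean((a_sin$amplitude[1, i] - 1)^2)), 0.01)
  d <- wrapi(a_sin$phase[1, i] - a_cos$phase[1, i] + pi / 2)
  expect_lt(sqrt(mean(d^2)), 0.01)
})

test_that("constant channels are flagged degenerate and rejected by metrics", {
  x <- rbind(rep(3, 100), sin(2 * pi * 10 * (1:100) / 100))
  a <- analytic_signal(x, fs = 100)
  expect_true(a$degenerate[1])
  expect_false(a$degenerate[2])
  expect_error(phase_difference(a, c(1, 2)), "degenerate")
  expect_error(wpli(a, c(1, 2)), "degenerate")
  expect_warning(m <- pairwise_matrix(a, "PLV"), "degenerate")
  expect_true(is.na(m$values[1, 2]))
})

test_that("phase difference wraps into (-pi, pi] and resolves labels", {
  z <- rbind(exp(1i * rep(0.3, 10)), exp(1i * rep(0.3 - pi / 2, 10)))
  a <- analytic_from_complex(z, fs = 10)
  th <- phase_difference(a, c(1, 2))
  expect_equal(th$theta, rep(pi / 2, 10))
  # same channel twice: identically zero
  expect_equal(phase_difference(a, c(1, 1))$theta, rep(0, 10))
  # wrap: 3*pi/2 becomes -pi/2
  z2 <- rbind(exp(1i * rep(3 * pi / 4, 5)), exp(1i * rep(-3 * pi / 4, 5)))
  a2 <- analytic_from_complex(z2, fs = 10)
  expect_equal(phase_difference(a2, c(1, 2))$theta, rep(-pi / 2, 5))
  expect_error(phase_difference(a, c(1, 7)), "out of range")
})

test_that("PLV matches its defining cases", {
  expect_equal(plv(rep(0.7, 50))$value, 1)           # complete locking
  expect_equal(plv(rep(c(0, pi), 10))$value, 0, tolerance = 1e-12)
  expect_equal(plv(c(0, pi / 2, pi, 3 * pi / 2))$value, 0, tolerance = 1e-12)
})

test_that("PLI matches its defining cases", {
  expect_equal(pli(rep(pi / 2, 9))$value, 1)
  expect_equal(pli(rep(c(pi / 4, -pi / 4), 8))$value, 0)
  expect_equal(pli(c(pi / 4, pi / 4, -pi / 4))$value, 1 / 3)
  expect_equal(pli(c(pi / 4, pi / 4, -pi / 4))$signed, 1 / 3)
})

test_that("wPLI matches its defining cases", {
  n <- 16
  # constant pi/2 lag, equal amplitudes -> 1
  z <- rbind(exp(1i * (1:n) * 0.3), exp(1i * ((1:n) * 0.3 - pi / 2)))
  expect_equal(wpli(analytic_from_complex(z, 10), c(1, 2))$value, 1)
  # identical channels (pure zero lag) -> 0 by the 0/0 convention
  z2 <- rbind(z[1, ], z[1, ])
  expect_equal(wpli(analytic_from_complex(z2, 10), c(1, 2))$value, 0)
  # Im(X) samples {+2, +1, -1} -> (2 + 1 - 1) / (2 + 1 + 1) = 0.5
  z3 <- rbind(complex(real = rep(1, 3)), 1 - 1i * c(2, 1, -1))
  expect_equal(wpli(analytic_from_complex(z3, 10), c(1, 2))$value, 0.5)
})

test_that("metrics equal brute-force evaluation on short windows", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(2:16, 1)
    theta <- runif(n, -pi, pi)
    expect_equal(plv(theta)$value, brute_plv(theta), tolerance = 1e-12)
    expect_equal(pli(theta)$value, brute_pli(theta), tolerance = 1e-12)
    z1 <- complex(real = rnorm(n), imaginary = rnorm(n))
    z2 <- complex(real = rnorm(n), imaginary = rnorm(n))
    a <- analytic_from_complex(rbind(z1, z2), 10)
    expect_equal(wpli(a, c(1, 2))$value, brute_wpli(z1, z2),
                 tolerance = 1e-12)
    m <- pairwise_matrix(a, "wPLI")
    expect_equal(m$values[1, 2], brute_wpli(z1, z2), tolerance = 1e-12)
  }
})

test_that("pairwise matrices are symmetric with per-metric diagonals", {
  set.seed(3)
  z <- matrix(complex(real = rnorm(3 * 64), imaginary = rnorm(3 * 64)), 3)
  a <- analytic_from_complex(z, 10)
  for (metric in c("PLV", "PLI", "wPLI")) {
    m <- pairwise_matrix(a, metric)
    expect_equal(m$values, t(m$values))
    expect_equal(unname(diag(m$values)),
                 rep(if (metric == "PLV") 1 else 0, 3))
    expect_equal(sum(upper.tri(m$values)), 3)   # C(3,2) pair values
    off <- m$values[upper.tri(m$values)]
    expect_true(all(off >= 0 & off <= 1))
  }
})

test_that("19 channels give 171 distinct pair values", {
  sim <- generate_recording(channel_layout(), 1, 250, list(), seed = 1)
  a <- analytic_signal(sim$recording)
  m <- pairwise_matrix(a, "wPLI")
  expect_equal(sum(upper.tri(m$values)), 171)
})

test_that("metrics are invariant to a global phase rotation", {
  set.seed(4)
  n <- 256
  phi <- rbind(cumsum(rnorm(n, 0.8, 0.1)), cumsum(rnorm(n, 0.8, 0.1)))
  amp <- matrix(1 + 0.3 * abs(rnorm(2 * n)), 2)
  z <- amp * exp(1i * phi)
  zr <- z * exp(1i * 1.234)   # same constant added to every channel's phase
  a <- analytic_from_complex(z, 10); ar <- analytic_from_complex(zr, 10)
  expect_equal(plv(phase_difference(a, c(1, 2)))$value,
               plv(phase_difference(ar, c(1, 2)))$value, tolerance = 1e-12)
  expect_equal(pli(phase_difference(a, c(1, 2)))$value,
               pli(phase_difference(ar, c(1, 2)))$value, tolerance = 1e-12)
  expect_equal(wpli(a, c(1, 2))$value, wpli(ar, c(1, 2))$value,
               tolerance = 1e-12)
})

test_that("PLV ignores amplitude rescaling but wPLI weights by amplitude", {
  set.seed(5)
  n <- 512
  phi1 <- cumsum(rnorm(n, 0.8, 0.15))
  phi2 <- phi1 - 0.6 + 0.8 * rnorm(n)
  amp <- 1 + 0.8 * abs(rnorm(n))
  z <- rbind(exp(1i * phi1), amp * exp(1i * phi2))
  zs <- rbind(exp(1i * phi1), 5 * amp * exp(1i * phi2))   # uniform rescale
  a <- analytic_from_complex(z, 10); as_ <- analytic_from_complex(zs, 10)
  expect_equal(plv(phase_difference(a, c(1, 2)))$value,
               plv(phase_difference(as_, c(1, 2)))$value, tolerance = 1e-12)
  # uniform rescale cancels in wPLI too...
  expect_equal(wpli(a, c(1, 2))$value, wpli(as_, c(1, 2))$value,
               tolerance = 1e-12)
  # ...but reweighting individual samples changes wPLI, not PLV
  w <- rep(1, n); w[seq(1, n, by = 3)] <- 4
  zw <- rbind(z[1, ], w * z[2, ])
  aw <- analytic_from_complex(zw, 10)
  expect_equal(plv(phase_difference(a, c(1, 2)))$value,
               plv(phase_difference(aw, c(1, 2)))$value, tolerance = 1e-12)
  expect_gt(abs(wpli(aw, c(1, 2))$value - wpli(a, c(1, 2))$value), 1e-4)
})
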