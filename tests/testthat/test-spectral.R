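fake_traj <- function(times, values) {
  structure(list(times = times, states = cbind(x = values),
                 var_names = "x"), class = "ssa_trajectory")
}

test_that("zero-order hold carries the last event value forward", {
  traj <- fake_traj(c(0, 1.5), c(5, 6))
  ser <- resample_zoh(traj, 1, n_points = 4, t_max = 4)  # grid 0,1,2,3
  expect_equal(ser$values, c(5, 5, 6, 6))
  expect_equal(ser$dt, 1)
  # right-continuity exactly at an event time
  ser2 <- resample_zoh(traj, 1, n_points = 4, t_max = 6)  # grid 0,1.5,3,4.5
  expect_equal(ser2$values, c(5, 6, 6, 6))
  # a constant trajectory resamples to a constant series
  expect_equal(resample_zoh(fake_traj(0, 7), 1, 8, t_max = 2)$values,
               rep(7, 8))
  expect_error(resample_zoh(fake_traj(c(0, 1), c(1, 2)), 1, n_points = 12),
               "power of two")
})

test_that("an on-bin sinusoid concentrates all spectral power in its bin", {
  N <- 1024; dt <- 0.5; k <- 37
  t <- (0:(N - 1)) * dt
  ser <- structure(list(values = sin(2 * pi * k * t / (N * dt)), dt = dt,
                        t0 = 0), class = "uniform_series")
  ps <- power_spectrum(ser)
  expect_equal(length(ps$psd), 512L)
  expect_equal(ps$frequencies[1], 1 / (N * dt))
  expect_equal(which.max(ps$psd), k)
  expect_lt(max(ps$psd[-k]) / ps$psd[k], 1e-10)
})

test_that("the one-sided spectrum preserves signal power (Parseval)", {
  set.seed(11)
  x <- rnorm(1024)
  ser <- structure(list(values = x, dt = 0.25, t0 = 0),
                   class = "uniform_series")
  ps <- power_spectrum(ser)
  # |X_i|^2 = psd_i * 2 df; double-count all bins except Nyquist
  mod2 <- ps$psd * 2 * ps$df
  lhs <- (2 * sum(mod2[1:511]) + mod2[512]) / 1024
  rhs <- sum((x - mean(x))^2)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("white noise has a flat expected spectrum", {
  set.seed(21)
  acc <- 0
  for (r in 1:200) {
    x <- rnorm(256)
    ser <- structure(list(values = x, dt = 1, t0 = 0),
                     class = "uniform_series")
    acc <- acc + power_spectrum(ser)$psd
  }
  acc <- acc / 200
  expect_lt(max(abs(acc / mean(acc) - 1)), 0.35)  # Monte-Carlo flatness
})

test_that("normalization yields a unit-mass spectrum and is scale free", {
  mk <- function(psd) structure(list(frequencies = seq_along(psd),
                                     psd = psd, df = 1,
                                     normalized = FALSE),
                                class = "power_spectrum")
  expect_equal(normalize_psd(mk(c(4, 0, 0)))$psd, c(1, 0, 0))
  expect_equal(normalize_psd(mk(rep(1, 512)))$psd, rep(1 / 512, 512))
  expect_equal(normalize_psd(mk(c(2, 6)))$psd,
               normalize_psd(mk(c(4, 12)))$psd)
  expect_error(normalize_psd(mk(numeric(8))), "degenerate")
  s <- normalize_psd(mk(runif(16)))
  expect_true(s$normalized)
  expect_equal(sum(s$psd), 1, tolerance = 1e-12)
})

test_that("spectral entropy closed forms and bounds hold", {
  expect_equal(spectral_entropy(rep(1 / 512, 512)), 1)
  expect_equal(spectral_entropy(c(1, numeric(511))), 0)
  expect_equal(spectral_entropy(c(0.5, 0.5, numeric(510))), 1 / 9)
  expect_equal(round(1 / log2(512), 1), 0.1)  # the paper-scale constant k
  set.seed(31)
  for (r in 1:50) {
    p <- runif(512); p <- p / sum(p)
    S <- spectral_entropy(p)
    expect_gte(S, 0); expect_lte(S, 1)
    # mixing toward uniform never decreases entropy
    expect_gte(spectral_entropy((p + 1 / 512) / 2), S - 1e-12)
  }
  expect_error(spectral_entropy(c(0.5, 0.4)), "sum to 1")
})

test_that("a noisy tone is more ordered than pure white noise", {
  set.seed(41)
  t <- (0:1023) * 0.36
  tone <- sin(t) + rnorm(1024, sd = 0.2)
  noise <- rnorm(1024)
  S_of <- function(x) {
    ser <- structure(list(values = x, dt = 0.36, t0 = 0),
                     class = "uniform_series")
    spectral_entropy(normalize_psd(power_spectrum(ser)))
  }
  expect_lt(S_of(tone), S_of(noise))
})

test_that("state histograms weight values by holding time", {
  h1 <- state_histogram(fake_traj(0, 3), n_bins = 5, n_points = 64)
  expect_equal(sum(h1$counts), 64)
  expect_equal(sum(h1$counts > 0), 1L)
  # two states held equally long split the mass evenly
  traj <- fake_traj(c(0, 5), c(0, 10))
  h2 <- state_histogram(traj, n_bins = 2, n_points = 64, t_max = 10)
  expect_equal(h2$counts, c(32, 32))
  expect_error(state_histogram(traj, n_bins = 0), "at least 1")
})
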