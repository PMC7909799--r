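test_that("Baillie-Pilcher indexing matches hand arithmetic", {
  expect_equal(baillie_pilcher_index(rep(2, 6))$values, rep(100, 6))
  # spike year: 100 * 2 / ((1+1+2+1+1)/5)
  idx <- baillie_pilcher_index(c(1, 1, 1, 2, 1, 1, 1))
  expect_equal(idx$values[4], 100 * 2 / (6 / 5), tolerance = 1e-12)
  # scale invariance
  w <- c(0.4, 0.9, 1.1, 0.7, 1.3, 0.8, 1.0)
  expect_equal(baillie_pilcher_index(w)$values,
               baillie_pilcher_index(10 * w)$values, tolerance = 1e-12)
})

test_that("spline detrending is neutral on constants and linear ramps but keeps fast oscillations", {
  expect_equal(spline_detrend(rep(2, 40))$values, rep(1, 40),
               tolerance = 1e-6)
  ramp <- seq(1, 3, length.out = 60)
  expect_lt(abs(mean(spline_detrend(ramp)$values) - 1), 0.01)
  # +-20% oscillation of period 8 under a stiffness of 40 years survives
  osc <- 1 + 0.2 * sin(2 * pi * (1:60) / 8)
  idx <- spline_detrend(osc, stiffness = 40)$values
  expect_gte(max(idx) - 1, 0.15)
  expect_gte(1 - min(idx), 0.15)
})

test_that("detrending operators are scale invariant", {
  set.seed(3)
  w <- runif(50, 0.5, 2)
  for (c_ in c(0.1, 7)) {
    expect_equal(spline_detrend(w)$values, spline_detrend(c_ * w)$values,
                 tolerance = 1e-9)
    expect_equal(double_detrend(w)$values, double_detrend(c_ * w)$values,
                 tolerance = 1e-6)
  }
})

test_that("double detrending flattens a pure negative exponential", {
  tt <- 1:80
  w <- 1.4 * exp(-0.04 * tt) + 0.5
  curve <- seasonwood:::neg_exp_curve(w)
  expect_lt(max(abs(w / curve - 1)), 0.02)
  expect_equal(double_detrend(rep(1.3, 40))$values, rep(1, 40),
               tolerance = 1e-6)
})

test_that("double-detrended indices average close to one on random growth series", {
  set.seed(11)
  for (k in 1:8) {
    n <- sample(30:80, 1)
    w <- (runif(1, 0.5, 2) * exp(-runif(1, 0.01, 0.08) * (1:n)) +
            runif(1, 0.2, 0.8)) * exp(rnorm(n, 0, 0.15))
    expect_lt(abs(mean(double_detrend(w)$values) - 1), 0.05)
  }
})

test_that("leave-one-out screening keeps coherent series and drops noise", {
  set.seed(5)
  n <- 80
  common <- rnorm(n)
  trees <- lapply(1:5, function(i) {
    w <- if (i <= 4) exp(0.25 * sqrt(0.7) * common +
                           0.25 * sqrt(0.3) * rnorm(n))
         else exp(0.25 * rnorm(n))   # independent noise series
    season_series(paste0("t", i), 1901, w * 0.7, w * 0.3)
  })
  scr <- leave_one_out_screen(site_collection("s", trees))
  expect_equal(scr$rejected, "t5")
  expect_lt(scr$r[["t5"]], 0.4)
  expect_equal(sort(names(scr$retained$trees)), paste0("t", 1:4))
  # vacuous threshold rejects nothing
  scr0 <- leave_one_out_screen(site_collection("s", trees), r_min = 0)
  expect_length(scr0$rejected, 0L)
})

test_that("identical series all survive screening with r = 1", {
  w <- exp(rnorm(40, 0, 0.2))
  trees <- lapply(1:5, function(i)
    season_series(paste0("t", i), 1901, w * 0.7, w * 0.3))
  scr <- leave_one_out_screen(site_collection("s", trees))
  expect_length(scr$rejected, 0L)
  expect_equal(unname(scr$r), rep(1, 5), tolerance = 1e-12)
})

test_that("site chronology averages and is stable to dropping one series", {
  i1 <- index_series(1901, rep(0.8, 30))
  i2 <- index_series(1901, rep(1.2, 30))
  expect_equal(site_chronology(list(i1, i2))$values, rep(1, 30))
  expect_equal(site_chronology(list(i1))$values, i1$values)
  set.seed(2)
  idx <- lapply(1:8, function(i) index_series(1901, 1 + rnorm(30, 0, 0.1)))
  full <- site_chronology(idx)$values
  dropped <- site_chronology(idx[-3])$values
  m <- index_matrix(idx)
  bound <- max(abs(m[, 3] - full)) / (8 - 1) + 1e-12
  expect_lte(max(abs(dropped - full)), bound)
})

test_that("EPS and SNR follow the population-signal closed form", {
  # identical series: perfect signal
  w <- exp(rnorm(40, 0, 0.2))
  idx <- lapply(1:6, function(i) index_series(1901, w))
  st <- eps_snr(idx)
  expect_equal(st$eps, 1)
  expect_equal(st$snr, Inf)
  # closed form: n = 20, rbar = 0.5
  expect_equal(20 * 0.5 / (20 * 0.5 + 0.5), 10 / 10.5, tolerance = 1e-12)
  # generated series: eps must equal the formula applied to measured rbar
  set.seed(8)
  common <- rnorm(50)
  idx2 <- lapply(1:7, function(i)
    index_series(1901, 1 + 0.1 * common + 0.1 * rnorm(50)))
  st2 <- eps_snr(idx2)
  expect_equal(st2$eps,
               7 * st2$rbar / (7 * st2$rbar + 1 - st2$rbar), tolerance = 1e-12)
  expect_equal(st2$snr, 7 * st2$rbar / (1 - st2$rbar), tolerance = 1e-12)
  # eps strictly increasing in n at fixed rbar
  eps_of <- function(n, r) n * r / (n * r + 1 - r)
  expect_true(all(diff(eps_of(2:30, 0.3)) > 0))
})

test_that("EPS closed form matches synthetic series with known signal share", {
  set.seed(21)
  n_series <- 12; n_years <- 500
  share <- 0.4   # common-signal share of variance
  common <- rnorm(n_years)
  idx <- lapply(seq_len(n_series), function(i)
    index_series(1901, sqrt(share) * common + sqrt(1 - share) * rnorm(n_years)))
  st <- eps_snr(idx)
  expect_equal(st$rbar, share, tolerance = 0.05)
  expect_equal(st$eps, n_series * share / (n_series * share + 1 - share),
               tolerance = 0.02)
})

test_that("the reliable span tracks where the common signal lives", {
  w <- exp(rnorm(60, 0, 0.2))
  idx <- lapply(1:6, function(i) index_series(1901, w))
  expect_equal(reliable_span(idx), c(1901, 1960))
  expect_equal(reliable_span(idx, eps_min = 0), c(1901, 1960))
  # common signal only after 1930; pure noise before
  set.seed(13)
  common <- c(rep(0, 30), rnorm(30))
  idx2 <- lapply(1:10, function(i) {
    v <- ifelse(seq_len(60) <= 30, rnorm(60, 0, 0.35),
                0.3 * common + 0.12 * rnorm(60))
    index_series(1901, 1 + v)
  })
  rs <- reliable_span(idx2)
  expect_gte(rs[1], 1921)  # within one window step of the 1931 signal onset
  expect_lte(rs[1], 1941)
  expect_equal(rs[2], 1960)
})
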