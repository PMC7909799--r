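# shared generator: a chronology driven by known monthly couplings and an
# optional defoliation effect, built directly from the linear model
make_model_data <- function(seed, b, n_years = 80, noise_sd = 0.08) {
  climate <- simulate_climate(n_years + 1, 1930, seed = seed)
  years <- seq(1931, length.out = n_years)
  X <- seasonwood:::climate_design(climate, years)
  events <- seq(1938, max(years) - 5, by = 12)
  O <- defoliation_dummy(events, years)
  set.seed(seed * 13 + 1)
  I <- 1 - 0.019 * X[, "TJUL"] + 0.0017 * X[, "PMAY"] + b * O +
    rnorm(n_years, 0, noise_sd)
  list(chron = index_series(1931, as.numeric(I), "double_detrend"),
       climate = climate, events = events, X = X, O = O)
}

test_that("the defoliation dummy marks the post-event suppression years", {
  expect_equal(defoliation_dummy(c(1950), 1948:1954),
               c(0L, 0L, 0L, 1L, 1L, 0L, 0L))
  expect_equal(defoliation_dummy(c(1950), 1948:1954, effect_lags = 1:3),
               c(0L, 0L, 0L, 1L, 1L, 1L, 0L))
  expect_length(defoliation_dummy(integer(), 1948:1954), 7L)
})

test_that("response screening flags the true monthly driver and little else", {
  g <- make_model_data(3, b = 0)
  # chronology driven by May precipitation only, 30% effect share
  set.seed(33)
  eff <- 0.002 * g$X[, "PMAY"]
  I <- 1 + eff + rnorm(80, 0, sd(eff) * sqrt(7 / 3))
  scr <- response_screen(index_series(1931, as.numeric(I)), g$climate,
                         n_boot = 500, seed = 5)
  expect_true(scr$significant[scr$variable == "PMAY"])
  expect_gte(mean(!scr$significant[scr$variable != "PMAY"]), 0.9)
  expect_equal(nrow(scr), 42L)   # 21 months x T and P
})

test_that("pure-noise chronologies show no systematic response excess", {
  rates <- vapply(1:5, function(s) {
    g <- make_model_data(s + 40, b = 0)
    set.seed(s)
    I <- 1 + rnorm(80, 0, 0.1)
    scr <- response_screen(index_series(1931, as.numeric(I)), g$climate,
                           n_boot = 300, seed = s)
    mean(scr$significant)
  }, numeric(1))
  expect_lte(mean(rates), 0.10)
})

test_that("model fits recover coefficients and collapse when the dummy is empty", {
  g <- make_model_data(7, b = -0.19)
  m <- fit_models(g$chron, g$climate, c("TJUL", "PMAY"), g$events)
  expect_true("O" %in% names(m$weather_outbreak$coefficients))
  expect_false("O" %in% names(m$weather$coefficients))
  ci <- confint(m$weather_outbreak$fit)["O", ]
  expect_lt(ci[1], -0.19 + 0.25)
  expect_gt(m$weather_outbreak$r2adj, m$weather$r2adj)
  # closed-form least-squares oracle on the same design
  d <- m$data
  beta <- solve(crossprod(cbind(1, as.matrix(d[, c("TJUL", "PMAY", "O")]))),
                crossprod(cbind(1, as.matrix(d[, c("TJUL", "PMAY", "O")])),
                          d$I))
  full <- lm(I ~ TJUL + PMAY + O, data = d)
  expect_equal(unname(coef(full)), as.numeric(beta), tolerance = 1e-8)
  # all-zero dummy: the two fits coincide
  m0 <- fit_models(g$chron, g$climate, c("TJUL", "PMAY"),
                   rep(0L, length(series_years(g$chron))))
  expect_equal(sort(names(m0$weather$coefficients)),
               sort(setdiff(names(m0$weather_outbreak$coefficients), "O")))
  expect_equal(m0$weather$r2adj, m0$weather_outbreak$r2adj, tolerance = 0.02)
})

test_that("backward selection removes an irrelevant noise predictor", {
  drops <- vapply(1:10, function(s) {
    g <- make_model_data(s + 60, b = 0)
    m <- fit_models(g$chron, g$climate, c("TJUL", "PMAY", "Tfeb"), g$events)
    !"Tfeb" %in% names(m$weather$coefficients)
  }, logical(1))
  expect_gte(mean(drops), 0.8)
})

test_that("the bootstrap model comparison is powerful with a real effect and calibrated without", {
  g <- make_model_data(11, b = -0.19)
  m <- fit_models(g$chron, g$climate, c("TJUL", "PMAY"), g$events)
  cmp <- bootstrap_r2_compare(m, n_boot = 100, seed = 2)
  expect_lt(cmp$p, 0.001)
  expect_gt(mean(cmp$r2_outbreak), mean(cmp$r2_weather))
  expect_error(bootstrap_r2_compare(m, n_boot = 1), "at least 2")
  # same seed reproduces
  cmp2 <- bootstrap_r2_compare(m, n_boot = 100, seed = 2)
  expect_identical(cmp$r2_outbreak, cmp2$r2_outbreak)
  # null rejection rate over a handful of seeds stays small
  rej <- vapply(1:10, function(s) {
    g0 <- make_model_data(s + 80, b = 0)
    m0 <- fit_models(g0$chron, g0$climate, c("TJUL", "PMAY"), g0$events)
    bootstrap_r2_compare(m0, n_boot = 60, seed = s)$p < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.3)
})

test_that("superposed epoch analysis flags injected post-event suppression", {
  set.seed(5)
  v <- rnorm(100, 1, 0.08)
  yrs <- 1915:2014
  events <- c(1925, 1941, 1957, 1973, 1990)
  for (e in events) for (l in 1:2)
    v[match(e + l, yrs)] <- v[match(e + l, yrs)] - 0.3
  r <- sea(index_series(1915, v), events, seed = 7)
  expect_equal(r$lag[r$significant], c(1L, 2L))
  expect_lt(r$departure[r$lag == 1], r$upper[r$lag == 1])
  expect_error(sea(index_series(1915, v), integer()), "3 usable")
  expect_error(sea(index_series(1915, v), c(1925, 1941)), "3 usable")
})

test_that("superposed epoch analysis keeps its false-flag rate near the nominal level", {
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    v <- rnorm(100, 1, 0.08)
    events <- sort(sample(1925:2004, 5))
    r <- sea(index_series(1915, v), events, seed = s + 1, n_draws = 400)
    sum(r$significant)
  }, numeric(1))
  expect_lte(mean(hits), 0.05 * 9 + 0.15)
})
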