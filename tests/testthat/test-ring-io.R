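test_that("Tucson decadal blocks decode to dated millimetre series", {
  f <- withr::local_tempfile(fileext = ".rwl")
  writeLines("TST01 1990 100 200 300 999", f)
  s <- read_rwl(f)
  expect_length(s, 1L)
  expect_equal(s[[1]]$first_year, 1990L)
  expect_equal(s[[1]]$total, c(1.00, 2.00, 3.00))
  expect_equal(series_years(s[[1]]), 1990:1992)
})

test_that("the -9999 stop marker switches units to 0.001 mm", {
  f <- withr::local_tempfile(fileext = ".rwl")
  writeLines("TST01 1990 1000 2000 3000 -9999", f)
  s <- read_rwl(f)
  expect_equal(s[[1]]$total, c(1.000, 2.000, 3.000))
})

test_that("rwl write/read round trip preserves years, values and flags", {
  set.seed(1)
  n <- 37
  w <- round(runif(n, 0.2, 3), 2)
  miss <- rep(FALSE, n); miss[10] <- TRUE; w[10] <- 0
  orig <- season_series("AB123", 1947, w * 0.7, w * 0.3, missing = miss)
  for (units in c("0.01", "0.001")) {
    f <- withr::local_tempfile(fileext = ".rwl")
    write_rwl(orig, f, kind = "total", units = units)
    back <- read_rwl(f)[[1]]
    expect_equal(series_years(back), series_years(orig))
    expect_equal(back$total, orig$total, tolerance = 1e-8)
    expect_equal(back$missing, orig$missing)
  }
})

test_that("malformed and duplicate rwl input is rejected with line context", {
  f <- withr::local_tempfile(fileext = ".rwl")
  writeLines(c("TST01 1990 100 999", "TST01 1990 100 999"), f)
  expect_error(read_rwl(f), "duplicate series id")
  writeLines("TST01 abcd 100", f)
  expect_error(read_rwl(f), "line 1")
})

test_that("seasonal CSV assembles per-core series with total = EW + LW", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(tree = "t1", core = "t1a", year = 2000:2002,
                   earlywood = 1, latewood = 0.5)
  write.csv(df, f, row.names = FALSE)
  s <- read_seasonal_csv(f)
  expect_length(s, 1L)
  expect_equal(s[[1]]$total, rep(1.5, 3))
  # duplicate (core, year)
  write.csv(df[c(1, 1, 2), ], f, row.names = FALSE)
  expect_error(read_seasonal_csv(f), "duplicate")
  # non-consecutive years
  df2 <- df; df2$year <- c(2000, 2002, 2003)
  write.csv(df2, f, row.names = FALSE)
  expect_error(read_seasonal_csv(f), "consecutive")
  # negative width
  df3 <- df; df3$earlywood[2] <- -1
  write.csv(df3, f, row.names = FALSE)
  expect_error(read_seasonal_csv(f), "negative")
  # empty table
  write.csv(df[0, ], f, row.names = FALSE)
  expect_warning(out <- read_seasonal_csv(f), "empty")
  expect_length(out, 0L)
})

test_that("seasonal CSV round trip preserves the series", {
  sim <- suppressWarnings(simulate_site(synth_config(n_trees = 5L,
                                                     n_years = 30L, seed = 4)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_seasonal_csv(sim$collection$trees, f)
  back <- read_seasonal_csv(f)
  expect_length(back, 5L)
  orig <- sim$collection$trees[[1]]
  got <- back[[which(vapply(back, `[[`, "", "tree_id") == orig$tree_id)]]
  expect_equal(got$earlywood, orig$earlywood, tolerance = 1e-12)
  expect_equal(got$latewood, orig$latewood, tolerance = 1e-12)
})

test_that("core averaging is idempotent, takes means, and handles offsets", {
  a <- season_series("t", 1990, rep(2, 10) * 0.7, rep(2, 10) * 0.3,
                     core_ids = "a")
  expect_equal(average_cores_per_tree(list(a, a))$total, a$total)
  b <- season_series("t", 1990, rep(4, 10) * 0.7, rep(4, 10) * 0.3,
                     core_ids = "b")
  expect_equal(average_cores_per_tree(list(a, b))$total, rep(3, 10))
  # offset spans 1990-1999 and 1995-2004: mean on the overlap only
  cc <- season_series("t", 1995, rep(4, 10) * 0.7, rep(4, 10) * 0.3,
                      core_ids = "c")
  avg <- average_cores_per_tree(list(a, cc))
  expect_equal(series_years(avg), 1990:2004)
  expect_equal(avg$total, c(rep(2, 5), rep(3, 5), rep(4, 5)))
  # disjoint spans refuse concatenation
  d <- season_series("t", 2010, rep(1, 5) * 0.7, rep(1, 5) * 0.3,
                     core_ids = "d")
  expect_error(average_cores_per_tree(list(a, d)), "overlap")
})

test_that("averaging output satisfies the seasonal-sum invariant", {
  set.seed(7)
  for (k in 1:10) {
    cores <- lapply(1:3, function(i) {
      n <- sample(10:20, 1)
      fy <- 1980 + sample(0:5, 1)
      e <- runif(n, 0.3, 1.5); l <- runif(n, 0.1, 0.8)
      season_series("t", fy, e, l, core_ids = paste0("c", i))
    })
    avg <- average_cores_per_tree(cores)
    expect_lt(max(abs(avg$total - (avg$earlywood + avg$latewood))), 0.01)
  }
})

test_that("climate tables validate coverage and uniqueness", {
  good <- expand.grid(month = 1:12, year = 2000:2002)
  good$temperature <- 0; good$precipitation <- 10
  expect_s3_class(as_climate_table(good), "climate_table")
  expect_error(as_climate_table(good[-15, ]), "gap")
  expect_error(as_climate_table(rbind(good, good[1, ])), "duplicate")
})
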