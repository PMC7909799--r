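# Build the year-by-variable monthly predictor matrix: previous-year January
# through December (lowercase month tag) and current-year January through
# September (uppercase), for temperature (T...) and precipitation (P...).
# Rows are chronology years with complete climate coverage.
climate_design <- function(climate, years) {
  mon <- c("jan", "feb", "mar", "apr", "may", "jun",
           "jul", "aug", "sep", "oct", "nov", "dec")
  key <- paste(climate$year, climate$month)
  grab <- function(var, yr, m) {
    i <- match(paste(yr, m), key)
    climate[[var]][i]
  }
  cols <- list()
  for (v in c("temperature", "precipitation")) {
    tag <- if (v == "temperature") "T" else "P"
    for (m in 1:12)  # previous year
      cols[[paste0(tag, mon[m])]] <- grab(v, years - 1L, m)
    for (m in 1:9)   # current year through September
      cols[[paste0(tag, toupper(mon[m]))]] <- grab(v, years, m)
  }
  X <- do.call(cbind, cols)
  rownames(X) <- years
  ok <- stats::complete.cases(X)
  X[ok, , drop = FALSE]
}

#' Bootstrapped response-function screening of monthly climate variables
#'
#' Classical response-function analysis: the 42 monthly predictors
#' (temperature and precipitation, previous-year January through current-year
#' September) are reduced to principal components (enough components to
#' explain 95 percent of the predictor variance, capped at a third of the
#' sample size so the regression stays well conditioned), the chronology is
#' regressed on the component scores in each bootstrap resample of years, and
#' the coefficients are back-transformed to the monthly variables. A sparse
#' retention of components would leak a true monthly signal into correlated
#' neighbours, so the basis is kept nearly complete. A variable is significant
#' when its bootstrap `1 - alpha` percentile interval excludes zero.
#' Zero-variance variables are excluded with a warning.
#'
#' @param chronology an [index_series()] site chronology.
#' @param climate a climate table ([as_climate_table()]).
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed.
#' @return data frame (one row per variable) with `variable`, `coef` (median
#'   bootstrap response coefficient), `lower`, `upper`, `significant`;
#'   attribute `"years"` records the years used.
#' @export
response_screen <- function(chronology, climate, n_boot = 1000L,
                            alpha = 0.05, seed = 1L) {
  years <- series_years(chronology)
  X <- climate_design(climate, years)
  use_years <- as.integer(rownames(X))
  if (length(use_years) < 30L)
    stop("chronology and climate overlap shorter than 30 years")
  y <- chronology$values[match(use_years, years)]
  keep <- !is.na(y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance climate variable(s) excluded: ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  Xs <- scale(X)
  pc <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  k <- min(which(cumsum(ev) / sum(ev) >= 0.95)[1L],
           max(2L, floor(length(y) / 3)))
  if (qr(Xs)$rank < k) stop("degenerate (collinear) climate matrix")
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  n <- length(y)
  coefs <- with_seed(seed, {
    out <- matrix(NA_real_, n_boot, ncol(Xs))
    for (b in seq_len(n_boot)) {
      i <- sample.int(n, n, replace = TRUE)
      fit <- stats::lm.fit(cbind(1, scores[i, , drop = FALSE]), y[i])
      out[b, ] <- as.numeric(rot %*% fit$coefficients[-1L])
    }
    out
  })
  lo <- apply(coefs, 2L, stats::quantile, alpha / 2)
  hi <- apply(coefs, 2L, stats::quantile, 1 - alpha / 2)
  med <- apply(coefs, 2L, stats::median)
  res <- data.frame(variable = colnames(Xs), coef = med,
                    lower = lo, upper = hi,
                    significant = lo > 0 | hi < 0,
                    row.names = NULL)
  attr(res, "years") <- as.integer(rownames(X))
  res
}

#' Defoliation dummy variable from event years
#'
#' Builds the 0/1 indicator of post-defoliation growth suppression: years at
#' the chosen lags after any event get 1. The default lags `c(1, 2)` encode
#' the two-season suppression that follows late-summer defoliation.
#'
#' @param event_years integer defoliation years.
#' @param years integer years the model covers.
#' @param effect_lags integer lags after an event marked as affected
#'   (default `c(1, 2)`).
#' @return integer 0/1 vector along `years`.
#' @export
defoliation_dummy <- function(event_years, years, effect_lags = c(1L, 2L)) {
  affected <- unique(unlist(lapply(event_years, function(e) e + effect_lags)))
  as.integer(years %in% affected)
}

#' Fit the climate-only and climate-plus-defoliation linear models
#'
#' Ordinary least squares of the growth index on the selected monthly climate
#' variables, without (`weather`) and with (`weather_outbreak`) the
#' defoliation dummy. Predictors are pruned independently in both models by
#' backward stepwise elimination on AIC; the dummy itself is never eligible
#' for elimination.
#'
#' @param chronology an [index_series()].
#' @param climate a climate table.
#' @param selected_vars character vector of monthly variable names (as in
#'   [response_screen()] output, e.g. `"TJUL"`, `"Pjan"`).
#' @param dummy 0/1 vector along the modelled years, or event years from
#'   which [defoliation_dummy()] builds it.
#' @param effect_lags lags used when `dummy` is given as event years.
#' @return list with `weather` and `weather_outbreak`, each a list holding
#'   `coefficients`, `r2adj`, `aic`, `fit` (the `lm` object), plus the
#'   modelling `data`.
#' @export
fit_models <- function(chronology, climate, selected_vars, dummy,
                       effect_lags = c(1L, 2L)) {
  years <- series_years(chronology)
  X <- climate_design(climate, years)
  use_years <- as.integer(rownames(X))
  y <- chronology$values[match(use_years, years)]
  miss <- setdiff(selected_vars, colnames(X))
  if (length(miss)) stop("unknown climate variable(s): ",
                         paste(miss, collapse = ", "))
  O <- if (length(dummy) == length(use_years) && all(dummy %in% c(0, 1)))
    as.integer(dummy) else defoliation_dummy(dummy, use_years, effect_lags)
  dat <- data.frame(I = y, X[, selected_vars, drop = FALSE], O = O)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < 5L * (length(selected_vars) + 1L))
    stop("fewer than 5 observations per candidate predictor")
  fit2 <- stats::lm(I ~ . - O, data = dat)
  fit2 <- stats::step(fit2, direction = "backward", trace = 0)
  fit3 <- stats::lm(I ~ ., data = dat)
  fit3 <- stats::step(fit3, direction = "backward", trace = 0,
                      scope = list(lower = ~O))
  pack <- function(fit) {
    list(coefficients = stats::coef(fit),
         r2adj = summary(fit)$adj.r.squared,
         aic = stats::AIC(fit), fit = fit)
  }
  list(weather = pack(fit2), weather_outbreak = pack(fit3), data = dat)
}

#' Bootstrap comparison of the climate-only and defoliation models
#'
#' For each model, resamples the modelled years with replacement `n_boot`
#' times, refits the fixed predictor sets, and records the adjusted R
#' squared. The two bootstrap samples of R2adj are compared with Friedman's
#' rank test (replicate index as the block). Resamples in which the dummy has
#' zero variance fall back to the climate-only fit for that replicate and are
#' counted in `n_degenerate`.
#'
#' @param models output of [fit_models()].
#' @param n_boot number of bootstrap resamples (default 100).
#' @param seed integer seed.
#' @param linked use the same resampled rows for both models within a
#'   replicate (default `FALSE`: each model gets its own resamples, so the
#'   replicate-to-replicate variation of both samples is exchangeable under
#'   the no-effect null).
#' @return list with `p` (Friedman), `r2_weather`, `r2_outbreak`,
#'   `n_degenerate`.
#' @export
bootstrap_r2_compare <- function(models, n_boot = 100L, seed = 1L,
                                 linked = FALSE) {
  if (n_boot < 2L) stop("n_boot must be at least 2 for the rank test")
  dat <- models$data
  v2 <- setdiff(names(stats::coef(models$weather$fit)), "(Intercept)")
  v3 <- setdiff(names(stats::coef(models$weather_outbreak$fit)), "(Intercept)")
  n <- nrow(dat)
  r2adj_of <- function(vars, rows) {
    d <- dat[rows, , drop = FALSE]
    if ("O" %in% vars && stats::var(d$O) == 0) return(NA_real_)
    X <- as.matrix(cbind(`(Intercept)` = 1, d[, vars, drop = FALSE]))
    fit <- stats::lm.fit(X, d$I)
    p <- fit$rank - 1L
    rss <- sum(fit$residuals^2)
    tss <- sum((d$I - mean(d$I))^2)
    1 - (rss / (n - p - 1L)) / (tss / (n - 1L))
  }
  res <- with_seed(seed, {
    r2w <- r2o <- numeric(n_boot)
    degen <- 0L
    for (b in seq_len(n_boot)) {
      i2 <- sample.int(n, n, replace = TRUE)
      i3 <- if (linked) i2 else sample.int(n, n, replace = TRUE)
      r2w[b] <- r2adj_of(v2, i2)
      r3 <- r2adj_of(v3, i3)
      if (is.na(r3)) {          # degenerate resample: no defoliation years
        degen <- degen + 1L
        r3 <- r2adj_of(setdiff(v3, "O"), i3)
      }
      r2o[b] <- r3
    }
    list(r2w = r2w, r2o = r2o, degen = degen)
  })
  p <- stats::friedman.test(cbind(res$r2w, res$r2o))$p.value
  list(p = p, r2_weather = res$r2w, r2_outbreak = res$r2o,
       n_degenerate = res$degen)
}

#' Superposed epoch analysis of a chronology around event years
#'
#' Averages the centered chronology at each lag relative to the events and
#' compares every lag's mean departure with the distribution obtained from
#' `n_draws` random pseudo-event sets of the same size (drawn without
#' replacement from the analyzed years). A lag is flagged as significant
#' growth suppression when its departure falls below the `alpha/2` percentile
#' of the null distribution; `sig_pos` marks the upper tail analogously.
#'
#' @param chronology an [index_series()].
#' @param event_years integer event years (at least 3).
#' @param lags integer lags to evaluate (default -3..5).
#' @param n_draws size of the null ensemble (default 1000).
#' @param alpha two-sided significance level (default 0.05).
#' @param seed integer seed.
#' @return data frame with `lag`, `departure`, `lower`, `upper`,
#'   `significant` (suppression flag), `sig_pos`, `n_events`.
#' @export
sea <- function(chronology, event_years, lags = -3:5, n_draws = 1000L,
                alpha = 0.05, seed = 1L) {
  years <- series_years(chronology)
  v <- chronology$values - mean(chronology$values, na.rm = TRUE)
  event_years <- sort(unique(as.integer(event_years)))
  usable <- event_years[vapply(event_years, function(e)
    any((e + lags) %in% years), logical(1))]
  if (length(usable) < 3L) stop("fewer than 3 usable events")
  dep_of <- function(ev) {
    vapply(lags, function(l) {
      i <- match(ev + l, years)
      mean(v[i[!is.na(i)]], na.rm = TRUE)
    }, numeric(1))
  }
  dep <- dep_of(usable)
  null <- with_seed(seed, {
    m <- matrix(NA_real_, n_draws, length(lags))
    for (d in seq_len(n_draws)) {
      ev <- sample(years, length(usable), replace = FALSE)
      m[d, ] <- dep_of(ev)
    }
    m
  })
  lo <- apply(null, 2L, stats::quantile, alpha / 2, na.rm = TRUE)
  hi <- apply(null, 2L, stats::quantile, 1 - alpha / 2, na.rm = TRUE)
  data.frame(lag = lags, departure = dep, lower = lo, upper = hi,
             significant = dep < lo, sig_pos = dep > hi,
             n_events = length(usable), row.names = NULL)
}
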