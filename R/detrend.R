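#' Baillie-Pilcher standardization
#'
#' Classical pointer-year standardization: each width is expressed as a
#' percentage of the centered 5-year running mean, the window truncated at the
#' series ends. For a smooth series the index hovers around 100.
#'
#' @param w numeric width vector (mm), or a `season_series` together with
#'   `fraction`.
#' @param fraction wood fraction to index when `w` is a `season_series`.
#' @param first_year calendar year of `w[1]` when `w` is a bare vector.
#' @return an [index_series()] with basis `"baillie_pilcher"`; years whose
#'   running mean is zero are `NA`.
#' @export
baillie_pilcher_index <- function(w, fraction = "total", first_year = 1L) {
  if (inherits(w, "season_series")) {
    first_year <- w$first_year
    w <- w[[fraction]]
  }
  n <- length(w)
  if (n < 5L) stop("Baillie-Pilcher indexing needs at least 5 rings")
  rm5 <- vapply(seq_len(n), function(t) {
    win <- max(1L, t - 2L):min(n, t + 2L)
    mean(w[win])
  }, numeric(1))
  idx <- ifelse(rm5 > 0, 100 * w / rm5, NA_real_)
  index_series(first_year, idx, "baillie_pilcher")
}

# Cubic smoothing spline on an annual grid, parameterized by the period (in
# years) at which its frequency response falls to 50%. Implemented as the
# discrete second-difference penalty smoother s = (I + lambda D'D)^{-1} w with
# lambda = (2 sin(pi/p))^{-4}, whose transfer function 1/(1 + lambda
# (2 sin(pi f))^4) equals 0.5 at f = 1/p. The penalty null space is linear, so
# linear trends pass through unchanged.
ff_spline <- function(w, period) {
  n <- length(w)
  if (period <= 2) return(w)
  lambda <- (2 * sin(pi / period))^-4
  D <- diff(diag(n), differences = 2)
  s <- solve(diag(n) + lambda * crossprod(D), w)
  as.numeric(s)
}

#' Cubic smoothing-spline detrending
#'
#' Divides a width series by a cubic smoothing spline whose frequency response
#' is 50% at the chosen stiffness, the conventional flexible-spline
#' standardization for detecting interannual disturbance signals. Missing-ring
#' widths are linearly interpolated before the spline is fitted so that dating
#' is preserved; their indices are flagged `NA`.
#'
#' @param w numeric width vector, or a `season_series` (uses `fraction`).
#' @param stiffness 50% frequency-response cutoff: years if `>= 1`, a fraction
#'   of the series length if `< 1`. Default 0.67 of the series length.
#' @param fraction wood fraction when `w` is a `season_series`.
#' @param first_year calendar year of `w[1]` for bare vectors.
#' @param missing optional logical vector of missing-ring flags.
#' @return an [index_series()] with basis `"spline"`; indices where the spline
#'   is non-positive (or the ring missing) are `NA`.
#' @export
spline_detrend <- function(w, stiffness = 0.67, fraction = "total",
                           first_year = 1L, missing = NULL) {
  if (inherits(w, "season_series")) {
    first_year <- w$first_year
    missing <- w$missing
    w <- w[[fraction]]
  }
  n <- length(w)
  if (n < 10L) stop("spline detrending needs at least 10 rings")
  if (is.null(missing)) missing <- rep(FALSE, n)
  period <- if (stiffness < 1) stiffness * n else stiffness
  wi <- w
  if (any(missing)) {
    ok <- which(!missing)
    if (length(ok) < 2L) stop("too few measured rings to interpolate")
    wi[missing] <- stats::approx(ok, w[ok], xout = which(missing),
                                 rule = 2)$y
  }
  s <- ff_spline(wi, period)
  idx <- ifelse(s > 0, wi / s, NA_real_)
  idx[missing] <- NA_real_
  index_series(first_year, idx, "spline")
}

# Modified negative exponential a*exp(-b*t)+k (a > 0, b > 0, k >= 0) fitted by
# bounded nls; falls back to a non-positive-slope line, then to the mean.
neg_exp_curve <- function(w) {
  n <- length(w)
  tt <- seq_len(n)
  fit <- NULL
  try({
    a0 <- max(w[1:min(5L, n)]) - min(w)
    k0 <- max(min(w), 1e-3)
    fit <- stats::nls(w ~ a * exp(-b * tt) + k,
                      start = list(a = max(a0, 1e-3), b = 0.02, k = k0),
                      lower = c(a = 1e-8, b = 1e-8, k = 0),
                      algorithm = "port",
                      control = stats::nls.control(warnOnly = TRUE))
  }, silent = TRUE)
  if (!is.null(fit)) {
    curve <- as.numeric(stats::fitted(fit))
    if (all(curve > 0)) return(curve)
  }
  lf <- stats::lm(w ~ tt)
  if (stats::coef(lf)[2L] <= 0) {
    curve <- as.numeric(stats::fitted(lf))
    if (all(curve > 0)) return(curve)
  }
  rep(mean(w), n)
}

#' Double detrending: negative exponential, then spline
#'
#' First pass divides by a fitted modified negative exponential
#' `a*exp(-b*t) + k` (falling back to a non-increasing line, then to the series
#' mean, when that fit fails); second pass applies [spline_detrend()] to the
#' first-pass index. The usual standardization before climate-growth
#' modelling.
#'
#' @inheritParams spline_detrend
#' @return an [index_series()] with basis `"double_detrend"`.
#' @export
double_detrend <- function(w, stiffness = 0.67, fraction = "total",
                           first_year = 1L, missing = NULL) {
  if (inherits(w, "season_series")) {
    first_year <- w$first_year
    missing <- w$missing
    w <- w[[fraction]]
  }
  if (length(w) < 20L) stop("double detrending needs at least 20 rings")
  if (is.null(missing)) missing <- rep(FALSE, length(w))
  wi <- w
  if (any(missing)) {
    ok <- which(!missing)
    wi[missing] <- stats::approx(ok, w[ok], xout = which(missing), rule = 2)$y
  }
  curve <- neg_exp_curve(wi)
  pass1 <- wi / curve
  out <- spline_detrend(pass1, stiffness = stiffness, first_year = first_year,
                        missing = missing)
  out$basis <- "double_detrend"
  out
}
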