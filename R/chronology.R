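#' Align a list of index series into a year-by-series matrix
#'
#' @param indices list of [index_series()].
#' @return numeric matrix, rownames = years, one column per series.
#' @export
index_matrix <- function(indices) {
  if (inherits(indices, "index_series")) indices <- list(indices)
  spans <- lapply(indices, series_years)
  years <- seq.int(min(unlist(spans)), max(unlist(spans)))
  m <- matrix(NA_real_, length(years), length(indices))
  rownames(m) <- years
  nm <- names(indices)
  colnames(m) <- if (!is.null(nm)) nm else paste0("s", seq_along(indices))
  for (k in seq_along(indices))
    m[match(spans[[k]], years), k] <- indices[[k]]$values
  m
}

# mean pairwise Pearson correlation over a window; pairs overlapping fewer
# than min_overlap years are excluded (with one warning)
rbar_of <- function(m, min_overlap = 10L) {
  k <- ncol(m)
  rs <- c()
  short <- FALSE
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    ok <- stats::complete.cases(m[, c(i, j)])
    if (sum(ok) < min_overlap) { short <- TRUE; next }
    if (stats::sd(m[ok, i]) == 0 || stats::sd(m[ok, j]) == 0) next
    rs <- c(rs, stats::cor(m[ok, i], m[ok, j]))
  }
  if (short) warning("pairs overlapping fewer than ", min_overlap,
                     " years excluded from rbar")
  if (!length(rs)) return(NA_real_)
  mean(rs)
}

#' Chronology quality statistics: rbar, EPS and SNR
#'
#' `rbar` is the mean pairwise Pearson correlation between index series over
#' the window (pairwise-complete, pairs with under 10 overlapping years
#' excluded); `EPS = n*rbar / (n*rbar + 1 - rbar)` and `SNR = n*rbar /
#' (1 - rbar)` follow the standard population-signal definitions. Perfectly
#' correlated series give `EPS = 1` and infinite SNR; a negative `rbar` is
#' reported as zero signal with a warning.
#'
#' @param indices list of [index_series()].
#' @param window optional `c(first, last)` years; default full union span.
#' @return list of class `"chronology_stats"` with `rbar`, `eps`, `snr`,
#'   `n_trees` and `window`.
#' @export
eps_snr <- function(indices, window = NULL) {
  m <- index_matrix(indices)
  years <- as.integer(rownames(m))
  if (!is.null(window))
    m <- m[years >= window[1L] & years <= window[2L], , drop = FALSE]
  else
    window <- range(years)
  covered <- colSums(!is.na(m)) > 0L
  m <- m[, covered, drop = FALSE]
  n <- ncol(m)
  if (n < 2L) stop("EPS/SNR need at least 2 overlapping series")
  rbar <- rbar_of(m)
  if (is.na(rbar)) stop("no series pair with sufficient overlap in window")
  if (rbar <= 0) {
    warning("non-positive rbar (", signif(rbar, 3), "); EPS and SNR set to 0")
    eps <- 0; snr <- 0
  } else if (rbar >= 1 - 1e-12) {
    eps <- 1; snr <- Inf
  } else {
    eps <- n * rbar / (n * rbar + 1 - rbar)
    snr <- n * rbar / (1 - rbar)
  }
  structure(list(rbar = rbar, eps = eps, snr = snr, n_trees = n,
                 window = as.integer(window)),
            class = "chronology_stats")
}

#' @export
print.chronology_stats <- function(x, ...) {
  cat(sprintf("<chronology_stats> %d-%d, n = %d: rbar %.3f, EPS %.3f, SNR %.2f\n",
              x$window[1L], x$window[2L], x$n_trees, x$rbar, x$eps, x$snr))
  invisible(x)
}

#' Leave-one-out correlation screening of tree series
#'
#' Each tree's Baillie-Pilcher index is correlated with the mean index of all
#' other trees over their common years; trees with `r < r_min` are rejected
#' and, by default, the screen is repeated on the survivors until no further
#' rejection (a fixed point, so the result does not depend on processing
#' order). Screening stops rather than reducing a site below two trees.
#'
#' @param collection a [site_collection()].
#' @param r_min rejection threshold for Pearson r (default 0.4).
#' @param iterate re-screen after rejections until stable (default `TRUE`).
#' @return list with `retained` (a `site_collection`), `rejected` (character
#'   ids) and `r` (named vector of the final-pass correlations).
#' @export
leave_one_out_screen <- function(collection, r_min = 0.4, iterate = TRUE) {
  if (length(collection$trees) < 3L)
    stop("screening needs at least 3 series")
  idx <- lapply(collection$trees, baillie_pilcher_index)
  keep <- names(idx)
  rejected <- character()
  r_all <- stats::setNames(rep(NA_real_, length(keep)), keep)
  repeat {
    m <- index_matrix(idx[keep])
    r <- vapply(seq_along(keep), function(k) {
      others <- rowMeans(m[, -k, drop = FALSE], na.rm = TRUE)
      ok <- !is.na(m[, k]) & !is.nan(others) & !is.na(others)
      if (sum(ok) < 10L) return(NA_real_)
      if (stats::sd(m[ok, k]) == 0 || stats::sd(others[ok]) == 0) return(NA_real_)
      stats::cor(m[ok, k], others[ok])
    }, numeric(1))
    names(r) <- keep
    r_all[keep] <- r
    drop_now <- keep[!is.na(r) & r < r_min]
    if (!length(drop_now)) break
    if (length(keep) - length(drop_now) < 2L) {
      warning("screening stopped: rejection would leave fewer than 2 series")
      break
    }
    rejected <- c(rejected, drop_now)
    keep <- setdiff(keep, drop_now)
    if (!iterate) break
  }
  list(retained = site_collection(collection$site_id,
                                  unname(collection$trees[keep]),
                                  reliable_span = NULL),
       rejected = rejected, r = r_all)
}

#' Build a site chronology by averaging index series
#'
#' Per-year arithmetic mean over the series covering that year; optionally the
#' Tukey biweight robust mean. Years inside the span covered by no series stay
#' `NA` (gap).
#'
#' @param indices list of [index_series()].
#' @param robust use the biweight robust mean (default `FALSE`).
#' @return an [index_series()] (basis of the inputs if shared, else `"raw"`).
#' @export
site_chronology <- function(indices, robust = FALSE) {
  if (inherits(indices, "index_series")) indices <- list(indices)
  m <- index_matrix(indices)
  vals <- apply(m, 1L, function(row) {
    v <- row[!is.na(row)]
    if (!length(v)) return(NA_real_)
    if (robust) tbrm(v) else mean(v)
  })
  bases <- unique(vapply(indices, `[[`, character(1), "basis"))
  out <- index_series(as.integer(rownames(m)[1L]), as.numeric(vals),
                      if (length(bases) == 1L) bases else "raw")
  out
}

# Tukey's biweight robust mean (c = 9, median/MAD scaling)
tbrm <- function(x, C = 9) {
  med <- stats::median(x)
  s <- stats::median(abs(x - med))
  if (s == 0) return(med)
  u <- (x - med) / (C * s)
  w <- (1 - u^2)^2
  w[abs(u) >= 1] <- 0
  sum(w * x) / sum(w)
}

#' EPS-reliable span of a chronology
#'
#' Slides a window (anchored at the first year of the union span) across the
#' site and computes EPS in each; returns the union of the longest contiguous
#' run of windows with `EPS >= eps_min`. A trailing window anchored at the
#' last year is added when the step does not land there exactly.
#'
#' @param indices list of [index_series()].
#' @param window_len window length in years (default 20).
#' @param overlap window overlap in years (default 10; the step is
#'   `window_len - overlap`).
#' @param eps_min EPS threshold (default 0.85).
#' @return `c(first, last)` years, or `NULL` (with a warning) if no window
#'   passes.
#' @export
reliable_span <- function(indices, window_len = 20L, overlap = 10L,
                          eps_min = 0.85) {
  m <- index_matrix(indices)
  years <- as.integer(rownames(m))
  if (length(years) < window_len) stop("span shorter than the window length")
  step <- max(1L, window_len - overlap)
  starts <- seq.int(years[1L], years[length(years)] - window_len + 1L, by = step)
  last_start <- years[length(years)] - window_len + 1L
  if (starts[length(starts)] != last_start) starts <- c(starts, last_start)
  pass <- vapply(starts, function(s) {
    win <- c(s, s + window_len - 1L)
    st <- tryCatch(suppressWarnings(eps_snr(indices, win)),
                   error = function(e) NULL)
    !is.null(st) && st$eps >= eps_min
  }, logical(1))
  if (!any(pass)) {
    warning("no window reaches EPS >= ", eps_min)
    return(NULL)
  }
  r <- rle(pass)
  ends <- cumsum(r$lengths)
  best <- which(r$values)[which.max(r$lengths[r$values])]
  i1 <- if (best == 1L) 1L else ends[best - 1L] + 1L
  i2 <- ends[best]
  c(starts[i1], starts[i2] + window_len - 1L)
}

#' Standardize, screen and summarize a site in one step
#'
#' Convenience pipeline: Baillie-Pilcher screening ([leave_one_out_screen()]),
#' spline detrending of the survivors, site chronology, EPS/SNR and the
#' EPS-reliable span, returned as an annotated [site_collection()].
#'
#' @param collection a `site_collection` of raw seasonal series.
#' @param r_min screening threshold (default 0.4).
#' @param stiffness spline stiffness for the chronology (default 0.67).
#' @param eps_min reliability threshold (default 0.85).
#' @return the screened collection with `chronology`, `reliable_span` and a
#'   `stats` element (`chronology_stats`) filled in.
#' @export
prepare_site <- function(collection, r_min = 0.4, stiffness = 0.67,
                         eps_min = 0.85) {
  scr <- leave_one_out_screen(collection, r_min = r_min)
  col <- scr$retained
  idx <- lapply(col$trees, spline_detrend, stiffness = stiffness)
  col$chronology <- site_chronology(idx)
  col$reliable_span <- tryCatch(reliable_span(idx, eps_min = eps_min),
                                warning = function(w) NULL)
  col$stats <- tryCatch(suppressWarnings(eps_snr(idx)), error = function(e) NULL)
  col$screening <- scr[c("rejected", "r")]
  col
}
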