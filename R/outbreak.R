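#' Parameters of the OUTBREAK-style suppression detector
#'
#' @param std depth of the suppression threshold in standard deviations below
#'   the series mean.
#' @param lng minimum number of consecutive suppressed years.
#' @param abrupt maximum growth-change ratio (unit fraction) at the onset
#'   year; e.g. 0.8 demands at least a 20 percent drop.
#' @param min_tree_prop minimum proportion of trees flagged at a year for it
#'   to be reported (default 0.10).
#' @param min_event_gap minimum spacing of reported events (default 2).
#' @return list of class `"outbreak_params"`.
#' @export
outbreak_params <- function(std = 0.6, lng = 2L, abrupt = 0.8,
                            min_tree_prop = 0.10, min_event_gap = 2L) {
  stopifnot(std > 0, lng >= 1L, abrupt > 0, abrupt <= 1,
            min_tree_prop > 0, min_tree_prop <= 1)
  structure(list(std = std, lng = as.integer(lng), abrupt = abrupt,
                 min_tree_prop = min_tree_prop,
                 min_event_gap = as.integer(min_event_gap)),
            class = "outbreak_params")
}

#' Per-tree onset flags of sustained, abrupt growth suppression
#'
#' Year `t` is flagged when (a) the detrended indices in years `t` through
#' `t + lng - 1` all lie at or below `mean(index) - std * sd(index)` and (b)
#' the index-to-index growth-change ratio at the onset, `index_t /
#' index_(t-1)`, is at most `abrupt`. A constant series (zero standard
#' deviation) yields no flags.
#'
#' @param index an [index_series()], normally [spline_detrend()] output.
#' @param params an [outbreak_params()] object.
#' @return logical vector along the series years (`FALSE` where undefined).
#' @export
outbreak_flag_tree <- function(index, params = outbreak_params()) {
  v <- index$values
  n <- length(v)
  flags <- rep(FALSE, n)
  if (n < params$lng + 1L) {
    warning("series shorter than lng + 1; no flags")
    return(flags)
  }
  mu <- mean(v, na.rm = TRUE)
  sdv <- stats::sd(v, na.rm = TRUE)
  if (is.na(sdv) || sdv == 0) return(flags)
  thr <- mu - params$std * sdv
  below <- !is.na(v) & v <= thr
  for (t in 2:(n - params$lng + 1L)) {
    if (!all(below[t:(t + params$lng - 1L)])) next
    if (is.na(v[t - 1L]) || is.na(v[t]) || v[t - 1L] <= 0) next
    if (v[t] / v[t - 1L] <= params$abrupt) flags[t] <- TRUE
  }
  flags
}

#' OUTBREAK-style detection across a site
#'
#' Spline-detrends every tree's total ring width, computes per-tree onset
#' flags with [outbreak_flag_tree()], and reports year `t` when the proportion
#' of flagged trees reaches `min_tree_prop`. Runs of reported years closer
#' than `min_event_gap` keep the first year.
#'
#' @param collection a [site_collection()].
#' @param params an [outbreak_params()] object.
#' @param span optional `c(first, last)` years to analyze.
#' @param stiffness spline stiffness passed to [spline_detrend()].
#' @return a [detection_result()]; `support` holds the flagged-tree
#'   proportion per event, `per_tree` the full flag matrix.
#' @export
outbreak_detect <- function(collection, params = outbreak_params(),
                            span = NULL, stiffness = 0.67) {
  if (length(collection$trees) < 5L) stop("needs at least 5 trees")
  if (is.null(span))
    span <- if (!is.null(collection$reliable_span)) collection$reliable_span
            else site_span(collection)
  full <- seq.int(site_span(collection)[1L], site_span(collection)[2L])
  fm <- matrix(FALSE, length(full), length(collection$trees),
               dimnames = list(full, names(collection$trees)))
  nm <- matrix(FALSE, length(full), length(collection$trees),
               dimnames = list(full, names(collection$trees)))
  for (tr in collection$trees) {
    idx <- spline_detrend(tr, stiffness = stiffness)
    fl <- outbreak_flag_tree(idx, params)
    rows <- as.character(series_years(tr))
    fm[rows, tr$tree_id] <- fl
    nm[rows, tr$tree_id] <- TRUE
  }
  years <- as.integer(rownames(fm))
  inside <- years >= span[1L] & years <= span[2L]
  prop <- rowSums(fm) / pmax(rowSums(nm), 1L)
  hit <- inside & rowSums(nm) >= 5L & prop >= params$min_tree_prop
  events <- thin_events(years[hit], params$min_event_gap)
  sup <- data.frame(year = events, prop_trees = prop[match(events, years)])
  detection_result(collection$site_id, "outbreak", events, span,
                   support = sup, per_tree = fm)
}
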