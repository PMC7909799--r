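#' Parameters of the moving-window local-minimum detector
#'
#' @param width half-window in years; a year is compared with the widths from
#'   `t - width` to `t + width`.
#' @param perc minimum proportion of trees (unit fraction) with a local
#'   minimum at the same year.
#' @param allow_ties count a year tied for the window minimum as a minimum
#'   (default `FALSE`: ties disqualify).
#' @param combine_adjacent experimental variant summing the proportions of two
#'   adjacent years before thresholding (default `FALSE`).
#' @param min_event_gap minimum spacing of reported events (default 2).
#' @return list of class `"mwm_params"`.
#' @export
mwm_params <- function(width = 3L, perc = 0.35, allow_ties = FALSE,
                       combine_adjacent = FALSE, min_event_gap = 2L) {
  stopifnot(width >= 1L, perc > 0, perc <= 1)
  structure(list(width = as.integer(width), perc = perc,
                 allow_ties = allow_ties, combine_adjacent = combine_adjacent,
                 min_event_gap = as.integer(min_event_gap)),
            class = "mwm_params")
}

#' Local-minimum flags of one raw width series
#'
#' Year `t` is flagged when the full window `t - width .. t + width` lies
#' inside the series and `w_t` is strictly smaller than every other width in
#' the window; a tie for the minimum disqualifies the year unless
#' `allow_ties`. Years within `width` of either end are never flagged.
#'
#' @param w numeric width vector (absolute widths, not detrended).
#' @param width half-window in years.
#' @param allow_ties see [mwm_params()].
#' @return logical vector along `w`.
#' @export
local_minimum_flags <- function(w, width = 3L, allow_ties = FALSE) {
  n <- length(w)
  if (n < 2L * width + 1L)
    stop("series shorter than the full window 2*width + 1")
  flags <- rep(FALSE, n)
  for (t in (width + 1L):(n - width)) {
    win <- w[(t - width):(t + width)]
    others <- win[-(width + 1L)]
    flags[t] <- if (allow_ties) w[t] <= min(others) else w[t] < min(others)
  }
  flags
}

#' Moving-window detection across a site
#'
#' Flags each tree's local ring-width minima with [local_minimum_flags()] on
#' the raw (absolute) total widths and reports year `t` when the proportion of
#' flagged trees reaches `perc`.
#'
#' @param collection a [site_collection()].
#' @param params an [mwm_params()] object.
#' @param span optional `c(first, last)` years to analyze.
#' @return a [detection_result()]; `support` holds the proportions.
#' @export
mwm_detect <- function(collection, params = mwm_params(), span = NULL) {
  if (length(collection$trees) < 5L) stop("needs at least 5 trees")
  if (is.null(span))
    span <- if (!is.null(collection$reliable_span)) collection$reliable_span
            else site_span(collection)
  full <- seq.int(site_span(collection)[1L], site_span(collection)[2L])
  fm <- matrix(FALSE, length(full), length(collection$trees),
               dimnames = list(full, names(collection$trees)))
  nm <- fm
  for (tr in collection$trees) {
    fl <- local_minimum_flags(tr$total, params$width, params$allow_ties)
    rows <- as.character(series_years(tr))
    fm[rows, tr$tree_id] <- fl
    nm[rows, tr$tree_id] <- TRUE
  }
  years <- as.integer(rownames(fm))
  prop <- rowSums(fm) / pmax(rowSums(nm), 1L)
  eff <- prop
  if (params$combine_adjacent)
    eff <- prop + c(prop[-1L], 0)   # proportion of year t plus year t + 1
  inside <- years >= span[1L] & years <= span[2L]
  hit <- inside & rowSums(nm) >= 5L & eff >= params$perc
  events <- thin_events(years[hit], params$min_event_gap)
  sup <- data.frame(year = events, prop_trees = prop[match(events, years)])
  detection_result(collection$site_id, "mwm", events, span,
                   support = sup, per_tree = fm)
}
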