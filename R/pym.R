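#' Relative growth change (RGC)
#'
#' Ratio of the current year's absolute growth to the previous year's,
#' expressed in percent: `RGC_t = 100 * R_t / R_(t-1)`. Undefined (`NA`) at
#' the first year, wherever the previous width is zero, and at or next to a
#' missing ring.
#'
#' @param w numeric width vector, or a `season_series` (with `fraction`).
#' @param missing optional logical missing-ring flags.
#' @param fraction wood fraction when `w` is a `season_series`.
#' @return numeric vector of percentages, same length as `w`, `NA` where
#'   undefined.
#' @export
rgc <- function(w, missing = NULL, fraction = "total") {
  if (inherits(w, "season_series")) {
    missing <- w$missing
    w <- w[[fraction]]
  }
  n <- length(w)
  if (n < 2L) stop("RGC needs at least 2 years")
  if (is.null(missing)) missing <- rep(FALSE, n)
  out <- c(NA_real_, 100 * w[-1L] / w[-n])
  out[c(FALSE, w[-n] == 0)] <- NA_real_
  out[missing] <- NA_real_
  out[c(FALSE, missing[-n])] <- NA_real_
  out
}

#' Parameters of the pointer-year method
#'
#' @param change_l latewood RGC threshold in percent. Under the default
#'   `"drop"` semantics a tree passes in year `t+1` when its latewood RGC is
#'   at most `100 - change_l` (i.e. at least a `change_l` percent decline);
#'   under the literal `"ratio"` semantics when its RGC is below `change_l`.
#' @param sync_l minimum percentage of evaluable trees passing the latewood
#'   test.
#' @param change_e,sync_e the same pair for earlywood in year `t+2`.
#' @param threshold_semantics `"drop"` (default) or `"ratio"`, see `change_l`.
#' @param min_event_gap minimum spacing of reported events in years (default
#'   2); within a closer run the earliest year is kept.
#' @param min_trees minimum number of evaluable trees for a year to be tested
#'   (default 5).
#' @return list of class `"pym_params"`.
#' @export
pym_params <- function(change_l = 10, sync_l = 55, change_e = 10, sync_e = 55,
                       threshold_semantics = c("drop", "ratio"),
                       min_event_gap = 2L, min_trees = 5L) {
  threshold_semantics <- match.arg(threshold_semantics)
  stopifnot(change_l > 0, change_l <= 100, change_e > 0, change_e <= 100,
            sync_l > 0, sync_l <= 100, sync_e > 0, sync_e <= 100,
            min_event_gap >= 1L)
  structure(list(change_l = change_l, sync_l = sync_l, change_e = change_e,
                 sync_e = sync_e, threshold_semantics = threshold_semantics,
                 min_event_gap = as.integer(min_event_gap),
                 min_trees = as.integer(min_trees)),
            class = "pym_params")
}

# keep the earliest year of each run of flagged years closer than `gap`
thin_events <- function(years, gap) {
  years <- sort(years)
  keep <- integer()
  last <- -Inf
  for (y in years) {
    if (y - last >= gap) { keep <- c(keep, y); last <- y }
  }
  keep
}

#' Pointer-year detection of defoliation years
#'
#' Flags year `t` as a defoliation year when (a) the latewood RGC in year
#' `t+1` passes the `change_l` threshold in at least `sync_l` percent of the
#' evaluable trees and (b) the earlywood RGC in year `t+2` passes the
#' `change_e` threshold in at least `sync_e` percent. Evaluable trees are
#' those with a defined RGC in the tested year; years with fewer than
#' `min_trees` evaluable trees in either season are skipped with a warning.
#' Runs of flagged years closer than `min_event_gap` are reported by their
#' first year.
#'
#' @param collection a [site_collection()] of per-tree seasonal series.
#' @param params a [pym_params()] object.
#' @param span optional `c(first, last)` years to analyze (default: the
#'   site's reliable span if set, else the full span).
#' @return a [detection_result()]; `support` holds the passing fractions.
#' @export
pym_detect <- function(collection, params = pym_params(), span = NULL) {
  if (length(collection$trees) < 5L)
    stop("pointer-year detection needs at least 5 trees")
  if (is.null(span))
    span <- if (!is.null(collection$reliable_span)) collection$reliable_span
            else site_span(collection)
  if (span[2L] - span[1L] < 2L) stop("analyzed span shorter than 3 years")
  lw <- apply_rgc_matrix(collection, "latewood")
  ew <- apply_rgc_matrix(collection, "earlywood")
  years <- as.integer(rownames(lw))
  pass <- function(m, change) {
    if (params$threshold_semantics == "drop") m <= (100 - change)
    else m < change
  }
  pl <- pass(lw, params$change_l)
  pe <- pass(ew, params$change_e)
  cand <- years[years >= span[1L] & years <= span[2L]]
  flags <- logical(length(cand))
  frac_l <- frac_e <- rep(NA_real_, length(cand))
  skipped <- 0L
  for (k in seq_along(cand)) {
    t1 <- match(cand[k] + 1L, years)
    t2 <- match(cand[k] + 2L, years)
    if (is.na(t1) || is.na(t2)) next
    nl <- sum(!is.na(pl[t1, ]))
    ne <- sum(!is.na(pe[t2, ]))
    if (nl < params$min_trees || ne < params$min_trees) {
      skipped <- skipped + 1L
      next
    }
    frac_l[k] <- sum(pl[t1, ], na.rm = TRUE) / nl
    frac_e[k] <- sum(pe[t2, ], na.rm = TRUE) / ne
    flags[k] <- frac_l[k] >= params$sync_l / 100 &&
                frac_e[k] >= params$sync_e / 100
  }
  if (skipped > 0L)
    warning(skipped, " year(s) skipped: fewer than ", params$min_trees,
            " evaluable trees")
  events <- thin_events(cand[flags], params$min_event_gap)
  sup <- data.frame(year = events,
                    frac_latewood = frac_l[match(events, cand)],
                    frac_earlywood = frac_e[match(events, cand)])
  detection_result(collection$site_id, "pym", events, span, support = sup)
}

# year-by-tree matrix of seasonal RGC values (percent)
apply_rgc_matrix <- function(collection, fraction) {
  span <- site_span(collection)
  years <- seq.int(span[1L], span[2L])
  m <- matrix(NA_real_, length(years), length(collection$trees),
              dimnames = list(years, names(collection$trees)))
  for (tr in collection$trees)
    m[as.character(series_years(tr)), tr$tree_id] <-
      rgc(tr[[fraction]], missing = tr$missing)
  m
}

#' Merge per-site detections into regional events
#'
#' Pools the event years of several sites and clusters them by single linkage:
#' years whose chain-wise gaps are at most `tolerance` fall into one regional
#' event, reported by its earliest year and member sites.
#'
#' @param per_site list of [detection_result()] objects.
#' @param tolerance maximum year gap linking two events (default 2).
#' @return data frame with `year` (earliest of the cluster), `n_years`,
#'   `years` (collapsed string) and `sites`.
#' @export
merge_site_events <- function(per_site, tolerance = 2L) {
  if (inherits(per_site, "detection_result")) per_site <- list(per_site)
  tab <- do.call(rbind, lapply(per_site, function(d) {
    if (!length(d$event_years)) return(NULL)
    data.frame(site = d$site_id, year = d$event_years)
  }))
  if (is.null(tab))
    return(data.frame(year = integer(), n_years = integer(),
                      years = character(), sites = character()))
  tab <- tab[order(tab$year), , drop = FALSE]
  yrs <- sort(unique(tab$year))
  cluster <- cumsum(c(1L, diff(yrs) > tolerance))
  out <- do.call(rbind, lapply(split(yrs, cluster), function(ys) {
    sites <- sort(unique(tab$site[tab$year %in% ys]))
    data.frame(year = min(ys), n_years = length(ys),
               years = paste(ys, collapse = ","),
               sites = paste(sites, collapse = ","))
  }))
  rownames(out) <- NULL
  out
}
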