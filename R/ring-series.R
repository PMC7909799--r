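#' Seasonal ring-width series for one tree (or one core)
#'
#' Container for a dated sequence of earlywood, latewood and total ring widths.
#' Years are consecutive calendar years starting at `first_year` (a ring's year
#' is its growth year). Locally absent ("missing") rings are stored with width
#' 0 and `missing = TRUE`; they stay in the series so that dating is preserved,
#' but growth-change ratios at and next to them are undefined.
#'
#' @param tree_id character scalar identifying the tree.
#' @param first_year calendar year of the first ring.
#' @param earlywood,latewood numeric vectors of seasonal widths in mm.
#' @param total optional numeric vector of total ring widths in mm; defaults to
#'   `earlywood + latewood`. Where supplied it must agree with the seasonal sum
#'   to within 0.01 mm except at missing rings.
#' @param core_ids character vector of measurement core ids contributing to the
#'   series (one id for a raw core, several after per-tree averaging).
#' @param missing logical vector flagging locally absent rings.
#' @return An object of class `"season_series"`.
#' @export
season_series <- function(tree_id, first_year, earlywood, latewood,
                          total = NULL, core_ids = tree_id, missing = NULL) {
  n <- length(earlywood)
  if (n < 1L) stop("series must contain at least one ring")
  if (length(latewood) != n) stop("earlywood and latewood differ in length")
  if (is.null(total)) total <- earlywood + latewood
  if (length(total) != n) stop("total differs in length from seasonal vectors")
  if (is.null(missing)) missing <- rep(FALSE, n)
  missing <- as.logical(missing)
  if (length(missing) != n) stop("missing flags differ in length")
  if (anyNA(earlywood) || anyNA(latewood) || anyNA(total)) {
    stop("widths must not contain NA; use missing flags for absent rings")
  }
  if (any(earlywood < 0) || any(latewood < 0) || any(total < 0)) {
    stop("negative ring width in tree ", tree_id)
  }
  bad <- !missing & abs(total - (earlywood + latewood)) > 0.01
  if (any(bad)) {
    stop("total and earlywood + latewood disagree by more than 0.01 mm at year ",
         first_year + which(bad)[1L] - 1L, " of tree ", tree_id)
  }
  structure(
    list(tree_id = as.character(tree_id),
         core_ids = as.character(core_ids),
         first_year = as.integer(first_year),
         earlywood = as.numeric(earlywood),
         latewood = as.numeric(latewood),
         total = as.numeric(total),
         missing = missing),
    class = "season_series")
}

#' @export
print.season_series <- function(x, ...) {
  yr <- series_years(x)
  cat(sprintf("<season_series> tree %s: %d rings, %d-%d (%d cores, %d missing)\n",
              x$tree_id, length(x$total), min(yr), max(yr),
              length(x$core_ids), sum(x$missing)))
  invisible(x)
}

#' Calendar years covered by a series
#'
#' @param x a `season_series` or `index_series` object.
#' @return Integer vector of consecutive calendar years.
#' @export
series_years <- function(x) {
  n <- if (!is.null(x$total)) length(x$total) else length(x$values)
  seq.int(x$first_year, length.out = n)
}

#' Dimensionless growth-index series
#'
#' A dated vector of standardized (detrended) growth indices, as produced by
#' [baillie_pilcher_index()], [spline_detrend()], [double_detrend()] or
#' [site_chronology()]. Undefined indices (e.g. where a detrending curve hits
#' zero) are stored as `NA` and carried along as flags.
#'
#' @param first_year calendar year of the first value.
#' @param values numeric vector of indices (`NA` = undefined).
#' @param basis character scalar naming the standardization
#'   (`"baillie_pilcher"`, `"spline"`, `"double_detrend"`, `"zscore"`, `"raw"`).
#' @return An object of class `"index_series"`.
#' @export
index_series <- function(first_year, values, basis = "raw") {
  if (length(values) < 1L) stop("index series must have length >= 1")
  basis <- match.arg(basis,
                     c("baillie_pilcher", "spline", "double_detrend",
                       "zscore", "raw"))
  if (any(is.infinite(values))) stop("index values must be finite or NA")
  structure(list(first_year = as.integer(first_year),
                 values = as.numeric(values),
                 basis = basis),
            class = "index_series")
}

#' @export
print.index_series <- function(x, ...) {
  yr <- series_years(x)
  cat(sprintf("<index_series> basis %s: %d years, %d-%d (%d undefined)\n",
              x$basis, length(x$values), min(yr), max(yr),
              sum(is.na(x$values))))
  invisible(x)
}

#' Collection of per-tree series for one site
#'
#' Groups the screened per-tree [season_series()] objects of a sampling site
#' together with, optionally, the EPS-reliable span and a site chronology.
#'
#' @param site_id character scalar.
#' @param trees list of `season_series`, one per tree; tree ids must be unique.
#' @param reliable_span optional `c(first, last)` calendar years.
#' @param chronology optional `index_series` site chronology.
#' @return An object of class `"site_collection"`.
#' @export
site_collection <- function(site_id, trees, reliable_span = NULL,
                            chronology = NULL) {
  if (length(trees) < 1L) stop("a site needs at least one tree")
  ids <- vapply(trees, function(t) t$tree_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate tree ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(trees) <- ids
  span <- range(unlist(lapply(trees, series_years)))
  if (!is.null(reliable_span)) {
    reliable_span <- as.integer(reliable_span)
    if (length(reliable_span) != 2L || reliable_span[1L] > reliable_span[2L])
      stop("reliable_span must be c(first, last) with first <= last")
    if (reliable_span[1L] < span[1L] || reliable_span[2L] > span[2L])
      stop("reliable_span lies outside the union of tree spans")
  }
  structure(list(site_id = as.character(site_id), trees = trees,
                 reliable_span = reliable_span, chronology = chronology),
            class = "site_collection")
}

#' @export
print.site_collection <- function(x, ...) {
  span <- range(unlist(lapply(x$trees, series_years)))
  cat(sprintf("<site_collection> %s: %d trees, %d-%d\n",
              x$site_id, length(x$trees), span[1L], span[2L]))
  if (!is.null(x$reliable_span))
    cat(sprintf("  reliable span: %d-%d\n",
                x$reliable_span[1L], x$reliable_span[2L]))
  invisible(x)
}

#' Span of a site collection
#'
#' @param collection a `site_collection`.
#' @return `c(first, last)` calendar years of the union of tree spans.
#' @export
site_span <- function(collection) {
  as.integer(range(unlist(lapply(collection$trees, series_years))))
}

#' Extract one wood fraction of every tree as a year-by-tree matrix
#'
#' @param collection a `site_collection`.
#' @param fraction `"total"`, `"earlywood"` or `"latewood"`.
#' @param na_missing replace widths at missing rings with `NA` (default `TRUE`).
#' @return Numeric matrix with rownames = years, colnames = tree ids; years a
#'   tree does not cover are `NA`.
#' @export
site_matrix <- function(collection, fraction = c("total", "earlywood", "latewood"),
                        na_missing = TRUE) {
  fraction <- match.arg(fraction)
  span <- site_span(collection)
  years <- seq.int(span[1L], span[2L])
  m <- matrix(NA_real_, length(years), length(collection$trees),
              dimnames = list(years, names(collection$trees)))
  for (tr in collection$trees) {
    v <- tr[[fraction]]
    if (na_missing) v[tr$missing] <- NA_real_
    m[as.character(series_years(tr)), tr$tree_id] <- v
  }
  m
}

#' Detection result of one outbreak-reconstruction method
#'
#' @param site_id character scalar.
#' @param method one of `"pym"`, `"outbreak"`, `"mwm"`, `"mica"`.
#' @param event_years integer vector of inferred defoliation years (sorted).
#' @param support data frame of per-event supporting statistics (one row per
#'   event year), or `NULL`.
#' @param span `c(first, last)` years actually analyzed.
#' @param per_tree optional year-by-tree logical flag matrix.
#' @return An object of class `"detection_result"`.
#' @export
detection_result <- function(site_id, method, event_years, span,
                             support = NULL, per_tree = NULL) {
  method <- match.arg(method, c("pym", "outbreak", "mwm", "mica"))
  event_years <- as.integer(sort(event_years))
  if (length(event_years) &&
      (min(event_years) < span[1L] || max(event_years) > span[2L]))
    stop("event years outside the analyzed span")
  structure(list(site_id = site_id, method = method,
                 event_years = event_years, span = as.integer(span),
                 support = support, per_tree = per_tree),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> %s/%s, span %d-%d: %s\n",
              x$site_id, x$method, x$span[1L], x$span[2L],
              if (length(x$event_years)) paste(x$event_years, collapse = ", ")
              else "no events"))
  invisible(x)
}
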