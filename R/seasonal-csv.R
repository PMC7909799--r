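#' Read a long-format seasonal ring-width table
#'
#' Expects a CSV with columns `tree`, `core`, `year`, `earlywood`, `latewood`
#' (widths in mm) and assembles one [season_series()] per core, with
#' `total = earlywood + latewood`. An optional logical/0-1 column `missing`
#' flags locally absent rings.
#'
#' @param path path to the CSV file.
#' @return list of per-core `season_series` (the `tree_id` is the tree, the
#'   single `core_ids` entry the core); empty list (with a warning) for an
#'   empty table.
#' @export
read_seasonal_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tree", "core", "year", "earlywood", "latewood")
  if (!all(need %in% names(df)))
    stop("seasonal CSV must have columns ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("empty seasonal table: ", path)
    return(list())
  }
  if (any(df$earlywood < 0 | df$latewood < 0))
    stop("negative width in ", path)
  if (anyDuplicated(df[, c("core", "year")]))
    stop("duplicate (core, year) rows in ", path)
  has_missing <- "missing" %in% names(df)
  out <- list()
  for (core in unique(df$core)) {
    d <- df[df$core == core, , drop = FALSE]
    d <- d[order(d$year), , drop = FALSE]
    if (!all(diff(d$year) == 1L))
      stop("non-consecutive years in core ", core)
    if (length(unique(d$tree)) != 1L)
      stop("core ", core, " assigned to several trees")
    miss <- if (has_missing) as.logical(d$missing) else
      (d$earlywood == 0 & d$latewood == 0)
    out[[length(out) + 1L]] <-
      season_series(tree_id = d$tree[1L], first_year = d$year[1L],
                    earlywood = d$earlywood, latewood = d$latewood,
                    core_ids = as.character(core), missing = miss)
  }
  out
}

#' Write seasonal series to a long-format CSV
#'
#' @param series list of `season_series` (or one).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_seasonal_csv <- function(series, path) {
  if (inherits(series, "season_series")) series <- list(series)
  rows <- lapply(series, function(s) {
    data.frame(tree = s$tree_id, core = s$core_ids[1L],
               year = series_years(s), earlywood = s$earlywood,
               latewood = s$latewood, missing = as.integer(s$missing))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Average several cores of one tree into a single seasonal series
#'
#' Earlywood and latewood are averaged per calendar year over the cores that
#' cover that year (plain arithmetic mean); the total is recomputed as their
#' sum. Cores must jointly cover a contiguous span: if a core does not overlap
#' the span accumulated so far, averaging is refused rather than concatenating
#' across a gap. A year is flagged missing only if every covering core flags
#' it; a locally absent ring measured as 0 participates in the mean.
#'
#' @param cores list of `season_series` sharing one `tree_id`.
#' @return one `season_series` for the tree, with all core ids recorded.
#' @export
average_cores_per_tree <- function(cores) {
  if (inherits(cores, "season_series")) cores <- list(cores)
  if (length(cores) < 1L) stop("no cores supplied")
  ids <- unique(vapply(cores, `[[`, character(1), "tree_id"))
  if (length(ids) != 1L)
    stop("cores belong to different trees: ", paste(ids, collapse = ", "))
  ord <- order(vapply(cores, `[[`, integer(1), "first_year"))
  cores <- cores[ord]
  spans <- lapply(cores, series_years)
  if (length(cores) > 1L) {
    covered <- spans[[1L]]
    for (k in 2L:length(cores)) {
      if (!length(intersect(covered, spans[[k]])))
        stop("cores of tree ", ids, " share no overlapping years; ",
             "refusing to concatenate disjoint spans")
      covered <- union(covered, spans[[k]])
    }
  }
  years <- seq.int(min(unlist(spans)), max(unlist(spans)))
  acc <- function(field) {
    m <- matrix(NA_real_, length(years), length(cores))
    for (k in seq_along(cores))
      m[match(spans[[k]], years), k] <- cores[[k]][[field]]
    m
  }
  ew <- rowMeans(acc("earlywood"), na.rm = TRUE)
  lw <- rowMeans(acc("latewood"), na.rm = TRUE)
  missm <- matrix(NA, length(years), length(cores))
  for (k in seq_along(cores))
    missm[match(spans[[k]], years), k] <- cores[[k]]$missing
  miss <- apply(missm, 1L, function(r) all(r[!is.na(r)]))
  season_series(tree_id = ids, first_year = years[1L],
                earlywood = ew, latewood = lw,
                core_ids = unlist(lapply(cores, `[[`, "core_ids")),
                missing = miss)
}

#' Assemble a site collection from per-core seasonal series
#'
#' Groups cores by tree id, averages each tree's cores with
#' [average_cores_per_tree()], and wraps the result in a [site_collection()].
#'
#' @param site_id character scalar.
#' @param cores list of per-core `season_series`.
#' @return a `site_collection`.
#' @export
collect_site <- function(site_id, cores) {
  ids <- vapply(cores, `[[`, character(1), "tree_id")
  trees <- lapply(split(cores, ids), average_cores_per_tree)
  site_collection(site_id, unname(trees))
}

#' Read a monthly climate table
#'
#' CSV with columns `year`, `month`, `temperature` (monthly mean, deg C) and
#' `precipitation` (monthly sum, mm). Exactly one row per (year, month) and no
#' gaps inside the covered span are required.
#'
#' @param path path to the CSV file.
#' @return data frame of class `"climate_table"`.
#' @export
read_climate_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_climate_table(df)
}

#' Validate a monthly climate data frame
#'
#' @param df data frame with columns `year`, `month`, `temperature`,
#'   `precipitation`.
#' @return the validated data frame, classed `"climate_table"`.
#' @export
as_climate_table <- function(df) {
  need <- c("year", "month", "temperature", "precipitation")
  if (!all(need %in% names(df)))
    stop("climate table must have columns ", paste(need, collapse = ", "))
  if (any(df$month < 1 | df$month > 12)) stop("month outside 1..12")
  if (anyDuplicated(df[, c("year", "month")]))
    stop("duplicate (year, month) rows in climate table")
  df <- df[order(df$year, df$month), , drop = FALSE]
  full <- expand.grid(month = 1:12, year = seq(min(df$year), max(df$year)))
  # interior gaps are errors; a partial first/last year is tolerated
  interior <- full$year > min(df$year) & full$year < max(df$year)
  key <- paste(df$year, df$month)
  if (!all(paste(full$year[interior], full$month[interior]) %in% key))
    stop("gap inside the covered span of the climate table")
  class(df) <- c("climate_table", "data.frame")
  df
}
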