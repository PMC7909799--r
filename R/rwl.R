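#' Read a Tucson (RWL) decadal ring-width file
#'
#' Parses the standard dendrochronological interchange format: each line holds
#' a series id, the calendar year of the first value on the line, and up to ten
#' integer widths; a series ends with the stop marker `999` (units 0.01 mm) or
#' `-9999` (units 0.001 mm). The units are inferred per series from the marker.
#' Width 0 encodes a locally absent ring and is flagged missing.
#'
#' @param path path to the file.
#' @param kind which wood fraction the file holds; stored as an attribute and
#'   used by [read_seasonal_rwl()] when pairing files.
#' @return A list of single-core [season_series()] objects in mm. For
#'   `kind = "earlywood"`/`"latewood"` the other fraction is set to zero and
#'   `total` equals the stored fraction; such partial series are meant to be
#'   combined with [read_seasonal_rwl()].
#' @export
read_rwl <- function(path, kind = c("total", "earlywood", "latewood")) {
  kind <- match.arg(kind)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  series <- list()   # id -> list(decades = list(year, values), done)
  order_ids <- character()
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1L]]
    if (length(tok) < 3L)
      stop("malformed decade line ", i, " in ", path, ": fewer than 3 fields")
    id <- tok[1L]
    year <- suppressWarnings(as.integer(tok[2L]))
    vals <- suppressWarnings(as.numeric(tok[-(1:2)]))
    if (is.na(year) || anyNA(vals))
      stop("malformed decade line ", i, " in ", path, ": non-numeric field")
    if (!is.null(series[[id]]) && isTRUE(series[[id]]$done))
      stop("duplicate series id '", id, "' at line ", i, " in ", path)
    if (is.null(series[[id]])) {
      series[[id]] <- list(values = numeric(), start = year,
                           next_year = year, done = FALSE, divisor = NA_real_)
      order_ids <- c(order_ids, id)
    } else if (year != series[[id]]$next_year) {
      stop("malformed decade line ", i, " in ", path,
           ": expected start year ", series[[id]]$next_year, " for series ", id)
    }
    stop_at <- which(vals == 999 | vals == -9999)
    if (length(stop_at)) {
      marker <- vals[stop_at[1L]]
      series[[id]]$divisor <- if (marker == -9999) 1000 else 100
      vals <- vals[seq_len(stop_at[1L] - 1L)]
      series[[id]]$done <- TRUE
    }
    series[[id]]$values <- c(series[[id]]$values, vals)
    series[[id]]$next_year <- year + length(vals)
  }
  # Single-fraction files carry the measured widths in `total` (and, so the
  # seasonal-sum invariant holds, in `earlywood` for total/earlywood files or
  # `latewood` for latewood files, the other fraction being zero). The `kind`
  # attribute records what was measured; read_seasonal_rwl() reassembles full
  # seasonal series from an earlywood/latewood file pair.
  lapply(order_ids, function(id) {
    s <- series[[id]]
    div <- if (is.na(s$divisor)) 100 else s$divisor
    w <- s$values / div
    miss <- s$values == 0
    zero <- rep(0, length(w))
    ss <- season_series(tree_id = id, first_year = s$start,
                        earlywood = if (kind == "latewood") zero else w,
                        latewood = if (kind == "latewood") w else zero,
                        total = w, core_ids = id, missing = miss)
    attr(ss, "kind") <- kind
    ss
  })
}

#' Write series to a Tucson (RWL) decadal file
#'
#' Inverse of [read_rwl()]. Values are rounded to the format precision
#' (0.01 mm with stop marker 999, 0.001 mm with marker -9999).
#'
#' @param series list of `season_series` (or a single one).
#' @param path output path.
#' @param kind wood fraction to write (`total`, `earlywood`, `latewood`).
#' @param units `"0.01"` or `"0.001"` mm; selects the stop marker.
#' @return `path`, invisibly.
#' @export
write_rwl <- function(series, path, kind = c("total", "earlywood", "latewood"),
                      units = c("0.01", "0.001")) {
  kind <- match.arg(kind)
  units <- match.arg(units)
  if (inherits(series, "season_series")) series <- list(series)
  mult <- if (units == "0.01") 100 else 1000
  marker <- if (units == "0.01") "999" else "-9999"
  con <- file(path, "w")
  on.exit(close(con))
  for (s in series) {
    w <- round(s[[kind]] * mult)
    w[s$missing] <- 0
    years <- series_years(s)
    vals <- c(as.character(w), marker)
    yrs <- c(years, max(years) + 1L)
    pos <- 1L
    while (pos <= length(vals)) {
      y <- yrs[pos]
      n_in_decade <- 10L - (y %% 10L)   # fill to the end of the decade
      if (n_in_decade == 0L) n_in_decade <- 10L
      take <- min(n_in_decade, length(vals) - pos + 1L)
      block <- vals[pos:(pos + take - 1L)]
      writeLines(paste(c(sprintf("%-8s", s$tree_id), y, block), collapse = " "),
                 con)
      pos <- pos + take
    }
  }
  invisible(path)
}

#' Read paired earlywood/latewood RWL files into seasonal series
#'
#' Matches series ids across the two files, requires identical spans, and
#' assembles full seasonal series with `total = earlywood + latewood`.
#'
#' @param ew_path,lw_path paths to the earlywood and latewood RWL files.
#' @return list of [season_series()].
#' @export
read_seasonal_rwl <- function(ew_path, lw_path) {
  ew <- read_rwl(ew_path, "earlywood")
  lw <- read_rwl(lw_path, "latewood")
  ids_e <- vapply(ew, `[[`, character(1), "tree_id")
  ids_l <- vapply(lw, `[[`, character(1), "tree_id")
  common <- intersect(ids_e, ids_l)
  if (!length(common)) stop("no common series ids between the two files")
  miss <- setdiff(union(ids_e, ids_l), common)
  if (length(miss)) warning("series present in only one file dropped: ",
                            paste(miss, collapse = ", "))
  lapply(common, function(id) {
    e <- ew[[match(id, ids_e)]]
    l <- lw[[match(id, ids_l)]]
    if (e$first_year != l$first_year || length(e$total) != length(l$total))
      stop("earlywood and latewood spans differ for series ", id)
    season_series(tree_id = id, first_year = e$first_year,
                  earlywood = e$total, latewood = l$total,
                  core_ids = id, missing = e$missing | l$missing)
  })
}
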