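#' Documented reference outbreak windows
#'
#' @param windows list of `c(first, last)` year pairs (or a 2-column matrix);
#'   must be sorted and non-overlapping.
#' @param match_lead years a detection may precede a window and still count as
#'   a hit (default 2).
#' @return list of class `"reference_outbreaks"`.
#' @export
reference_outbreaks <- function(windows, match_lead = 2L) {
  if (is.matrix(windows))
    windows <- lapply(seq_len(nrow(windows)), function(i) windows[i, ])
  windows <- lapply(windows, as.integer)
  ok <- all(vapply(windows, function(w) length(w) == 2L && w[1L] <= w[2L],
                   logical(1)))
  if (!ok) stop("each window must be c(first, last) with first <= last")
  starts <- vapply(windows, `[[`, integer(1), 1L)
  ends <- vapply(windows, `[[`, integer(1), 2L)
  o <- order(starts)
  windows <- windows[o]; starts <- starts[o]; ends <- ends[o]
  if (length(windows) > 1L && any(starts[-1L] <= ends[-length(ends)]))
    stop("windows overlap")
  structure(list(windows = windows, match_lead = as.integer(match_lead)),
            class = "reference_outbreaks")
}

#' The outbreak windows documented for the Biysk pine forest
#'
#' The two pine looper outbreaks recorded by the regional Forest Protection
#' Center, 1996-1999 and 2003-2008, used for detector calibration.
#'
#' @param match_lead years a detection may precede a window (default 2).
#' @return a [reference_outbreaks()] object.
#' @export
documented_outbreaks <- function(match_lead = 2L) {
  reference_outbreaks(list(c(1996L, 1999L), c(2003L, 2008L)), match_lead)
}

#' Score detected events against documented outbreak windows
#'
#' A window counts as hit when at least one event year falls inside
#' `[first - match_lead, last]`; each event is credited to at most one window
#' (windows take, greedily in chronological order, the earliest unused
#' qualifying event). Events crediting no window are false positives.
#'
#' @param detection a [detection_result()] or an integer vector of event
#'   years.
#' @param reference a [reference_outbreaks()] object.
#' @return list with `true_positives`, `false_negatives`, `false_positives`
#'   and the logical `hit` vector per window.
#' @export
score_params <- function(detection, reference) {
  events <- if (inherits(detection, "detection_result"))
    detection$event_years else as.integer(sort(detection))
  used <- rep(FALSE, length(events))
  hit <- logical(length(reference$windows))
  for (i in seq_along(reference$windows)) {
    w <- reference$windows[[i]]
    cand <- which(!used & events >= w[1L] - reference$match_lead &
                    events <= w[2L])
    if (length(cand)) {
      used[cand[1L]] <- TRUE
      hit[i] <- TRUE
    }
  }
  list(true_positives = sum(hit), false_negatives = sum(!hit),
       false_positives = sum(!used), hit = hit)
}

# direction of increasing stringency (fewer detections) per parameter
stringency_direction <- c(
  change_l = -1, sync_l = 1, change_e = -1, sync_e = 1,  # pym (drop semantics)
  width = 1, perc = 1,                                   # mwm
  std = 1, lng = 1, abrupt = -1, min_tree_prop = 1,      # outbreak
  lim = -1, q = -1, rng = -1                             # mica
)

#' Grid-search calibration of a detector against documented outbreaks
#'
#' Evaluates the detector on every parameter combination of the grid. For
#' `pym`, `mwm` and `mica` the objective is lexicographic: maximize the number
#' of documented windows hit, then minimize false positives, then prefer the
#' most stringent thresholds; remaining ties break by grid order. For
#' `outbreak` the objective is the mean flagged-tree proportion inside the
#' reference windows, among combinations hitting all windows. When no
#' combination hits every window the best effort is returned with a warning.
#'
#' @param method `"pym"`, `"outbreak"`, `"mwm"` or `"mica"`.
#' @param collection a [site_collection()].
#' @param reference a [reference_outbreaks()] object.
#' @param grid named list of candidate values per parameter (names as in the
#'   corresponding `*_params()` constructor).
#' @param ... further fixed arguments passed to the detector.
#' @return list with `best` (parameter list), `best_result` (the detection),
#'   `table` (data frame of every combination with its scores).
#' @export
grid_search <- function(method = c("pym", "outbreak", "mwm", "mica"),
                        collection, reference, grid, ...) {
  method <- match.arg(method)
  if (!length(grid) || !all(lengths(grid) > 0)) stop("empty grid")
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  make <- switch(method, pym = pym_params, outbreak = outbreak_params,
                 mwm = mwm_params, mica = mica_params)
  detect <- switch(method,
                   pym = function(p, ...) pym_detect(collection, p, ...),
                   outbreak = function(p, ...) outbreak_detect(collection, p, ...),
                   mwm = function(p, ...) mwm_detect(collection, p, ...),
                   mica = function(p, ...) mica_detect_site(collection, p, ...))
  rows <- vector("list", nrow(combos))
  dets <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    pars <- do.call(make, as.list(combos[i, , drop = FALSE]))
    det <- suppressWarnings(detect(pars, ...))
    sc <- score_params(det, reference)
    extra <- 0
    if (method == "outbreak") {
      win_years <- unlist(lapply(reference$windows,
                                 function(w) seq.int(w[1L], w[2L])))
      pt <- det$per_tree
      inwin <- rownames(pt) %in% as.character(win_years)
      extra <- if (any(inwin)) mean(rowMeans(pt[inwin, , drop = FALSE])) else 0
    }
    rows[[i]] <- cbind(combos[i, , drop = FALSE],
                       data.frame(hits = sc$true_positives,
                                  false_positives = sc$false_positives,
                                  n_events = length(det$event_years),
                                  mean_prop_in_windows = extra))
    dets[[i]] <- det
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  sv <- vapply(names(grid), function(p) {
    d <- stringency_direction[[p]]
    if (is.null(d) || is.na(d)) d <- 0
    d * rank(tab[[p]], ties.method = "average")
  }, numeric(nrow(tab)))
  stringency <- rowSums(matrix(sv, nrow = nrow(tab)))
  full <- tab$hits == length(reference$windows)
  if (!any(full))
    warning("no parameter combination hits every documented window; ",
            "returning the best effort")
  ord <- if (method == "outbreak") {
    order(-tab$hits, -tab$mean_prop_in_windows, seq_len(nrow(tab)))
  } else {
    order(-tab$hits, tab$false_positives, -stringency, seq_len(nrow(tab)))
  }
  best_i <- ord[1L]
  list(best = as.list(combos[best_i, , drop = FALSE]),
       best_result = dets[[best_i]], table = tab)
}

#' Published per-site optimal detector parameters
#'
#' The calibrated parameter values for the three Biysk pine forest reference
#' sites (Zarech'e, Sokolovo, Lesnoye): PYM `change.l`/`sync.l`/`change.e`/
#' `sync.e`, MWM `width`/`perc`, OUTBREAK `std`/`lng`/`abrupt`, MICA
#' `lim`/`lng`/`q`/`rng`.
#'
#' @param site `"zareche"`, `"sokolovo"` or `"lesnoye"`.
#' @param method `"pym"`, `"mwm"`, `"outbreak"` or `"mica"`.
#' @return the matching `*_params()` object.
#' @export
reference_params <- function(site = c("zareche", "sokolovo", "lesnoye"),
                             method = c("pym", "mwm", "outbreak", "mica")) {
  site <- match.arg(site)
  method <- match.arg(method)
  p <- switch(site,
    zareche = list(
      pym = pym_params(10, 55, 10, 55),
      mwm = mwm_params(3, 0.35),
      outbreak = outbreak_params(0.6, 2, 0.8),
      mica = mica_params(-1.3, 3, 0.2, 2)),
    sokolovo = list(
      pym = pym_params(10, 50, 10, 50),
      mwm = mwm_params(4, 0.25),
      outbreak = outbreak_params(0.5, 2, 0.8),
      mica = mica_params(-0.8, 2, 0.2, 2)),
    lesnoye = list(
      pym = pym_params(15, 55, 10, 65),
      mwm = mwm_params(3, 0.30),
      outbreak = outbreak_params(0.5, 2, 0.8),
      mica = mica_params(-0.9, 2, 0.1, 4)))
  p[[method]]
}
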