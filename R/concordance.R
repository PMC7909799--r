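#' Lag-tolerant matching of pointer-year events against another method
#'
#' Every year of the analyzed span is classified into the 2x2 contingency
#' layout: a pointer-year event year `t` counts as concordant (A) when an
#' unconsumed event of the other method lies within `[t + lag[1], t + lag[2]]`
#' (the reference detectors respond to the ring-width minimum, which trails
#' defoliation by up to four years); matching is greedy, earliest pointer
#' year first, consuming the earliest qualifying event. Unmatched pointer
#' years are B, unconsumed other-method events are C (counted at their own
#' year), and every remaining span year is D.
#'
#' @param pym_events integer years detected by the pointer-year method (or a
#'   [detection_result()]).
#' @param other_events integer years of the other method (or a
#'   `detection_result`).
#' @param span `c(first, last)` years of the analyzed interval.
#' @param lag_window allowed lag range of the other method behind a pointer
#'   year, default `c(0, 4)`.
#' @return a `confusion_table` (see [confusion_table()]); its `pairs` element
#'   records the matched year pairs.
#' @export
match_events <- function(pym_events, other_events, span, lag_window = c(0, 4)) {
  if (inherits(pym_events, "detection_result"))
    pym_events <- pym_events$event_years
  if (inherits(other_events, "detection_result"))
    other_events <- other_events$event_years
  pym_events <- sort(as.integer(pym_events))
  other_events <- sort(as.integer(other_events))
  n_years <- span[2L] - span[1L] + 1L
  if (n_years < 1L) stop("empty span")
  if (length(pym_events) &&
      (min(pym_events) < span[1L] || max(pym_events) > span[2L]))
    stop("pointer-year events outside the span")
  used <- rep(FALSE, length(other_events))
  matched <- rep(FALSE, length(pym_events))
  pairs <- NULL
  for (i in seq_along(pym_events)) {
    t <- pym_events[i]
    cand <- which(!used & other_events >= t + lag_window[1L] &
                    other_events <= t + lag_window[2L])
    if (length(cand)) {
      used[cand[1L]] <- TRUE
      matched[i] <- TRUE
      pairs <- rbind(pairs, data.frame(pym = t, other = other_events[cand[1L]]))
    }
  }
  A <- sum(matched)
  B <- sum(!matched)
  C <- sum(!used)
  D <- n_years - A - B - C
  ct <- confusion_table(A, B, C, D)
  ct$pairs <- pairs
  ct$span <- as.integer(span)
  ct
}

#' 2x2 contingency table of method agreement
#'
#' Layout: A = both methods positive, B = pointer-year method positive only,
#' C = other method positive only, D = both negative. Accuracy, sensitivity
#' and specificity, Fisher's exact test and (after [by_adjust()]) corrected
#' p-values hang off this object.
#'
#' @param A,B,C,D non-negative integer counts.
#' @return list of class `"confusion_table"` with the counts and `acc`,
#'   `sens`, `spec` (NA where the margin is empty) and `fisher_p`.
#' @export
confusion_table <- function(A, B, C, D) {
  counts <- c(A = A, B = B, C = C, D = D)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  m <- confusion_metrics(list(A = A, B = B, C = C, D = D))
  structure(list(A = A, B = B, C = C, D = D,
                 acc = m$acc, sens = m$sens, spec = m$spec,
                 fisher_p = fisher_exact(A, B, C, D)),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("<confusion_table> A=%d B=%d C=%d D=%d | acc %.3f sens %s spec %s | Fisher p = %.4g\n",
              x$A, x$B, x$C, x$D, x$acc,
              ifelse(is.na(x$sens), "NA", sprintf("%.3f", x$sens)),
              ifelse(is.na(x$spec), "NA", sprintf("%.3f", x$spec)),
              x$fisher_p))
  invisible(x)
}

#' Accuracy, sensitivity and specificity of a 2x2 table
#'
#' `acc = (A+D)/N`, `sens = A/(A+B)`, `spec = D/(C+D)`; a metric with an
#' empty margin is `NA`.
#'
#' @param table a `confusion_table` or a list/vector with A, B, C, D.
#' @return list with `acc`, `sens`, `spec`.
#' @export
confusion_metrics <- function(table) {
  A <- table$A; B <- table$B; C <- table$C; D <- table$D
  n <- A + B + C + D
  list(acc = if (n > 0) (A + D) / n else NA_real_,
       sens = if (A + B > 0) A / (A + B) else NA_real_,
       spec = if (C + D > 0) D / (C + D) else NA_real_)
}

#' Two-sided Fisher exact test of a 2x2 table
#'
#' Sum of the probabilities of all tables with the observed margins whose
#' hypergeometric probability does not exceed the observed one. A table with
#' a zero margin has p = 1.
#'
#' @param A,B,C,D non-negative counts; alternatively `A` may be a
#'   `confusion_table` or 2x2 matrix.
#' @return the two-sided p-value.
#' @export
fisher_exact <- function(A, B = NULL, C = NULL, D = NULL) {
  if (inherits(A, "confusion_table")) {
    m <- matrix(c(A$A, A$C, A$B, A$D), 2L)
  } else if (is.matrix(A)) {
    m <- A
  } else {
    m <- matrix(c(A, C, B, D), 2L)
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
  stats::fisher.test(m)$p.value
}

#' Benjamini-Yekutieli correction of a p-value family
#'
#' Step-up false-discovery-rate adjustment valid under arbitrary dependence,
#' with the harmonic-sum inflation `c(m) = sum(1/i)`. Adjusted values are
#' monotone in rank and capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as `p`.
#' @export
by_adjust <- function(p) {
  if (!length(p)) stop("empty p-value vector")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  stats::p.adjust(p, method = "BY")
}

#' Concordance report between pointer-year events and the other methods
#'
#' Runs [match_events()] for each listed method, assembles the contingency
#' tables and metrics, and applies the Benjamini-Yekutieli correction across
#' the whole family of tests.
#'
#' @param pym a [detection_result()] from [pym_detect()].
#' @param others named list of `detection_result` objects.
#' @param span analyzed span (default the pointer-year result's span).
#' @param lag_window see [match_events()].
#' @return data frame with one row per method: counts, acc/sens/spec, raw and
#'   adjusted Fisher p; the tables themselves as attribute `"tables"`.
#' @export
concordance_report <- function(pym, others, span = NULL,
                               lag_window = c(0, 4)) {
  if (is.null(span)) span <- pym$span
  tabs <- lapply(others, function(o)
    match_events(pym, o, span = span, lag_window = lag_window))
  df <- do.call(rbind, lapply(names(tabs), function(nm) {
    t <- tabs[[nm]]
    data.frame(method = nm, A = t$A, B = t$B, C = t$C, D = t$D,
               acc = t$acc, sens = t$sens, spec = t$spec,
               fisher_p = t$fisher_p)
  }))
  df$adjusted_p <- by_adjust(df$fisher_p)
  attr(df, "tables") <- tabs
  df
}
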