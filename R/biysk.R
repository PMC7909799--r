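#' Published Biysk pine forest reconstruction reference data
#'
#' The pointer-year defoliation chronology reported for three Scots pine
#' sites in the Biysk pine forest (Zarech'e: 7 events 1949-2001; Sokolovo: 9
#' events 1915-2002; Lesnoye: 5 events 1949-1995) and, per site and reference
#' method, how many of those events the method confirmed (an event counts as
#' confirmed when the method detects a growth reduction in the event year or
#' up to four years after). For the independent-component method at Zarech'e
#' the analyzed interval starts in 1967, so only the 5 events inside it enter
#' its denominator.
#'
#' @param what `"events"` for the per-site event years, `"confirmations"`
#'   for the per-method confirmation counts.
#' @return data frame.
#' @export
biysk_reference <- function(what = c("events", "confirmations")) {
  what <- match.arg(what)
  f <- system.file("extdata",
                   if (what == "events") "biysk_pym_events.csv"
                   else "biysk_confirmations.csv",
                   package = "seasonwood", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

#' Event-level sensitivity of the reference methods
#'
#' Reduces each site-by-method confirmation count to a 2x2 table (confirmed
#' events = A, unconfirmed = B) via [confusion_table()] and reports the
#' resulting sensitivity `A / (A + B)`, the confirmed fraction of
#' pointer-year events.
#'
#' @return data frame with `site`, `method`, `sens`.
#' @export
biysk_sensitivity <- function() {
  conf <- biysk_reference("confirmations")
  sens <- vapply(seq_len(nrow(conf)), function(i) {
    A <- conf$n_confirmed[i]
    B <- conf$n_events[i] - A
    confusion_metrics(confusion_table(A, B, 0L, 0L))$sens
  }, numeric(1))
  data.frame(site = conf$site, method = conf$method, sens = sens)
}
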