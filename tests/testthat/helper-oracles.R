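# Independent brute-force oracles and small fixture builders. These
# deliberately re-derive results by direct enumeration/counting, separate
# from the package's implementations.

# --- fixture builders -------------------------------------------------------

# a site of flat seasonal series with optional multiplicative season drops:
# drops = list(list(year=, trees=, latewood=frac, earlywood=frac))
flat_site <- function(n_trees = 20, n_years = 60, first_year = 1901,
                      ew = 0.7, lw = 0.3, drops = list()) {
  trees <- lapply(seq_len(n_trees), function(i) {
    e <- rep(ew, n_years)
    l <- rep(lw, n_years)
    for (d in drops) {
      if (!(i %in% d$trees)) next
      j <- d$year - first_year + 1
      if (!is.null(d$latewood)) l[j] <- l[j] * (1 - d$latewood)
      if (!is.null(d$earlywood)) e[j] <- e[j] * (1 - d$earlywood)
    }
    season_series(sprintf("T%02d", i), first_year, e, l)
  })
  site_collection("fixture", trees)
}

# --- pointer-year oracle ----------------------------------------------------

# direct per-year counting of threshold passes (drop semantics)
pym_oracle <- function(collection, change_l, sync_l, change_e, sync_e,
                       min_trees = 5, gap = 2) {
  span <- site_span(collection)
  years <- seq(span[1], span[2])
  lw <- sapply(collection$trees, function(tr)
    rgc(tr$latewood, missing = tr$missing)[match(years, series_years(tr))])
  ew <- sapply(collection$trees, function(tr)
    rgc(tr$earlywood, missing = tr$missing)[match(years, series_years(tr))])
  flagged <- c()
  for (t in years) {
    i1 <- match(t + 1, years); i2 <- match(t + 2, years)
    if (is.na(i1) || is.na(i2)) next
    vl <- lw[i1, ]; ve <- ew[i2, ]
    nl <- sum(!is.na(vl)); ne <- sum(!is.na(ve))
    if (nl < min_trees || ne < min_trees) next
    if (sum(vl <= 100 - change_l, na.rm = TRUE) / nl >= sync_l / 100 &&
        sum(ve <= 100 - change_e, na.rm = TRUE) / ne >= sync_e / 100)
      flagged <- c(flagged, t)
  }
  keep <- c(); last <- -Inf
  for (y in flagged) if (y - last >= gap) { keep <- c(keep, y); last <- y }
  as.integer(keep)
}

# --- OUTBREAK oracle --------------------------------------------------------

outbreak_tree_oracle <- function(v, std, lng, abrupt) {
  n <- length(v)
  flags <- rep(FALSE, n)
  s <- stats::sd(v)
  if (s == 0) return(flags)
  thr <- mean(v) - std * s
  for (t in 2:n) {
    if (t + lng - 1 > n) next
    if (all(v[t:(t + lng - 1)] <= thr) && v[t] / v[t - 1] <= abrupt)
      flags[t] <- TRUE
  }
  flags
}

# --- moving-window oracle ---------------------------------------------------

mwm_oracle <- function(w, width) {
  n <- length(w)
  flags <- rep(FALSE, n)
  for (t in seq_len(n)) {
    if (t - width < 1 || t + width > n) next
    win <- w[(t - width):(t + width)]
    # strictly smaller than every other width: nothing below it and no tie
    flags[t] <- sum(win < w[t]) == 0 && sum(win == w[t]) == 1
  }
  flags
}

# --- Fisher exact oracle ----------------------------------------------------

# two-sided p by full enumeration over tables with the observed margins
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(ks, r1, n - r1, c1)
  p_obs <- stats::dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# --- event-matching oracle --------------------------------------------------

match_oracle <- function(pym, other, span, lag = c(0, 4)) {
  pym <- sort(pym); other <- sort(other)
  used <- rep(FALSE, length(other))
  A <- 0
  for (t in pym) {
    cand <- which(!used & other >= t + lag[1] & other <= t + lag[2])
    if (length(cand)) { used[cand[1]] <- TRUE; A <- A + 1 }
  }
  B <- length(pym) - A
  C <- sum(!used)
  D <- (span[2] - span[1] + 1) - A - B - C
  c(A = A, B = B, C = C, D = D)
}

# --- window-scoring oracle --------------------------------------------------

score_oracle <- function(events, windows, lead) {
  events <- sort(events)
  used <- rep(FALSE, length(events))
  hits <- 0
  for (w in windows) {
    cand <- which(!used & events >= w[1] - lead & events <= w[2])
    if (length(cand)) { used[cand[1]] <- TRUE; hits <- hits + 1 }
  }
  c(tp = hits, fn = length(windows) - hits, fp = sum(!used))
}
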