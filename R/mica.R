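# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Parameters of the independent-component detector
#'
#' @param lim component threshold in standardized units (typically negative);
#'   a run needs component values strictly below `lim`.
#' @param lng minimum run length in years.
#' @param q quantile (unit fraction) of the detrended site chronology used to
#'   confirm a run.
#' @param rng maximum offset in years between a component run and a
#'   chronology low.
#' @param n_components number of components, or `NULL` (default) for the
#'   smallest number of principal components explaining at least 80 percent of
#'   the variance, capped at 5.
#' @param seed integer seed for the ICA initialization (default 1).
#' @return list of class `"mica_params"`.
#' @export
mica_params <- function(lim = -1.3, lng = 3L, q = 0.2, rng = 2L,
                        n_components = NULL, seed = 1L) {
  stopifnot(lng >= 1L, q > 0, q < 1, rng >= 0)
  structure(list(lim = lim, lng = as.integer(lng), q = q,
                 rng = as.integer(rng), n_components = n_components,
                 seed = as.integer(seed)),
            class = "mica_params")
}

#' Standardize a site to its common span as a year-by-tree z-score matrix
#'
#' Truncates every series to the latest common start year (the early sections
#' of longer series are removed, as required for a rectangular decomposition)
#' and scales each tree to zero mean, unit standard deviation.
#'
#' @param collection a [site_collection()].
#' @param min_years minimum common span (default 30).
#' @return numeric matrix (years x trees) with attribute `removed_years`, a
#'   named vector of the number of early years dropped per tree.
#' @export
standardize_matrix <- function(collection, min_years = 30L) {
  if (length(collection$trees) < 5L) stop("needs at least 5 trees")
  firsts <- vapply(collection$trees, `[[`, integer(1), "first_year")
  lasts <- vapply(collection$trees, function(t) max(series_years(t)), integer(1))
  from <- max(firsts)
  to <- min(lasts)
  if (to - from + 1L < min_years)
    stop("common span shorter than ", min_years, " years")
  years <- seq.int(from, to)
  m <- matrix(NA_real_, length(years), length(collection$trees),
              dimnames = list(years, names(collection$trees)))
  for (tr in collection$trees)
    m[, tr$tree_id] <- tr$total[match(years, series_years(tr))]
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance series: ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  z <- scale(m)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  attr(z, "removed_years") <- stats::setNames(from - firsts, names(firsts))
  z
}

#' Fixed-point independent component analysis of a standardized matrix
#'
#' Symmetric FastICA-style decomposition: the matrix is whitened by singular
#' value decomposition, an orthogonal unmixing matrix is estimated by the
#' fixed-point iteration with the `tanh` contrast, and the component time
#' series are rescaled to unit variance. The sign of each component is
#' oriented so that it correlates positively with the mean standardized
#' series, making "decrease below a threshold" well defined. Deterministic
#' for a fixed seed.
#'
#' @param z standardized year-by-tree matrix ([standardize_matrix()] output).
#' @param n_components number of components (`NULL`: principal components
#'   explaining 80 percent of variance, capped at 5).
#' @param seed integer seed for the random initial unmixing matrix.
#' @param maxit,tol fixed-point iteration controls.
#' @return list with `components` (years x k matrix, year rownames),
#'   `mixing` (trees x k), `n_components`, `iterations`.
#' @export
ica_decompose <- function(z, n_components = NULL, seed = 1L,
                          maxit = 500L, tol = 1e-5, restarts = 3L) {
  n <- nrow(z)
  p <- ncol(z)
  if (is.null(n_components)) {
    ev <- svd(z, nu = 0, nv = 0)$d^2
    n_components <- min(5L, which(cumsum(ev) / sum(ev) >= 0.80)[1L])
  }
  k <- n_components
  if (k > p) stop("more components than trees")
  sv <- svd(scale(z, scale = FALSE), nu = k, nv = 0)
  Z <- sv$u * sqrt(n - 1)             # whitened scores, cov = I
  orth <- function(M) {
    s <- svd(M)
    s$u %*% t(s$v)
  }
  W <- NULL
  it <- 0L
  for (attempt in 0:restarts) {
    W <- orth(with_seed(seed + 1000L * attempt,
                        matrix(stats::rnorm(k * k), k, k)))
    it <- 0L
    converged <- FALSE
    while (it < maxit) {
      it <- it + 1L
      S <- Z %*% W
      G <- tanh(S)
      W1 <- orth(crossprod(Z, G) / n -
                   W * matrix(colMeans(1 - G^2), k, k, byrow = TRUE))
      delta <- max(abs(abs(diag(crossprod(W1, W))) - 1))
      W <- W1
      if (delta < tol) { converged <- TRUE; break }
    }
    if (converged) break
    if (attempt == restarts)
      stop("ICA did not converge in ", maxit, " iterations (",
           restarts + 1L, " starts); try another seed or fewer components")
  }
  S <- Z %*% W
  S <- scale(S)
  attr(S, "scaled:center") <- NULL
  attr(S, "scaled:scale") <- NULL
  ref <- rowMeans(z)
  for (j in seq_len(k)) {
    r <- stats::cor(S[, j], ref)
    if (!is.na(r) && r < 0) S[, j] <- -S[, j]
  }
  rownames(S) <- rownames(z)
  mixing <- crossprod(z, S) / (n - 1)   # correlation-scale loadings
  list(components = S, mixing = mixing, n_components = k, iterations = it)
}

# maximal runs of TRUE of length >= lng: data.frame(start_i, end_i)
runs_of <- function(flag, lng) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & r$lengths >= lng
  data.frame(start = starts[ok], end = ends[ok])
}

#' Independent-component detection of defoliation runs
#'
#' Scans every component for maximal runs of at least `lng` consecutive years
#' strictly below `lim`; a run is confirmed when the detrended site chronology
#' falls below its `q`-quantile (computed over the analyzed span) within
#' `rng` years of the run. Confirmed overlapping runs are merged and each is
#' reported by its start year.
#'
#' @param components years x k component matrix ([ica_decompose()] output).
#' @param site_index an [index_series()] site chronology covering the same
#'   span (spline-detrended).
#' @param params a [mica_params()] object.
#' @param site_id site label for the result (default `"site"`).
#' @return a [detection_result()]; `support` holds the run extent and the
#'   offset to the nearest chronology low.
#' @export
mica_detect <- function(components, site_index, params = mica_params(),
                        site_id = "site") {
  years <- as.integer(rownames(components))
  idx_years <- series_years(site_index)
  common <- intersect(years, idx_years)
  if (!length(common)) stop("components and chronology share no years")
  chron <- site_index$values[match(common, idx_years)]
  qthr <- stats::quantile(chron, params$q, na.rm = TRUE, names = FALSE)
  low_years <- common[!is.na(chron) & chron < qthr]
  allruns <- NULL
  for (j in seq_len(ncol(components))) {
    rn <- runs_of(components[, j] < params$lim, params$lng)
    if (nrow(rn))
      allruns <- rbind(allruns,
                       data.frame(start = years[rn$start], end = years[rn$end]))
  }
  events <- integer()
  sup <- NULL
  if (!is.null(allruns)) {
    confirmed <- allruns[vapply(seq_len(nrow(allruns)), function(i) {
      any(low_years >= allruns$start[i] - params$rng &
          low_years <= allruns$end[i] + params$rng)
    }, logical(1)), , drop = FALSE]
    if (nrow(confirmed)) {
      confirmed <- confirmed[order(confirmed$start, confirmed$end), , drop = FALSE]
      merged <- confirmed[1L, , drop = FALSE]
      for (i in seq_len(nrow(confirmed))[-1L]) {
        last <- nrow(merged)
        if (confirmed$start[i] <= merged$end[last]) {
          merged$end[last] <- max(merged$end[last], confirmed$end[i])
        } else {
          merged <- rbind(merged, confirmed[i, ])
        }
      }
      events <- merged$start
      sup <- data.frame(year = merged$start, run_end = merged$end)
    }
  }
  detection_result(site_id, "mica", events, range(common), support = sup)
}

#' Full independent-component pipeline for a site
#'
#' Standardizes the site to its common span, decomposes it with
#' [ica_decompose()], builds the spline-detrended site chronology over the
#' same span, and runs [mica_detect()]. Bit-reproducible for a fixed seed.
#'
#' @param collection a [site_collection()].
#' @param params a [mica_params()] object (its `seed` drives the ICA).
#' @param stiffness spline stiffness for the confirmation chronology.
#' @return a [detection_result()].
#' @export
mica_detect_site <- function(collection, params = mica_params(),
                             stiffness = 0.67) {
  z <- standardize_matrix(collection)
  # When the requested component count exceeds the number of genuinely
  # non-Gaussian sources the fixed-point iteration can cycle without
  # converging; retry deterministically with fewer components.
  dec <- NULL
  k_try <- params$n_components
  repeat {
    dec <- tryCatch(ica_decompose(z, n_components = k_try,
                                  seed = params$seed),
                    error = function(e) e)
    if (!inherits(dec, "error")) break
    k_prev <- if (is.null(k_try)) attr(dec, "k") else k_try
    k_now <- if (is.null(k_try)) NULL else k_try - 1L
    if (is.null(k_try)) {
      ev <- svd(z, nu = 0, nv = 0)$d^2
      k_now <- min(5L, which(cumsum(ev) / sum(ev) >= 0.80)[1L]) - 1L
    }
    if (k_now < 2L) stop(dec)
    warning("ICA not converged; retrying with ", k_now, " components")
    k_try <- k_now
  }
  years <- as.integer(rownames(z))
  idx <- lapply(collection$trees, function(tr) {
    keep <- series_years(tr) %in% years
    spline_detrend(tr$total[keep], stiffness = stiffness,
                   first_year = years[1L], missing = tr$missing[keep])
  })
  chron <- site_chronology(idx)
  res <- mica_detect(dec$components, chron, params, collection$site_id)
  res$n_components <- dec$n_components
  res
}
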