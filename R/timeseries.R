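#' Aggregate per-cell records into condition-level time series
#'
#' Computes, per condition and per parameter, the population mean and
#' sample standard deviation (n-1 denominator) over all cells present at
#' each cycle, together with the cell count. Cycles with no cells are
#' filled by last observation carried forward and flagged in `filled`.
#'
#' @param records Records data frame (see [simulate_trajectories()]).
#' @param params Parameter columns to aggregate; defaults to whichever of
#'   the eleven canonical parameters are present.
#' @return A named list of `condition_series` objects, one per condition.
#'   Each holds `condition`, integer `cycles` (1..N), an `N x P` `mean`
#'   matrix, matching `sd` and `n_cells`, and the `filled` flag vector.
#' @examples
#' cfg <- acquisition_config(duration = 1)
#' rec <- simulate_trajectories(cfg, builtin_archetypes()$control, seed = 1)
#' s <- aggregate_records(rec)[["control"]]
#' dim(s$mean)
#' @export
aggregate_records <- function(records, params = NULL) {
  if (is.null(records) || nrow(records) == 0L)
    stop("no records to aggregate", call. = FALSE)
  if (is.null(params))
    params <- intersect(param_names(), names(records))
  if (!length(params))
    stop("records contain none of the canonical parameter columns",
         call. = FALSE)
  if (any(records$cycle < 1L))
    stop("cycle indices must be >= 1", call. = FALSE)
  out <- lapply(split(records, records$condition), function(sub) {
    N <- max(sub$cycle)
    cyc <- sort(unique(sub$cycle))
    f <- factor(sub$cycle, levels = seq_len(N))
    n_cells <- as.integer(table(f))
    spl <- split(seq_len(nrow(sub)), f)[cyc]
    mu <- matrix(NA_real_, N, length(params),
                 dimnames = list(NULL, params))
    sdv <- mu
    for (p in params) {
      v <- sub[[p]]
      mu[cyc, p] <- vapply(spl, function(i) mean(v[i]), numeric(1))
      sdv[cyc, p] <- vapply(spl, function(i)
        if (length(i) > 1) stats::sd(v[i]) else 0, numeric(1))
    }
    if (any(n_cells == 1L))
      warning("condition '", sub$condition[1],
              "': cycles with a single cell have SD 0", call. = FALSE)
    filled <- n_cells == 0L
    if (any(filled)) {
      warning("condition '", sub$condition[1], "': ", sum(filled),
              " empty cycle(s) filled by last observation carried forward",
              call. = FALSE)
      for (i in which(filled)) {
        if (i == 1L)
          stop("condition '", sub$condition[1],
               "' has no cells at the first cycle", call. = FALSE)
        mu[i, ] <- mu[i - 1L, ]
        sdv[i, ] <- sdv[i - 1L, ]
      }
    }
    structure(list(condition = sub$condition[1], cycles = seq_len(N),
                   mean = mu, sd = sdv, n_cells = n_cells,
                   filled = filled),
              class = "condition_series")
  })
  out
}

#' @export
print.condition_series <- function(x, ...) {
  cat(sprintf("<condition_series> '%s': %d cycles x %d parameters, %d-%d cells\n",
              x$condition, length(x$cycles), ncol(x$mean),
              min(x$n_cells), max(x$n_cells)))
  invisible(x)
}

#' Center and scale a condition's mean series
#'
#' Z-scores each parameter's population-mean series over its cycles
#' (independently per parameter), retaining the location and scale so the
#' transform can be inverted. Constant series are rejected: a
#' zero-variance series carries no frequency information.
#'
#' @param series A `condition_series` (one element of
#'   [aggregate_records()]'s output).
#' @param center,scale Logical; both default `TRUE` (subtract the mean,
#'   divide by the SD).
#' @return A `centered_series` object: `condition`, `cycles`, z-scored
#'   matrix `x`, and the `location`/`scale` vectors used.
#' @examples
#' s <- structure(list(condition = "demo", cycles = 1:3,
#'                     mean = cbind(area = c(1, 2, 3)),
#'                     sd = cbind(area = c(0, 0, 0)),
#'                     n_cells = rep(2L, 3), filled = rep(FALSE, 3)),
#'                class = "condition_series")
#' center_scale(s)$x
#' @export
center_scale <- function(series, center = TRUE, scale = TRUE) {
  stopifnot(inherits(series, "condition_series") ||
            inherits(series, "centered_series"))
  if (inherits(series, "centered_series")) {
    m <- series$x
    cond <- series$condition
    cycles <- series$cycles
  } else {
    m <- series$mean
    cond <- series$condition
    cycles <- series$cycles
  }
  loc <- rep(0, ncol(m))
  scl <- rep(1, ncol(m))
  names(loc) <- names(scl) <- colnames(m)
  for (j in seq_len(ncol(m))) {
    if (center) loc[j] <- mean(m[, j])
    s <- stats::sd(m[, j])
    if (scale) {
      if (!is.finite(s) || s < 1e-12)
        stop("parameter '", colnames(m)[j], "' of condition '", cond,
             "' has zero variance; cannot scale", call. = FALSE)
      scl[j] <- s
    }
    m[, j] <- (m[, j] - loc[j]) / scl[j]
  }
  structure(list(condition = cond, cycles = cycles, x = m,
                 location = loc, scale = scl),
            class = "centered_series")
}

#' @export
print.centered_series <- function(x, ...) {
  cat(sprintf("<centered_series> '%s': %d cycles x %d parameters\n",
              x$condition, length(x$cycles), ncol(x$x)))
  invisible(x)
}

#' Parameter-parameter correlation within a condition
#'
#' Pearson correlation between every pair of parameter mean-series of one
#' condition (the per-condition parameter heat map). Zero-variance
#' parameters get `NA` rows/columns with a warning.
#'
#' @param series A `condition_series`.
#' @return Symmetric `P x P` correlation matrix with unit diagonal.
#' @export
parameter_correlation <- function(series) {
  stopifnot(inherits(series, "condition_series"))
  m <- series$mean
  if (nrow(m) < 3)
    stop("need at least 3 cycles for a correlation matrix", call. = FALSE)
  v <- apply(m, 2, stats::sd)
  bad <- !is.finite(v) | v < 1e-12
  r <- suppressWarnings(stats::cor(m))
  if (any(bad)) {
    warning("zero-variance parameter(s): ",
            paste(colnames(m)[bad], collapse = ", "),
            "; correlation undefined", call. = FALSE)
    r[bad, ] <- NA_real_
    r[, bad] <- NA_real_
  }
  d <- diag(r)
  d[!bad] <- 1
  diag(r) <- d
  r
}
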