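#' Discrete Fourier transform of a centered series
#'
#' Computes, for every parameter of a centered condition series, the DFT
#' coefficients `X_k = sum_{n=0}^{N-1} x_n exp(-i 2 pi k n / N)`
#' (the standard negative-exponent convention, as implemented by
#' [stats::fft()]).
#'
#' @param series A `centered_series` (see [center_scale()]), or a plain
#'   numeric vector for a single unnamed series.
#' @return For a `centered_series`, a named list of `spectrum` objects
#'   (one per parameter), each holding `condition`, `parameter`, `N` and
#'   the complex coefficient vector `coef` (`k = 0..N-1`). For a numeric
#'   vector, a single `spectrum`.
#' @examples
#' sp <- dft(cos(2 * pi * 3 * (0:399) / 400))
#' which.max(Mod(sp$coef[2:200]))  # bin k = 3
#' @export
dft <- function(series) {
  if (is.numeric(series)) {
    return(one_spectrum(series, condition = NA_character_,
                        parameter = NA_character_))
  }
  stopifnot(inherits(series, "centered_series"))
  m <- series$x
  stats::setNames(lapply(colnames(m), function(p)
    one_spectrum(m[, p], series$condition, p)), colnames(m))
}

one_spectrum <- function(x, condition, parameter) {
  if (length(x) < 4)
    stop("need at least 4 samples for a spectrum", call. = FALSE)
  if (any(!is.finite(x)))
    stop("non-finite value at cycle ", which(!is.finite(x))[1],
         call. = FALSE)
  structure(list(condition = condition, parameter = parameter,
                 N = length(x), coef = stats::fft(x)),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s/%s: N = %d\n",
              x$condition, x$parameter, x$N))
  invisible(x)
}

#' Dominant Fourier feature of a spectrum
#'
#' Finds the frequency bin of maximal amplitude in the positive-frequency
#' band `k = 1 .. floor(N/2)` (excluding the DC bin, which centering
#' annihilates, and the Nyquist bin for even `N`; ties resolve to the
#' smallest `k`). The amplitude is reported as `2 |X_k| / N`, so a unit
#' cosine reports amplitude 1; the phase is `Arg(X_k)` in `(-pi, pi]`.
#'
#' @param spectrum A `spectrum` from [dft()].
#' @return A one-row data frame: `condition`, `parameter`, `k_star`,
#'   `period` (cycles, `N / k_star`), `amplitude`, `phase`.
#' @examples
#' dominant_feature(dft(0.7 * cos(2 * pi * 5 * (0:399) / 400)))
#' @export
dominant_feature <- function(spectrum) {
  stopifnot(inherits(spectrum, "spectrum"))
  N <- spectrum$N
  k_hi <- if (N %% 2 == 0) N %/% 2 - 1L else N %/% 2
  band <- 2:(k_hi + 1L)                       # coef[k+1] holds bin k
  amps <- Mod(spectrum$coef[band])
  if (max(amps) < 1e-12 * N)
    stop("spectrum is zero on the search band (constant series?)",
         call. = FALSE)
  # ties (within round-off) resolve to the smallest frequency
  k_star <- which(amps >= max(amps) * (1 - 1e-9))[1]
  X <- spectrum$coef[k_star + 1L]
  data.frame(condition = spectrum$condition,
             parameter = spectrum$parameter,
             k_star = as.integer(k_star),
             period = N / k_star,
             amplitude = 2 * Mod(X) / N,
             phase = Arg(X),
             stringsAsFactors = FALSE)
}

#' Dominant Fourier features for a set of centered series
#'
#' Convenience wrapper: applies [dft()] and [dominant_feature()] to every
#' parameter of every centered condition series.
#'
#' @param centered A `centered_series` or a list of them.
#' @return Data frame with one row per (condition, parameter).
#' @export
spectral_features <- function(centered) {
  if (inherits(centered, "centered_series")) centered <- list(centered)
  do.call(rbind, lapply(centered, function(cs)
    do.call(rbind, lapply(dft(cs), dominant_feature))))
}

#' Assemble the condition-by-feature matrix
#'
#' Builds the conditions x 22 matrix of dominant Fourier features (11
#' amplitudes in canonical parameter order, then the 11 matching phases)
#' and optionally z-scores each column across conditions (n-1 denominator),
#' which is the normalization applied before condition clustering.
#'
#' @param features Data frame from [spectral_features()] (columns
#'   `condition`, `parameter`, `amplitude`, `phase`).
#' @param normalize Z-score columns across conditions (requires >= 3
#'   conditions). Columns that are constant across conditions are centered
#'   but left unscaled, with a warning.
#' @param params Parameter order; defaults to the canonical eleven
#'   restricted to those present.
#' @return A `feature_matrix`: numeric matrix with condition rownames,
#'   `amp_*`/`phase_*` colnames and attribute `normalized`.
#' @export
build_feature_matrix <- function(features, normalize = TRUE,
                                 params = NULL) {
  stopifnot(is.data.frame(features),
            all(c("condition", "parameter", "amplitude", "phase") %in%
                  names(features)))
  if (is.null(params))
    params <- intersect(param_names(), unique(features$parameter))
  conds <- unique(features$condition)
  key <- paste(features$condition, features$parameter)
  want <- as.vector(outer(conds, params, paste))
  if (anyDuplicated(key))
    stop("duplicated (condition, parameter) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "),
         call. = FALSE)
  miss <- setdiff(want, key)
  if (length(miss))
    stop("missing (condition, parameter) pair(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  pick <- match(want, key)
  amp <- matrix(features$amplitude[pick], nrow = length(conds),
                dimnames = list(conds, paste0("amp_", params)))
  ph <- matrix(features$phase[pick], nrow = length(conds),
               dimnames = list(conds, paste0("phase_", params)))
  m <- cbind(amp, ph)
  as_feature_matrix(m, normalize)
}

#' Coerce a plain matrix to a feature matrix, optionally normalizing
#'
#' @param m Numeric matrix, conditions in rows, features in columns.
#' @param normalize Z-score each column across conditions.
#' @return A `feature_matrix` (attribute `normalized` records whether the
#'   column z-scoring was applied).
#' @export
as_feature_matrix <- function(m, normalize = FALSE) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (normalize) {
    if (nrow(m) < 3)
      stop("column z-scoring needs at least 3 conditions", call. = FALSE)
    mu <- colMeans(m)
    s <- apply(m, 2, stats::sd)
    if (any(s < 1e-12)) {
      warning("constant feature column(s) centered but not scaled: ",
              paste(colnames(m)[s < 1e-12], collapse = ", "),
              call. = FALSE)
      s[s < 1e-12] <- 1
    }
    m <- sweep(sweep(m, 2, mu), 2, s, "/")
  }
  structure(m, class = c("feature_matrix", class(matrix())),
            normalized = normalize)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d conditions x %d features (%snormalized)\n",
              nrow(x), ncol(x), if (attr(x, "normalized")) "" else "not "))
  print(round(unclass(x), 3), ...)
  invisible(x)
}
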