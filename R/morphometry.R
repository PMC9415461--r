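#' Morphometry calibration
#'
#' Physical constants needed to turn a refractive-index/height frame into
#' the eleven phenotypic parameters.
#'
#' @param ri_increment Specific refractive increment relating
#'   refractive-index excess to dry-mass concentration, um^3/pg.
#' @param medium_index Refractive index of the culture medium.
#' @param pixel_size Pixel pitch, um.
#' @param field_area Denominator of the relative cell area, um^2
#'   (the full imaging-field area).
#' @param granularity_window Side of the local-mean window used by the
#'   granularity estimator, um.
#' @return An object of class `morphometry_calibration`.
#' @export
morphometry_calibration <- function(ri_increment = 0.19,
                                    medium_index = 1.333,
                                    pixel_size = 0.5,
                                    field_area = 236^2,
                                    granularity_window = 2) {
  if (ri_increment <= 0)
    stop("configuration error: 'ri_increment' must be > 0", call. = FALSE)
  if (medium_index <= 1 || medium_index >= 1.40)
    stop("configuration error: 'medium_index' must lie in (1, 1.40)",
         call. = FALSE)
  if (pixel_size <= 0 || field_area <= 0 || granularity_window <= 0)
    stop("configuration error: sizes must be > 0", call. = FALSE)
  structure(list(ri_increment = ri_increment, medium_index = medium_index,
                 pixel_size = pixel_size, field_area = field_area,
                 granularity_window = granularity_window),
            class = "morphometry_calibration")
}

#' Extract the eleven phenotypic parameters from one frame
#'
#' Recomputes, for every labeled cell in a [field_frame()], the parameters
#' a segmentation/analysis package would report:
#' area `A` (pixel count x pixel_size^2), relative area
#' `100 * A / field_area`, perimeter `P` (polygon length of the
#' marching-squares boundary at the 0.5 level of the lightly smoothed
#' label mask), form factor `4*pi*A/P^2`, extent (A over the axis-aligned
#' bounding-box area), compactness `P^2/(4*pi*A)`, eccentricity of the
#' second-moment equivalent ellipse, mean refractive index, dry mass
#' `sum((ri - n_m) * height) * pixel_size^2 / alpha`, volume
#' `sum(height) * pixel_size^2`, dry mass density `DM/V`, and granularity
#' `10 + 100 * sd(high-pass refractive index inside the cell)`.
#'
#' Labels covering fewer than 5 pixels are skipped with a warning
#' (sub-resolution objects).
#'
#' @param frame A [field_frame()].
#' @param calib A [morphometry_calibration()]; its `pixel_size` is taken
#'   from the frame.
#' @param condition Condition label stamped on the records.
#' @return A records data frame (same layout as
#'   [simulate_trajectories()]).
#' @examples
#' cfg <- acquisition_config(field_side = 60, duration = 0.1,
#'                           initial_cells_min = 2, initial_cells_max = 2)
#' ff <- simulate_field_frames(cfg, builtin_archetypes()$control, seed = 1)
#' extract_features(ff$frames[[1]], morphometry_calibration(field_area = 60^2))
#' @export
extract_features <- function(frame, calib = morphometry_calibration(),
                             condition = "sample") {
  stopifnot(inherits(frame, "field_frame"),
            inherits(calib, "morphometry_calibration"))
  px <- frame$pixel_size
  n_m <- calib$medium_index
  mask <- frame$label_mask
  labels <- sort(setdiff(unique(as.vector(mask)), 0L))
  out <- vector("list", length(labels))
  keep <- logical(length(labels))
  for (li in seq_along(labels)) {
    lab <- labels[li]
    idx <- which(mask == lab, arr.ind = TRUE)
    n <- nrow(idx)
    if (n < 5L) {
      warning("label ", lab, " at cycle ", frame$cycle,
              " has fewer than 5 pixels; record skipped", call. = FALSE)
      next
    }
    ri <- frame$ri_map[mask == lab]
    if (any(ri < n_m - 1e-9))
      stop("refractive index below the medium index inside label ", lab,
           call. = FALSE)
    hgt <- frame$height_map[mask == lab]
    area <- n * px^2
    per <- label_perimeter(mask == lab, px)
    ff <- 4 * pi * area / per^2
    bbox <- (diff(range(idx[, 1])) + 1) * (diff(range(idx[, 2])) + 1) * px^2
    ext <- area / bbox
    ecc <- moments_eccentricity(idx)
    dm <- sum((ri - n_m) * hgt) * px^2 / calib$ri_increment
    vol <- sum(hgt) * px^2
    gran <- granularity_score(frame$ri_map, mask == lab,
                              calib$granularity_window, px)
    out[[li]] <- data.frame(
      condition = condition, cell_id = sprintf("c%03d", lab),
      cycle = frame$cycle, alive = TRUE,
      area = area, area_pct = 100 * area / calib$field_area,
      perimeter = per, form_factor = ff, extent = ext,
      compactness = per^2 / (4 * pi * area), eccentricity = ecc,
      mean_ri = mean(ri), dmd = if (vol > 0) dm / vol else NA_real_,
      dry_mass = dm, granularity = gran, volume = vol,
      stringsAsFactors = FALSE
    )
    keep[li] <- TRUE
  }
  if (!any(keep)) return(empty_records(condition))
  rec <- do.call(rbind, out[keep])
  rownames(rec) <- NULL
  rec
}

#' Extract features from a sequence of frames
#'
#' Concatenates [extract_features()] over a frame sequence; cell identity
#' is carried by the mask label (the frame generator keeps labels
#' persistent across cycles).
#'
#' @param frames List of [field_frame()] objects sharing grid geometry.
#' @inheritParams extract_features
#' @return A records data frame with one row per label per frame.
#' @export
features_from_frames <- function(frames, calib = morphometry_calibration(),
                                 condition = "sample") {
  if (!length(frames)) return(empty_records(condition))
  d1 <- dim(frames[[1]]$label_mask)
  p1 <- frames[[1]]$pixel_size
  recs <- lapply(frames, function(f) {
    if (!all(dim(f$label_mask) == d1) || f$pixel_size != p1)
      stop("frame geometry mismatch at cycle ", f$cycle, call. = FALSE)
    extract_features(f, calib, condition)
  })
  rec <- do.call(rbind, recs)
  rownames(rec) <- NULL
  rec
}

# perimeter: marching-squares contour (0.5 level) of the 3x3 box-smoothed
# binary mask; smoothing removes the staircase bias of the raw digitization
label_perimeter <- function(bin, px) {
  n1 <- nrow(bin)
  n2 <- ncol(bin)
  pad <- matrix(0, n1 + 4, n2 + 4)
  pad[3:(n1 + 2), 3:(n2 + 2)] <- bin
  sm <- box3(pad)
  cl <- grDevices::contourLines(x = seq_len(nrow(sm)) * px,
                                y = seq_len(ncol(sm)) * px,
                                z = sm, levels = 0.5)
  sum(vapply(cl, function(co) {
    x <- c(co$x, co$x[1])
    y <- c(co$y, co$y[1])
    sum(sqrt(diff(x)^2 + diff(y)^2))
  }, numeric(1)))
}

# 3x3 box mean with zero padding
box3 <- function(m) {
  n1 <- nrow(m)
  n2 <- ncol(m)
  p <- matrix(0, n1 + 2, n2 + 2)
  p[2:(n1 + 1), 2:(n2 + 1)] <- m
  s <- matrix(0, n1, n2)
  for (di in 0:2) for (dj in 0:2)
    s <- s + p[(1 + di):(n1 + di), (1 + dj):(n2 + dj)]
  s / 9
}

# eccentricity of the second-moment equivalent ellipse from pixel centers
moments_eccentricity <- function(idx) {
  x <- idx[, 1] - mean(idx[, 1])
  y <- idx[, 2] - mean(idx[, 2])
  n <- length(x)
  mu20 <- sum(x^2) / n
  mu02 <- sum(y^2) / n
  mu11 <- sum(x * y) / n
  tr <- mu20 + mu02
  dt <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- tr / 2 + dt
  l2 <- tr / 2 - dt
  if (l1 <= 0) return(0)
  sqrt(max(0, 1 - l2 / l1))
}

# 10 + 100 * sd of the high-pass RI inside the cell; the local mean uses a
# mask-normalized box window of side granularity_window
granularity_score <- function(ri_map, bin, window_um, px) {
  w <- max(3L, 2L * floor(window_um / px / 2) + 1L)   # odd, >= 3
  half <- (w - 1L) %/% 2L
  num <- boxsum(ri_map * bin, half)
  den <- boxsum(bin + 0, half)
  inside <- which(bin)
  resid <- ri_map[inside] - num[inside] / den[inside]
  if (length(resid) < 2) return(10)
  10 + 100 * stats::sd(resid)
}

# (2*half+1)^2 box sum via a summed-area table
boxsum <- function(m, half) {
  n1 <- nrow(m)
  n2 <- ncol(m)
  p <- matrix(0, n1 + 2 * half, n2 + 2 * half)
  p[(half + 1):(n1 + half), (half + 1):(n2 + half)] <- m
  sat <- apply(apply(p, 2, cumsum), 1, cumsum)   # transposed SAT
  sat <- t(sat)
  z <- matrix(0, nrow(sat) + 1, ncol(sat) + 1)
  z[-1, -1] <- sat
  i1 <- (2 * half + 1):(n1 + 2 * half)
  i0 <- 1:n1
  j1 <- (2 * half + 1):(n2 + 2 * half)
  j0 <- 1:n2
  z[i1 + 1, j1 + 1] - z[i0, j1 + 1] - z[i1 + 1, j0] + z[i0, j0]
}
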