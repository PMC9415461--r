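#' A synthetic imaging-field frame
#'
#' One imaging cycle of a simulated field: an integer label mask (0 =
#' background, k = cell k), a refractive-index map (background at the
#' medium index), and an optical-height map (um, exactly 0 outside cells).
#' All three grids share the dimension `round(field_side / pixel_size)`.
#'
#' @param cycle Integer cycle index.
#' @param label_mask Integer matrix of cell labels.
#' @param ri_map Numeric matrix of refractive indices, `>= medium_index`.
#' @param height_map Numeric matrix of optical heights (um).
#' @param pixel_size Pixel pitch, um.
#' @param medium_index Medium refractive index.
#' @return An object of class `field_frame`.
#' @export
field_frame <- function(cycle, label_mask, ri_map, height_map,
                        pixel_size, medium_index = 1.333) {
  if (!all(dim(label_mask) == dim(ri_map)) ||
      !all(dim(label_mask) == dim(height_map)))
    stop("frame grids must share dimensions", call. = FALSE)
  if (any(ri_map < medium_index - 1e-12))
    stop("ri_map below the medium index", call. = FALSE)
  if (any(height_map[label_mask == 0] != 0))
    stop("height_map must be 0 outside cells", call. = FALSE)
  structure(list(cycle = as.integer(cycle),
                 label_mask = label_mask, ri_map = ri_map,
                 height_map = height_map, pixel_size = pixel_size,
                 medium_index = medium_index),
            class = "field_frame")
}

#' @export
print.field_frame <- function(x, ...) {
  cat(sprintf("<field_frame> cycle %d, %dx%d px (%g um/px), %d cells\n",
              x$cycle, nrow(x$label_mask), ncol(x$label_mask), x$pixel_size,
              length(setdiff(unique(as.vector(x$label_mask)), 0L))))
  invisible(x)
}

#' Render synthetic imaging frames for an archetype
#'
#' Re-runs [simulate_trajectories()] under the same seed and renders every
#' cell at every cycle as a non-overlapping ellipse whose area and
#' eccentricity track that cell's trajectory targets. Heights follow a
#' semi-ellipsoidal dome scaled so the closed-form dry mass
#' `sum((ri - n_m) * height) * pixel_size^2 / alpha` matches the
#' trajectory's dry-mass target up to rasterization error; the
#' refractive-index excess inside a cell is `ri_increment * dmd` modulated
#' by multiplicative white-noise texture (the granularity carrier).
#'
#' @inheritParams simulate_trajectories
#' @param texture_rel_sd Relative SD of the per-pixel refractive-index
#'   texture (bounded below so `ri >= medium_index` always holds).
#' @return List with `frames` (list of [field_frame()] objects, one per
#'   cycle) and `records` (the trajectory targets the frames were rendered
#'   from).
#' @examples
#' cfg <- acquisition_config(field_side = 60, duration = 0.2,
#'                           initial_cells_min = 2, initial_cells_max = 2)
#' ff <- simulate_field_frames(cfg, builtin_archetypes()$control, seed = 1)
#' length(ff$frames)
#' @export
simulate_field_frames <- function(config = acquisition_config(),
                                  archetype,
                                  seed = config$seed,
                                  condition = archetype$name,
                                  texture_rel_sd = 0.45) {
  stopifnot(inherits(config, "acquisition_config"),
            inherits(archetype, "archetype_spec"))
  rec <- simulate_trajectories(config, archetype, seed = seed,
                               condition = condition)
  npx <- round(config$field_side / config$pixel_size)
  n_m <- archetype$medium_index
  cells <- if (nrow(rec)) sort(unique(rec$cell_id)) else character()
  geom <- with_seed(seed + 86243L,
                    place_cells(rec, cells, config))
  frames <- vector("list", config$n_cycles)
  with_seed(seed + 191117L, for (cyc in seq_len(config$n_cycles)) {
    mask <- matrix(0L, npx, npx)
    ri <- matrix(n_m, npx, npx)
    hgt <- matrix(0, npx, npx)
    sub <- rec[rec$cycle == cyc, , drop = FALSE]
    for (j in seq_len(nrow(sub))) {
      k <- match(sub$cell_id[j], cells)
      g <- render_ellipse(sub[j, ], geom[k, ], config, n_m,
                          archetype$ri_increment, texture_rel_sd, npx)
      if (length(g$idx)) {
        mask[g$idx] <- k
        ri[g$idx] <- g$ri
        hgt[g$idx] <- g$height
      }
    }
    frames[[cyc]] <- field_frame(cyc, mask, ri, hgt, config$pixel_size, n_m)
  })
  list(frames = frames, records = rec)
}

# one fixed center and orientation per cell, rejection-sampled so that
# circumscribing circles never touch over the whole acquisition
place_cells <- function(rec, cells, config) {
  n <- length(cells)
  geom <- matrix(NA_real_, n, 3, dimnames = list(cells,
                                                 c("cx", "cy", "theta")))
  if (n == 0) return(geom)
  amax <- vapply(cells, function(id) {
    s <- rec[rec$cell_id == id, ]
    max(sqrt(s$area / (pi * sqrt(pmax(1 - s$eccentricity^2, 1e-6)))))
  }, numeric(1))
  margin <- amax + 1
  for (k in seq_len(n)) {
    lo <- margin[k]
    hi <- config$field_side - margin[k]
    if (hi <= lo)
      stop("field too crowded to place cells without overlap; ",
           "use a larger field or fewer cells", call. = FALSE)
    ok <- FALSE
    for (try in seq_len(5000)) {
      cx <- stats::runif(1, lo, hi)
      cy <- stats::runif(1, lo, hi)
      prev <- seq_len(k - 1L)
      if (k == 1L || all(sqrt((geom[prev, "cx"] - cx)^2 +
                              (geom[prev, "cy"] - cy)^2) >
                         amax[prev] + amax[k] + 1)) {
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("field too crowded to place cells without overlap; ",
           "use a larger field or fewer cells", call. = FALSE)
    geom[k, ] <- c(cx, cy, stats::runif(1, 0, pi))
  }
  geom
}

render_ellipse <- function(row, g, config, n_m, alpha, tex_sd, npx) {
  px <- config$pixel_size
  e <- min(row$eccentricity, 0.999)
  a <- sqrt(row$area / (pi * sqrt(1 - e^2)))
  b <- a * sqrt(1 - e^2)
  i0 <- max(1L, floor((g["cx"] - a) / px))
  i1 <- min(npx, ceiling((g["cx"] + a) / px))
  j0 <- max(1L, floor((g["cy"] - a) / px))
  j1 <- min(npx, ceiling((g["cy"] + a) / px))
  ii <- i0:i1
  jj <- j0:j1
  xg <- (ii - 0.5) * px - g["cx"]
  yg <- (jj - 0.5) * px - g["cy"]
  X <- matrix(xg, length(ii), length(jj))
  Y <- matrix(yg, length(ii), length(jj), byrow = TRUE)
  u <- (X * cos(g["theta"]) + Y * sin(g["theta"])) / a
  v <- (-X * sin(g["theta"]) + Y * cos(g["theta"])) / b
  q <- u^2 + v^2
  sel <- which(q <= 1)
  if (!length(sel)) return(list(idx = integer()))
  idx <- cbind(ii[(sel - 1) %% length(ii) + 1],
               jj[(sel - 1) %/% length(ii) + 1])
  # dome height scaled to the target volume (= dry_mass / dmd)
  h0 <- 1.5 * row$volume / (pi * a * b)
  height <- h0 * sqrt(1 - q[sel])
  tex <- pmax(stats::rnorm(length(sel), 0, tex_sd), -0.95)
  ri <- n_m + alpha * row$dmd * (1 + tex)
  list(idx = idx, ri = ri, height = height)
}
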