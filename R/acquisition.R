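#' Acquisition configuration
#'
#' Describes one continuous live-imaging acquisition: a square field imaged
#' at a fixed interval for a fixed duration, seeded with a random number of
#' cells. The defaults mirror a 236 um x 236 um field imaged every 3 min
#' for 20 h (400 cycles) starting with 15-25 cells.
#'
#' @param field_side Side of the square imaging field, um.
#' @param pixel_size Pixel pitch of rendered frames, um/pixel.
#' @param interval Imaging interval, minutes.
#' @param duration Total acquisition time, hours. The number of cycles is
#'   `floor(duration * 60 / interval)`.
#' @param initial_cells_min,initial_cells_max Inclusive range from which the
#'   initial cell count of a simulated field is drawn uniformly.
#' @param seed Default integer seed used by the simulators.
#' @return An object of class `acquisition_config`: a validated list with
#'   the above fields plus `n_cycles`.
#' @examples
#' cfg <- acquisition_config()
#' cfg$n_cycles  # 400
#' @export
acquisition_config <- function(field_side = 236, pixel_size = 0.5,
                               interval = 3, duration = 20,
                               initial_cells_min = 15, initial_cells_max = 25,
                               seed = 1L) {
  chk_num <- function(x, name, lo = NULL, int = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("configuration error: '", name, "' must be a finite number",
           call. = FALSE)
    if (!is.null(lo) && x < lo)
      stop("configuration error: '", name, "' must be >= ", lo, call. = FALSE)
    if (int && x != round(x))
      stop("configuration error: '", name, "' must be an integer",
           call. = FALSE)
    x
  }
  chk_num(field_side, "field_side", lo = 1e-9)
  chk_num(pixel_size, "pixel_size", lo = 1e-9)
  chk_num(interval, "interval", lo = 1e-9)
  chk_num(duration, "duration", lo = 1e-9)
  chk_num(initial_cells_min, "initial_cells_min", lo = 0, int = TRUE)
  chk_num(initial_cells_max, "initial_cells_max", lo = 0, int = TRUE)
  chk_num(seed, "seed", int = TRUE)
  if (initial_cells_min > initial_cells_max)
    stop("configuration error: 'initial_cells_min' exceeds 'initial_cells_max'",
         call. = FALSE)
  n_cycles <- as.integer(floor(duration * 60 / interval))
  if (n_cycles < 1L)
    stop("configuration error: 'duration'/'interval' give zero cycles",
         call. = FALSE)
  structure(list(field_side = field_side, pixel_size = pixel_size,
                 interval = interval, duration = duration,
                 n_cycles = n_cycles,
                 initial_cells_min = as.integer(initial_cells_min),
                 initial_cells_max = as.integer(initial_cells_max),
                 seed = as.integer(seed)),
            class = "acquisition_config")
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf(
    "<acquisition_config> %g um field (%g um/px), every %g min for %g h (%d cycles), %d-%d initial cells, seed %d\n",
    x$field_side, x$pixel_size, x$interval, x$duration, x$n_cycles,
    x$initial_cells_min, x$initial_cells_max, x$seed))
  invisible(x)
}

# hours -> 1-based cycle index under a config (cycle c is at time c*interval)
hours_to_cycle <- function(hours, config) {
  pmin(pmax(1L, as.integer(round(hours * 60 / config$interval))),
       config$n_cycles)
}

# evaluate under a private RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
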