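#' Simulate per-cell phenotypic trajectories
#'
#' Generates one acquisition's worth of per-cell records for a single
#' condition. Each cell's value of each free parameter at cycle `c` is
#' `mean_trajectory(c) * m + e(c)`, where `m` is a lognormal per-cell
#' multiplicative effect (log-SD `cell_effect_sd`, one draw per cell per
#' parameter) and `e` is stationary AR(1) Gaussian noise, clipped to the
#' parameter's physical domain. Division appends a fresh daughter track
#' from the division cycle onward; death truncates a track (no records are
#' emitted after the death event). Derived columns (`area_pct`,
#' `compactness`, `mean_ri`, `volume`) satisfy the record identities exactly
#' (see [archetype_spec()]).
#'
#' @param config An [acquisition_config()].
#' @param archetype An [archetype_spec()], e.g. one of
#'   [builtin_archetypes()].
#' @param seed Integer seed; defaults to `config$seed`. The same
#'   config/archetype/seed triple reproduces the records bit-identically.
#' @param condition Condition label for the records; defaults to the
#'   archetype name.
#' @return A data frame with columns `condition`, `cell_id`, `cycle`,
#'   `alive`, the eleven phenotypic parameters in canonical order, and the
#'   internal `volume` column (um^3) carried so that
#'   `dmd * volume == dry_mass` holds exactly.
#' @examples
#' cfg <- acquisition_config(duration = 1)   # 20 cycles
#' rec <- simulate_trajectories(cfg, builtin_archetypes()$control, seed = 7)
#' head(rec)
#' @export
simulate_trajectories <- function(config = acquisition_config(),
                                  archetype,
                                  seed = config$seed,
                                  condition = archetype$name) {
  stopifnot(inherits(config, "acquisition_config"),
            inherits(archetype, "archetype_spec"))
  with_seed(seed, {
    n0 <- if (config$initial_cells_min == config$initial_cells_max)
      config$initial_cells_min
    else sample(config$initial_cells_min:config$initial_cells_max, 1L)
    cells <- simulate_events(n0, archetype, config)
    build_records(cells, archetype, config, condition)
  })
}

# division/death bookkeeping: returns data.frame(cell_id, birth, death)
# death = last cycle with a record (n_cycles if the cell survives)
simulate_events <- function(n0, a, config) {
  N <- config$n_cycles
  dt_h <- config$interval / 60
  p_div <- if (is.null(a$division_rate)) 0 else a$division_rate * dt_h
  arrest_cycle <- if (is.null(a$arrest_onset)) Inf
                  else a$arrest_onset * 60 / config$interval
  death_cycle <- if (is.null(a$death_onset)) Inf
                 else a$death_onset * 60 / config$interval
  hazard <- if (is.null(a$death_hazard)) 0 else a$death_hazard
  birth <- rep(1L, n0)
  death <- rep(NA_integer_, n0)
  i <- 1L
  while (i <= length(birth)) {         # daughters appended are iterated too
    cyc <- birth[i]
    while (cyc <= N) {
      if (hazard > 0 && cyc > death_cycle && stats::runif(1) < hazard) {
        death[i] <- cyc
        break
      }
      if (p_div > 0 && cyc <= arrest_cycle && cyc < N &&
          stats::runif(1) < p_div) {
        birth <- c(birth, cyc + 1L)    # daughter track starts next cycle
        death <- c(death, NA_integer_)
      }
      cyc <- cyc + 1L
    }
    i <- i + 1L
  }
  death[is.na(death)] <- N
  if (length(birth) == 0L)
    return(data.frame(cell_id = character(), birth = integer(),
                      death = integer()))
  data.frame(cell_id = sprintf("c%03d", seq_along(birth)),
             birth = as.integer(birth), death = as.integer(death))
}

empty_records <- function(condition) {
  cols <- c(record_id_cols(), param_names(), "volume")
  rec <- as.data.frame(stats::setNames(rep(list(numeric()), length(cols)),
                                       cols))
  rec$condition <- character()
  rec$cell_id <- character()
  rec$cycle <- integer()
  rec$alive <- logical()
  rec
}

build_records <- function(cells, a, config, condition) {
  if (nrow(cells) == 0L) return(empty_records(condition))
  free <- free_params()
  M <- mean_trajectories(a, config)
  rho <- a$noise_autocorr
  rng <- calibration_ranges()
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cyc <- seq.int(cells$birth[i], cells$death[i])
    n <- length(cyc)
    vals <- matrix(NA_real_, n, length(free), dimnames = list(NULL, free))
    for (p in free) {
      m <- if (a$cell_effect_sd > 0) exp(stats::rnorm(1, 0, a$cell_effect_sd))
           else 1
      sd_p <- a$noise_sd[[p]]
      e <- if (sd_p > 0) ar1_noise(n, rho, sd_p) else numeric(n)
      vals[, p] <- M[cyc, p] * m + e
    }
    vals <- clip_physical(vals)
    out[[i]] <- data.frame(
      condition = condition, cell_id = cells$cell_id[i], cycle = cyc,
      alive = TRUE,
      area = vals[, "area"],
      area_pct = 100 * vals[, "area"] / config$field_side^2,
      perimeter = vals[, "perimeter"],
      form_factor = vals[, "form_factor"],
      extent = vals[, "extent"],
      compactness = 1 / vals[, "form_factor"],
      eccentricity = vals[, "eccentricity"],
      mean_ri = a$medium_index + a$ri_increment * vals[, "dmd"],
      dmd = vals[, "dmd"],
      dry_mass = vals[, "dry_mass"],
      granularity = vals[, "granularity"],
      volume = vals[, "dry_mass"] / vals[, "dmd"],
      stringsAsFactors = FALSE
    )
  }
  rec <- do.call(rbind, out)
  rownames(rec) <- NULL
  rec
}

# stationary AR(1): x_t = rho x_{t-1} + sqrt(1-rho^2) sd eps_t, x_0 ~ N(0, sd)
ar1_noise <- function(n, rho, sd) {
  e <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
  as.numeric(stats::filter(e, rho, method = "recursive",
                           init = stats::rnorm(1, 0, sd)))
}

# clip free parameters to their physical domains (not calibration ranges)
clip_physical <- function(vals) {
  eps <- 1e-6
  pos <- c("area", "perimeter", "dmd", "dry_mass", "granularity")
  for (p in pos) vals[, p] <- pmax(vals[, p], eps)
  vals[, "form_factor"] <- pmin(pmax(vals[, "form_factor"], eps), 1)
  vals[, "extent"] <- pmin(pmax(vals[, "extent"], eps), 1)
  vals[, "eccentricity"] <- pmin(pmax(vals[, "eccentricity"], 0), 1)
  vals
}
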