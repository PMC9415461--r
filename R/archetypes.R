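#' Mode-of-action archetype specification
#'
#' An archetype encodes the population-level phenotypic dynamics of one
#' treatment condition as piecewise-linear mean trajectories (knots in
#' hours) for nine free parameters, plus a per-cell heterogeneity model,
#' an AR(1) measurement-noise model, and an event model (mitotic arrest,
#' death hazard, division rate).
#'
#' Two parameters and the cell volume are derived rather than free, so that
#' per-record identities hold exactly: relative area
#' `area_pct = 100 * area / field_side^2`, compactness
#' `compactness = 1 / form_factor`, mean refractive index
#' `mean_ri = medium_index + ri_increment * dmd`, and
#' `volume = dry_mass / dmd`.
#'
#' @param name Condition label.
#' @param knots Named list with one `cbind(hours, value)` matrix per free
#'   parameter (`area`, `perimeter`, `form_factor`, `extent`,
#'   `eccentricity`, `dmd`, `dry_mass`, `granularity`); rows sorted by time.
#' @param cell_effect_sd Log-scale SD of the lognormal per-cell
#'   multiplicative effect (one draw per cell per parameter, constant in
#'   time). Dimensionless.
#' @param noise_sd Named vector of stationary AR(1) noise SDs, in each
#'   parameter's own units. Missing entries default to 0.
#' @param noise_autocorr AR(1) coefficient in `[0, 1)`.
#' @param arrest_onset Time (h) after which cells stop dividing, or `NULL`.
#' @param death_onset,death_hazard Death model: after `death_onset` (h) each
#'   cell dies with per-cycle probability `death_hazard`; `NULL` disables.
#' @param division_rate Per-cell per-hour division probability, or `NULL`.
#' @param medium_index Refractive index of the culture medium.
#' @param ri_increment Specific refractive increment relating dry mass
#'   density to refractive-index excess, um^3/pg.
#' @return An object of class `archetype_spec`.
#' @seealso [builtin_archetypes()]
#' @export
archetype_spec <- function(name, knots, cell_effect_sd = 0.1,
                           noise_sd = NULL, noise_autocorr = 0.6,
                           arrest_onset = NULL, death_onset = NULL,
                           death_hazard = NULL, division_rate = NULL,
                           medium_index = 1.333, ri_increment = 0.19) {
  free <- free_params()
  if (!is.list(knots) || !all(free %in% names(knots)))
    stop("configuration error: 'knots' must name all of: ",
         paste(free, collapse = ", "), call. = FALSE)
  rng <- calibration_ranges()
  for (p in free) {
    k <- knots[[p]]
    if (!is.matrix(k)) k <- matrix(k, ncol = 2)
    if (ncol(k) != 2 || nrow(k) < 1 || any(!is.finite(k)))
      stop("configuration error: knots for '", p,
           "' must be a finite (hours, value) matrix", call. = FALSE)
    if (is.unsorted(k[, 1], strictly = FALSE))
      stop("configuration error: knots for '", p,
           "' are not sorted by time", call. = FALSE)
    r <- rng[[p]]
    if (any(k[, 2] < r[1] | k[, 2] > r[2]))
      stop("configuration error: knot value for '", p,
           "' outside calibration range [", r[1], ", ", r[2], "]",
           call. = FALSE)
    colnames(k) <- c("hours", "value")
    knots[[p]] <- k
  }
  # derived parameters must also respect their calibration ranges at knots
  ri_at <- medium_index + ri_increment * knots$dmd[, "value"]
  if (any(ri_at < rng$mean_ri[1] | ri_at > rng$mean_ri[2]))
    stop("configuration error: derived mean RI outside calibration range",
         call. = FALSE)
  cmp_at <- 1 / knots$form_factor[, "value"]
  if (any(cmp_at < rng$compactness[1] | cmp_at > rng$compactness[2]))
    stop("configuration error: derived compactness outside calibration range",
         call. = FALSE)
  if (!is.numeric(cell_effect_sd) || cell_effect_sd < 0)
    stop("configuration error: 'cell_effect_sd' must be >= 0", call. = FALSE)
  if (!is.numeric(noise_autocorr) || noise_autocorr < 0 || noise_autocorr >= 1)
    stop("configuration error: 'noise_autocorr' must lie in [0, 1)",
         call. = FALSE)
  ns <- stats::setNames(numeric(length(free)), free)
  if (!is.null(noise_sd)) {
    if (is.null(names(noise_sd)) || !all(names(noise_sd) %in% free))
      stop("configuration error: 'noise_sd' names must be free parameters",
           call. = FALSE)
    if (any(noise_sd < 0))
      stop("configuration error: 'noise_sd' must be >= 0", call. = FALSE)
    ns[names(noise_sd)] <- noise_sd
  }
  for (nm in c("arrest_onset", "death_onset", "death_hazard",
               "division_rate")) {
    v <- get(nm)
    if (!is.null(v) && (!is.numeric(v) || length(v) != 1L || v < 0))
      stop("configuration error: '", nm, "' must be a single value >= 0",
           call. = FALSE)
  }
  if (!is.null(death_hazard) && death_hazard > 1)
    stop("configuration error: 'death_hazard' is a probability (<= 1)",
         call. = FALSE)
  structure(list(name = name, knots = knots, cell_effect_sd = cell_effect_sd,
                 noise_sd = ns, noise_autocorr = noise_autocorr,
                 arrest_onset = arrest_onset, death_onset = death_onset,
                 death_hazard = death_hazard, division_rate = division_rate,
                 medium_index = medium_index, ri_increment = ri_increment),
            class = "archetype_spec")
}

#' @export
print.archetype_spec <- function(x, ...) {
  cat(sprintf("<archetype_spec> '%s': %d free-parameter trajectories, cell effect sd %g, AR(1) rho %g\n",
              x$name, length(x$knots), x$cell_effect_sd, x$noise_autocorr))
  invisible(x)
}

free_params <- function() {
  c("area", "perimeter", "form_factor", "extent", "eccentricity",
    "dmd", "dry_mass", "granularity")
}

derived_params <- function() c("area_pct", "compactness", "mean_ri")

default_noise_sd <- function() {
  c(area = 8, perimeter = 3, form_factor = 0.012, extent = 0.01,
    eccentricity = 0.012, dmd = 0.003, dry_mass = 3.5, granularity = 0.2)
}

kn <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  colnames(m) <- c("hours", "value")
  m
}

#' Built-in mode-of-action archetypes
#'
#' Returns the three calibrated archetypes the package ships:
#'
#' * `control` — untreated cells: slow growth in area and dry mass, broadly
#'   stable shape, ongoing division.
#' * `stabilizer` — microtubule-stabilizer phenotype: cells enter an
#'   unresolved mitotic arrest at about 10 h and round up (form factor
#'   rises, eccentricity falls), while dry mass density falls through the
#'   first half of the acquisition with near-constant dry mass.
#' * `disruptor` — microtubule-disruptor phenotype: cell area contracts
#'   by more than 20 percent within about 2 h, dry mass density rises along
#'   the acquisition with a slight fall at the end, and a late death hazard
#'   removes necrotic cells.
#'
#' @return Named list of [archetype_spec()] objects
#'   (`control`, `stabilizer`, `disruptor`).
#' @examples
#' names(builtin_archetypes())
#' @export
builtin_archetypes <- function() {
  list(
    control = archetype_spec(
      "control",
      knots = list(
        area        = kn(0, 400, 20, 550),
        perimeter   = kn(0, 160, 20, 190),
        form_factor = kn(0, 0.40, 20, 0.38),
        extent      = kn(0, 0.60, 20, 0.58),
        eccentricity = kn(0, 0.78, 20, 0.80),
        dmd         = kn(0, 0.120, 20, 0.125),
        dry_mass    = kn(0, 140, 20, 170),
        granularity = kn(0, 10, 20, 10.5)
      ),
      noise_sd = default_noise_sd(),
      division_rate = 0.03
    ),
    stabilizer = archetype_spec(
      "stabilizer",
      knots = list(
        area        = kn(0, 450, 10, 430, 20, 380),
        perimeter   = kn(0, 180, 10, 170, 20, 120),
        form_factor = kn(0, 0.35, 10, 0.40, 20, 0.65),
        extent      = kn(0, 0.55, 10, 0.60, 20, 0.70),
        eccentricity = kn(0, 0.80, 10, 0.75, 20, 0.50),
        dmd         = kn(0, 0.150, 10, 0.110, 20, 0.115),
        dry_mass    = kn(0, 150, 10, 150, 20, 155),
        granularity = kn(0, 10, 10, 11, 20, 12)
      ),
      noise_sd = default_noise_sd(),
      arrest_onset = 10, division_rate = 0.03
    ),
    disruptor = archetype_spec(
      "disruptor",
      knots = list(
        area        = kn(0, 450, 2, 340, 16, 300, 20, 290),
        perimeter   = kn(0, 180, 2, 130, 20, 110),
        form_factor = kn(0, 0.35, 2, 0.50, 20, 0.55),
        extent      = kn(0, 0.55, 2, 0.65, 20, 0.66),
        eccentricity = kn(0, 0.80, 2, 0.65, 20, 0.60),
        dmd         = kn(0, 0.110, 16, 0.160, 20, 0.150),
        dry_mass    = kn(0, 150, 16, 150, 20, 140),
        granularity = kn(0, 10, 20, 13)
      ),
      noise_sd = default_noise_sd(),
      division_rate = 0.01, death_onset = 12, death_hazard = 0.003
    )
  )
}

# piecewise-linear mean trajectory of every free parameter, one column each,
# evaluated at the config's cycle times (flat extrapolation past end knots)
mean_trajectories <- function(archetype, config) {
  hours <- seq_len(config$n_cycles) * config$interval / 60
  vapply(free_params(), function(p) {
    k <- archetype$knots[[p]]
    if (nrow(k) == 1) rep(k[1, "value"], length(hours))
    else stats::approx(k[, "hours"], k[, "value"], xout = hours,
                       rule = 2)$y
  }, numeric(length(hours)))
}
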