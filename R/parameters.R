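#' The eleven phenotypic parameters
#'
#' Metadata for the eleven phenotypic parameters measured per cell per
#' imaging cycle: seven cell-morphology parameters (area, relative area,
#' perimeter, form factor, extent, compactness, eccentricity) and four
#' cell-composition parameters derived from quantitative phase imaging
#' (mean refractive index, average dry mass density, dry mass, granularity).
#' The calibration range of each parameter is the axis range within which
#' population means are expected to move for the cell system the package
#' models (an adherent NSCLC line imaged every 3 min for 20 h).
#'
#' @return A data frame with one row per parameter, in canonical order:
#'   `param` (internal label), `short` (plot abbreviation), `units`,
#'   `subtype` (`"morphology"` or `"composition"`), and the calibration
#'   range `low`, `high`.
#' @examples
#' phenotype_parameters()
#' @export
phenotype_parameters <- function() {
  data.frame(
    param = c("area", "area_pct", "perimeter", "form_factor", "extent",
              "compactness", "eccentricity", "mean_ri", "dmd", "dry_mass",
              "granularity"),
    short = c("A", "A%", "P", "FF", "EX", "C", "EC", "RI", "DMD", "DM", "G"),
    units = c("um^2", "%", "um", "", "", "", "", "", "pg/um^3", "pg", ""),
    subtype = c(rep("morphology", 7), rep("composition", 4)),
    low  = c(0, 0.4, 50, 0, 0.4, 0, 0.2, 1.34, 0.05, 80, 5),
    high = c(1000, 2, 400, 0.8, 0.8, 15, 1, 1.37, 0.2, 250, 15),
    stringsAsFactors = FALSE
  )
}

#' Calibration ranges for the phenotypic parameters
#'
#' @return Named list mapping each parameter label to its `c(low, high)`
#'   calibration range.
#' @seealso [phenotype_parameters()]
#' @export
calibration_ranges <- function() {
  p <- phenotype_parameters()
  stats::setNames(lapply(seq_len(nrow(p)), function(i) c(p$low[i], p$high[i])),
                  p$param)
}

# canonical parameter order used everywhere downstream
param_names <- function() phenotype_parameters()$param

# columns a records table must carry besides the parameters
record_id_cols <- function() c("condition", "cell_id", "cycle", "alive")
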