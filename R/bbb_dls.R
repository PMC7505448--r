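#' @title Transwell BBB permeability and DLS summaries
#' @description Volume-corrected fluorescence accounting for the
#'   four-compartment transwell blood-brain-barrier permeability assay,
#'   intensity-weighted dynamic-light-scattering summary statistics, and
#'   absorbance fold-changes.
#' @name bbb_dls
NULL

.BBB_COMPARTMENTS <- c("apical_supernatant", "apical_pellet",
                       "basal_supernatant", "basal_pellet",
                       "cell_lysate", "filter")

#' Construct transwell fluorescence readings
#'
#' Each compartment carries the plate-reader value, the volume actually
#' sampled into the plate, and the total volume of the pool it
#' represents, so dilution/concentration factors (e.g. a pellet
#' resuspended 5x concentrated) are explicit inputs rather than hidden
#' constants.
#'
#' @param readings Named numeric vector of fluorescence values (>= 0)
#'   over the compartments `apical_supernatant`, `apical_pellet`,
#'   `basal_supernatant`, `basal_pellet`, `cell_lysate`, `filter`.
#' @param sampled_volume,total_volume Named numeric vectors (same names)
#'   in microliters; `sampled_volume <= total_volume` when the sample is
#'   a subaliquot, while a concentrated resuspension is expressed by a
#'   `total_volume` exceeding the resuspension volume.
#' @return A `fluorescence_readings` object.
#' @export
fluorescence_readings <- function(readings, sampled_volume, total_volume) {
  for (v in list(readings, sampled_volume, total_volume)) {
    if (!all(.BBB_COMPARTMENTS %in% names(v))) {
      stop("all six compartments must be named: ",
           paste(.BBB_COMPARTMENTS, collapse = ", "))
    }
  }
  if (any(readings < 0)) stop("readings must be >= 0")
  if (any(sampled_volume <= 0)) stop("sampled volumes must be > 0")
  structure(list(readings = readings[.BBB_COMPARTMENTS],
                 sampled_volume = sampled_volume[.BBB_COMPARTMENTS],
                 total_volume = total_volume[.BBB_COMPARTMENTS]),
            class = "fluorescence_readings")
}

#' Default transwell sampling volumes
#'
#' The standard assay layout: 400 uL collected apically and 1.4 mL
#' basally; 200 uL of each supernatant read; apical pellet resuspended
#' in 400 uL (200 read), basal pellet resuspended 5x concentrated in
#' 280 uL (200 read, representing 1400 uL); cell lysate and filter read
#' whole.
#'
#' @return List with `sampled_volume` and `total_volume` vectors usable
#'   with [fluorescence_readings()].
#' @export
default_bbb_volumes <- function() {
  list(
    sampled_volume = c(apical_supernatant = 200, apical_pellet = 200,
                       basal_supernatant = 200, basal_pellet = 200,
                       cell_lysate = 250, filter = 250),
    total_volume = c(apical_supernatant = 400, apical_pellet = 400,
                     basal_supernatant = 1400, basal_pellet = 1400,
                     cell_lysate = 250, filter = 250)
  )
}

#' Total fluorescence per compartment
#'
#' Scales each reading by its volume factor:
#' `total = reading * total_volume / sampled_volume`. Linear in the
#' readings.
#'
#' @param readings A [fluorescence_readings()].
#' @return Named numeric vector of compartment totals.
#' @export
compartment_totals <- function(readings) {
  readings$readings * readings$total_volume / readings$sampled_volume
}

#' Four-compartment permeability percentages
#'
#' Pools apical supernatant+pellet and basal supernatant+pellet, sets
#' the grand total to 100 %, and reports the partition used for
#' transwell permeability tables: tracer that passed the bare filter,
#' passed the cell barrier (BBB), stayed apical, or was retained inside
#' the endothelial cells.
#'
#' @param totals Named compartment totals from [compartment_totals()],
#'   or a [fluorescence_readings()] (converted internally).
#' @return A `permeability_result`: named numeric vector
#'   `pct_passed_filter`, `pct_passed_bbb`, `pct_retained_apical`,
#'   `pct_retained_cells`, summing to 100.
#' @export
permeability_percentages <- function(totals) {
  if (inherits(totals, "fluorescence_readings")) {
    totals <- compartment_totals(totals)
  }
  grand <- sum(totals)
  if (grand <= 0) stop("all-zero fluorescence: cannot normalize")
  out <- c(
    pct_passed_filter = unname(totals["filter"]),
    pct_passed_bbb = unname(totals["basal_supernatant"] + totals["basal_pellet"]),
    pct_retained_apical = unname(totals["apical_supernatant"] + totals["apical_pellet"]),
    pct_retained_cells = unname(totals["cell_lysate"])
  ) / grand * 100
  structure(out, class = "permeability_result")
}

#' @export
print.permeability_result <- function(x, ...) {
  cat("Transwell permeability partition (% of total fluorescence)\n")
  lbl <- c(pct_passed_filter = "Passed TW filter",
           pct_passed_bbb = "Passed BBB",
           pct_retained_apical = "Retained apical side",
           pct_retained_cells = "Retained in cells")
  for (k in names(lbl)) cat(sprintf("  %-22s %6.2f\n", lbl[k], x[k]))
  invisible(x)
}

#' Intensity-weighted DLS summary
#'
#' Mean hydrodynamic diameter as the intensity-weighted mean of the
#' diameter grid, and polydispersity index as the intensity-weighted
#' relative variance `var_w / mean^2` (zero only for a single point
#' mass). The relative-variance convention replaces cumulant fitting of
#' raw correlograms, which plate-level exports do not carry.
#'
#' @param diameters Numeric grid of hydrodynamic diameters (nm).
#' @param intensity Non-negative weights, same length, positive total.
#' @return List with `mean_hd` (nm) and `pdi`.
#' @examples
#' dls_summary(c(50, 90), c(1, 1)) # mean 70 nm, PDI 400/4900
#' @export
dls_summary <- function(diameters, intensity) {
  if (length(diameters) != length(intensity)) stop("length mismatch")
  if (any(intensity < 0)) stop("weights must be >= 0")
  tot <- sum(intensity)
  if (tot <= 0) stop("zero total intensity")
  w <- intensity / tot
  m <- sum(w * diameters)
  v <- sum(w * (diameters - m)^2)
  list(mean_hd = m, pdi = v / m^2)
}

#' Fold change between two absorbance (or other) values
#'
#' @param value_before,value_after Values before/after treatment;
#'   `value_after` must be positive.
#' @return `value_before / value_after`.
#' @export
fold_change <- function(value_before, value_after) {
  if (any(value_after <= 0)) stop("value_after must be > 0")
  value_before / value_after
}
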