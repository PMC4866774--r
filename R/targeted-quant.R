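#' Internal-standard normalization of a peak area
#'
#' Divides the analyte peak area by the matching internal-standard area
#' (here, the U-13C labeled analogue from a labeled E. coli extract spiked
#' into every sample). The resulting response ratio is invariant to global
#' instrument-sensitivity changes that scale both channels.
#'
#' @param area Analyte peak area(s), >= 0.
#' @param is_area Internal-standard peak area(s), > 0.
#' @return Response ratio(s) `area / is_area`.
#' @examples
#' is_normalize(10, 2)  # 5
#' @export
is_normalize <- function(area, is_area) {
  if (anyNA(area) || any(area < 0)) stop("peak areas must be non-negative")
  if (anyNA(is_area) || any(is_area <= 0))
    stop("internal-standard areas must be positive; drop affected rows")
  area / is_area
}

#' Fit a calibration curve
#'
#' Ordinary least-squares line through external standards of known
#' concentration, relating response ratio to concentration.
#'
#' @param concentration Known standard concentrations (>= 2 points).
#' @param ratio Measured response ratios at those concentrations.
#' @param metabolite_id Optional label carried in the result.
#' @return An object of class `calibration_curve` with `slope`, `intercept`.
#' @examples
#' fit_calibration(c(0, 1, 2), c(0, 2, 4))  # slope 2, intercept 0
#' @export
fit_calibration <- function(concentration, ratio, metabolite_id = NULL) {
  if (length(concentration) < 2L || length(concentration) != length(ratio))
    stop("calibration requires >= 2 (concentration, ratio) points")
  fit <- stats::lm(ratio ~ concentration)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope <= 0)
    stop("calibration slope must be positive")
  structure(list(metabolite_id = metabolite_id, slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 points = data.frame(concentration = concentration,
                                     ratio = ratio)),
            class = "calibration_curve")
}

#' Convert response ratios to concentrations
#'
#' Inverts the fitted calibration line: concentration =
#' (ratio - intercept) / slope. Ratios falling below the intercept map to
#' concentration 0 and are flagged.
#'
#' @param ratio Response ratio(s) from [is_normalize()].
#' @param curve A [fit_calibration()] result.
#' @return Data frame with `concentration` and logical `floored`.
#' @examples
#' calibrate(3, fit_calibration(c(0, 1, 2), c(0, 2, 4)))  # 1.5
#' @export
calibrate <- function(ratio, curve) {
  if (!inherits(curve, "calibration_curve"))
    stop("curve must be a fitted calibration_curve")
  conc <- (ratio - curve$intercept) / curve$slope
  floored <- conc < 0
  conc[floored] <- 0
  data.frame(concentration = conc, floored = floored)
}

#' Normalize concentrations to cellular protein
#'
#' @param concentration Metabolite concentration(s).
#' @param protein_mg Protein content of the sample in mg, > 0.
#' @return Concentration per mg protein.
#' @examples
#' protein_normalize(4, 2)  # 2
#' @export
protein_normalize <- function(concentration, protein_mg) {
  if (anyNA(protein_mg) || any(protein_mg <= 0))
    stop("protein content must be positive; reject affected samples")
  concentration / protein_mg
}

#' Quantify a targeted peak table
#'
#' Composes the targeted-metabolomics pipeline row-wise: internal-standard
#' normalization, calibration against the matching curve, then protein
#' normalization. The derivatized-pyruvate branch (phenylhydrazine
#' derivatization with a [U-13C]pyruvate internal standard) runs through the
#' same path with its own internal-standard column — a configuration, not
#' separate code.
#'
#' @param peaks Data frame with columns `sample_id`, `metabolite_id`,
#'   `peak_area`, `internal_standard_area`, `protein_mg`.
#' @param curves Named list of [fit_calibration()] curves, one per
#'   metabolite; metabolites without a curve keep the response ratio
#'   (relative quantification).
#' @return The input with added `ratio`, `concentration`, `floored`,
#'   `conc_per_mg` columns.
#' @export
quantify_peak_table <- function(peaks, curves = list()) {
  need <- c("sample_id", "metabolite_id", "peak_area",
            "internal_standard_area", "protein_mg")
  if (!all(need %in% names(peaks)))
    stop("peak table must have columns: ", paste(need, collapse = ", "))
  peaks$ratio <- is_normalize(peaks$peak_area, peaks$internal_standard_area)
  peaks$concentration <- peaks$ratio
  peaks$floored <- FALSE
  for (m in intersect(names(curves), unique(peaks$metabolite_id))) {
    sel <- peaks$metabolite_id == m
    cal <- calibrate(peaks$ratio[sel], curves[[m]])
    peaks$concentration[sel] <- cal$concentration
    peaks$floored[sel] <- cal$floored
  }
  peaks$conc_per_mg <- protein_normalize(peaks$concentration, peaks$protein_mg)
  peaks
}
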