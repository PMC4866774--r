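#' Oxygen-consumption trace
#'
#' Container for an extracellular-flux (Seahorse-style) OCR trace:
#' timestamped measurement loops plus injection events. With oligomycin
#' present from assay start (permeabilized-cell protocol), the phases are
#' basal, fCCP (uncoupled maximal respiration), succinate/rotenone, and
#' antimycin A (non-mitochondrial floor).
#'
#' @param time Measurement times (seconds), strictly increasing, >= 0.
#' @param ocr OCR values at those times.
#' @param injections Data frame with `time` and `label` (one of `fccp`,
#'   `succinate_rotenone`, `antimycin_a`), ordered by time.
#' @param cell_count Optional cell count for normalization.
#' @return An object of class `ocr_trace`.
#' @export
ocr_trace <- function(time, ocr, injections, cell_count = NULL) {
  if (length(time) != length(ocr)) stop("time and ocr lengths differ")
  if (any(time < 0)) stop("measurements before time 0 are invalid")
  if (is.unsorted(time, strictly = TRUE))
    stop("measurement times must be strictly increasing")
  if (nrow(injections) > 0) {
    if (!all(c("time", "label") %in% names(injections)))
      stop("injections need 'time' and 'label' columns")
    if (is.unsorted(injections$time)) stop("injections must be ordered")
  }
  structure(list(time = time, ocr = ocr, injections = injections,
                 cell_count = cell_count), class = "ocr_trace")
}

#' Split an OCR trace into injection-delimited phases
#'
#' Basal = measurement loops before the first injection; each later phase
#' contains the loops between consecutive injections (and after the last).
#' The phases partition the trace: no loop belongs to two phases.
#'
#' @param trace An [ocr_trace()].
#' @return Named list of data frames (`time`, `ocr`), one per phase.
#' @export
segment_phases <- function(trace) {
  stopifnot(inherits(trace, "ocr_trace"))
  inj <- trace$injections
  bounds <- c(-Inf, inj$time, Inf)
  labels <- c("basal", as.character(inj$label))
  phases <- lapply(seq_along(labels), function(i) {
    # loops at or after an injection belong to its phase
    sel <- trace$time >= bounds[i] & trace$time < bounds[i + 1L]
    data.frame(time = trace$time[sel], ocr = trace$ocr[sel])
  })
  names(phases) <- labels
  phases
}

#' fCCP-driven (maximal uncoupled) OCR
#'
#' Mean OCR of the fCCP phase minus the mean of the antimycin-A phase (the
#' non-mitochondrial floor). The floor subtraction is the standard reading
#' of "fCCP-driven" and can be switched off.
#'
#' @param trace An [ocr_trace()].
#' @param subtract_floor Subtract the antimycin-A phase mean (default TRUE).
#' @return A single OCR value.
#' @export
fccp_driven_ocr <- function(trace, subtract_floor = TRUE) {
  phases <- segment_phases(trace)
  if (!"fccp" %in% names(phases) || nrow(phases$fccp) == 0L)
    stop("trace has no fccp phase")
  val <- mean(phases$fccp$ocr)
  if (subtract_floor) {
    if (!"antimycin_a" %in% names(phases) ||
        nrow(phases$antimycin_a) == 0L)
      stop("trace has no antimycin_a phase")
    val <- val - mean(phases$antimycin_a$ocr)
  }
  val
}

#' Normalize an OCR value to cell number
#'
#' @param value OCR value(s).
#' @param cell_count Cells in the well, > 0.
#' @param per Report per this many cells (default 1e4).
#' @return OCR per `per` cells.
#' @examples
#' cell_normalize(100, 10000)  # 100 per 1e4 cells
#' @export
cell_normalize <- function(value, cell_count, per = 1e4) {
  if (anyNA(cell_count) || any(cell_count <= 0))
    stop("cell count must be positive")
  value / cell_count * per
}
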