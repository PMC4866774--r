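# Monoisotopic masses of the elements occurring in the compound library.
.monoisotopic_masses <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
                          O = 15.9949146221, P = 30.97376151,
                          S = 31.97207069)

.mass_13c_shift <- 1.003355
.proton_mass <- 1.007276

# Adduct mass deltas (Da) relative to the neutral monoisotopic mass, for
# negative-mode flow injection: deprotonated [M-H]-, fluoride [M+F]-,
# sodium [M+Na-2H]- and potassium [M+K-2H]-.
.adduct_deltas <- c(deprotonated = -1.007276,
                    fluoride = +18.998403,
                    sodium = +20.974666,
                    potassium = +36.948606)

#' Monoisotopic mass of an elemental formula
#'
#' Supports the elements C, H, N, O, P, S in Hill-like notation (e.g.
#' `"C3H6O3"` for lactate, mass 90.031694).
#'
#' @param formula Character vector of elemental formulas.
#' @return Numeric vector of monoisotopic neutral masses (Da).
#' @examples
#' formula_monoisotopic_mass("C3H6O3")
#' @export
formula_monoisotopic_mass <- function(formula) {
  vapply(formula, function(f) {
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    parts <- regmatches(f, list(m))[[1]]
    parts <- parts[nzchar(parts)]
    total <- 0
    seen <- 0L
    for (p in parts) {
      el <- gsub("[0-9]", "", p)
      ct <- gsub("[A-Za-z]", "", p)
      ct <- if (nzchar(ct)) as.integer(ct) else 1L
      if (!el %in% names(.monoisotopic_masses))
        stop(sprintf("unsupported element '%s' in formula '%s'", el, f))
      total <- total + .monoisotopic_masses[[el]] * ct
      seen <- seen + nchar(p)
    }
    if (seen != nchar(f)) stop(sprintf("cannot parse formula '%s'", f))
    total
  }, 0, USE.NAMES = FALSE)
}

#' Read a compound library
#'
#' Loads a TSV with columns `compound_id`, `name`, `formula`,
#' `monoisotopic_mass` (Da). Stored masses are checked against the formula
#' to within 1e-4 Da. The package ships a synthetic stand-in library of 222
#' compounds (`brain_library_synthetic.tsv` under `extdata`) emulating the
#' annotated brain metabolome.
#'
#' @param path Path to the library TSV. Defaults to the packaged synthetic
#'   brain library.
#' @return Data frame of compound records.
#' @examples
#' lib <- read_compound_library()
#' nrow(lib)
#' @export
read_compound_library <- function(path = system.file(
    "extdata", "brain_library_synthetic.tsv", package = "mpctrace")) {
  lib <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "name", "formula", "monoisotopic_mass")
  if (!all(need %in% names(lib)))
    stop("compound library must have columns: ", paste(need, collapse = ", "))
  if (any(lib$monoisotopic_mass <= 0)) stop("monoisotopic masses must be > 0")
  calc <- formula_monoisotopic_mass(lib$formula)
  bad <- abs(calc - lib$monoisotopic_mass) > 1e-4
  if (any(bad))
    stop("stored mass inconsistent with formula for: ",
         paste(lib$compound_id[bad], collapse = ", "))
  lib
}

#' Enumerate ionic species for a compound library
#'
#' Generates every (compound, adduct, isotope shift) combination whose m/z
#' falls inside the acquisition window. The m/z of a candidate is the
#' neutral monoisotopic mass plus the adduct delta plus
#' `isotope_shift * 1.003355` (number of 13C).
#'
#' @param library Data frame from [read_compound_library()].
#' @param adducts Subset of `c("deprotonated", "fluoride", "sodium",
#'   "potassium")`.
#' @param max_isotope Highest 13C isotope shift enumerated (default 2).
#' @param mz_range Retained m/z window (default the instrument's 50-1000).
#' @return Data frame of ion candidates: `compound_id`, `adduct`,
#'   `isotope_shift`, `mz`, sorted by `mz`.
#' @examples
#' lib <- data.frame(compound_id = "lactate", name = "lactate",
#'                   formula = "C3H6O3", monoisotopic_mass = 90.031694)
#' enumerate_ions(lib, adducts = "deprotonated", max_isotope = 0)
#' @export
enumerate_ions <- function(library, adducts = names(.adduct_deltas),
                           max_isotope = 2L, mz_range = c(50, 1000)) {
  if (length(adducts) == 0L) stop("adduct set must be non-empty")
  unknown <- setdiff(adducts, names(.adduct_deltas))
  if (length(unknown))
    stop("unknown adduct label(s): ", paste(unknown, collapse = ", "))
  if (nrow(library) == 0L)
    return(data.frame(compound_id = character(), adduct = character(),
                      isotope_shift = integer(), mz = numeric()))
  grid <- expand.grid(row = seq_len(nrow(library)), adduct = adducts,
                      isotope_shift = 0:max_isotope,
                      stringsAsFactors = FALSE)
  out <- data.frame(
    compound_id = library$compound_id[grid$row],
    adduct = grid$adduct,
    isotope_shift = as.integer(grid$isotope_shift),
    mz = library$monoisotopic_mass[grid$row] +
      .adduct_deltas[grid$adduct] +
      grid$isotope_shift * .mass_13c_shift,
    stringsAsFactors = FALSE)
  out <- out[out$mz >= mz_range[1] & out$mz <= mz_range[2], , drop = FALSE]
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate centroid peaks by accurate mass
#'
#' Matches each peak to every ion candidate within an absolute mass
#' tolerance (the instrument method uses 0.001 a.m.u.). Candidates are
#' binary-searched on their sorted m/z, so matching is O((n + m) log n).
#' When several candidates match one peak, all are reported and the smallest
#' absolute error is flagged `primary`. Unmatched peaks are omitted.
#'
#' @param peaks Data frame with columns `mz` and `intensity`.
#' @param candidates Data frame from [enumerate_ions()].
#' @param tolerance Absolute tolerance in Da (default 0.001).
#' @return Data frame of annotations: `mz`, `intensity`, `compound_id`,
#'   `adduct`, `isotope_shift`, `candidate_mz`, `mass_error`, `primary`.
#' @export
annotate_peaks <- function(peaks, candidates, tolerance = 0.001) {
  if (is.na(tolerance) || tolerance < 0) stop("tolerance must be >= 0")
  empty <- data.frame(mz = numeric(), intensity = numeric(),
                      compound_id = character(), adduct = character(),
                      isotope_shift = integer(), candidate_mz = numeric(),
                      mass_error = numeric(), primary = logical())
  if (nrow(peaks) == 0L || nrow(candidates) == 0L) return(empty)
  candidates <- candidates[order(candidates$mz), , drop = FALSE]
  cmz <- candidates$mz
  lo <- findInterval(peaks$mz - tolerance, cmz) + 1L
  hi <- findInterval(peaks$mz + tolerance, cmz)
  keep <- lo <= hi
  if (!any(keep)) return(empty)
  rows <- lapply(which(keep), function(i) {
    j <- lo[i]:hi[i]
    err <- peaks$mz[i] - cmz[j]
    j <- j[abs(err) <= tolerance]
    if (!length(j)) return(NULL)
    err <- peaks$mz[i] - cmz[j]
    data.frame(mz = peaks$mz[i], intensity = peaks$intensity[i],
               compound_id = candidates$compound_id[j],
               adduct = candidates$adduct[j],
               isotope_shift = candidates$isotope_shift[j],
               candidate_mz = cmz[j], mass_error = err,
               primary = abs(err) == min(abs(err)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Collapse annotations to a metabolite-ion table
#'
#' The unit of the downstream differential analysis is the annotated
#' metabolite ion: one row per distinct (compound, adduct), with the summed
#' intensity of its monoisotopic (isotope shift 0) peaks. Rows are ordered
#' by candidate m/z for deterministic output.
#'
#' @param annotations Data frame from [annotate_peaks()].
#' @return Data frame with `compound_id`, `adduct`, `mz`, `intensity`.
#' @export
collapse_to_ion_table <- function(annotations) {
  ann <- annotations[annotations$isotope_shift == 0L, , drop = FALSE]
  if (nrow(ann) == 0L)
    return(data.frame(compound_id = character(), adduct = character(),
                      mz = numeric(), intensity = numeric()))
  key <- paste(ann$compound_id, ann$adduct, sep = "\r")
  agg <- stats::aggregate(ann$intensity, by = list(key = key), FUN = sum)
  first <- ann[!duplicated(key), c("compound_id", "adduct", "candidate_mz")]
  first$key <- key[!duplicated(key)]
  out <- merge(first, agg, by = "key")
  out <- data.frame(compound_id = out$compound_id, adduct = out$adduct,
                    mz = out$candidate_mz, intensity = out$x,
                    stringsAsFactors = FALSE)
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}
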