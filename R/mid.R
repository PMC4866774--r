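#' Mass isotopomer distributions
#'
#' A mass isotopomer distribution (MID) for an n-carbon metabolite is a
#' numeric vector of length n+1 giving the fractional abundances of the
#' M+0 ... M+n isotopologues. Entries are non-negative and sum to 1.
#'
#' @param mid Numeric vector of isotopologue fractions (M+0 first).
#' @param tol Tolerance on the unit-sum constraint.
#' @return `validate_mid()` returns `mid` invisibly, or throws an error.
#' @examples
#' validate_mid(c(0.5, 0.3, 0.2))
#' @export
validate_mid <- function(mid, tol = 1e-9) {
  if (!is.numeric(mid) || length(mid) < 1L)
    stop("an MID must be a numeric vector of length >= 1")
  if (anyNA(mid)) stop("MID contains missing values")
  if (any(mid < -tol)) stop("MID entries must be non-negative")
  if (abs(sum(mid) - 1) > tol)
    stop(sprintf("MID entries must sum to 1 (got %.12f)", sum(mid)))
  invisible(mid)
}

#' Convolve two mass isotopomer distributions
#'
#' The MID of a condensation product (e.g. citrate formed from acetyl-CoA
#' and oxaloacetate at the citrate synthase step) is the discrete
#' convolution of the substrate MIDs: a molecule carrying i labels from one
#' backbone and j from the other contributes to M+(i+j).
#'
#' @param a,b Valid MIDs (see [validate_mid()]).
#' @return An MID of length `length(a) + length(b) - 1`.
#' @examples
#' convolve_mids(c(0.5, 0.5), c(0.5, 0.5))  # 0.25, 0.50, 0.25
#' @export
convolve_mids <- function(a, b) {
  validate_mid(a)
  validate_mid(b)
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i + seq_along(b) - 1L
    out[idx] <- out[idx] + a[i] * b
  }
  out / sum(out)
}

#' Carbon-weighted fractional labeling of an MID
#'
#' Returns the mean fraction of labeled carbons, sum(i * M_i) / n, a single
#' summary of total label incorporation.
#'
#' @param mid A valid MID of length n+1.
#' @return A fraction in \[0, 1\].
#' @examples
#' fractional_labeling(c(0.5, 0, 0.5))  # 0.5
#' @export
fractional_labeling <- function(mid) {
  validate_mid(mid)
  n <- length(mid) - 1L
  if (n == 0L) return(0)
  sum((seq_along(mid) - 1L) * mid) / n
}
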