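#' Natural-abundance correction matrix for 13C
#'
#' Builds the lower-triangular matrix whose entry \[i, j\] (0-based masses)
#' is the probability of observing i total labeled carbons given j
#' tracer-labeled carbons, when each of the remaining n - j carbons carries a
#' natural 13C independently with probability `p_nat`:
#' entry\[i, j\] = choose(n - j, i - j) p^(i-j) (1-p)^(n-i) for i >= j.
#' Columns sum to 1.
#'
#' Only carbon is corrected; the measured fragments here are small enough
#' that H/N/O isotope contributions are handled upstream by the instrument
#' software. `n_carbons` is the carbon count of the measured fragment, so
#' fragment-specific acquisition is supported by constructing one matrix per
#' fragment length.
#'
#' @param n_carbons Carbon count of the measured (fragment) backbone, >= 1.
#' @param p_nat Natural 13C abundance, in \[0, 1). Default 0.0107.
#' @return An (n+1) x (n+1) matrix of class `correction_matrix`.
#' @examples
#' correction_matrix(2)            # columns are binomial(2 - j, 0.0107)
#' correction_matrix(2, p_nat = 0) # identity
#' @export
correction_matrix <- function(n_carbons, p_nat = 0.0107) {
  if (length(n_carbons) != 1L || is.na(n_carbons) || n_carbons < 1)
    stop("n_carbons must be a positive integer")
  n <- as.integer(n_carbons)
  if (is.na(p_nat) || p_nat < 0 || p_nat >= 1)
    stop("p_nat must lie in [0, 1)")
  cm <- matrix(0, n + 1L, n + 1L)
  for (j in 0:n) {
    i <- j:n
    cm[i + 1L, j + 1L] <- stats::dbinom(i - j, n - j, p_nat)
  }
  dimnames(cm) <- list(paste0("M+", 0:n), paste0("M+", 0:n))
  structure(cm, p_nat = p_nat, class = c("correction_matrix", "matrix"))
}

#' Correct a measured MID for naturally occurring 13C
#'
#' Solves cm x = raw for the tracer-derived distribution, clamps small
#' negative solution entries (measurement noise) to zero and renormalizes to
#' unit sum. The matrix is well conditioned for the fragment sizes used here
#' (n <= 6), so exact triangular inversion is appropriate.
#'
#' @param raw Measured isotopologue fraction vector of length n+1 (need not
#'   be exactly normalized; it is normalized on input).
#' @param cm A [correction_matrix()] with matching dimension.
#' @return The corrected MID.
#' @examples
#' cm <- correction_matrix(2)
#' correct_mid(as.numeric(cm %*% c(1, 0, 0)), cm)  # recovers c(1, 0, 0)
#' @export
correct_mid <- function(raw, cm) {
  stopifnot(inherits(cm, "correction_matrix"))
  if (length(raw) != nrow(cm))
    stop(sprintf("raw MID has length %d but the matrix expects %d",
                 length(raw), nrow(cm)))
  if (anyNA(raw) || any(raw < 0)) stop("raw intensities must be non-negative")
  s <- sum(raw)
  if (s <= 0) stop("raw intensities sum to zero")
  x <- as.numeric(solve(unclass(cm), raw / s))
  x[x < 0] <- 0
  if (sum(x) == 0) stop("correction yielded an empty distribution")
  x / sum(x)
}

#' Forward-contaminate an MID with natural 13C
#'
#' The adjoint of [correct_mid()]: given a tracer-derived MID, returns the
#' distribution that would be measured once each unlabeled carbon can carry a
#' natural 13C. Used by the synthetic-data generators and by round-trip
#' tests.
#'
#' @param mid A valid MID of length n+1.
#' @param cm A matching [correction_matrix()].
#' @return The contaminated MID.
#' @export
contaminate_mid <- function(mid, cm) {
  stopifnot(inherits(cm, "correction_matrix"))
  validate_mid(mid)
  if (length(mid) != nrow(cm))
    stop("MID length does not match the correction matrix")
  as.numeric(unclass(cm) %*% mid)
}
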