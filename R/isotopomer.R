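# Internal positional-isotopomer engine.
#
# A pool of an n-carbon metabolite is represented as a probability vector of
# length 2^n over binary labeling patterns; bit k (1-based carbon k) set means
# carbon k carries 13C. All atom-mapped reaction steps reduce to three
# primitives: carbon selection (marginalization), backbone condensation
# (outer product) and orientation averaging for symmetric intermediates.
# n <= 6 throughout, so the dense representation is cheap.

iso_unlabeled <- function(n) {
  v <- numeric(2^n)
  v[1L] <- 1
  v
}

# Pattern with exactly `positions` labeled, mixed at molecule level with
# unlabeled according to enrichment e (tracer purity).
iso_source <- function(n, positions, enrichment) {
  v <- numeric(2^n)
  v[1L] <- 1 - enrichment
  idx <- if (length(positions)) sum(2^(positions - 1L)) else 0L
  v[idx + 1L] <- v[idx + 1L] + enrichment
  v
}

iso_bit <- function(x, k) bitwAnd(bitwShiftR(x, k - 1L), 1L)

# Index map for selecting ordered source carbons into a product backbone:
# product carbon j derives from substrate carbon carbons[j]. Returns, for
# each substrate pattern (0-based), the 0-based product pattern.
iso_select_map <- function(n_src, carbons) {
  p <- 0:(2^n_src - 1L)
  q <- integer(length(p))
  for (j in seq_along(carbons)) {
    q <- q + bitwShiftL(iso_bit(p, carbons[j]), j - 1L)
  }
  q
}

iso_apply_map <- function(v, map, n_out) {
  out <- numeric(2^n_out)
  for (i in seq_along(v)) {
    k <- map[i] + 1L
    out[k] <- out[k] + v[i]
  }
  out
}

iso_select <- function(v, n_src, carbons) {
  iso_apply_map(v, iso_select_map(n_src, carbons), length(carbons))
}

# Condensation: substrate 1 contributes product carbons 1..n1, substrate 2
# carbons n1+1..n1+n2 (compose with iso_select for other orderings).
iso_combine <- function(v1, v2) as.vector(outer(v1, v2))

# Orientation average for a chemically symmetric metabolite (succinate,
# fumarate): the two end-to-end orientations are indistinguishable.
iso_symmetrize <- function(v, n) {
  (v + iso_select(v, n, n:1)) / 2
}

iso_popcount <- function(n) {
  p <- 0:(2^n - 1L)
  cnt <- integer(length(p))
  for (k in seq_len(n)) cnt <- cnt + iso_bit(p, k)
  cnt
}

iso_to_mid <- function(v, n) {
  mid <- numeric(n + 1L)
  cnt <- iso_popcount(n) + 1L
  for (i in seq_along(v)) mid[cnt[i]] <- mid[cnt[i]] + v[i]
  mid
}
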