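#' Principal component analysis of an intensity matrix
#'
#' Column-centered (optionally unit-scaled) singular value decomposition of
#' a samples x metabolites matrix, as used to visualize genotype and diet
#' separation in the brain metabolome.
#'
#' @param x Numeric matrix, samples in rows, metabolites in columns.
#' @param scale Unit-scale the columns before decomposition.
#' @return List with `scores` (samples x PCs), `loadings` (metabolites x
#'   PCs), `explained_variance` (per-PC variances) and
#'   `explained_fraction`.
#' @export
metabolome_pca <- function(x, scale = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("PCA needs at least 2 samples and 2 metabolites")
  sds <- apply(x, 2, stats::sd)
  if (all(sds == 0)) {
    warning("constant matrix: all components have zero variance")
    k <- min(nrow(x) - 1L, ncol(x))
    return(list(scores = matrix(0, nrow(x), k),
                loadings = matrix(0, ncol(x), k),
                explained_variance = rep(0, k),
                explained_fraction = rep(NaN, k)))
  }
  if (scale && any(sds == 0))
    stop("cannot unit-scale zero-variance metabolites")
  fit <- stats::prcomp(x, center = TRUE, scale. = scale)
  ev <- fit$sdev^2
  list(scores = fit$x, loadings = fit$rotation,
       explained_variance = ev, explained_fraction = ev / sum(ev))
}

#' Benjamini-Hochberg adjusted q values
#'
#' Step-up false-discovery-rate adjustment of a p-value vector; a thin,
#' validating interface over [stats::p.adjust()].
#'
#' @param pvals Numeric vector of p values in \[0, 1\].
#' @return Adjusted q values, a monotone transform of the p-value ranks.
#' @examples
#' bh_qvalues(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_qvalues <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0) || any(pvals > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

.two_group_t <- function(a, b, welch = FALSE) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # degenerate: no within-group variance; equal means are uninformative
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(list(t = 0, p = 1))
    return(list(t = Inf * sign(mean(a) - mean(b)), p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Univariate differential screen (genotype contrast)
#'
#' Per metabolite: a two-sample Student's t test of mutant versus wild type
#' on log-transformed intensities (the noise model is log-normal), the log2
#' ratio of raw group means, and Benjamini-Hochberg q values across all
#' tested metabolites. A metabolite passes when q < `q_thresh` and
#' |log2FC| > `fc_thresh`.
#'
#' @param x Samples x metabolites intensity matrix (rownames = sample ids).
#' @param genotype Factor/character per sample, `"wt"` or `"gt"`.
#' @param q_thresh,fc_thresh Screen thresholds (defaults 0.01 and 0.5).
#' @param log_transform Run the t test on log2 intensities (default TRUE).
#' @param welch Use Welch's unequal-variance t test instead of Student's.
#' @return Data frame with `metabolite`, `log2fc` (gt over wt), `t`, `p`,
#'   `q`, `passes`.
#' @export
univariate_screen <- function(x, genotype, q_thresh = 0.01, fc_thresh = 0.5,
                              log_transform = TRUE, welch = FALSE) {
  x <- as.matrix(x)
  genotype <- as.character(genotype)
  if (length(genotype) != nrow(x))
    stop("genotype must have one entry per sample (row)")
  if (!all(genotype %in% c("wt", "gt")))
    stop("genotype labels must be 'wt' or 'gt'")
  if (sum(genotype == "wt") < 2L || sum(genotype == "gt") < 2L)
    stop("each compared group needs >= 2 samples")
  gt <- x[genotype == "gt", , drop = FALSE]
  wt <- x[genotype == "wt", , drop = FALSE]
  tx_gt <- if (log_transform) log2(gt) else gt
  tx_wt <- if (log_transform) log2(wt) else wt
  res <- lapply(seq_len(ncol(x)), function(j) {
    ht <- .two_group_t(tx_gt[, j], tx_wt[, j], welch = welch)
    data.frame(metabolite = colnames(x)[j],
               log2fc = log2(mean(gt[, j]) / mean(wt[, j])),
               t = ht$t, p = ht$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_qvalues(out$p)
  out$passes <- out$q < q_thresh & abs(out$log2fc) > fc_thresh
  out
}

#' Per-diet screens and their union
#'
#' Runs [univariate_screen()] separately within each diet and reports the
#' union of passing metabolites ("significant in at least one of the two
#' dietary regimes").
#'
#' @param x Samples x metabolites intensity matrix.
#' @param design Data frame with per-sample `genotype` and `diet` columns.
#' @param ... Passed to [univariate_screen()].
#' @return List with one screen table per diet plus `union_hits` (character
#'   vector of metabolite ids) and `union_count`.
#' @export
screen_by_diet <- function(x, design, ...) {
  stopifnot(nrow(design) == nrow(x),
            all(c("genotype", "diet") %in% names(design)))
  diets <- unique(as.character(design$diet))
  screens <- lapply(diets, function(d) {
    sel <- design$diet == d
    univariate_screen(x[sel, , drop = FALSE], design$genotype[sel], ...)
  })
  names(screens) <- diets
  hits <- sort(unique(unlist(lapply(screens,
                                    function(s) s$metabolite[s$passes]))))
  c(screens, list(union_hits = hits, union_count = length(hits)))
}

#' Fold-change table against a reference group
#'
#' Per metabolite, the ratio of each group's mean intensity to the reference
#' group's mean (e.g. steady-state abundance of mutant relative to wild
#' type).
#'
#' @param x Samples x metabolites intensity matrix.
#' @param group Per-sample group labels.
#' @param reference Reference group label (default `"wt"`).
#' @return Data frame with `metabolite`, `group`, `ratio`,
#'   `reference_zero` flag (ratio undefined when the reference mean is 0).
#' @export
fold_change_table <- function(x, group, reference = "wt") {
  x <- as.matrix(x)
  group <- as.character(group)
  if (!reference %in% group) stop("reference group is empty")
  ref_mean <- colMeans(x[group == reference, , drop = FALSE])
  others <- setdiff(unique(group), reference)
  if (length(others) == 0L)
    return(data.frame(metabolite = character(), group = character(),
                      ratio = numeric(), reference_zero = logical()))
  out <- do.call(rbind, lapply(others, function(g) {
    gm <- colMeans(x[group == g, , drop = FALSE])
    data.frame(metabolite = colnames(x), group = g,
               ratio = ifelse(ref_mean == 0, NA_real_, gm / ref_mean),
               reference_zero = ref_mean == 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Phosphocreatine / creatine ratio
#'
#' Per-sample PCr/Cr, a proxy of cellular energy charge, with group means
#' when a grouping is supplied.
#'
#' @param x Samples x metabolites intensity matrix containing both
#'   metabolite columns.
#' @param group Optional per-sample group labels.
#' @param pcr,cr Column names of phosphocreatine and creatine.
#' @return List with `per_sample` (data frame `sample`, `ratio`, `flagged`)
#'   and, if grouped, `group_means`.
#' @export
pcr_cr_ratio <- function(x, group = NULL, pcr = "phosphocreatine",
                         cr = "creatine") {
  x <- as.matrix(x)
  if (!all(c(pcr, cr) %in% colnames(x)))
    stop("matrix must contain both phosphocreatine and creatine columns")
  flagged <- x[, cr] == 0
  ratio <- ifelse(flagged, NA_real_, x[, pcr] / x[, cr])
  per_sample <- data.frame(
    sample = if (is.null(rownames(x))) seq_len(nrow(x)) else rownames(x),
    ratio = ratio, flagged = flagged, stringsAsFactors = FALSE)
  out <- list(per_sample = per_sample)
  if (!is.null(group)) {
    out$group_means <- tapply(ratio, as.character(group), mean,
                              na.rm = TRUE)
  }
  out
}

#' Relative expression by the 2^-ddCq method
#'
#' Computes per-sample delta-Cq = Cq_target - Cq_reference (here, 28S rRNA),
#' calibrates against the mean delta-Cq of the wild-type group, and returns
#' 2^-ddCq.
#'
#' @param cq_target Per-sample Cq of the target transcript.
#' @param cq_reference Per-sample Cq of the reference gene (must be finite).
#' @param group Per-sample group labels.
#' @param calibrator_group Group whose mean delta-Cq defines expression 1
#'   (default `"wt"`).
#' @return Data frame with `group`, `dcq`, `relative_expression`.
#' @examples
#' qpcr_relative_expression(c(20, 20, 24.32), c(12, 12, 12),
#'                          c("wt", "wt", "gt"))
#' @export
qpcr_relative_expression <- function(cq_target, cq_reference, group,
                                     calibrator_group = "wt") {
  if (anyNA(cq_target) || anyNA(cq_reference) ||
      any(!is.finite(cq_target)) || any(!is.finite(cq_reference)))
    stop("Cq values must be finite; reject samples missing the reference")
  group <- as.character(group)
  if (!calibrator_group %in% group) stop("calibrator group is empty")
  dcq <- cq_target - cq_reference
  ddcq <- dcq - mean(dcq[group == calibrator_group])
  data.frame(group = group, dcq = dcq,
             relative_expression = 2^(-ddcq), stringsAsFactors = FALSE)
}
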