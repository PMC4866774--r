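test_that("PCA decomposes and reconstructs the centered matrix", {
  set.seed(5)
  x <- matrix(rlnorm(8 * 20, log(1e5), 0.5), 8, 20,
              dimnames = list(paste0("s", 1:8), paste0("m", 1:20)))
  fit <- metabolome_pca(x)
  centered <- scale(x, center = TRUE, scale = FALSE)
  expect_lt(max(abs(fit$scores %*% t(fit$loadings) - centered)), 1e-9)
  expect_equal(sum(fit$explained_variance), sum(apply(x, 2, var)))
  # two perfectly correlated metabolites: PC1 carries all variance
  y <- cbind(a = 1:6, b = 2 * (1:6) + 3)
  expect_equal(metabolome_pca(y)$explained_fraction[1], 1)
  # duplicated identical samples: zero variance, with a warning
  z <- matrix(5, 4, 3)
  expect_warning(res <- metabolome_pca(z), "constant")
  expect_true(all(res$scores == 0))
  # metabolite reordering leaves scores unchanged up to sign
  perm <- sample(ncol(x))
  fit2 <- metabolome_pca(x[, perm])
  for (k in 1:3)
    expect_equal(abs(fit2$scores[, k]), abs(fit$scores[, k]),
                 tolerance = 1e-8)
})

test_that("BH q values match the step-up arithmetic", {
  expect_equal(bh_qvalues(0.03), 0.03)
  # frozen by hand: m*p/rank with cumulative minima from the largest rank
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  # step-up: q_i = min_{j >= i} (m * p_j / j)
  manual <- c(0.010, 0.040, 0.084, 0.084, 0.084, 0.100, 0.105714285714286,
              0.216, 0.216, 0.216)
  expect_equal(bh_qvalues(p), manual, tolerance = 1e-12)
  # monotone in p rank
  set.seed(9)
  pr <- runif(50)
  expect_true(all(diff(bh_qvalues(sort(pr))) >= 0))
  expect_error(bh_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the univariate screen matches hand t-test arithmetic", {
  x <- cbind(met = c(10, 11, 9, 20, 22, 18))
  genotype <- c("wt", "wt", "wt", "gt", "gt", "gt")
  res <- univariate_screen(x, genotype, log_transform = FALSE)
  # pooled-variance Student t on the raw arrays, frozen from the textbook
  # formula: t = 10 / sqrt(2.5 * 2/3), df = 4
  expect_equal(res$t, 7.7459666924, tolerance = 1e-9)
  expect_equal(res$p, 0.001496481056, tolerance = 1e-9)
  expect_equal(res$log2fc, 1)
  # identical groups: nothing passes
  same <- matrix(rep(c(5, 6, 7, 5, 6, 7), 3), 6, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  expect_false(any(univariate_screen(same, genotype)$passes))
  # degenerate zero-variance metabolite with equal means: p = 1
  flat <- cbind(flat = rep(2, 6))
  expect_equal(univariate_screen(flat, genotype)$p, 1)
})

test_that("relaxing screen thresholds never shrinks the passing set", {
  gen <- gen_intensity_matrix("paper_brain_normal", seed = 4)
  strict <- univariate_screen(gen$intensities, gen$design$genotype,
                              q_thresh = 0.01, fc_thresh = 0.5)
  loose_q <- univariate_screen(gen$intensities, gen$design$genotype,
                               q_thresh = 0.05, fc_thresh = 0.5)
  loose_fc <- univariate_screen(gen$intensities, gen$design$genotype,
                                q_thresh = 0.01, fc_thresh = 0.25)
  expect_true(all(strict$metabolite[strict$passes] %in%
                    loose_q$metabolite[loose_q$passes]))
  expect_true(all(strict$metabolite[strict$passes] %in%
                    loose_fc$metabolite[loose_fc$passes]))
})

test_that("the screen recovers programmed hit sets without false positives", {
  # programmed effects >= 2-fold, CV 10%, n = 4/group: exact recovery in
  # at least 95% of seeds
  ok <- vapply(1:20, function(s) {
    gen <- gen_intensity_matrix("paper_brain_normal", seed = s)
    res <- univariate_screen(gen$intensities, gen$design$genotype)
    setequal(res$metabolite[res$passes],
             gen$truth$metabolite[gen$truth$is_hit])
  }, TRUE)
  expect_gte(mean(ok), 0.95)
})

test_that("fold-change tables are ratios of group means", {
  x <- rbind(matrix(c(10, 12, 20, 24), 2, 2), matrix(c(40, 44, 10, 10), 2, 2))
  colnames(x) <- c("a", "b")
  grp <- c("wt", "wt", "gt", "gt")
  fc <- fold_change_table(x, grp)
  expect_equal(fc$ratio, c(42 / 11, 10 / 22))
  # reference against itself: all ratios 1
  self <- fold_change_table(x[1:2, ], c("wt", "wt"), reference = "wt")
  expect_equal(nrow(self), 0L)  # no non-reference group
  fc2 <- fold_change_table(rbind(x[1:2, ], x[1:2, ]),
                           c("wt", "wt", "gt", "gt"))
  expect_equal(fc2$ratio, c(1, 1))
  # zero reference mean is flagged
  x0 <- cbind(z = c(0, 0, 5, 5))
  fc0 <- fold_change_table(x0, grp)
  expect_true(fc0$reference_zero)
  expect_true(is.na(fc0$ratio))
})

test_that("PCr/Cr ratios report per sample and by group", {
  x <- cbind(phosphocreatine = c(10, 20, 5, 5),
             creatine = c(10, 10, 10, 0))
  out <- pcr_cr_ratio(x, group = c("wt", "wt", "gt", "gt"))
  expect_equal(out$per_sample$ratio[1:3], c(1, 2, 0.5))
  expect_true(out$per_sample$flagged[4])
  expect_equal(unname(out$group_means["wt"]), 1.5)
  expect_error(pcr_cr_ratio(x[, 1, drop = FALSE]), "creatine")
})

test_that("2^-ddCq relative expression follows cycle arithmetic", {
  # calibrator samples themselves average to expression 1
  res <- qpcr_relative_expression(c(20, 20, 21), c(12, 12, 12),
                                  c("wt", "wt", "gt"))
  expect_equal(mean(res$relative_expression[res$group == "wt"]), 1)
  # one extra cycle halves expression
  expect_equal(res$relative_expression[3], 0.5)
  # 4.32 extra cycles: about 5% of wild type
  res2 <- qpcr_relative_expression(c(20, 24.32), c(12, 12), c("wt", "gt"))
  expect_equal(res2$relative_expression[2], 0.050067, tolerance = 1e-5)
  expect_error(qpcr_relative_expression(c(20, NA), c(12, 12),
                                        c("wt", "gt")), "finite")
})
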