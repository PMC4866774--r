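test_that("generators are deterministic under a fixed seed", {
  a <- gen_intensity_matrix("paper_brain_normal", seed = 2)
  b <- gen_intensity_matrix("paper_brain_normal", seed = 2)
  expect_identical(a, b)
  expect_false(identical(
    a$intensities,
    gen_intensity_matrix("paper_brain_normal", seed = 3)$intensities))
  c1 <- gen_cq_table(seed = 2)
  c2 <- gen_cq_table(seed = 2)
  expect_identical(c1, c2)
})

test_that("noiseless matrices hit programmed group means exactly", {
  gen <- gen_intensity_matrix("paper_mef_targeted", seed = 1, cv = 0)
  x <- gen$intensities
  g <- gen$design$genotype
  for (m in colnames(x)) {
    fc_prog <- gen$truth$fold_change[gen$truth$metabolite == m &
                                       gen$truth$group == "gt"]
    expect_equal(mean(x[g == "gt", m]) / mean(x[g == "wt", m]), fc_prog,
                 tolerance = 1e-12)
  }
  # within-group values are constant at baseline x fold
  expect_equal(var(x[g == "wt", 1]), 0)
})

test_that("the MEF profile encodes the mutant metabolite pattern", {
  gen <- gen_intensity_matrix("paper_mef_targeted", seed = 1, cv = 0)
  fc <- fold_change_table(gen$intensities, gen$design$genotype)
  gt <- fc[fc$group == "gt", ]
  expect_equal(gt$ratio[gt$metabolite == "aspartate"], 4)
  expect_lt(gt$ratio[gt$metabolite == "citrate"], 0.1)
  expect_gt(gt$ratio[gt$metabolite == "lactate"], 2)
  # rescue restores levels close to wild type
  rescue <- fc[fc$group == "rescue", ]
  expect_true(all(rescue$ratio > 0.8 & rescue$ratio < 1.25))
})

test_that("isotopologue tables round-trip through the correction", {
  sc <- flux_scenario(f_mpc = 0, f_gln = 0.85, f_reductive = 0.45,
                      dilution = 0.25)
  tr <- tracer_spec("glucose", "U")
  # no contamination, no noise: table equals the simulator output
  clean <- gen_isotopologue_data(sc, tr, p_nat = 0, noise_cv = 0, seed = 1)
  expect_equal(clean$data$value, clean$truth$truth, tolerance = 1e-12)
  # natural contamination then correction recovers the simulator MIDs
  dirty <- gen_isotopologue_data(sc, tr, p_nat = 0.0107, noise_cv = 0,
                                 seed = 1)
  for (m in unique(dirty$data$metabolite)) {
    raw <- dirty$data$value[dirty$data$metabolite == m]
    truth <- dirty$truth$truth[dirty$truth$metabolite == m]
    cm <- correction_matrix(length(raw) - 1L)
    expect_lt(max(abs(correct_mid(raw, cm) - truth)), 1e-9)
  }
  # corrected citrate M+2 stays ~0 in the carrier-null scenario
  cit <- dirty$data$value[dirty$data$metabolite == "citrate"]
  cm6 <- correction_matrix(6)
  expect_lt(correct_mid(cit, cm6)[3], 1e-9)
})

test_that("FIA peak generation controls noise and decoys by construction", {
  lib <- read_compound_library()
  # zero error, no decoys: every peak annotated, no extras
  fia0 <- gen_fia_peaklist(lib, mass_error_sd = 0, n_decoys = 0, seed = 5)
  cands <- enumerate_ions(lib, adducts = "deprotonated", max_isotope = 0)
  ann0 <- annotate_peaks(fia0$peaks, cands)
  expect_equal(nrow(fia0$peaks), nrow(cands))
  # every emitted peak is annotated and no foreign m/z appears (compounds
  # with identical masses legitimately share peak positions)
  expect_setequal(unique(ann0$mz), unique(fia0$peaks$mz))
  # decoys are placed >= 0.005 Da away and never annotate at 0.001
  fia_d <- gen_fia_peaklist(lib, mass_error_sd = 0, n_decoys = 50, seed = 5)
  decoy_mz <- fia_d$truth$mz[fia_d$truth$decoy]
  ann_d <- annotate_peaks(fia_d$peaks, cands)
  expect_false(any(decoy_mz %in% ann_d$mz))
  # 0.0002 Da jitter keeps >= 99% of true peaks within the 0.001 window
  fia_j <- gen_fia_peaklist(lib, mass_error_sd = 2e-4, n_decoys = 0,
                            seed = 5)
  ann_j <- annotate_peaks(fia_j$peaks, cands)
  expect_gte(length(unique(ann_j$mz)) / nrow(fia_j$peaks), 0.99)
})

test_that("Cq tables encode the programmed expression levels", {
  gen <- gen_cq_table(seed = 1, cq_sd = 0)
  cq <- gen$cq
  ref <- cq[cq$gene == "rRNA_28S", ]
  for (tg in c("MPC1", "MPC2")) {
    tgt <- cq[cq$gene == tg, ]
    rel <- qpcr_relative_expression(tgt$cq, ref$cq, tgt$genotype)
    means <- tapply(rel$relative_expression, rel$group, mean)
    prog <- gen$truth[gen$truth$gene == tg, ]
    expect_equal(as.numeric(means[prog$genotype]), prog$relative_expression,
                 tolerance = 1e-10)
  }
  # noiseless calibrator group sits exactly at 1; MPC1 null offset is
  # -log2(0.05) = 4.32 cycles
  mpc1 <- cq[cq$gene == "MPC1", ]
  dcq <- mpc1$cq - ref$cq
  expect_equal(mean(dcq[mpc1$genotype == "gt"]) -
                 mean(dcq[mpc1$genotype == "wt"]),
               -log2(0.05), tolerance = 1e-10)
})

test_that("OCR scenarios encode the carrier-dependent fCCP response", {
  wt <- gen_ocr_trace("wt", noise_sd = 0, seed = 1)
  mut <- gen_ocr_trace("mutant", noise_sd = 0, seed = 1)
  mut_mp <- gen_ocr_trace("mutant", methyl_pyruvate = TRUE, noise_sd = 0,
                          seed = 1)
  truth <- attr(wt, "truth")
  expect_equal(fccp_driven_ocr(wt), truth[["fccp"]] - truth[["antimycin_a"]])
  expect_lt(fccp_driven_ocr(mut), fccp_driven_ocr(wt))
  expect_gt(fccp_driven_ocr(mut_mp), 0.9 * fccp_driven_ocr(wt))
})
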