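.default_thresholds <- list(q_thresh = 0.01, fc_thresh = 0.5,
                            tol = 0.001, p_nat = 0.0107)

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.check_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config) || is.null(config$study))
    stop("config must be a list (or YAML file) with a 'study' field")
  known <- c("tracer", "mef_targeted", "brain", "ocr", "qpcr")
  if (!config$study %in% known)
    stop(sprintf("unknown study '%s'; expected one of: %s", config$study,
                 paste(known, collapse = ", ")))
  config$seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  for (th in names(.default_thresholds)) {
    if (is.null(config[[th]])) config[[th]] <- .default_thresholds[[th]]
    if (!is.numeric(config[[th]]) || config[[th]] <= 0)
      stop(sprintf("threshold '%s' must be positive", th))
  }
  config
}

#' Run one study end to end
#'
#' Generates the study's synthetic inputs from the packaged profiles, runs
#' the corresponding analysis stages, writes the result tables as TSV under
#' `out_dir`, and returns a summary list of the headline quantities. Output
#' is deterministic under a fixed seed (byte-identical tables).
#'
#' Studies:
#' * `tracer` — simulated steady-state MIDs for wild-type and MPC1-null
#'   scenarios under the three tracers, plus a measured-and-corrected
#'   isotopologue round trip.
#' * `mef_targeted` — targeted MEF intensity matrix and fold changes versus
#'   wild type.
#' * `brain` — FIA peak-list annotation against the packaged library, PCA,
#'   per-diet univariate screens with FDR and their union, PCr/Cr ratios.
#' * `ocr` — synthetic traces and fCCP-driven OCR per scenario.
#' * `qpcr` — synthetic Cq table and 2^-ddCq relative expression.
#'
#' @param config List (or path to a YAML file) with fields `study` (one of
#'   the above), `seed`, optional `out_dir`, and optional thresholds
#'   `q_thresh` (default 0.01), `fc_thresh` (0.5), `tol` (0.001 Da),
#'   `p_nat` (0.0107).
#' @return Summary list (invisibly includes the paths written).
#' @export
run_study <- function(config) {
  config <- .check_config(config)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(x, file) {
    if (!is.null(out_dir)) .write_tsv(x, file.path(out_dir, file))
  }
  seed <- config$seed
  profiles <- load_profiles()
  summary <- list(study = config$study, seed = seed,
                  thresholds = config[names(.default_thresholds)])

  if (config$study == "tracer") {
    tracers <- list(u_glucose = tracer_spec("glucose", "U"),
                    u_glutamine = tracer_spec("glutamine", "U"),
                    c1_glutamine = tracer_spec("glutamine", 1))
    mid_rows <- list()
    for (sc_name in c("wt", "mpc1_gt")) {
      sc <- do.call(flux_scenario,
                    c(profiles$flux_scenarios[[sc_name]],
                      list(name = sc_name)))
      for (tr_name in names(tracers)) {
        mids <- simulate_steady_state(build_network(sc), tracers[[tr_name]])
        df <- as.data.frame(mids)
        df <- df[df$metabolite %in% c("citrate", "succinate", "malate",
                                      "aspartate"), ]
        df$scenario <- sc_name
        df$tracer <- tr_name
        mid_rows[[paste(sc_name, tr_name)]] <- df
        key <- function(m, i) df$fraction[df$metabolite == m &
                                          df$isotopologue == i]
        summary$mids[[sc_name]][[tr_name]] <- switch(
          tr_name,
          u_glucose = c(citrate_m2 = key("citrate", 2),
                        succinate_m2 = key("succinate", 2),
                        malate_m2 = key("malate", 2),
                        aspartate_m2 = key("aspartate", 2)),
          u_glutamine = c(succinate_m2 = key("succinate", 2),
                          succinate_m3 = key("succinate", 3),
                          malate_m2 = key("malate", 2),
                          malate_m3 = key("malate", 3)),
          c1_glutamine = c(aspartate_m1 = key("aspartate", 1),
                           malate_m1 = key("malate", 1),
                           succinate_m1 = key("succinate", 1)))
      }
    }
    tab <- do.call(rbind, mid_rows)
    rownames(tab) <- NULL
    emit(tab, "tracer_mids.tsv")
    # round trip through measurement emulation and correction
    sc <- do.call(flux_scenario, c(profiles$flux_scenarios$mpc1_gt,
                                   list(name = "mpc1_gt")))
    iso <- gen_isotopologue_data(sc, tracers$u_glutamine,
                                 p_nat = config$p_nat, seed = seed)
    emit(iso$data, "tracer_isotopologues_raw.tsv")
  }

  if (config$study == "mef_targeted") {
    gen <- gen_intensity_matrix("paper_mef_targeted", seed = seed)
    fc <- fold_change_table(gen$intensities, gen$design$genotype,
                            reference = "wt")
    emit(data.frame(sample_id = gen$design$sample_id,
                    genotype = gen$design$genotype, gen$intensities),
         "mef_intensities.tsv")
    emit(fc, "mef_fold_changes.tsv")
    summary$fold_changes <-
      stats::setNames(fc$ratio[fc$group == "gt"],
                      fc$metabolite[fc$group == "gt"])
  }

  if (config$study == "brain") {
    lib <- read_compound_library()
    fia <- gen_fia_peaklist(lib, mass_error_sd = 0, n_decoys = 0,
                            seed = seed)
    ann <- annotate_peaks(fia$peaks,
                          enumerate_ions(lib, adducts = "deprotonated",
                                         max_isotope = 0L),
                          tolerance = config$tol)
    ions <- collapse_to_ion_table(ann)
    emit(ions, "brain_ion_table.tsv")
    summary$n_ions <- nrow(ions)

    normal <- gen_intensity_matrix("paper_brain_normal", seed = seed)
    keto <- gen_intensity_matrix("paper_brain_keto", seed = seed + 1L)
    x <- rbind(normal$intensities, keto$intensities)
    design <- rbind(normal$design, keto$design)
    emit(data.frame(design, x), "brain_intensities.tsv")

    pca <- metabolome_pca(log2(x))
    emit(data.frame(sample_id = design$sample_id,
                    design[c("genotype", "diet")],
                    pca$scores[, 1:2, drop = FALSE]), "brain_pca_scores.tsv")
    summary$pc1_fraction <- pca$explained_fraction[1L]

    screens <- screen_by_diet(x, design, q_thresh = config$q_thresh,
                              fc_thresh = config$fc_thresh)
    for (d in c("normal", "keto"))
      emit(screens[[d]], sprintf("brain_screen_%s.tsv", d))
    summary$hits <- list(
      normal = sum(screens$normal$passes),
      keto = sum(screens$keto$passes),
      union = screens$union_count)

    keto_fc <- fold_change_table(keto$intensities, keto$design$genotype)
    summary$keto_lactate_increase_pct <-
      100 * (keto_fc$ratio[keto_fc$metabolite == "lactate"] - 1)

    for (d in list(normal, keto)) {
      pcr <- pcr_cr_ratio(d$intensities, group = d$design$genotype)
      summary$pcr_cr[[d$design$diet[1L]]] <- pcr$group_means
    }
  }

  if (config$study == "ocr") {
    runs <- list(wt = c("wt", FALSE), mutant = c("mutant", FALSE),
                 mutant_methyl_pyr = c("mutant", TRUE))
    rows <- list()
    for (nm in names(runs)) {
      tr <- gen_ocr_trace(runs[[nm]][1L],
                          methyl_pyruvate = as.logical(runs[[nm]][2L]),
                          seed = seed)
      val <- fccp_driven_ocr(tr)
      per_cell <- cell_normalize(val, tr$cell_count)
      rows[[nm]] <- data.frame(scenario = nm, fccp_driven_ocr = val,
                               per_1e4_cells = per_cell)
      summary$fccp_driven_ocr[[nm]] <- val
    }
    emit(do.call(rbind, rows), "ocr_summary.tsv")
  }

  if (config$study == "qpcr") {
    gen <- gen_cq_table("paper_qpcr", seed = seed)
    cq <- gen$cq
    ref_gene <- default_profile("paper_qpcr")$reference_gene
    ref <- cq[cq$gene == ref_gene, ]
    rows <- list()
    for (tg in setdiff(unique(cq$gene), ref_gene)) {
      tgt <- cq[cq$gene == tg, ]
      stopifnot(identical(tgt$sample_id, ref$sample_id))
      rel <- qpcr_relative_expression(tgt$cq, ref$cq, tgt$genotype)
      rel$sample_id <- tgt$sample_id
      rel$gene <- tg
      rows[[tg]] <- rel
      summary$relative_expression[[tg]] <-
        tapply(rel$relative_expression, rel$group, mean)
    }
    emit(cq, "qpcr_cq.tsv")
    emit(do.call(rbind, rows), "qpcr_relative_expression.tsv")
  }

  summary
}

#' Run all five studies with the packaged profiles
#'
#' One-command reproduction entry point: runs the tracer, targeted MEF,
#' brain, OCR and qPCR studies in sequence with a shared seed, writes their
#' tables under `out_dir`, and emits a combined text report.
#'
#' @param seed Integer seed shared by all generators.
#' @param out_dir Output directory (created if needed); `NULL` for no file
#'   output.
#' @return Named list of per-study summaries (invisibly).
#' @export
reproduce_desk <- function(seed = 1L, out_dir = NULL) {
  studies <- c("tracer", "mef_targeted", "brain", "ocr", "qpcr")
  summaries <- lapply(studies, function(s) {
    run_study(list(study = s, seed = seed, out_dir = out_dir))
  })
  names(summaries) <- studies
  if (!is.null(out_dir))
    write_report(summaries, file.path(out_dir, "report.txt"))
  invisible(summaries)
}

#' Write a human-readable study report
#'
#' Lists the headline quantities of each completed study: annotated ion and
#' screen hit counts, key fold changes, PCr/Cr group means, fCCP-driven OCR
#' per scenario, relative expression, and the key MID fractions for the
#' three tracers; echoes the thresholds used.
#'
#' @param summaries A per-study summary list (from [reproduce_desk()] or a
#'   single [run_study()] result wrapped in a list).
#' @param path Output file; `""` prints to stdout.
#' @return `path`, invisibly.
#' @export
write_report <- function(summaries, path = "") {
  fmt <- function(x, d = 3) format(round(unlist(x), d), trim = TRUE)
  lines <- c("MPC metabolic study report",
             "==========================")
  for (nm in names(summaries)) {
    s <- summaries[[nm]]
    lines <- c(lines, "", sprintf("[%s] seed=%d", nm, s$seed),
               sprintf("  thresholds: q<%g |log2FC|>%g tol=%g Da p_nat=%g",
                       s$thresholds$q_thresh, s$thresholds$fc_thresh,
                       s$thresholds$tol, s$thresholds$p_nat))
    if (!is.null(s$mids)) {
      for (sc in names(s$mids)) for (tr in names(s$mids[[sc]])) {
        v <- s$mids[[sc]][[tr]]
        lines <- c(lines, sprintf("  %s / %s: %s", sc, tr,
                                  paste(names(v), fmt(v), sep = "=",
                                        collapse = " ")))
      }
    }
    if (!is.null(s$fold_changes))
      lines <- c(lines, sprintf("  gt/wt fold changes: %s",
                                paste(names(s$fold_changes),
                                      fmt(s$fold_changes, 2),
                                      sep = "=", collapse = " ")))
    if (!is.null(s$n_ions))
      lines <- c(lines, sprintf("  annotated metabolite ions: %d", s$n_ions))
    if (!is.null(s$hits))
      lines <- c(lines, sprintf(
        "  screen hits: normal=%d keto=%d union=%d",
        s$hits$normal, s$hits$keto, s$hits$union))
    if (!is.null(s$keto_lactate_increase_pct))
      lines <- c(lines, sprintf("  keto-diet lactate increase: %.1f%%",
                                s$keto_lactate_increase_pct))
    if (!is.null(s$pcr_cr)) {
      for (d in names(s$pcr_cr))
        lines <- c(lines, sprintf("  PCr/Cr (%s diet): %s", d,
                                  paste(names(s$pcr_cr[[d]]),
                                        fmt(s$pcr_cr[[d]], 2),
                                        sep = "=", collapse = " ")))
    }
    if (!is.null(s$fccp_driven_ocr))
      lines <- c(lines, sprintf("  fCCP-driven OCR: %s",
                                paste(names(s$fccp_driven_ocr),
                                      fmt(s$fccp_driven_ocr, 1),
                                      sep = "=", collapse = " ")))
    if (!is.null(s$relative_expression)) {
      for (tg in names(s$relative_expression))
        lines <- c(lines, sprintf("  %s relative expression: %s", tg,
                                  paste(names(s$relative_expression[[tg]]),
                                        fmt(s$relative_expression[[tg]]),
                                        sep = "=", collapse = " ")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
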