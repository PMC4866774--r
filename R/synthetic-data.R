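#' Packaged effect profiles and scenarios
#'
#' Loads the packaged YAML describing the synthetic-data generators'
#' conditions: the targeted MEF profile (aspartate x4, citrate depletion,
#' glycolytic intermediates elevated; n = 3/group), the brain profiles
#' (46 programmed hit ions among the 222 library compounds under normal
#' diet; only lactate and aspartate at x1.3 under ketogenic diet;
#' n = 4/group, CV 10%), the qPCR profile (MPC1 at 5%/50% of wild type in
#' gt/gt and gt/+, MPC2 unchanged), the wild-type and MPC1-null flux
#' scenarios, and the OCR phase plateaus.
#'
#' @param path YAML path; defaults to the packaged file.
#' @return Named list of profiles.
#' @export
load_profiles <- function(path = system.file("extdata", "profiles.yaml",
                                             package = "mpctrace")) {
  yaml::read_yaml(path)
}

#' @rdname load_profiles
#' @param name Profile name, e.g. `"paper_brain_normal"`.
#' @export
default_profile <- function(name) {
  profiles <- load_profiles()
  if (!name %in% names(profiles))
    stop(sprintf("unknown profile '%s'; available: %s", name,
                 paste(names(profiles), collapse = ", ")))
  profiles[[name]]
}

# CV of a log-normal -> sdlog
.cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

.profile_metabolites <- function(profile) {
  if (identical(profile$metabolites, "library"))
    read_compound_library()$compound_id
  else unlist(profile$metabolites)
}

.profile_folds <- function(profile, group, metabolites) {
  fc <- rep(1, length(metabolites))
  names(fc) <- metabolites
  prog <- profile$fold_changes[[group]]
  if (!is.null(prog)) {
    unknown <- setdiff(names(prog), metabolites)
    if (length(unknown))
      stop("profile programs unknown metabolites: ",
           paste(unknown, collapse = ", "))
    fc[names(prog)] <- unlist(prog)
  }
  if (any(fc <= 0)) stop("fold changes must be > 0")
  fc
}

#' Generate a synthetic intensity matrix with known ground truth
#'
#' Per sample and metabolite, intensity = baseline x group fold change x
#' log-normal noise at the profile's coefficient of variation. Baselines
#' are drawn once per metabolite (log-normal around 1e5). Deterministic
#' under a fixed seed; the programmed truth is returned alongside the data
#' so every downstream stage has a recovery oracle.
#'
#' @param profile A profile list (see [load_profiles()]) or its name.
#' @param seed Integer seed.
#' @param n_per_group,cv Optional overrides of the profile's replicate
#'   count and coefficient of variation.
#' @return List with `intensities` (samples x metabolites matrix),
#'   `design` (data frame `sample_id`, `genotype`, `diet`) and `truth`
#'   (per metabolite and non-reference group: programmed fold change and
#'   hit flag at |log2FC| > 0.5).
#' @export
gen_intensity_matrix <- function(profile, seed, n_per_group = NULL,
                                 cv = NULL) {
  if (is.character(profile)) profile <- default_profile(profile)
  n <- if (is.null(n_per_group)) profile$n_per_group else n_per_group
  cv <- if (is.null(cv)) profile$cv else cv
  groups <- if (is.null(profile$groups)) c("wt", "gt")
            else unlist(profile$groups)
  diet <- if (is.null(profile$diet)) "normal" else profile$diet
  metabolites <- .profile_metabolites(profile)
  withr::with_seed(seed, {
    baseline <- stats::rlnorm(length(metabolites), log(1e5), 1)
    names(baseline) <- metabolites
    rows <- list()
    design <- list()
    for (g in groups) {
      fc <- .profile_folds(profile, g, metabolites)
      for (r in seq_len(n)) {
        noise <- stats::rlnorm(length(metabolites), 0, .cv_to_sdlog(cv))
        rows[[length(rows) + 1L]] <- baseline * fc * noise
        design[[length(design) + 1L]] <-
          data.frame(sample_id = sprintf("%s_%s_%d", diet, g, r),
                     genotype = g, diet = diet, stringsAsFactors = FALSE)
      }
    }
    x <- do.call(rbind, rows)
    colnames(x) <- metabolites
    design <- do.call(rbind, design)
    rownames(x) <- design$sample_id
    truth <- do.call(rbind, lapply(setdiff(groups, groups[1L]), function(g) {
      fc <- .profile_folds(profile, g, metabolites)
      data.frame(metabolite = metabolites, group = g, fold_change = fc,
                 is_hit = abs(log2(fc)) > 0.5, row.names = NULL,
                 stringsAsFactors = FALSE)
    }))
    list(intensities = x, design = design, truth = truth)
  })
}

#' Generate raw isotopologue measurements from a flux scenario
#'
#' Runs the atom-transition simulator for the scenario and tracer,
#' forward-contaminates the ground-truth MIDs with the natural-abundance
#' matrix at `p_nat`, applies multiplicative log-normal noise and
#' renormalizes — emulating measured isotopologue fraction tables.
#'
#' @param scenario A [flux_scenario()].
#' @param tracer A [tracer_spec()].
#' @param metabolites Measured metabolites (default the four quantified
#'   TCA-cycle readouts).
#' @param p_nat Natural 13C abundance used for contamination.
#' @param noise_cv Multiplicative noise CV (0 = noiseless).
#' @param seed Integer seed.
#' @return List with `data` (data frame `metabolite`, `isotopologue`,
#'   `value`) and `truth` (the simulator MIDs in the same shape).
#' @export
gen_isotopologue_data <- function(scenario, tracer,
                                  metabolites = c("citrate", "succinate",
                                                  "malate", "aspartate"),
                                  p_nat = 0.0107, noise_cv = 0, seed = 1L) {
  net <- build_network(scenario)
  mids <- simulate_steady_state(net, tracer)
  withr::with_seed(seed, {
    rows <- lapply(metabolites, function(m) {
      mid <- mids[[m]]
      cm <- correction_matrix(length(mid) - 1L, p_nat)
      raw <- contaminate_mid(mid, cm)
      if (noise_cv > 0) {
        raw <- raw * stats::rlnorm(length(raw), 0, .cv_to_sdlog(noise_cv))
        raw <- raw / sum(raw)
      }
      data.frame(metabolite = m, isotopologue = seq_along(raw) - 1L,
                 value = raw, truth = mid, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    list(data = tab[c("metabolite", "isotopologue", "value")],
         truth = tab[c("metabolite", "isotopologue", "truth")])
  })
}

#' Generate a flow-injection centroid peak list
#'
#' Emits one peak per in-range ion of the library (deprotonated by default,
#' configurable adducts/isotopes), jitters each m/z with Gaussian error, and
#' appends uniform-random decoy peaks kept at least 0.005 Da away from any
#' candidate so that decoys are never annotatable at the 0.001 Da tolerance.
#'
#' @param library Compound library data frame ([read_compound_library()]).
#' @param mass_error_sd Gaussian m/z jitter SD in Da.
#' @param n_decoys Number of decoy peaks.
#' @param seed Integer seed.
#' @param adducts,max_isotope Passed to [enumerate_ions()].
#' @return List with `peaks` (data frame `mz`, `intensity`) and `truth`
#'   (candidate table with a `decoy` flag).
#' @export
gen_fia_peaklist <- function(library, mass_error_sd = 0, n_decoys = 0,
                             seed = 1L, adducts = "deprotonated",
                             max_isotope = 0L) {
  cands <- enumerate_ions(library, adducts = adducts,
                          max_isotope = max_isotope)
  withr::with_seed(seed, {
    mz <- cands$mz + stats::rnorm(nrow(cands), 0, mass_error_sd)
    intensity <- stats::rlnorm(nrow(cands), log(1e4), 1)
    decoy_mz <- numeric(0)
    while (length(decoy_mz) < n_decoys) {
      prop <- stats::runif(n_decoys - length(decoy_mz), 50, 1000)
      ok <- vapply(prop, function(m) min(abs(m - cands$mz)) >= 0.005, TRUE)
      decoy_mz <- c(decoy_mz, prop[ok])
    }
    peaks <- data.frame(
      mz = c(mz, decoy_mz),
      intensity = c(intensity,
                    stats::rlnorm(length(decoy_mz), log(1e3), 1)))
    truth <- rbind(
      data.frame(cands, decoy = FALSE, stringsAsFactors = FALSE),
      if (n_decoys > 0)
        data.frame(compound_id = NA_character_, adduct = NA_character_,
                   isotope_shift = NA_integer_, mz = decoy_mz, decoy = TRUE,
                   stringsAsFactors = FALSE))
    ord <- order(peaks$mz)
    list(peaks = peaks[ord, , drop = FALSE], truth = truth)
  })
}

#' Generate a synthetic oxygen-consumption trace
#'
#' Piecewise-constant phase plateaus (basal, fCCP, succinate/rotenone,
#' antimycin A) with Gaussian noise, emulating a permeabilized-MEF
#' extracellular-flux run with pyruvate/malate as substrates. The mutant
#' scenario has a blunted fCCP plateau, restored when membrane-permeable
#' methyl pyruvate bypasses the carrier.
#'
#' @param scenario `"wt"` or `"mutant"`.
#' @param methyl_pyruvate Supplement with methyl pyruvate.
#' @param noise_sd Gaussian noise SD on each measurement loop.
#' @param n_loops Measurement loops per phase.
#' @param loop_s Seconds between loops (3.5 min loop: 30 s mixing, 1 min
#'   waiting, 2 min measuring).
#' @param cell_count Cells per well.
#' @param seed Integer seed.
#' @return An [ocr_trace()]; the programmed plateaus are attached as
#'   attribute `truth`.
#' @export
gen_ocr_trace <- function(scenario = c("wt", "mutant"),
                          methyl_pyruvate = FALSE, noise_sd = 2,
                          n_loops = 3L, loop_s = 210, cell_count = 30000,
                          seed = 1L) {
  scenario <- match.arg(scenario)
  key <- paste0(scenario, if (methyl_pyruvate) "_methyl_pyr")
  plateaus <- unlist(load_profiles()$ocr_scenarios[[key]])
  phases <- c("basal", "fccp", "succinate_rotenone", "antimycin_a")
  withr::with_seed(seed, {
    time <- ocr <- numeric(0)
    inj_time <- numeric(0)
    t0 <- 0
    for (ph in phases) {
      if (ph != "basal") inj_time <- c(inj_time, t0)
      tt <- t0 + seq_len(n_loops) * loop_s
      time <- c(time, tt)
      ocr <- c(ocr, plateaus[[ph]] + stats::rnorm(n_loops, 0, noise_sd))
      t0 <- max(tt) + loop_s / 2
    }
    trace <- ocr_trace(time, ocr,
                       injections = data.frame(time = inj_time,
                                               label = phases[-1L],
                                               stringsAsFactors = FALSE),
                       cell_count = cell_count)
    attr(trace, "truth") <- plateaus
    trace
  })
}

#' Generate a synthetic qPCR Cq table
#'
#' Emits Cq values for the target transcripts (MPC1, MPC2) and the 28S rRNA
#' reference per sample, constructed so that the programmed relative
#' expressions (gt/gt MPC1 at 5% of wild type, gt/+ at 50%, MPC2 unchanged)
#' hold exactly under 2^-ddCq before noise: a programmed expression of 0.05
#' corresponds to a delta-delta-Cq offset of -log2(0.05) = 4.32 cycles.
#'
#' @param profile qPCR profile list or name (default `"paper_qpcr"`).
#' @param seed Integer seed.
#' @param cq_sd Optional override of the profile's per-well Cq noise SD.
#' @return List with `cq` (data frame `sample_id`, `genotype`, `gene`,
#'   `cq`) and `truth` (programmed relative expression per target and
#'   genotype).
#' @export
gen_cq_table <- function(profile = "paper_qpcr", seed = 1L, cq_sd = NULL) {
  if (is.character(profile)) profile <- default_profile(profile)
  sd <- if (is.null(cq_sd)) profile$cq_sd else cq_sd
  genotypes <- unlist(profile$genotypes)
  targets <- names(profile$target_dcq_wt)
  n <- profile$n_per_group
  withr::with_seed(seed, {
    rows <- list()
    for (g in genotypes) {
      for (r in seq_len(n)) {
        sid <- sprintf("%s_%d", g, r)
        cq_ref <- profile$reference_cq + stats::rnorm(1, 0, sd)
        rows[[length(rows) + 1L]] <-
          data.frame(sample_id = sid, genotype = g,
                     gene = profile$reference_gene, cq = cq_ref,
                     stringsAsFactors = FALSE)
        for (tg in targets) {
          dcq <- profile$target_dcq_wt[[tg]] -
            log2(profile$relative_expression[[tg]][[g]])
          rows[[length(rows) + 1L]] <-
            data.frame(sample_id = sid, genotype = g, gene = tg,
                       cq = profile$reference_cq + dcq +
                         stats::rnorm(1, 0, sd),
                       stringsAsFactors = FALSE)
        }
      }
    }
    truth <- do.call(rbind, lapply(targets, function(tg) {
      data.frame(gene = tg, genotype = genotypes,
                 relative_expression =
                   unlist(profile$relative_expression[[tg]][genotypes]),
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
    list(cq = do.call(rbind, rows), truth = truth)
  })
}
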