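#' Flux scenario for the TCA-cycle labeling network
#'
#' Branch-fraction parameterization of central-carbon metabolism. Steady-state
#' MIDs depend only on the relative contribution of each producing route to a
#' pool, so the network is parameterized by fractions rather than absolute
#' fluxes:
#'
#' * `f_mpc` — fraction of mitochondrial acetyl-CoA derived from glycolytic
#'   pyruvate via the MPC/PDH route. `f_mpc = 0` encodes the MPC1-null state
#'   in which pyruvate cannot enter mitochondria.
#' * `f_gln` — fraction of alpha-ketoglutarate entering from glutamine
#'   (anaplerosis) rather than from citrate oxidation.
#' * `f_reductive` — fraction of alpha-ketoglutarate consumed by reductive
#'   carboxylation to citrate (the remainder is oxidized); the marker of
#'   reductive glutamine metabolism.
#' * `f_anaplerotic_pc` — fraction of oxaloacetate made by pyruvate
#'   carboxylation.
#' * `dilution` — fraction of each non-source pool exchanged with unlabeled
#'   medium per iteration.
#'
#' @param f_mpc,f_gln,f_reductive,f_anaplerotic_pc,dilution Fractions in
#'   \[0, 1\].
#' @param name Optional scenario label used in error messages and reports.
#' @return An object of class `flux_scenario`.
#' @examples
#' flux_scenario(f_mpc = 0, f_gln = 0.85, f_reductive = 0.45, name = "mpc1_gt")
#' @export
flux_scenario <- function(f_mpc = 1, f_gln = 0, f_reductive = 0,
                          f_anaplerotic_pc = 0, dilution = 0, name = NULL) {
  fr <- c(f_mpc = f_mpc, f_gln = f_gln, f_reductive = f_reductive,
          f_anaplerotic_pc = f_anaplerotic_pc, dilution = dilution)
  if (anyNA(fr) || any(fr < 0) || any(fr > 1))
    stop("all flux-scenario fractions must lie in [0, 1]")
  structure(as.list(fr), name = name, class = "flux_scenario")
}

#' @export
print.flux_scenario <- function(x, ...) {
  nm <- attr(x, "name")
  cat("Flux scenario", if (!is.null(nm)) sprintf("'%s'", nm), "\n")
  for (f in names(x)) cat(sprintf("  %-17s %.3f\n", f, x[[f]]))
  invisible(x)
}

#' Tracer specification
#'
#' Describes the labeled substrate supplied to the cells: which positions of
#' glucose or glutamine carry 13C, and the fraction of tracer molecules that
#' carry the stated pattern (enrichment/purity; the remainder is unlabeled).
#'
#' @param substrate `"glucose"` or `"glutamine"`.
#' @param labeled_positions Integer vector of 1-based carbon positions, or
#'   `"U"` for uniform labeling of all carbons.
#' @param enrichment Fraction of tracer molecules carrying the label pattern.
#' @return An object of class `tracer_spec`.
#' @examples
#' tracer_spec("glutamine", 1)      # [1-13C]glutamine
#' tracer_spec("glucose", "U")      # [U-13C]glucose
#' @export
tracer_spec <- function(substrate = c("glucose", "glutamine"),
                        labeled_positions = "U", enrichment = 1) {
  substrate <- match.arg(substrate)
  n <- if (substrate == "glucose") 6L else 5L
  if (identical(labeled_positions, "U")) labeled_positions <- seq_len(n)
  labeled_positions <- as.integer(labeled_positions)
  if (any(labeled_positions < 1L) || any(labeled_positions > n))
    stop(sprintf("labeled positions must lie within 1..%d for %s", n, substrate))
  if (is.na(enrichment) || enrichment < 0 || enrichment > 1)
    stop("enrichment must lie in [0, 1]")
  structure(list(substrate = substrate,
                 labeled_positions = sort(unique(labeled_positions)),
                 enrichment = enrichment, n_carbons = n),
            class = "tracer_spec")
}

# Pool sizes (carbon counts) of the fixed metabolite set.
.tca_pools <- c(glucose = 6L, glutamine = 5L, glutamate = 5L,
                pyruvate = 3L, lactate = 3L, accoa = 2L, citrate = 6L,
                akg = 5L, succinate = 4L, fumarate = 4L, malate = 4L,
                oaa = 4L, aspartate = 4L)

#' Build the atom-mapped TCA-cycle labeling network
#'
#' Assembles the fixed metabolite set (glucose, pyruvate, acetyl-CoA,
#' citrate/isocitrate, alpha-ketoglutarate, succinate, fumarate, malate,
#' oxaloacetate, aspartate, glutamate, glutamine, lactate) together with the
#' atom-mapped reactions connecting them: glycolysis (glucose to two
#' pyruvates), pyruvate dehydrogenase (C1 lost as CO2), citrate synthase,
#' the oxidative span citrate -> alpha-KG -> succinate (each step releasing
#' one CO2 from an oxaloacetate-derived carboxyl; alpha-KG loses its C1),
#' symmetric scrambling at succinate and fumarate, reductive carboxylation
#' (alpha-KG + CO2 -> citrate) with citrate cleavage to oxaloacetate +
#' acetyl-CoA, glutamine -> glutamate -> alpha-KG (carbons preserved),
#' oxaloacetate <-> aspartate, and pyruvate carboxylation. The free CO2 pool
#' is held at natural (unlabeled) composition.
#'
#' Reactions whose branch fraction is zero in `scenario` are flagged
#' inactive; succinate and fumarate are always flagged symmetric.
#'
#' @param scenario A [flux_scenario()].
#' @return An object of class `tracer_network` with elements `pools`
#'   (named carbon counts), `reactions` (data frame with `id`, `substrates`,
#'   `products`, `released_co2`, `active`), `symmetric_pools`, and the
#'   scenario.
#' @export
build_network <- function(scenario) {
  stopifnot(inherits(scenario, "flux_scenario"))
  rx <- data.frame(
    id = c("glycolysis", "ldh", "pdh", "cs", "idh_kgdh_ox", "kgdh_sdh",
           "fum_hydratase", "mdh", "gls", "gdh", "got", "red_idh",
           "acl", "pc"),
    substrates = c("glucose", "pyruvate", "pyruvate", "oaa+accoa",
                   "citrate", "akg", "succinate", "malate", "glutamine",
                   "glutamate", "oaa", "akg+co2", "citrate", "pyruvate+co2"),
    products = c("2 pyruvate", "lactate", "accoa", "citrate", "akg",
                 "succinate", "fumarate", "oaa", "glutamate", "akg",
                 "aspartate", "citrate", "oaa+accoa", "oaa"),
    released_co2 = c(0L, 0L, 1L, 0L, 1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L,
                     0L, 0L),
    stringsAsFactors = FALSE
  )
  rx$active <- TRUE
  if (scenario$f_mpc == 0) rx$active[rx$id == "pdh"] <- FALSE
  if (scenario$f_gln == 0) rx$active[rx$id %in% c("gls", "gdh")] <- FALSE
  if (scenario$f_reductive == 0)
    rx$active[rx$id %in% c("red_idh", "acl")] <- FALSE
  if (scenario$f_reductive == 1) rx$active[rx$id == "kgdh_sdh"] <- FALSE
  if (scenario$f_anaplerotic_pc == 0) rx$active[rx$id == "pc"] <- FALSE
  structure(list(pools = .tca_pools, reactions = rx,
                 symmetric_pools = c("succinate", "fumarate"),
                 scenario = scenario),
            class = "tracer_network")
}

# One synchronous update of all pools given the current state. Atom maps
# (product carbon <- substrate carbon), with OAA numbered C1 (carboxyl next
# to the keto carbon) .. C4 and acetyl-CoA C1 (carboxyl), C2 (methyl):
#   glycolysis   pyruvate <- glucose (3,2,1) / (4,5,6), halves averaged
#   PDH          acetyl-CoA <- pyruvate (2,3); pyruvate C1 lost as CO2
#   CS           citrate c1..c4 <- OAA, c5..c6 <- acetyl-CoA
#   IDH+KGDH ox  alpha-KG <- citrate (2,3,4,5,6); c1 (OAA-derived) lost
#   KGDH->SDH    succinate <- alpha-KG (2,3,4,5); K1 lost as CO2
#   reductive    citrate c1 <- CO2 (unlabeled), c2..c6 <- alpha-KG 1..5
#   ACL          OAA <- citrate (1,2,3,4); acetyl-CoA <- citrate (5,6)
#   PC           OAA c1..c3 <- pyruvate, c4 <- CO2 (unlabeled)
.tca_update <- function(state, source_pools, sc, maps) {
  d <- sc$dilution
  dilute <- function(v, n) if (d > 0) (1 - d) * v + d * iso_unlabeled(n) else v
  new <- state

  upd <- function(pool, v) {
    if (pool %in% names(source_pools)) source_pools[[pool]]
    else dilute(v, .tca_pools[[pool]])
  }

  new$glucose   <- upd("glucose",   iso_unlabeled(6L))
  new$glutamine <- upd("glutamine", iso_unlabeled(5L))
  new$glutamate <- upd("glutamate", state$glutamine)
  new$pyruvate  <- upd("pyruvate",
                       0.5 * iso_apply_map(state$glucose, maps$glyc1, 3L) +
                       0.5 * iso_apply_map(state$glucose, maps$glyc2, 3L))
  new$lactate   <- upd("lactate", state$pyruvate)

  pdh     <- iso_apply_map(state$pyruvate, maps$pdh, 2L)
  acl_ac  <- iso_apply_map(state$citrate, maps$acl_ac, 2L)
  new$accoa <- upd("accoa",
                   sc$f_mpc * pdh +
                   (1 - sc$f_mpc) * (sc$f_reductive * acl_ac +
                                     (1 - sc$f_reductive) * iso_unlabeled(2L)))

  cs  <- iso_combine(state$oaa, state$accoa)             # bits 1-4 OAA, 5-6 AcCoA
  red <- iso_combine(c(1, 0), state$akg)                 # bit 1 CO2, 2-6 alpha-KG
  new$citrate <- upd("citrate",
                     (1 - sc$f_reductive) * cs + sc$f_reductive * red)

  ox <- iso_apply_map(state$citrate, maps$ox, 5L)
  new$akg <- upd("akg", sc$f_gln * state$glutamate + (1 - sc$f_gln) * ox)

  new$succinate <- upd("succinate",
                       iso_symmetrize(iso_apply_map(state$akg, maps$kgdh, 4L), 4L))
  new$fumarate  <- upd("fumarate", iso_symmetrize(state$succinate, 4L))
  new$malate    <- upd("malate", state$fumarate)

  pc      <- iso_combine(state$pyruvate, c(1, 0))        # bits 1-3 pyruvate, 4 CO2
  acl_oaa <- iso_apply_map(state$citrate, maps$acl_oaa, 4L)
  new$oaa <- upd("oaa",
                 sc$f_anaplerotic_pc * pc +
                 (1 - sc$f_anaplerotic_pc) *
                   (sc$f_reductive * acl_oaa +
                    (1 - sc$f_reductive) * state$malate))
  new$aspartate <- upd("aspartate", state$oaa)
  new
}

.tca_maps <- function() {
  list(glyc1   = iso_select_map(6L, c(3L, 2L, 1L)),
       glyc2   = iso_select_map(6L, c(4L, 5L, 6L)),
       pdh     = iso_select_map(3L, c(2L, 3L)),
       ox      = iso_select_map(6L, 2:6),
       kgdh    = iso_select_map(5L, 2:5),
       acl_ac  = iso_select_map(6L, 5:6),
       acl_oaa = iso_select_map(6L, 1:4))
}

#' Simulate steady-state mass isotopomer distributions
#'
#' Propagates a 13C tracer through the atom-mapped network by synchronous
#' fixed-point iteration over positional isotopomer distributions: at each
#' iteration every pool is recomputed as the branch-fraction-weighted mixture
#' of its producing reactions (condensations as backbone products,
#' decarboxylations as marginalizations, orientation averages at the
#' symmetric pools), then mixed with unlabeled medium according to the
#' scenario's `dilution`. Iteration stops when the largest per-entry change
#' drops below `tol`.
#'
#' With `single_pass = TRUE` a single topologically ordered sweep is
#' performed from a fully unlabeled state, with cycle-feedback inputs held
#' unlabeled — the acyclic "first turn" configuration used for oracle
#' comparisons (e.g. one oxidative pass of \[U-13C\]glutamine gives
#' succinate M+4 = 1).
#'
#' @param network A [build_network()] result.
#' @param tracer A [tracer_spec()].
#' @param tol Convergence threshold on the max per-entry change.
#' @param max_iter Iteration cap; exceeding it is an error naming the
#'   scenario.
#' @param single_pass Run the acyclic single-sweep mode instead of iterating
#'   to steady state.
#' @return A named list of MIDs (class `mid_set`), one per metabolite, each
#'   of length n_carbons + 1, non-negative, summing to 1. The number of
#'   iterations used is attached as attribute `iterations`.
#' @examples
#' net <- build_network(flux_scenario(f_mpc = 1, f_gln = 0.8))
#' mids <- simulate_steady_state(net, tracer_spec("glucose", "U"))
#' mids$citrate
#' @export
simulate_steady_state <- function(network, tracer, tol = 1e-9,
                                  max_iter = 10000L, single_pass = FALSE) {
  stopifnot(inherits(network, "tracer_network"), inherits(tracer, "tracer_spec"))
  sc <- network$scenario
  maps <- .tca_maps()

  src <- iso_source(tracer$n_carbons, tracer$labeled_positions,
                    tracer$enrichment)
  source_pools <- stats::setNames(list(src), tracer$substrate)

  state <- lapply(.tca_pools, iso_unlabeled)
  if (single_pass) {
    # Sequential sweep: each pool sees already-updated upstream pools and
    # unlabeled values for pools not yet reached (feedback edges broken).
    order <- c("glucose", "glutamine", "glutamate", "pyruvate", "lactate",
               "accoa", "akg", "citrate", "succinate", "fumarate", "malate",
               "oaa", "aspartate")
    for (pool in order) {
      state[[pool]] <- .tca_update(state, source_pools, sc, maps)[[pool]]
    }
    iters <- 1L
  } else {
    iters <- 0L
    repeat {
      iters <- iters + 1L
      if (iters > max_iter) {
        nm <- attr(sc, "name")
        stop(sprintf(
          "steady-state iteration did not converge within %d iterations%s",
          max_iter,
          if (is.null(nm)) "" else sprintf(" (scenario '%s')", nm)))
      }
      new <- .tca_update(state, source_pools, sc, maps)
      delta <- max(vapply(names(state),
                          function(p) max(abs(new[[p]] - state[[p]])), 0))
      state <- new
      if (delta < tol) break
    }
  }

  mids <- lapply(names(.tca_pools), function(p) {
    mid <- iso_to_mid(state[[p]], .tca_pools[[p]])
    mid / sum(mid)
  })
  names(mids) <- names(.tca_pools)
  structure(mids, iterations = iters, class = "mid_set")
}

#' @export
print.mid_set <- function(x, digits = 4, ...) {
  cat("Steady-state mass isotopomer distributions",
      sprintf("(%d iterations)\n", attr(x, "iterations")))
  for (m in names(x)) {
    cat(sprintf("  %-10s %s\n", m,
                paste(format(round(x[[m]], digits), nsmall = digits),
                      collapse = " ")))
  }
  invisible(x)
}

#' Convert a simulated MID set to a long data frame
#'
#' @param x A `mid_set` from [simulate_steady_state()].
#' @param ... Unused.
#' @return Data frame with columns `metabolite`, `isotopologue` (0 = M+0)
#'   and `fraction`.
#' @export
as.data.frame.mid_set <- function(x, ...) {
  do.call(rbind, lapply(names(x), function(m) {
    data.frame(metabolite = m,
               isotopologue = seq_along(x[[m]]) - 1L,
               fraction = as.numeric(x[[m]]),
               stringsAsFactors = FALSE)
  }))
}

#' Write simulated MIDs as TSV
#'
#' @param x A `mid_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mids_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
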