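---
title: "Models and methods behind mpctrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mpctrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpctrace)
```

`mpctrace` implements the computational workflow of a study of
mitochondrial pyruvate carrier (MPC) deficiency: when MPC1 is lost,
glycolytic pyruvate can no longer enter mitochondria, the pyruvate
dehydrogenase (PDH) / citrate synthase (CS) route into the TCA cycle is
blocked, and cells compensate through glutamine anaplerosis and reductive
carboxylation of alpha-ketoglutarate. The package covers the five assays
used to establish that picture — 13C tracing, natural-abundance
correction, targeted LC-MS/MS quantification, non-targeted flow-injection
metabolomics with differential statistics, and extracellular-flux
respirometry — plus seeded generators that emulate each assay's design, so
every stage has a recovery oracle.

## The carbon-atom-transition simulator

### Model

Each n-carbon metabolite pool is represented internally by a distribution
over its $2^n$ positional labeling patterns; mass isotopomer
distributions (MIDs, the observable) are obtained by summing patterns with
equal label counts. Reactions are encoded as explicit atom maps, and
three primitives express all of them:

* **selection/marginalization** for cleavages and decarboxylations (e.g.
  PDH releases pyruvate C1 as CO2; the oxidative citrate-to-alpha-KG span
  releases an oxaloacetate-derived carboxyl, and alpha-KG loses its C1 on
  the way to succinate);
* **backbone condensation** (outer product) for CS
  (acetyl-CoA + oxaloacetate), reductive carboxylation (CO2 + alpha-KG)
  and pyruvate carboxylation (pyruvate + CO2);
* **orientation averaging** for succinate and fumarate, whose two
  end-to-end orientations are chemically indistinguishable.

The free CO2 pool is held at natural (unlabeled) composition: the system
is open, and refixation of labeled CO2 is not tracked except through the
explicit carboxylation reactions, which take unlabeled CO2. The
glucose-to-pyruvate atom map is the standard glycolytic one (C1-C2-C3 and
C4-C5-C6 halves mirrored about the triose step); this is immaterial for
uniform tracers but documented for positional ones.

### Branch-fraction parameterization

Steady-state MIDs depend only on the relative contributions of the routes
producing each pool, never on absolute fluxes, so the network is
parameterized by branch fractions (`flux_scenario()`): `f_mpc` (fraction
of acetyl-CoA from pyruvate via MPC/PDH; 0 encodes the MPC1-null state),
`f_gln` (fraction of alpha-KG from glutamine), `f_reductive` (fraction of
alpha-KG consumed reductively; its citrate-lyase products feed the
oxaloacetate and acetyl-CoA pools), `f_anaplerotic_pc` (oxaloacetate from
pyruvate carboxylation), and `dilution` (fraction of each non-source pool
exchanged with unlabeled medium per iteration). Kinetic or ODE modeling
and flux estimation by fitting are deliberately out of scope — the study
interprets MIDs qualitatively (directions and near-zero claims), so the
simulator's job is to reproduce those signatures, not bar heights.

The packaged scenarios place the wild type at
`f_mpc = 0.85, f_gln = 0.70, f_reductive = 0.08, f_anaplerotic_pc = 0.05`
and the mutant at `f_mpc = 0, f_gln = 0.85, f_reductive = 0.45,
f_anaplerotic_pc = 0`, both with `dilution = 0.25`. The study reports
directions only, so these values are a fixed design choice made once:
they reproduce the observed signatures (M+2 collapse under
[U-13C]glucose, the M+2-to-M+3 shift under [U-13C]glutamine, the
appearance of aspartate M+1 under [1-13C]glutamine) with magnitudes
plausible for proliferating fibroblasts.

### Numerics

The steady state is found by synchronous fixed-point iteration from a
fully unlabeled state, with tolerance $10^{-9}$ on the maximum per-entry
change and a cap of 10,000 iterations (an error names the scenario if the
cap is hit). The network is small and the update is a strict contraction
whenever any unlabeled inflow exists, so convergence takes a handful of
iterations in practice. Tracer enrichment is modeled at molecule level —
a fraction `e` of tracer molecules carries the stated pattern, the rest
are unlabeled — which matches how tracer purity enters an experiment.

A `single_pass = TRUE` mode performs one topologically ordered sweep with
cycle-feedback inputs held unlabeled. This is the acyclic "first turn"
configuration: one oxidative pass of [U-13C]glutamine yields pure
succinate M+4 (alpha-KG M+5 minus one labeled CO2). The literal reading
of `dilution` (per-iteration exchange) cannot express this configuration
— full exchange per iteration simply unlabels everything — so the single
pass is exposed as an explicit mode rather than a dilution setting, and
it is the configuration the test suite compares against an exhaustive
atom-placement enumeration oracle.

### Known limitations

Malate is produced only via fumarate in this network (there is no reverse
malate-dehydrogenase exchange with oxaloacetate), so label arriving
through the reductive route reaches aspartate — via the citrate-lyase
oxaloacetate moiety — but not malate. Real cells exchange
malate/oxaloacetate rapidly; interpreting simulated malate M+1 under
[1-13C]glutamine should keep that in mind. Succinate is likewise produced
only oxidatively, so a scenario with `f_reductive = 1` leaves succinate
fed by a formally zero flux; its MID is then the mixture limit of the
producing route, which is the intended reading of a branch-fraction
model.

## Natural-abundance correction

Measured isotopologue intensities are corrected for naturally occurring
13C by inverting the binomial contamination model: with j tracer-derived
labels on an n-carbon fragment, the probability of observing i total
labels is $\binom{n-j}{i-j} p^{i-j} (1-p)^{n-i}$ with $p = 0.0107$ by
default. The matrix is lower-triangular with unit column sums; for the
fragment sizes used here ($n \le 6$) its condition number is tiny, so
exact triangular solving is used rather than constrained least squares,
with small negative solution entries (noise) clamped to zero and the
result renormalized. Only carbon is corrected, matching the acquisition
convention; hydrogen/nitrogen/oxygen isotopes are not modeled. Fragment
specific correction is supported by letting `n_carbons` be the fragment's
carbon count. Fractional labeling is the carbon-weighted mean
$\sum_i i M_i / n$.

## Targeted quantification

Peak areas are divided by the matching internal-standard signal (a
uniformly 13C-labeled E. coli extract, or [U-13C]pyruvate for the
phenylhydrazine-derivatized pyruvate branch — the same code path with a
different standard), converted to concentrations through an ordinary
least-squares calibration line (the fit form is not dictated by the
source protocol; OLS through the provided standards is the default
choice), floored at zero with a flag when a ratio falls below the
intercept, and normalized to cellular protein. On noiseless synthetic
data the pipeline recovers ground-truth concentrations exactly, which is
the module's end-to-end test. Chromatogram peak detection/integration is
out of scope: the generators emit peak areas directly.

## Flow-injection annotation

Negative-mode flow-injection QTOF peaks are annotated by accurate mass
against a compound library, using an absolute tolerance of 0.001 Da and
enumerating deprotonated ([M-H]-, -1.007276), fluoride ([M+F]-,
+18.998403), sodium ([M+Na-2H]-, +20.974666) and potassium
([M+K-2H]-, +36.948606) species plus up to two 13C isotope shifts
(+1.003355 each), retained within m/z 50-1000. Whether "F-" in the
acquisition convention denotes a fluoride adduct or formate is
ambiguous; the adduct set is configurable so either reading is a
configuration change. Ambiguous matches are all reported with the
smallest-error one flagged primary, because the analysis unit downstream
is the annotated ion, not a unique compound. Matching is binary-search
based and tested against brute-force all-pairs matching.

Since no compound database can be bundled, the package ships a synthetic
stand-in library (`brain_library_synthetic.tsv`): 222 entries, of which
75 are real metabolites with exact formulas and monoisotopic masses
(computed from standard atomic masses) and the rest are synthetic filler
compounds with plausible random formulas, so that the annotated-ion count
of the emulated brain metabolome matches the study's 222.

## Differential statistics

The univariate screen runs a two-sample Student's t test per metabolite
on log2 intensities — the generators' noise is log-normal, so the
log-scale test is exact-model; Welch's test is available behind a flag —
with the fold change reported as the log2 ratio of raw group means and
Benjamini-Hochberg adjustment across all tested metabolites. BH is the
conservative default reading of "FDR-adjusted"; a q-value estimator in
the Storey sense would be less conservative and is deliberately not
substituted. A metabolite passes at q < 0.01 and |log2FC| > 0.5, and
"significant in at least one diet" is the union of per-diet passing sets.
Degenerate metabolites with zero variance in both groups and equal means
get p = 1 by convention. PCA is the column-centered SVD
(`stats::prcomp`), reported with scores, loadings and explained variance.
The 2^-ddCq method normalizes each target Cq to the 28S rRNA reference
and calibrates against the wild-type group's mean delta-Cq.

## Respirometry

Traces are segmented at the injection events into basal, fCCP,
succinate/rotenone and antimycin-A phases (oligomycin is present from
assay start in the permeabilized protocol, so no coupling phase exists).
"fCCP-driven OCR" is not defined algebraically in the source protocol;
the standard reading — fCCP-phase mean minus the antimycin-A
(non-mitochondrial) floor — is the default, and the floor subtraction can
be switched off to expose the other convention. Cell-number normalization
is linear and commutes with the floor subtraction.

## Synthetic-data generators

Every generator is deterministic under a fixed seed and emits its ground
truth alongside the data. The noise model throughout is multiplicative
log-normal with CV 10% by default (standard for MS intensity data, and
exact-model for the log-scale t tests). Replicate counts follow the
study designs: 3/group for the targeted MEF experiment, 4/group for
brain samples (the study does not print the brain n; 4 is a typical
embryo-litter yield and fixed here once). The packaged profiles encode
the printed effect sizes:

* `paper_mef_targeted` — aspartate x4, citrate x0.05, pyruvate/lactate
  x2.5, phosphoenolpyruvate and 2/3-phosphoglycerate x2, malate/fumarate
  x2 in the mutant; the rescue line sits near wild type.
* `paper_brain_normal` — exactly 46 programmed hit ions among the 222
  library compounds (lactate, pyruvate, aspartate, malate, fumarate and
  NAAG up; glutamine, glutamate, GABA, phosphocreatine, citrate and
  glutathione down; plus filler hits), all at |log2FC| >= 1 so the screen
  recovery is a sharp integer test at n = 4 and CV 10%.
* `paper_brain_keto` — all effects nulled except lactate and aspartate at
  x1.3: elevated, but with log2(1.3) = 0.38 below the 0.5 fold-change
  threshold, so they are detectable without passing the strict screen —
  exactly the rescued phenotype.
* `paper_qpcr` — MPC1 at 100%/50%/5% of wild type in wt / gt-het / gt-hom
  (a programmed 5% is a delta-delta-Cq offset of 4.32 cycles), MPC2
  unchanged; per-well Cq noise SD 0.15 cycles.
* OCR scenarios — plateaus (pmol O2/min) with the mutant's blunted fCCP
  response on pyruvate/malate restored by membrane-permeable methyl
  pyruvate.

What the generators do **not** emulate: raw spectra and chromatograms,
retention-time structure, instrument drift, batch effects, missing
values, or heteroscedastic noise floors. Passing recovery tests on these
fixtures therefore demonstrates the correctness of the statistical
machinery under its assumed model, not robustness to the full messiness
of real acquisitions.

## Orchestration and problem sizes

`run_study()` runs one of the five studies (tracer, targeted MEF, brain,
OCR, qPCR) from a config list or YAML file; `reproduce_desk()` runs all
five under one seed and writes TSV tables plus a text report; both are
deterministic to the byte under a fixed seed. The problem sizes are the
study's own: 222 ions x 16 brain samples, 12 targeted MEF samples, 13
metabolite pools in the simulator, a few hundred FIA peaks — the whole
desk reproduction completes in seconds. The package is an R library
first; the exported functions plus `scripts/acceptance.R` are the
command-line surface.
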