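# mpctrace

Computational toolkit for studying the metabolic consequences of
mitochondrial pyruvate carrier (MPC) loss. When MPC1 is absent, cytosolic
pyruvate cannot reach the mitochondrial matrix: the pyruvate dehydrogenase
(PDH) / citrate synthase (CS) entry into the TCA cycle is blocked, citrate
is depleted, glycolytic end products accumulate, and cells compensate with
glutamine anaplerosis and reductive carboxylation of alpha-ketoglutarate
(alpha-KG). `mpctrace` implements the quantitative workflow behind that
picture for researchers analyzing stable-isotope tracing and metabolomics
data:

* **Carbon-atom-transition simulator** — steady-state mass isotopomer
  distributions (MIDs) of TCA-cycle metabolites under [U-13C]glucose,
  [U-13C]glutamine or [1-13C]glutamine, for a branch-fraction flux
  scenario (`f_mpc`, `f_gln`, `f_reductive`, `f_anaplerotic_pc`,
  `dilution`). The M+2 isotopologue of citrate under [U-13C]glucose reads
  out the MPC/PDH/CS route; aspartate M+1 under [1-13C]glutamine reads out
  reductive carboxylation (oxidative turns release C1 of alpha-KG as CO2,
  the reductive route retains it).
* **Natural-abundance correction** — inversion of the binomial 13C
  contamination model, entry `[i,j] = C(n-j, i-j) p^(i-j) (1-p)^(n-i)`
  with `p = 0.0107`, plus fractional labeling `sum(i * M_i) / n`.
* **Targeted quantification** — internal-standard normalization,
  least-squares calibration, protein normalization.
* **Flow-injection annotation** — accurate-mass matching of negative-mode
  QTOF peaks (0.001 Da tolerance; deprotonated, fluoride, sodium and
  potassium adducts; 13C isotope shifts; m/z 50-1000) against a compound
  library, collapsed to a metabolite-ion table.
* **Differential statistics** — PCA, per-metabolite Student's t tests with
  Benjamini-Hochberg FDR (screen at q < 0.01 and |log2FC| > 0.5, with the
  per-diet union), fold-change tables, phosphocreatine/creatine ratios,
  and 2^-ddCq qPCR expression.
* **Respirometry** — phase segmentation of extracellular-flux OCR traces
  and fCCP-driven (maximal uncoupled) respiration above the antimycin-A
  floor.
* **Synthetic-data generators** — seeded emulators of every assay design,
  with packaged profiles encoding the study's effect sizes and ground
  truth emitted alongside each dataset.

## Worked example

Simulate the tracer experiment that distinguishes the wild type from the
MPC1-null mutant:

```r
library(mpctrace)

wt <- flux_scenario(f_mpc = 0.85, f_gln = 0.70, f_reductive = 0.08,
                    f_anaplerotic_pc = 0.05, dilution = 0.25, name = "wt")
mutant <- flux_scenario(f_mpc = 0, f_gln = 0.85, f_reductive = 0.45,
                        dilution = 0.25, name = "mpc1_gt")

glc <- tracer_spec("glucose", "U")
round(simulate_steady_state(build_network(wt), glc)$citrate, 3)
#> [1] 0.645 0.000 0.327 0.011 0.007 0.010 0.000
round(simulate_steady_state(build_network(mutant), glc)$citrate, 3)
#> [1] 1 0 0 0 0 0 0
```

The wild type puts 33% of citrate in M+2 (pyruvate entering via MPC, PDH
and CS contributes two labeled acetyl carbons); the mutant's citrate M+2
is exactly zero — the route is blocked. The reductive signature runs the
other way:

```r
gln1 <- tracer_spec("glutamine", 1)   # [1-13C]glutamine
simulate_steady_state(build_network(wt), gln1)$aspartate[2]
#> [1] 0.0011
simulate_steady_state(build_network(mutant), gln1)$aspartate[2]
#> [1] 0.0496
```

C1 of glutamine survives only the reductive route (oxidative turns lose
it as CO2), so aspartate M+1 rises from ~0 to ~5% as reductive
carboxylation expands in the mutant.

The full desk reproduction runs all five studies and writes TSV tables
plus a report:

```r
reproduce_desk(seed = 1, out_dir = "desk")
```

```text
[brain] seed=1
  thresholds: q<0.01 |log2FC|>0.5 tol=0.001 Da p_nat=0.0107
  annotated metabolite ions: 222
  screen hits: normal=46 keto=0 union=46
  PCr/Cr (normal diet): gt=12.40 wt=31.17
[ocr] seed=1
  fCCP-driven OCR: wt=104.7 mutant=39.7 mutant_methyl_pyr=99.7
[qpcr] seed=1
  MPC1 relative expression: gt=0.056 het=0.558 wt=1.007
```

222 metabolite ions are annotated in the emulated brain metabolome; 46
pass the univariate screen in at least one diet (all under normal diet —
the ketogenic diet rescues the metabolome); the PCr/Cr energy-charge
proxy collapses in mutant brains on normal diet only; mutant fCCP-driven
respiration on pyruvate/malate is restored by membrane-permeable methyl
pyruvate; and MPC1 mRNA in homozygous mutants sits at ~5% of wild type.

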