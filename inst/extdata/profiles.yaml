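# Packaged effect profiles encoding the study's printed effect sizes.
# Fold changes are mutant (gt) over wild type (wt); metabolites not listed
# have fold change 1 (null). Noise is multiplicative log-normal with the
# stated coefficient of variation.

paper_mef_targeted:
  assay: targeted
  n_per_group: 3
  cv: 0.10
  groups: [wt, gt, rescue]
  metabolites: [phosphoglycerate_23, phosphoenolpyruvate, pyruvate, lactate,
                citrate, alpha_ketoglutarate, succinate, fumarate, malate,
                aspartate, glutamate, glutamine]
  fold_changes:
    gt:
      phosphoglycerate_23: 2.0
      phosphoenolpyruvate: 2.0
      pyruvate: 2.5
      lactate: 2.5
      citrate: 0.05
      fumarate: 2.0
      malate: 2.0
      aspartate: 4.0
    rescue:
      citrate: 0.9
      aspartate: 1.1

paper_brain_normal:
  assay: fia
  diet: normal
  n_per_group: 4
  cv: 0.10
  metabolites: library          # the 222 compounds of the packaged library
  fold_changes:
    gt:
      lactate: 3.0
      pyruvate: 2.5
      aspartate: 4.0
      malate: 2.2
      fumarate: 2.2
      citrate: 0.3
      glutamine: 0.4
      glutamate: 0.4
      gaba: 0.35
      naag: 2.5
      phosphocreatine: 0.45
      proline: 2.2
      uracil: 2.2
      uridine: 2.2
      orotate: 2.2
      glutathione: 0.45
      M101: 2.2
      M102: 0.45
      M103: 2.2
      M104: 0.45
      M105: 2.2
      M106: 0.45
      M107: 2.2
      M108: 0.45
      M109: 2.2
      M110: 0.45
      M111: 2.2
      M112: 0.45
      M113: 2.2
      M114: 0.45
      M115: 2.2
      M116: 0.45
      M117: 2.2
      M118: 0.45
      M119: 2.2
      M120: 0.45
      M121: 2.2
      M122: 0.45
      M123: 2.2
      M124: 0.45
      M125: 2.2
      M126: 0.45
      M127: 2.2
      M128: 0.45
      M129: 2.2
      M130: 0.45

paper_brain_keto:
  assay: fia
  diet: keto
  n_per_group: 4
  cv: 0.10
  metabolites: library
  fold_changes:
    gt:
      lactate: 1.3
      aspartate: 1.3

paper_qpcr:
  assay: qpcr
  n_per_group: 4
  cq_sd: 0.15
  reference_gene: rRNA_28S
  reference_cq: 12.0
  genotypes: [wt, het, gt]
  target_dcq_wt:                # delta-Cq of each target in wild type
    MPC1: 8.0
    MPC2: 7.0
  relative_expression:          # programmed 2^-ddCq per genotype
    MPC1: {wt: 1.0, het: 0.5, gt: 0.05}
    MPC2: {wt: 1.0, het: 1.0, gt: 1.0}

flux_scenarios:
  wt:
    f_mpc: 0.85
    f_gln: 0.70
    f_reductive: 0.08
    f_anaplerotic_pc: 0.05
    dilution: 0.25
  mpc1_gt:
    f_mpc: 0.0
    f_gln: 0.85
    f_reductive: 0.45
    f_anaplerotic_pc: 0.0
    dilution: 0.25

ocr_scenarios:
  # plateau OCR (pmol O2/min) per phase, permeabilized MEFs with
  # pyruvate/malate; mutant fCCP response is blunted unless methyl pyruvate
  # bypasses the carrier
  wt:                {basal: 50, fccp: 120, succinate_rotenone: 150, antimycin_a: 15}
  wt_methyl_pyr:     {basal: 50, fccp: 125, succinate_rotenone: 150, antimycin_a: 15}
  mutant:            {basal: 45, fccp: 55,  succinate_rotenone: 150, antimycin_a: 15}
  mutant_methyl_pyr: {basal: 45, fccp: 115, succinate_rotenone: 150, antimycin_a: 15}
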