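seed: 1
group_sizes:
  normal: 28.0
  DCIS: 27.0
  invasive: 28.0
  mixed: 34.0
genes:
  ABCB1:
    baseline_mean: 6.0
    baseline_sd: 2.0
    n_cpgs: 5.0
    cpg_jitter_sd: 1.5
    hyper_shift: 30.0
    hypo_shift: 0.0
    hyper_fraction:
      DCIS: 0.41
      invasive: 0.39
      mixed: 0.44
    hypo_fraction:
      DCIS: 0.0
      invasive: 0.0
      mixed: 0.0
    missing_rate: 0.03
    normals_measured: 28
  CDKN2A:
    baseline_mean: 6.0
    baseline_sd: 1.5
    n_cpgs: 7.0
    cpg_jitter_sd: 1.5
    hyper_shift: 35.0
    hypo_shift: 0.0
    hyper_fraction:
      DCIS: 0.0
      invasive: 0.107
      mixed: 0.059
    hypo_fraction:
      DCIS: 0.0
      invasive: 0.0
      mixed: 0.0
    missing_rate: 0.03
    normals_measured: 5
  ESR1:
    baseline_mean: 7.0
    baseline_sd: 2.0
    n_cpgs: 5.0
    cpg_jitter_sd: 1.5
    hyper_shift: 30.0
    hypo_shift: 0.0
    hyper_fraction:
      DCIS: 0.0
      invasive: 0.0
      mixed: 0.0
    hypo_fraction:
      DCIS: 0.0
      invasive: 0.0
      mixed: 0.0
    missing_rate: 0.03
    normals_measured: 5
  FOXC1:
    baseline_mean: 6.0
    baseline_sd: 1.5
    n_cpgs: 8.0
    cpg_jitter_sd: 1.5
    hyper_shift: 35.0
    hypo_shift: 0.0
    hyper_fraction:
      DCIS: 0.222
      invasive: 0.536
      mixed: 0.676
    hypo_fraction:
      DCIS: 0.0
      invasive: 0.0
      mixed: 0.0
    missing_rate: 0.03
    normals_measured: 28
  GSTP1:
    baseline_mean: 6.0
    baseline_sd: 1.5
    n_cpgs: 5.0
    cpg_jitter_sd: 1.5
    hyper_shift: 40.0
    hypo_shift: 0.0
    hyper_fraction:
      DCIS: 0.222
      invasive: 0.143
      mixed: 0.265
    hypo_fraction:
      DCIS: 0.0
      invasive: 0.0
      mixed: 0.0
    missing_rate: 0.03
    normals_measured: 5
  IGF2:
    baseline_mean: 50.0
    baseline_sd: 4.0
    n_cpgs: 4.0
    cpg_jitter_sd: 1.5
    hyper_shift: 25.0
    hypo_shift: -30.0
    hyper_fraction:
      DCIS: 0.037
      invasive: 0.107
      mixed: 0.294
    hypo_fraction:
      DCIS: 0.37
      invasive: 0.393
      mixed: 0.147
    missing_rate: 0.03
    normals_measured: 5
  MGMT:
    baseline_mean: 6.0
    baseline_sd: 2.0
    n_cpgs: 6.0
    cpg_jitter_sd: 1.5
    hyper_shift: 30.0
    hypo_shift: 0.0
    hyper_fraction:
      DCIS: 0.037
      invasive: 0.036
      mixed: 0.059
    hypo_fraction:
      DCIS: 0.0
      invasive: 0.0
      mixed: 0.0
    missing_rate: 0.03
    normals_measured: 5
  MLH1:
    baseline_mean: 6.0
    baseline_sd: 1.5
    n_cpgs: 5.0
    cpg_jitter_sd: 1.5
    hyper_shift: 30.0
    hypo_shift: 0.0
    hyper_fraction:
      DCIS: 0.074
      invasive: 0.036
      mixed: 0.029
    hypo_fraction:
      DCIS: 0.0
      invasive: 0.0
      mixed: 0.0
    missing_rate: 0.03
    normals_measured: 5
  PPP2R2B:
    baseline_mean: 7.0
    baseline_sd: 2.0
    n_cpgs: 6.0
    cpg_jitter_sd: 1.5
    hyper_shift: 35.0
    hypo_shift: 0.0
    hyper_fraction:
      DCIS: 0.55
      invasive: 0.786
      mixed: 0.706
    hypo_fraction:
      DCIS: 0.0
      invasive: 0.0
      mixed: 0.0
    missing_rate: 0.15
    normals_measured: 28
  PTEN:
    baseline_mean: 7.0
    baseline_sd: 2.0
    n_cpgs: 4.0
    cpg_jitter_sd: 1.5
    hyper_shift: 30.0
    hypo_shift: 0.0
    hyper_fraction:
      DCIS: 0.185
      invasive: 0.143
      mixed: 0.235
    hypo_fraction:
      DCIS: 0.0
      invasive: 0.0
      mixed: 0.0
    missing_rate: 0.03
    normals_measured: 28
  RASSF1A:
    baseline_mean: 8.0
    baseline_sd: 2.5
    n_cpgs: 7.0
    cpg_jitter_sd: 1.5
    hyper_shift: 40.0
    hypo_shift: 0.0
    hyper_fraction:
      DCIS: 0.852
      invasive: 0.821
      mixed: 0.853
    hypo_fraction:
      DCIS: 0.0
      invasive: 0.0
      mixed: 0.0
    missing_rate: 0.03
    normals_measured: 5
factors:
  er:
    levels:
    - positive
    - negative
    - unknown
    prob:
    - 0.74
    - 0.23
    - 0.03
  pr:
    levels:
    - positive
    - negative
    - unknown
    prob:
    - 0.69
    - 0.28
    - 0.03
  tp53:
    levels:
    - wildtype
    - mutant
    - unknown
    prob:
    - 0.78
    - 0.19
    - 0.03
  ki67:
    levels:
    - positive
    - negative
    - unknown
    prob:
    - 0.29
    - 0.7
    - 0.01
  grade:
    levels:
    - A_I
    - B_II
    - C_III
    - unknown
    prob:
    - 0.25
    - 0.4
    - 0.33
    - 0.02
factor_effects: []
expression:
  target: FOXC1
  reference: PGK1
  diagnoses:
  - normal
  - DCIS
  - invasive
  normal_quantity: 1.0
  tumour_multiplier: 0.5
  log2_sd: 0.75
  reference_log2_sd: 0.25
  ct_noise_sd: 0.1
  standards_quantities:
  - 1.0
  - 0.1
  - 0.01
  - 0.001
  - 0.0001
  curves:
    FOXC1:
      slope: -3.3219
      intercept: 36.0
    PGK1:
      slope: -3.3219
      intercept: 30.0
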