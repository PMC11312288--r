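# Demo pipeline configuration: a scaled-down emulation of a wild-type vs
# AQP4-knockout corpus-callosum microarray study with planted microglial
# genes, a two-block microglial signature collection, and a qPCR validation
# plate. All stages enabled; rerunning with the same seed reproduces
# identical output hashes.
schema_version: 1
seed: 11
stages:
  simulate: yes
  de: yes
  enrich: yes
  compare: yes
  qpcr: yes
de:
  reference_prefix: WT
  test_prefix: KO
  q_threshold: 0.05
  fc_threshold: 1.5
  method: moderated
enrich:
  n_permutations: 499
  weight_exponent: 1
compare:
  mds_k: 2
  linkage: average
  n_clusters: 2
qpcr:
  reference_gene: 18S
  calibrator_group: WT
simulate:
  study:
    n_genes: 4000
    n_samples_per_condition: 3
    noise_sd_log2: 0.25
    baseline_log2_mean: 7
    planted_up:
      Spp1: 600
      Gpnmb: 45
      Itgax: 30
      Cd68: 12
      Atp6v0d2: 20
      Igf1: 8
      Lgals3: 10
      Apoe: 6
      Trem2: 5
    planted_down:
      Aqp4: 0.02
      Mal: 0.5
      Mog: 0.6
  signatures:
    n_genes: 500
    within_block_cosine: 0.9
    between_block_cosine: 0.2
    noise_sd: 0.1
    blocks:
      neurodevelopment: [PAM, ATM, CD11c, AQP4_AC, AQP4_CC]
      disease_ageing: [APP, Aged, DAM1, DAM2, MGnD, LDAM]
  qpcr:
    genes: [18S, Spp1, Gpnmb, Itgax, Cd68, Atp6v0d2, Igf1, Lgals3, Apoe, Trem2]
    reference_gene: 18S
    true_fold_changes:
      Spp1: 535
      Gpnmb: 300
      Itgax: 250
      Cd68: 8
      Atp6v0d2: 12
      Igf1: 6
      Lgals3: 5
      Apoe: 3
      Trem2: 2.5
    n_animals_per_group: 6
    ct_noise_sd: 0.3
    n_technical_replicates: 3
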