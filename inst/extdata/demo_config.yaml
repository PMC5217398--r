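# Demo run configuration: 200-gene synthetic transcriptome, six tag
# libraries (two genotypes x control / 0.5 h / 24 h stress), four stress
# contrasts and the two per-genotype time-point decompositions.
seed: 7
output_dir: demo_out
reference:
  synthetic:
    n_genes: 200
    length_min: 200
    length_max: 1200
scenario:
  frac_de: 0.1
  log2fc_magnitude: 2
noise:
  per_base_error_rate: 0.005
  adaptor_fraction: 0.02
  empty_fraction: 0.01
  length_anomaly_fraction: 0.01
  ambiguous_base_fraction: 0.01
libraries:
  - {id: A_CK,   condition: A, depth: 20000}
  - {id: A_0.5h, condition: B, depth: 20000}
  - {id: A_24h,  condition: B, depth: 20000}
  - {id: B_CK,   condition: A, depth: 20000}
  - {id: B_0.5h, condition: B, depth: 20000}
  - {id: B_24h,  condition: B, depth: 20000}
contrasts:
  - {a: A_CK, b: A_0.5h, label: A_0.5h_vs_CK}
  - {a: A_CK, b: A_24h,  label: A_24h_vs_CK}
  - {a: B_CK, b: B_0.5h, label: B_0.5h_vs_CK}
  - {a: B_CK, b: B_24h,  label: B_24h_vs_CK}
venn:
  - {t1: A_0.5h_vs_CK, t2: A_24h_vs_CK, label: A}
  - {t1: B_0.5h_vs_CK, t2: B_24h_vs_CK, label: B}
thresholds:
  fdr: 0.001
  lfc: 1
  go_p: 0.01
  go_fdr: 0.05
saturation: true
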