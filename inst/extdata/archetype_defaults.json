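{
  "config_version": "1.0",
  "adapter": "TGGAATTCTCGGGTGCCAAGG",
  "lengths": [18, 19, 20, 21, 22, 23, 24, 25, 26, 27, 28, 29, 30, 31, 32],
  "isomir_shift_probs": {
    "offsets": [-2, -1, 0, 1, 2],
    "probs": [0.05, 0.15, 0.60, 0.15, 0.05]
  },
  "archetypes": {
    "ovary_like": {
      "length_mixture": [0.015, 0.025, 0.045, 0.105, 0.340, 0.120, 0.080,
                         0.060, 0.050, 0.045, 0.040, 0.030, 0.020, 0.015, 0.010],
      "category_mixture": {
        "rRNA": 0.08, "tRNA": 0.05, "snRNA": 0.02, "snoRNA": 0.02,
        "miRNA_hairpin": 0.45, "LINE": 0.05, "LTR": 0.03, "satellite": 0.02,
        "other_repeat": 0.02, "exon": 0.08, "intergenic": 0.18
      },
      "fivep_u_bias": 0.30,
      "adapter_dimer_rate": 0.02,
      "low_quality_rate": 0.03
    },
    "testis_like": {
      "length_mixture": [0.010, 0.010, 0.020, 0.030, 0.050, 0.070, 0.170,
                         0.090, 0.100, 0.160, 0.090, 0.070, 0.050, 0.040, 0.040],
      "category_mixture": {
        "rRNA": 0.05, "tRNA": 0.04, "snRNA": 0.02, "snoRNA": 0.02,
        "miRNA_hairpin": 0.03, "LINE": 0.18, "LTR": 0.10, "satellite": 0.05,
        "other_repeat": 0.03, "exon": 0.10, "intergenic": 0.38
      },
      "fivep_u_bias": 0.65,
      "adapter_dimer_rate": 0.02,
      "low_quality_rate": 0.03
    },
    "ip_like": {
      "length_mixture": [0.010, 0.015, 0.020, 0.030, 0.040, 0.090, 0.200,
                         0.180, 0.110, 0.090, 0.070, 0.050, 0.040, 0.030, 0.025],
      "category_mixture": {
        "rRNA": 0.030, "tRNA": 0.025, "snRNA": 0.010, "snoRNA": 0.010,
        "miRNA_hairpin": 0.005, "LINE": 0.070, "LTR": 0.030, "satellite": 0.015,
        "other_repeat": 0.010, "exon": 0.150, "intergenic": 0.645
      },
      "fivep_u_bias": 0.70,
      "adapter_dimer_rate": 0.02,
      "low_quality_rate": 0.03
    }
  }
}
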