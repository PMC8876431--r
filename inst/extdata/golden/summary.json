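{
  "dmr_counts": {
    "context": ["CG", "CG", "CHG", "CHG", "CHH", "CHH"],
    "direction": ["hyper", "hypo", "hyper", "hypo", "hyper", "hypo"],
    "n": [0, 0, 0, 0, 2, 2]
  },
  "n_dmrs": 4,
  "correlations": {
    "r_positive": [0.99667828],
    "p_positive": [0.05190353],
    "n_positive": [3],
    "r_negative": ["NA"],
    "p_negative": ["NA"],
    "n_negative": [1],
    "n_excluded": [0]
  },
  "wilcoxon_p": 0.08827551
}
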