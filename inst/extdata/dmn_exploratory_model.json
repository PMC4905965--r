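{
  "description": "13-edge exploratory default-mode-network connectivity model: directed edges with lagged-to-lagged path coefficients per decade cohort (20s through 70s) and the published Pearson correlation of each coefficient vector with decade.",
  "cohorts": ["20s", "30s", "40s", "50s", "60s", "70s"],
  "edges": [
    {"source": "pC",   "target": "LMFG", "coefficients": [0.37, 0.33, 0.25, 0.20, 0.23, 0.17], "published_r": -0.93},
    {"source": "pC",   "target": "RIPL", "coefficients": [0.20, 0.29, 0.29, 0.36, 0.34, 0.41], "published_r": 0.94},
    {"source": "pC",   "target": "LIPL", "coefficients": [0.42, 0.39, 0.38, 0.37, 0.47, 0.44], "published_r": 0.46},
    {"source": "pC",   "target": "LMTG", "coefficients": [0.39, 0.32, 0.24, 0.27, 0.24, 0.14], "published_r": -0.93},
    {"source": "pC",   "target": "PCC",  "coefficients": [0.64, 0.61, 0.61, 0.59, 0.62, 0.60], "published_r": -0.59},
    {"source": "PCC",  "target": "LMTG", "coefficients": [0.30, 0.38, 0.41, 0.43, 0.41, 0.52], "published_r": 0.91},
    {"source": "PCC",  "target": "RMTG", "coefficients": [0.23, 0.27, 0.35, 0.32, 0.34, 0.42], "published_r": 0.92},
    {"source": "PCC",  "target": "MPFG", "coefficients": [0.47, 0.52, 0.47, 0.48, 0.41, 0.45], "published_r": -0.61},
    {"source": "PCC",  "target": "vACC", "coefficients": [0.23, 0.25, 0.24, 0.27, 0.19, 0.18], "published_r": -0.41},
    {"source": "MPFG", "target": "vACC", "coefficients": [0.42, 0.39, 0.31, 0.31, 0.44, 0.42], "published_r": 0.15},
    {"source": "MPFG", "target": "LMFG", "coefficients": [0.24, 0.27, 0.30, 0.36, 0.37, 0.41], "published_r": 0.99},
    {"source": "LIPL", "target": "RIPL", "coefficients": [0.49, 0.37, 0.27, 0.30, 0.16, 0.08], "published_r": -0.97},
    {"source": "LMTG", "target": "RMTG", "coefficients": [0.47, 0.36, 0.31, 0.30, 0.25, 0.27], "published_r": -0.89}
  ]
}
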