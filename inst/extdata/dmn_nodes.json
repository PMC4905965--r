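{
  "space": "Talairach",
  "nodes": [
    {"name": "pC",   "label": "Precuneus",                  "x": -4,  "y": -58, "z": 44},
    {"name": "PCC",  "label": "Posterior Cingulate Cortex", "x": -4,  "y": -52, "z": 22},
    {"name": "vACC", "label": "Ventral Anterior Cingulate", "x": 2,   "y": 32,  "z": -8},
    {"name": "RIPL", "label": "R Inferior Parietal Lobule", "x": 52,  "y": -28, "z": 24},
    {"name": "MPFG", "label": "Medial Prefrontal Gyrus",    "x": -2,  "y": 50,  "z": 18},
    {"name": "RMTG", "label": "R Middle Temporal Gyrus",    "x": 46,  "y": -66, "z": 16},
    {"name": "LMFG", "label": "L Middle Frontal Gyrus",     "x": -26, "y": 16,  "z": 14},
    {"name": "LIPL", "label": "L Inferior Parietal Lobule", "x": -56, "y": -36, "z": 28},
    {"name": "LMTG", "label": "L Middle Temporal Gyrus",    "x": -42, "y": -66, "z": 18}
  ]
}
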