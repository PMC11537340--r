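{
  "version": "1.0",
  "field_strength_t": 3,
  "hydroxyl": {
    "shifts_ppm": [0.66, 1.28, 2.08, 2.88],
    "protons": [1.0, 3.0, 0.36, 0.64],
    "labels": ["OH-6", "OH-2,3,4", "OH-1a", "OH-1b"],
    "T1_s": 1.2,
    "T2_s": 0.1,
    "exchange_rates_hz": {
      "normal": [2900, 6500, 5200, 14300],
      "tumor_acidic": [1500, 3100, 2500, 6000]
    }
  },
  "compartments": {
    "arterial": {
      "T1_s": 1.91, "T2_s": 0.152, "water_density": 0.856,
      "glucose_mM": {"normoglycemia": 6.15, "hyperglycemia": 19.8},
      "pH_regime": "normal"
    },
    "venous": {
      "T1_s": 1.73, "T2_s": 0.052, "water_density": 0.856,
      "glucose_mM": {"normoglycemia": 5.47, "hyperglycemia": 19.1},
      "pH_regime": "normal"
    },
    "GM_EES": {
      "T1_s": 3.48, "T2_s": 2.78, "water_density": 0.938,
      "glucose_mM": {"normoglycemia": 2.24, "hyperglycemia": 6.10},
      "pH_regime": "normal"
    },
    "GM_cell": {
      "T1_s": 1.08, "T2_s": 0.071, "water_density": 0.809,
      "glucose_mM": {"normoglycemia": 0.167, "hyperglycemia": 1.16},
      "pH_regime": "normal"
    },
    "WM_EES": {
      "T1_s": 3.48, "T2_s": 2.78, "water_density": 0.938,
      "glucose_mM": {"normoglycemia": 2.42, "hyperglycemia": 5.71},
      "pH_regime": "normal"
    },
    "WM_cell": {
      "T1_s": 0.65, "T2_s": 0.055, "water_density": 0.678,
      "glucose_mM": {"normoglycemia": 0.381, "hyperglycemia": 1.24},
      "pH_regime": "normal"
    },
    "TUMOR_EES": {
      "T1_s": 3.48, "T2_s": 2.78, "water_density": 0.938,
      "glucose_mM": {"normoglycemia": 5.45, "hyperglycemia": 17.6},
      "pH_regime": "tumor_acidic"
    },
    "TUMOR_cell": {
      "T1_s": 1.02, "T2_s": 0.071, "water_density": 0.674,
      "glucose_mM": {"normoglycemia": 0.811, "hyperglycemia": 4.41},
      "pH_regime": "normal"
    },
    "CSF_EES": {
      "T1_s": 3.48, "T2_s": 2.78, "water_density": 0.938,
      "glucose_mM": {"normoglycemia": 3.69, "hyperglycemia": 11.9},
      "pH_regime": "normal"
    }
  },
  "tissues": {
    "blood": {
      "blood_fraction": 1.0, "EES_fraction": 0.0, "cell_fraction": 0.0,
      "arterial_subfraction": 0.3, "venous_subfraction": 0.7,
      "EES": null, "cell": null,
      "blood_water_density": 0.856, "EES_water_density": 0.938,
      "cell_water_density": 0.856, "tissue_water_density": 0.856
    },
    "arterial": {
      "blood_fraction": 1.0, "EES_fraction": 0.0, "cell_fraction": 0.0,
      "arterial_subfraction": 1.0, "venous_subfraction": 0.0,
      "EES": null, "cell": null,
      "blood_water_density": 0.856, "EES_water_density": 0.938,
      "cell_water_density": 0.856, "tissue_water_density": 0.856
    },
    "venous": {
      "blood_fraction": 1.0, "EES_fraction": 0.0, "cell_fraction": 0.0,
      "arterial_subfraction": 0.0, "venous_subfraction": 1.0,
      "EES": null, "cell": null,
      "blood_water_density": 0.856, "EES_water_density": 0.938,
      "cell_water_density": 0.856, "tissue_water_density": 0.856
    },
    "GM": {
      "blood_fraction": 0.038, "EES_fraction": 0.22, "cell_fraction": 0.742,
      "arterial_subfraction": 0.3, "venous_subfraction": 0.7,
      "EES": "GM_EES", "cell": "GM_cell",
      "blood_water_density": 0.856, "EES_water_density": 0.938,
      "cell_water_density": 0.809, "tissue_water_density": 0.839
    },
    "WM": {
      "blood_fraction": 0.018, "EES_fraction": 0.22, "cell_fraction": 0.762,
      "arterial_subfraction": 0.3, "venous_subfraction": 0.7,
      "EES": "WM_EES", "cell": "WM_cell",
      "blood_water_density": 0.856, "EES_water_density": 0.938,
      "cell_water_density": 0.678, "tissue_water_density": 0.738
    },
    "TUMOR": {
      "blood_fraction": 0.05, "EES_fraction": 0.5, "cell_fraction": 0.45,
      "arterial_subfraction": 0.3, "venous_subfraction": 0.7,
      "EES": "TUMOR_EES", "cell": "TUMOR_cell",
      "blood_water_density": 0.856, "EES_water_density": 0.938,
      "cell_water_density": 0.674, "tissue_water_density": 0.815
    },
    "CSF": {
      "blood_fraction": 0.0, "EES_fraction": 1.0, "cell_fraction": 0.0,
      "arterial_subfraction": 0.3, "venous_subfraction": 0.7,
      "EES": "CSF_EES", "cell": null,
      "blood_water_density": 0.856, "EES_water_density": 0.938,
      "cell_water_density": 0.938, "tissue_water_density": 0.938
    }
  }
}
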