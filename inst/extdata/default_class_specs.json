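{
  "basophil": {
    "class_name": "basophil",
    "nucleus_shape": "round",
    "nucleus_area_fraction": 0.45,
    "granule_hue_range": [260, 290],
    "granule_density": 0.012,
    "cytoplasm_color": [0.8, 0.74, 0.88],
    "size_range": [120, 170],
    "lobe_count": [1, 1]
  },
  "eosinophil": {
    "class_name": "eosinophil",
    "nucleus_shape": "multilobed",
    "nucleus_area_fraction": 0.35,
    "granule_hue_range": [10, 40],
    "granule_density": 0.014,
    "cytoplasm_color": [0.93, 0.82, 0.76],
    "size_range": [130, 180],
    "lobe_count": [2, 2]
  },
  "erythroblast": {
    "class_name": "erythroblast",
    "nucleus_shape": "round",
    "nucleus_area_fraction": 0.55,
    "granule_hue_range": null,
    "granule_density": 0,
    "cytoplasm_color": [0.85, 0.56, 0.54],
    "size_range": [90, 130],
    "lobe_count": [1, 1]
  },
  "lymphocyte": {
    "class_name": "lymphocyte",
    "nucleus_shape": "round",
    "nucleus_area_fraction": 0.8,
    "granule_hue_range": null,
    "granule_density": 0,
    "cytoplasm_color": [0.7, 0.78, 0.92],
    "size_range": [90, 140],
    "lobe_count": [1, 1]
  },
  "monocyte": {
    "class_name": "monocyte",
    "nucleus_shape": "kidney",
    "nucleus_area_fraction": 0.5,
    "granule_hue_range": [210, 250],
    "granule_density": 0.002,
    "cytoplasm_color": [0.74, 0.78, 0.85],
    "size_range": [150, 200],
    "lobe_count": [1, 1]
  },
  "neutrophil": {
    "class_name": "neutrophil",
    "nucleus_shape": "multilobed",
    "nucleus_area_fraction": 0.4,
    "granule_hue_range": [300, 330],
    "granule_density": 0.009,
    "cytoplasm_color": [0.9, 0.85, 0.82],
    "size_range": [130, 180],
    "lobe_count": [3, 5]
  }
}
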