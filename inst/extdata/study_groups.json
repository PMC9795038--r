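{
  "signature": {
    "endo": "GACGATCATGTACAGGACCGG",
    "exo": "CACTATCATATATAGTACTGG"
  },
  "control_mean_cpm": 300,
  "knockdown_efficiency": 0.85,
  "groups": [
    {
      "group": "WT_control",
      "genotype": "+/+",
      "vector": "none",
      "n_cells": 12,
      "exo_fraction": 0.0,
      "fold_change": 1.0
    },
    {
      "group": "Bth_control",
      "genotype": "Bth/+",
      "vector": "none",
      "n_cells": 12,
      "exo_fraction": 0.0,
      "fold_change": 1.0
    },
    {
      "group": "AAV2_2_RNAi_replacement",
      "genotype": "Bth/+",
      "vector": "AAV2/2.miTmc1D11.mTmc1",
      "n_cells": 12,
      "exo_fraction": 0.764,
      "fold_change": 1.836
    },
    {
      "group": "AAV2_2_RNAi_replacement_WPRE",
      "genotype": "Bth/+",
      "vector": "AAV2/2.miTmc1D11.mTmc1.WPRE",
      "n_cells": 12,
      "exo_fraction": 0.965,
      "fold_change": 3.48
    }
  ]
}
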