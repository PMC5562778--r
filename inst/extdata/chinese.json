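{
  "name": "chinese",
  "physiology": {
    "body_weight_kg": 60,
    "tissue_fraction_pct": {
      "liver": 2.3,
      "fat": 18.7,
      "rapidly_perfused": 5.3,
      "slowly_perfused": 54.3,
      "blood": 7.9
    },
    "cardiac_output_constant": 15,
    "flow_fraction_pct": {
      "liver": 26.3,
      "fat": 6.75,
      "rapidly_perfused": 43.8,
      "slowly_perfused": 23.3
    }
  },
  "partition_coefficients": {
    "estragole": {
      "liver": 6.5,
      "fat": 105,
      "rapidly_perfused": 6.5,
      "slowly_perfused": 4.1
    },
    "hydroxyestragole": {
      "liver": 1.6
    }
  },
  "pathways": [
    {
      "pathway": "AP",
      "km_uM": 115,
      "vmax_invitro": 0.15,
      "protein_source": "microsomes"
    },
    {
      "pathway": "EE",
      "km_uM": 161,
      "vmax_invitro": 0.42,
      "protein_source": "microsomes"
    },
    {
      "pathway": "HE",
      "km_uM": 49,
      "vmax_invitro": 0.35,
      "protein_source": "microsomes"
    },
    {
      "pathway": "HA",
      "km_uM": 450,
      "vmax_invitro": 0.32,
      "protein_source": "microsomes"
    },
    {
      "pathway": "M5",
      "km_uM": 618,
      "vmax_invitro": 0.18,
      "protein_source": "microsomes"
    },
    {
      "pathway": "HEG",
      "km_uM": 4656,
      "vmax_invitro": 1.63,
      "protein_source": "microsomes"
    },
    {
      "pathway": "OE",
      "km_uM": 403,
      "vmax_invitro": 1.82,
      "protein_source": "S9"
    },
    {
      "pathway": "HES",
      "km_uM": 694,
      "vmax_invitro": 0.0014,
      "protein_source": "S9"
    }
  ],
  "protein_yields_mg_per_g": {
    "microsomes": 35,
    "S9": 143
  },
  "absorption": {
    "ka_per_h": 1
  },
  "mw_estragole": 148.2
}
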