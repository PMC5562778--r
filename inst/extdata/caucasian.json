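{
  "name": "caucasian",
  "physiology": {
    "body_weight_kg": 70,
    "tissue_fraction_pct": {
      "liver": 2.6,
      "fat": 21.4,
      "rapidly_perfused": 5,
      "slowly_perfused": 51.7,
      "blood": 7.9
    },
    "cardiac_output_constant": 15,
    "flow_fraction_pct": {
      "liver": 22.7,
      "fat": 5.2,
      "rapidly_perfused": 47.3,
      "slowly_perfused": 24.8
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
      "km_uM": 308,
      "vmax_invitro": 0.74,
      "protein_source": "microsomes"
    },
    {
      "pathway": "EE",
      "km_uM": 146,
      "vmax_invitro": 1.85,
      "protein_source": "microsomes"
    },
    {
      "pathway": "HE",
      "km_uM": 62,
      "vmax_invitro": 1.19,
      "protein_source": "microsomes"
    },
    {
      "pathway": "HA",
      "km_uM": 429,
      "vmax_invitro": 0.99,
      "protein_source": "microsomes"
    },
    {
      "pathway": "M5",
      "km_uM": 1451,
      "vmax_invitro": 1.18,
      "protein_source": "microsomes"
    },
    {
      "pathway": "HEG",
      "km_uM": 4607,
      "vmax_invitro": 4.29,
      "protein_source": "microsomes"
    },
    {
      "pathway": "OE",
      "km_uM": 521,
      "vmax_invitro": 2.8,
      "protein_source": "S9"
    },
    {
      "pathway": "HES",
      "km_uM": 423,
      "vmax_invitro": 0.004,
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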