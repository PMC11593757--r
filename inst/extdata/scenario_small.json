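{
  "n_persons": 300,
  "date_range": ["2018-11-01", "2024-03-01"],
  "factors": ["bp", "smoking"],
  "subgroup_mix": {
    "age_band": {
      "18-39": 0.416,
      "40-59": 0.324,
      "60-79": 0.21,
      "80+": 0.05
    },
    "sex": {
      "female": 0.503,
      "male": 0.497
    },
    "ethnicity": {
      "White": 0.777,
      "Asian": 0.11,
      "Black": 0.042,
      "Mixed": 0.017,
      "Other/Unknown": 0.054
    },
    "imd_quintile": {
      "1": 0.201,
      "2": 0.213,
      "3": 0.205,
      "4": 0.196,
      "5": 0.185
    }
  },
  "factor_log_rate": {
    "bp": -2.12026353620009,
    "smoking": -2.99573227355399
  },
  "subgroup_log_effects": {
    "age_band": {
      "18-39": 0,
      "40-59": 0.6,
      "60-79": 1.1,
      "80+": 1.4
    },
    "sex": {
      "female": 0,
      "male": -0.1
    },
    "ethnicity": {
      "White": 0,
      "Asian": 0.05,
      "Black": 0.05,
      "Mixed": 0,
      "Other/Unknown": -0.1
    },
    "imd_quintile": {
      "1": 0.1,
      "2": 0.05,
      "3": 0,
      "4": -0.02,
      "5": -0.05
    }
  },
  "seasonal_amplitude": {
    "bp": 0.1,
    "smoking": 0.1
  },
  "seasonal_phase": {
    "bp": 10,
    "smoking": 10
  },
  "annual_trend": 0.02,
  "disruption": {
    "bp": {
      "depth": 1,
      "onset": "2020-03-01",
      "half_life": 12,
      "offset": 0
    },
    "smoking": {
      "depth": 1,
      "onset": "2020-03-01",
      "half_life": 12,
      "offset": 0
    }
  },
  "dispersion_phi": 1.5,
  "dup_prob": 0.02,
  "valueless_prob": 0.03,
  "contaminant_probs": {
    "under18": 0.05,
    "unknown_sex": 0.002,
    "missing_area": 0.01
  },
  "death_hazard": {
    "18-39": 4e-05,
    "40-59": 0.0002,
    "60-79": 0.0012,
    "80+": 0.008
  },
  "seed": 42
}
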