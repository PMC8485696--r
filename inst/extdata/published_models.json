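{
  "schema_version": 1,
  "comment": "Best interval/region logistic models reported for each classification pair, with printed coefficients where available; reference metrics are the reported bootstrap/validation scores on the original (non-public) cohort and are metadata only.",
  "models": {
    "ST_SF": {
      "description": "short note, unknown sign (ST vs SF)",
      "interval_ms": [105, 330],
      "coefficients": {
        "(Intercept)": -3.23286,
        "R.BA.46": 0.08884,
        "R.BA.04": 0.05689,
        "R.BA.36": 0.06321,
        "L.BA.33": 0.02682,
        "L.BA.02": 0.07420
      },
      "reference_metrics": {
        "bootstrap_accuracy": 0.70,
        "validation_accuracy": 0.79,
        "validation_precision": 0.78,
        "validation_recall": 0.81,
        "validation_f1": 0.79
      }
    },
    "TT_FF": {
      "description": "short note, known sign (TT vs FF)",
      "interval_ms": [330, 530],
      "coefficients": {
        "(Intercept)": -2.82279,
        "R.BA.39": 0.09693,
        "L.BA.37": 0.03943,
        "L.BA.25": 0.06532,
        "R.BA.31": -0.02018
      },
      "reference_metrics": {
        "bootstrap_accuracy": 0.71,
        "validation_accuracy": 0.70,
        "validation_precision": 0.69,
        "validation_recall": 0.74,
        "validation_f1": 0.71
      }
    },
    "LT_LF": {
      "description": "long note, unknown sign, entire population (LT vs LF)",
      "interval_ms": [830, 855],
      "coefficients": {
        "(Intercept)": 0.4133,
        "L.BA.31": 0.4360,
        "L.BA.44": -0.3214,
        "R.Hippocampus": -0.2790,
        "L.BA.09": 0.4657,
        "R.BA.08": -0.4305
      },
      "reference_metrics": {
        "bootstrap_accuracy": 0.70,
        "validation_accuracy": 0.74,
        "validation_precision": 0.67,
        "validation_recall": 0.78,
        "validation_f1": 0.72
      }
    },
    "LT_LF_long_preferred": {
      "description": "long note, unknown sign, participants preferring long notes (LC/SC ratio above the mean)",
      "interval_ms": [800, 875],
      "regions": ["L.BA.40", "R.BA.04", "R.BA.09"],
      "coefficients": null,
      "reference_metrics": {
        "bootstrap_accuracy": 0.71,
        "validation_accuracy": 0.73,
        "validation_precision": 0.70,
        "validation_recall": 0.70,
        "validation_f1": 0.70
      }
    }
  }
}
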