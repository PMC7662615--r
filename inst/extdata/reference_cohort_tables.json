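{
  "loss_groups": {
    "states": ["I", "II", "III", "IV", "V"],
    "counts": [1221, 163, 28, 4, 2]
  },
  "gender": {
    "states": ["Women", "Men"],
    "counts": [185, 1233]
  },
  "age_groups": {
    "states": ["<29", "29-34", "35-39", "40-48", ">=49"],
    "counts": [273, 276, 269, 303, 297],
    "freq_pct": [19, 20, 19, 21, 21],
    "age_min": [17, 29, 35, 40, 49],
    "age_max": [28, 34, 39, 48, 66]
  },
  "family_history": {
    "states": ["No", "Yes"],
    "counts": [1239, 179]
  },
  "initial_pct": [89.04, 9.89, 1.01, 0.06, 0],
  "loss_by_gender": {
    "by": "gender",
    "rows": [
      {
        "gender": "Women",
        "pct": [96.08, 3.74, 0.18, 0, 0]
      },
      {
        "gender": "Men",
        "pct": [87.95, 10.84, 1.14, 0.07, 0]
      }
    ]
  },
  "loss_by_age": {
    "by": "age_group",
    "rows": [
      {
        "age_group": "<29",
        "pct": [95.97, 3.86, 0, 0.17, 0]
      },
      {
        "age_group": "29-34",
        "pct": [95.25, 4.52, 0.23, 0, 0]
      },
      {
        "age_group": "35-39",
        "pct": [93.75, 6.22, 0.03, 0, 0]
      },
      {
        "age_group": "40-48",
        "pct": [85.93, 12.93, 1.12, 0.02, 0]
      },
      {
        "age_group": ">=49",
        "pct": [74.83, 21.38, 3.67, 0.12, 0]
      }
    ]
  },
  "loss_by_family_history": {
    "by": "family_history",
    "rows": [
      {
        "family_history": "No",
        "pct": [89.26, 9.65, 1.03, 0.06, 0]
      },
      {
        "family_history": "Yes",
        "pct": [87.25, 11.87, 0.84, 0.04, 0]
      }
    ]
  },
  "loss_by_gender_age": {
    "by": ["gender", "age_group"],
    "rows": [
      {
        "gender": "Women",
        "age_group": "<29",
        "pct": [98.01, 1.99, 0, 0, 0]
      },
      {
        "gender": "Women",
        "age_group": "29-34",
        "pct": [97.46, 2.15, 0.38, 0, 0.01]
      },
      {
        "gender": "Women",
        "age_group": "35-39",
        "pct": [97.84, 2.16, 0, 0, 0]
      },
      {
        "gender": "Women",
        "age_group": "40-48",
        "pct": [93.15, 6.56, 0.29, 0, 0]
      },
      {
        "gender": "Women",
        "age_group": ">=49",
        "pct": [90.47, 9.27, 0.25, 0.01, 0]
      },
      {
        "gender": "Men",
        "age_group": "<29",
        "pct": [95.69, 4.11, 0, 0.19, 0]
      },
      {
        "gender": "Men",
        "age_group": "29-34",
        "pct": [94.8, 5.01, 0.2, 0, 0]
      },
      {
        "gender": "Men",
        "age_group": "35-39",
        "pct": [92.68, 7.29, 0.04, 0, 0]
      },
      {
        "gender": "Men",
        "age_group": "40-48",
        "pct": [85.13, 13.64, 1.21, 0.02, 0]
      },
      {
        "gender": "Men",
        "age_group": ">=49",
        "pct": [73.42, 22.47, 3.98, 0.13, 0]
      }
    ]
  },
  "loss_by_gender_family_history": {
    "by": ["gender", "family_history"],
    "rows": [
      {
        "gender": "Women",
        "family_history": "No",
        "pct": [96.17, 3.65, 0.18, 0, 0]
      },
      {
        "gender": "Women",
        "family_history": "Yes",
        "pct": [94.86, 4.98, 0.12, 0, 0.03]
      },
      {
        "gender": "Men",
        "family_history": "No",
        "pct": [88.14, 10.62, 1.17, 0.07, 0]
      },
      {
        "gender": "Men",
        "family_history": "Yes",
        "pct": [86.52, 12.53, 0.91, 0.04, 0]
      }
    ]
  },
  "loss_by_age_family_history": {
    "by": ["age_group", "family_history"],
    "rows": [
      {
        "age_group": "<29",
        "family_history": "No",
        "pct": [96.04, 3.78, 0, 0.19, 0]
      },
      {
        "age_group": "<29",
        "family_history": "Yes",
        "pct": [95.19, 4.81, 0, 0, 0]
      },
      {
        "age_group": "29-34",
        "family_history": "No",
        "pct": [95.38, 4.38, 0.24, 0, 0]
      },
      {
        "age_group": "29-34",
        "family_history": "Yes",
        "pct": [93.99, 5.85, 0.14, 0, 0.02]
      },
      {
        "age_group": "35-39",
        "family_history": "No",
        "pct": [93.82, 6.15, 0.03, 0, 0]
      },
      {
        "age_group": "35-39",
        "family_history": "Yes",
        "pct": [93.15, 6.81, 0.04, 0, 0]
      },
      {
        "age_group": "40-48",
        "family_history": "No",
        "pct": [85.95, 12.92, 1.11, 0.02, 0]
      },
      {
        "age_group": "40-48",
        "family_history": "Yes",
        "pct": [85.82, 13.03, 1.13, 0.02, 0]
      },
      {
        "age_group": ">=49",
        "family_history": "No",
        "pct": [75.04, 20.98, 3.87, 0.12, 0]
      },
      {
        "age_group": ">=49",
        "family_history": "Yes",
        "pct": [73.31, 24.27, 2.28, 0.14, 0]
      }
    ]
  },
  "loss_by_family_history_gender_age": {
    "by": ["family_history", "gender", "age_group"],
    "rows": [
      {
        "family_history": "No",
        "gender": "Women",
        "age_group": "<29",
        "pct": [98.04, 1.96, 0, 0, 0]
      },
      {
        "family_history": "No",
        "gender": "Women",
        "age_group": "29-34",
        "pct": [97.48, 2.13, 0.39, 0, 0]
      },
      {
        "family_history": "No",
        "gender": "Women",
        "age_group": "35-39",
        "pct": [97.92, 2.08, 0, 0, 0]
      },
      {
        "family_history": "No",
        "gender": "Women",
        "age_group": "40-48",
        "pct": [93.22, 6.47, 0.31, 0, 0]
      },
      {
        "family_history": "No",
        "gender": "Women",
        "age_group": ">=49",
        "pct": [90.56, 9.18, 0.25, 0.01, 0]
      },
      {
        "family_history": "No",
        "gender": "Men",
        "age_group": "<29",
        "pct": [95.76, 4.03, 0, 0.21, 0]
      },
      {
        "family_history": "No",
        "gender": "Men",
        "age_group": "29-34",
        "pct": [94.93, 4.86, 0.21, 0, 0]
      },
      {
        "family_history": "No",
        "gender": "Men",
        "age_group": "35-39",
        "pct": [92.7, 7.27, 0.04, 0, 0]
      },
      {
        "family_history": "No",
        "gender": "Men",
        "age_group": "40-48",
        "pct": [85.1, 13.67, 1.21, 0.02, 0]
      },
      {
        "family_history": "No",
        "gender": "Men",
        "age_group": ">=49",
        "pct": [73.58, 22.09, 4.21, 0.13, 0]
      },
      {
        "family_history": "Yes",
        "gender": "Women",
        "age_group": "<29",
        "pct": [97.35, 2.65, 0, 0, 0]
      },
      {
        "family_history": "Yes",
        "gender": "Women",
        "age_group": "29-34",
        "pct": [97.14, 2.39, 0.31, 0, 0.16]
      },
      {
        "family_history": "Yes",
        "gender": "Women",
        "age_group": "35-39",
        "pct": [96.78, 3.22, 0, 0, 0]
      },
      {
        "family_history": "Yes",
        "gender": "Women",
        "age_group": "40-48",
        "pct": [92.48, 7.43, 0.09, 0, 0]
      },
      {
        "family_history": "Yes",
        "gender": "Women",
        "age_group": ">=49",
        "pct": [89.49, 10.23, 0.25, 0.03, 0]
      },
      {
        "family_history": "Yes",
        "gender": "Men",
        "age_group": "<29",
        "pct": [95.03, 4.97, 0, 0, 0]
      },
      {
        "family_history": "Yes",
        "gender": "Men",
        "age_group": "29-34",
        "pct": [93.62, 6.26, 0.12, 0, 0]
      },
      {
        "family_history": "Yes",
        "gender": "Men",
        "age_group": "35-39",
        "pct": [92.52, 7.42, 0.05, 0, 0]
      },
      {
        "family_history": "Yes",
        "gender": "Men",
        "age_group": "40-48",
        "pct": [85.31, 13.46, 1.21, 0.02, 0]
      },
      {
        "family_history": "Yes",
        "gender": "Men",
        "age_group": ">=49",
        "pct": [72.29, 25.15, 2.41, 0.14, 0]
      }
    ]
  }
}
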