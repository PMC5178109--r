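{
  "version": "1.0",
  "comment": "Default VIPE threshold tables. Bands are inclusive integer intervals [lo, hi]; null means unbounded. Measured values are rounded half away from zero before lookup. Overlapping bands are resolved to the higher (worse) sub-score and flagged at load time.",
  "strata": [
    {"id": "NB_2MO", "label": "Newborn to 2 months", "lower_days": 0, "upper_days": 90},
    {"id": "3_11MO", "label": "3 to 11 months", "lower_days": 91, "upper_days": 364},
    {"id": "1_4Y", "label": "1 to 4 years", "lower_days": 365, "upper_days": 1825},
    {"id": "5_12Y", "label": "5 to 12 years", "lower_days": 1826, "upper_days": 4748},
    {"id": "GT_12Y", "label": "Over 12 years", "lower_days": 4749, "upper_days": null}
  ],
  "bands": {
    "NB_2MO": {
      "RR": [[null, 15, 4], [16, 19, 2], [20, 29, 1], [30, 60, 0], [61, 80, 2], [81, 90, 3], [91, null, 4]],
      "HR": [[null, 80, 4], [81, 90, 2], [91, 110, 1], [111, 149, 0], [150, 179, 2], [180, 189, 3], [190, null, 4]],
      "SPO2": [[null, 89, 4], [90, 92, 2], [93, 94, 1], [95, 100, 0]]
    },
    "3_11MO": {
      "RR": [[null, 15, 4], [16, 19, 2], [20, 24, 1], [25, 50, 0], [51, 70, 2], [71, 80, 3], [81, null, 4]],
      "HR": [[null, 70, 4], [71, 80, 2], [81, 100, 1], [101, 139, 0], [140, 169, 2], [170, 179, 3], [180, null, 4]],
      "SPO2": [[null, 89, 4], [90, 92, 2], [93, 94, 1], [95, 100, 0]]
    },
    "1_4Y": {
      "RR": [[null, 12, 4], [13, 15, 2], [16, 19, 1], [20, 40, 0], [41, 60, 2], [61, 70, 3], [71, null, 4]],
      "HR": [[null, 60, 4], [61, 70, 2], [71, 90, 1], [91, 119, 0], [120, 149, 2], [150, 169, 3], [170, null, 4]],
      "SPO2": [[null, 89, 4], [90, 92, 2], [93, 94, 1], [95, 100, 0]]
    },
    "5_12Y": {
      "RR": [[null, 10, 4], [11, 14, 2], [15, 17, 1], [18, 24, 0], [25, 36, 2], [37, 50, 3], [51, null, 4]],
      "HR": [[null, 50, 4], [50, 60, 2], [61, 70, 1], [71, 109, 0], [110, 129, 2], [130, 149, 3], [150, null, 4]],
      "SPO2": [[null, 89, 4], [90, 92, 2], [93, 94, 1], [95, 100, 0]]
    },
    "GT_12Y": {
      "RR": [[null, 9, 4], [10, 10, 2], [11, 11, 1], [12, 16, 0], [17, 22, 2], [23, 29, 3], [30, null, 4]],
      "HR": [[null, 40, 4], [41, 50, 2], [51, 60, 1], [61, 99, 0], [100, 119, 2], [120, 139, 3], [140, null, 4]],
      "SPO2": [[null, 89, 4], [90, 92, 2], [93, 94, 1], [95, 100, 0]]
    }
  },
  "temp_correction": {
    "hr_score_min": 2,
    "minus1_lo": 37.5,
    "minus2_excl_lo": 38.5
  },
  "color_map": [
    {"lo": 0, "hi": 0, "level": "BLUE"},
    {"lo": 1, "hi": 2, "level": "GREEN"},
    {"lo": 3, "hi": 5, "level": "YELLOW"},
    {"lo": 6, "hi": 9, "level": "ORANGE"},
    {"lo": 10, "hi": 12, "level": "RED"}
  ],
  "policy": {
    "RED":    {"max_wait_minutes": 0,   "destination": "resuscitation_room"},
    "ORANGE": {"max_wait_minutes": 10,  "destination": "observation_room"},
    "YELLOW": {"max_wait_minutes": 30,  "destination": "waiting_room"},
    "GREEN":  {"max_wait_minutes": 90,  "destination": "waiting_room"},
    "BLUE":   {"max_wait_minutes": 180, "destination": "waiting_room"}
  }
}
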