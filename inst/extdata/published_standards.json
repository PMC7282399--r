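{
  "source": "published standards table (pooled normative cohort, n = 1181)",
  "centile_columns": ["c3", "c10", "c25", "c50", "c75", "c90", "c97"],
  "domains": [
    {"domain": "cognitive",          "direction": "higher_is_better",
     "c3": 27.4, "c10": 38.5, "c25": 62.2, "c50": 79.5, "c75": 88.8, "c90": 92.6, "c97": 99.6},
    {"domain": "fine_motor",         "direction": "higher_is_better",
     "c3": 17.5, "c10": 25.7, "c25": 74.2, "c50": 91.4, "c75": 100.0, "c90": 100.0, "c97": 100.0},
    {"domain": "gross_motor",        "direction": "higher_is_better",
     "c3": 31.1, "c10": 51.7, "c25": 66.7, "c50": 81.6, "c75": 100.0, "c90": 100.0, "c97": 100.0},
    {"domain": "language",           "direction": "higher_is_better",
     "c3": 12.1, "c10": 17.8, "c25": 45.7, "c50": 71.7, "c75": 88.5, "c90": 95.1, "c97": 100.0},
    {"domain": "positive_behaviour", "direction": "higher_is_better",
     "c3": 37.8, "c10": 51.4, "c25": 70.0, "c50": 90.0, "c75": 100.0, "c90": 100.0, "c97": 100.0},
    {"domain": "negative_behaviour", "direction": "lower_is_better",
     "c3": 0.0, "c10": 0.0, "c25": 0.0, "c50": 25.0, "c75": 25.0, "c90": 50.0, "c97": 76.5}
  ]
}
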