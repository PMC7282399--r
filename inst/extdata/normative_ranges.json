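{
  "vision_norms": [
    {"measure": "acuity_logmar", "lower": 0.0, "upper": 0.6,
     "source": "editable default range for binocular Cardiff-card acuity at 24-30 months (synthetic placeholder bounds; replace with the test's published norms)"},
    {"measure": "contrast_percent", "lower": 0.5, "upper": 3.0,
     "source": "editable default range for Cardiff contrast sensitivity at 24-30 months (synthetic placeholder bounds; replace with the test's published norms)"}
  ],
  "milestone_windows": [
    {"milestone": "sitting_without_support",   "lower": 3.8, "upper": 9.2},
    {"milestone": "standing_with_assistance",  "lower": 4.8, "upper": 11.4},
    {"milestone": "hands_and_knees_crawling",  "lower": 5.2, "upper": 13.5},
    {"milestone": "walking_with_assistance",   "lower": 5.9, "upper": 13.7},
    {"milestone": "standing_alone",            "lower": 6.9, "upper": 16.9},
    {"milestone": "walking_alone",             "lower": 8.2, "upper": 17.6}
  ],
  "milestone_source": "WHO Multicentre Growth Reference Study windows of achievement for six gross motor milestones (months)"
}
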