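{
  "name": "RTOG 0915 peripheral lung SBRT dosimetric compliance criteria",
  "notes": "Volume-dependent R50% and D2cm bands are piecewise-linear in PTV volume through the anchor rows below (clamped outside the anchor range). Anchors are the published per-patient (PTV volume, minor-deviation band) pairs of a 20-patient peripheral lung SBRT cohort; the duplicate 20.1 cc volume carried two printed D2cm lower bounds (53.0 / 53.1) and is stored as their mean. OAR limits are single thresholds: values above the limit are deviations.",
  "r100_band": { "lower": 1.2, "upper": 1.5 },
  "v20_band": { "lower": 10.0, "upper": 15.0 },
  "r50_anchors": [
    { "ptv_cc": 11.1, "lower": 5.0, "upper": 5.9 },
    { "ptv_cc": 12.9, "lower": 4.7, "upper": 5.8 },
    { "ptv_cc": 15.0, "lower": 4.7, "upper": 5.7 },
    { "ptv_cc": 20.1, "lower": 4.6, "upper": 5.7 },
    { "ptv_cc": 21.0, "lower": 4.5, "upper": 5.5 },
    { "ptv_cc": 26.3, "lower": 4.4, "upper": 5.4 },
    { "ptv_cc": 27.1, "lower": 4.5, "upper": 5.4 },
    { "ptv_cc": 31.2, "lower": 4.3, "upper": 5.3 },
    { "ptv_cc": 36.2, "lower": 4.3, "upper": 5.3 },
    { "ptv_cc": 37.1, "lower": 4.2, "upper": 5.2 },
    { "ptv_cc": 39.7, "lower": 4.2, "upper": 5.2 },
    { "ptv_cc": 39.8, "lower": 4.2, "upper": 5.2 },
    { "ptv_cc": 50.9, "lower": 4.0, "upper": 5.0 },
    { "ptv_cc": 53.4, "lower": 3.9, "upper": 5.0 },
    { "ptv_cc": 56.5, "lower": 3.8, "upper": 4.9 },
    { "ptv_cc": 61.5, "lower": 3.7, "upper": 4.9 },
    { "ptv_cc": 68.1, "lower": 3.6, "upper": 4.8 },
    { "ptv_cc": 132.0, "lower": 3.1, "upper": 3.9 },
    { "ptv_cc": 163.0, "lower": 2.9, "upper": 3.7 }
  ],
  "d2cm_anchors": [
    { "ptv_cc": 11.1, "lower": 50.0, "upper": 58.0 },
    { "ptv_cc": 12.9, "lower": 50.0, "upper": 58.0 },
    { "ptv_cc": 15.0, "lower": 50.9, "upper": 59.1 },
    { "ptv_cc": 20.1, "lower": 53.05, "upper": 61.9 },
    { "ptv_cc": 21.0, "lower": 53.6, "upper": 62.4 },
    { "ptv_cc": 26.3, "lower": 55.3, "upper": 64.7 },
    { "ptv_cc": 27.1, "lower": 55.7, "upper": 65.0 },
    { "ptv_cc": 31.2, "lower": 57.0, "upper": 66.8 },
    { "ptv_cc": 36.2, "lower": 58.5, "upper": 69.1 },
    { "ptv_cc": 37.1, "lower": 58.8, "upper": 69.7 },
    { "ptv_cc": 39.7, "lower": 59.3, "upper": 70.8 },
    { "ptv_cc": 39.8, "lower": 59.3, "upper": 70.8 },
    { "ptv_cc": 50.9, "lower": 62.2, "upper": 77.5 },
    { "ptv_cc": 53.4, "lower": 62.6, "upper": 78.4 },
    { "ptv_cc": 56.5, "lower": 63.4, "upper": 80.2 },
    { "ptv_cc": 61.5, "lower": 64.4, "upper": 82.4 },
    { "ptv_cc": 68.1, "lower": 65.6, "upper": 85.1 },
    { "ptv_cc": 132.0, "lower": 73.7, "upper": 91.5 },
    { "ptv_cc": 163.0, "lower": 77.0, "upper": 94.0 }
  ],
  "oar_limits": {
    "cord_d035cc_gy": 20.8,
    "esophagus_d5cc_gy": 18.8,
    "heart_d15cc_gy": 28.0,
    "lung_d1000cc_gy": 12.8
  }
}
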