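{
  "format": "comma-separated UTF-8 text with a header row; missing values are empty cells; all category labels are lower-case snake tokens",
  "development_table": {
    "unit": "one row per development study x model (x outcome when a study reports AUCs for several outcomes); study-level columns repeat across the rows of a study",
    "columns": {
      "study_id": {"type": "text", "required": true},
      "model_id": {"type": "text", "required": true, "note": "models with different predictor sets are distinct ids; the same predictors for a different outcome share an id"},
      "design": {"type": "category", "required": true, "levels": ["cohort", "trial", "pooled"]},
      "outcome": {"type": "category", "required": false, "levels": ["mortality", "unfavorable"]},
      "dev_auc": {"type": "real in (0,1)", "required": false, "note": "development AUC for this model and outcome; must exceed 0.5 to enter dAUC computation"},
      "app_participants": {"type": "category", "required": true, "levels": ["L", "H", "U"]},
      "app_predictors": {"type": "category", "required": true, "levels": ["L", "H", "U"]},
      "app_outcome": {"type": "category", "required": true, "levels": ["L", "H", "U"]},
      "rob_participants": {"type": "category", "required": true, "levels": ["L", "H", "U"]},
      "rob_predictors": {"type": "category", "required": true, "levels": ["L", "H", "U"]},
      "rob_outcome": {"type": "category", "required": true, "levels": ["L", "H", "U"]},
      "rob_analysis": {"type": "category", "required": true, "levels": ["L", "H", "U"]},
      "usable_research": {"type": "boolean", "required": true},
      "usable_practice": {"type": "boolean", "required": true},
      "events_smallest_group": {"type": "nonnegative integer", "required": false},
      "total_df": {"type": "positive integer", "required": false},
      "overall_rob": {"type": "category", "required": false, "levels": ["L", "H", "U"], "note": "derived; recomputed mechanically from the four rob_* domains"},
      "overall_applicability": {"type": "category", "required": false, "levels": ["L", "H", "U"], "note": "derived; recomputed from the three app_* domains"}
    }
  },
  "validation_table": {
    "unit": "one row per (validation publication x model x outcome); distinct validation_ids count as unique validations",
    "columns": {
      "validation_id": {"type": "text", "required": true},
      "model_id": {"type": "text", "required": true, "note": "must refer to a model_id in the development table"},
      "publication_id": {"type": "text", "required": false},
      "design": {"type": "category", "required": true, "levels": ["cohort", "trial"]},
      "setting_match": {"type": "boolean", "required": true, "note": "validation meets the development study's setting; resolve 'not specified' to false upstream"},
      "inclusion_match": {"type": "boolean", "required": true},
      "outcome_match": {"type": "boolean", "required": true},
      "n": {"type": "positive integer", "required": false},
      "auc": {"type": "real in (0,1)", "required": true},
      "cal_intercept": {"type": "real", "required": false, "note": "carried as metadata only; no calibration synthesis"},
      "cal_slope": {"type": "real", "required": false, "note": "carried as metadata only"},
      "outcome": {"type": "category", "required": false, "levels": ["mortality", "unfavorable"]},
      "relatedness": {"type": "category", "required": false, "levels": ["related", "moderately", "distantly"], "note": "derived"},
      "design_similarity": {"type": "category", "required": false, "levels": ["similar", "cohort_to_trial", "trial_to_cohort"], "note": "derived"},
      "dauc_abs": {"type": "real", "required": false, "note": "derived"},
      "dauc_pct": {"type": "real percent", "required": false, "note": "derived"}
    }
  }
}
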