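# Builders for small in-memory evidence tables used across the suite.

make_dev_table <- function(n_models = 3L,
                           rob_analysis = rep("L", n_models),
                           dev_auc = rep(0.80, n_models),
                           design = rep("cohort", n_models),
                           outcome = rep("mortality", n_models)) {
  data.frame(
    study_id = sprintf("s%02d", seq_len(n_models)),
    model_id = sprintf("m%02d", seq_len(n_models)),
    design = design,
    outcome = outcome,
    dev_auc = dev_auc,
    app_participants = "L", app_predictors = "L", app_outcome = "L",
    rob_participants = "L", rob_predictors = "L", rob_outcome = "L",
    rob_analysis = rob_analysis,
    usable_research = TRUE, usable_practice = TRUE,
    stringsAsFactors = FALSE
  )
}

make_val_table <- function(model_id, auc,
                           design = rep("cohort", length(model_id)),
                           outcome = rep("mortality", length(model_id)),
                           setting = TRUE, inclusion = TRUE, outc = TRUE) {
  n <- length(model_id)
  data.frame(
    validation_id = sprintf("v%03d", seq_len(n)),
    model_id = model_id,
    publication_id = sprintf("p%03d", seq_len(n)),
    design = design,
    setting_match = rep_len(setting, n),
    inclusion_match = rep_len(inclusion, n),
    outcome_match = rep_len(outc, n),
    n = 500L,
    auc = auc,
    cal_intercept = NA_real_,
    cal_slope = NA_real_,
    outcome = outcome,
    stringsAsFactors = FALSE
  )
}

# Minimal derived-record table for the meta-regression and summaries.
make_derived_records <- function(n, dauc_pct, overall_rob = rep("L", n),
                                 design_similarity = rep("similar", n),
                                 model_id = sprintf("m%02d", seq_len(n)),
                                 dev_auc = rep(0.8, n),
                                 auc = NULL) {
  if (is.null(auc)) auc <- pmin(pmax(dev_auc + dauc_pct / 100 *
                                       (dev_auc - 0.5), 0.01), 0.99)
  data.frame(validation_id = sprintf("v%03d", seq_len(n)),
             model_id = model_id, overall_rob = overall_rob,
             design_similarity = design_similarity,
             dev_auc = dev_auc, auc = auc,
             dauc_abs = auc - dev_auc, dauc_pct = dauc_pct,
             stringsAsFactors = FALSE)
}
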