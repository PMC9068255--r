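test_that("binormal AUC follows the closed-form identity", {
  expect_equal(binormal_auc(0), 0.5)
  d <- seq(0, 5, by = 0.5)
  expect_true(all(diff(binormal_auc(d)) > 0))
  expect_gt(binormal_auc(6), 0.999)
  expect_equal(auc_to_delta(binormal_auc(1.3)), 1.3, tolerance = 1e-12)
})

test_that("binormal AUC agrees with Monte-Carlo pair estimation to 3 decimals", {
  set.seed(90)
  for (delta in c(0.5, 1.1, 2.0)) {
    pos <- rnorm(1e6, delta)
    neg <- rnorm(1e6)
    expect_equal(empirical_auc(pos, neg), binormal_auc(delta),
                 tolerance = 1.5e-3)
  }
})

test_that("empirical AUC equals the exhaustive pair-counting oracle", {
  pair_count_auc <- function(pos, neg) {
    tot <- 0
    for (p in pos) for (q in neg) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
    tot / (length(pos) * length(neg))
  }
  expect_equal(empirical_auc(c(2, 3), 1), 1)
  expect_equal(empirical_auc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(empirical_auc(c(1, 2, 3), 2), 0.5)  # (0 + 0.5 + 1)/3
  set.seed(91)
  for (rep in 1:40) {
    np <- sample(1:15, 1)
    nn <- sample(1:15, 1)
    # ties arise from the rounding
    pos <- round(rnorm(np, 0.5), 1)
    neg <- round(rnorm(nn), 1)
    expect_equal(empirical_auc(pos, neg), pair_count_auc(pos, neg))
  }
  expect_error(empirical_auc(numeric(), 1), "nonempty")
})

test_that("configuration is validated and the seed is mandatory", {
  expect_error(simulation_config(), "seed")
  expect_error(simulation_config(rob_probs = c(L = 0.5, H = 0.5, U = 0.5),
                                 seed = 1), "summing to 1")
  expect_error(simulation_config(true_auc_range = c(0.90, 0.99),
                                 optimism_by_rob = c(L = 0, H = 0.05, U = 0),
                                 seed = 1), "headroom")
  cfg <- simulation_config(seed = 7)
  expect_s3_class(cfg, "sim_config")
  expect_equal(length(cfg$validations_per_model), cfg$n_models)
})

test_that("generation is byte-identical for a fixed config and seed", {
  cfg <- simulation_config(n_models = 6, validations_per_model = 4,
                           seed = 314)
  a <- generate_evidence_base(cfg)
  b <- generate_evidence_base(cfg)
  expect_identical(a, b)
  t1 <- tempfile(fileext = ".csv")
  t2 <- tempfile(fileext = ".csv")
  write_report(a$validations, t1, "csv")
  write_report(b$validations, t2, "csv")
  expect_identical(readLines(t1), readLines(t2))
  unlink(c(t1, t2))
})

test_that("adding validations never perturbs model-level draws", {
  base <- generate_evidence_base(simulation_config(
    n_models = 6, validations_per_model = 3, seed = 555))
  more <- generate_evidence_base(simulation_config(
    n_models = 6, validations_per_model = 9, seed = 555))
  expect_identical(base$truth$models, more$truth$models)
  expect_identical(base$studies, more$studies)
})

test_that("emitted tables pass schema validation and judgments encode the class", {
  eb <- generate_evidence_base(simulation_config(n_models = 8, seed = 99))
  expect_silent(validate_dev_table(eb$studies))
  expect_silent(validate_val_table(eb$validations))
  # the PROBAST rollup over emitted domains reproduces the generative class
  studies <- assess_overall(eb$studies)
  per_model <- setNames(studies$overall_rob, studies$model_id)
  expect_identical(unname(per_model[eb$truth$models$model_id]),
                   eb$truth$models$rob)
  # and the signaling answers reproduce the domain judgments
  for (s in unique(eb$answers$study_id)) {
    ans <- signaling_answers(
      eb$answers$question_id[eb$answers$study_id == s],
      eb$answers$answer[eb$answers$study_id == s])
    analysis <- judge_domain(ans[ans$domain == "analysis", ])
    expect_identical(analysis$judgment,
                     studies$rob_analysis[studies$study_id == s][1])
  }
})

test_that("a null configuration yields mean dAUC near zero", {
  cfg <- simulation_config(n_models = 12, validations_per_model = 6,
                           true_auc_range = c(0.75, 0.75),
                           optimism_by_rob = c(L = 0, H = 0, U = 0),
                           dev_noise_sd = 0,
                           casemix_shift = c(similar = 0,
                                             cohort_to_trial = 0,
                                             trial_to_cohort = 0),
                           within_model_sd = 0,
                           n_pos = 2000, n_neg = 2000, seed = 2024)
  eb <- generate_evidence_base(cfg)
  d <- derive_validation_fields(eb$studies, eb$validations)
  expect_equal(mean(d$records$dauc_pct), 0, tolerance = 1.5)
})

test_that("generative optimism maps onto the expected percent change", {
  # true AUC 0.80, high-risk optimism +0.06: dev AUC 0.86, so the expected
  # change is 100 * (0.30 - 0.36) / 0.36 = -16.7%
  cfg <- simulation_config(n_models = 10, validations_per_model = 20,
                           models_per_study = 1,
                           true_auc_range = c(0.80, 0.80),
                           rob_probs = c(L = 0, H = 1, U = 0),
                           optimism_by_rob = c(L = 0, H = 0.06, U = 0),
                           dev_noise_sd = 0,
                           casemix_shift = c(similar = 0,
                                             cohort_to_trial = 0,
                                             trial_to_cohort = 0),
                           within_model_sd = 0,
                           n_pos = 2000, n_neg = 2000, seed = 808)
  eb <- generate_evidence_base(cfg)
  d <- derive_validation_fields(eb$studies, eb$validations)
  expect_equal(mean(d$records$dauc_pct), 100 * (0.30 - 0.36) / 0.36,
               tolerance = 1.2)
})

test_that("the effect-level simulator produces the requested structure", {
  set.seed(11)
  truth <- c(intercept = 9, rob_high = -30, rob_unclear = -13,
             design_cohort_to_trial = -18, design_trial_to_cohort = 0)
  sim <- simulate_dauc_effects(50, 4, truth, sigma_u = 5, sigma_e = 10)
  expect_equal(length(sim$y), 200L)
  expect_equal(ncol(sim$X), 5L)
  expect_equal(length(unique(sim$clusters)), 50L)
  # cluster-level covariates are constant within cluster
  expect_true(all(tapply(sim$records$overall_rob, sim$records$model_id,
                         function(x) length(unique(x))) == 1L))
})
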