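# Seeded generator of synthetic evidence bases with the statistical
# structure the synthesis assumes: per-model true discrimination on a
# binormal score scale, risk-of-bias-driven optimism at development,
# case-mix shifts by design transition, and finite-sample noise in
# validation AUCs.

#' AUC of a unit-variance binormal score model
#'
#' With case scores N(delta, 1) and non-case scores N(0, 1), the AUC is
#' `pnorm(delta / sqrt(2))`.
#'
#' @param delta Nonnegative separation of the score means.
#' @return AUC in `[0.5, 1)`.
#' @export
binormal_auc <- function(delta) {
  stopifnot(is.numeric(delta), all(delta >= 0))
  pnorm(delta / sqrt(2))
}

#' Score-mean separation achieving a given binormal AUC
#'
#' Inverse of [binormal_auc()].
#'
#' @param auc AUC in `[0.5, 1)`.
#' @return Nonnegative delta.
#' @export
auc_to_delta <- function(auc) {
  stopifnot(is.numeric(auc), all(auc >= 0.5), all(auc < 1))
  sqrt(2) * qnorm(auc)
}

#' Empirical (Mann-Whitney) AUC
#'
#' Probability that a random case score exceeds a random non-case score,
#' with ties counted half. Computed via mid-ranks, which is exactly the
#' pairwise count.
#'
#' @param pos_scores Scores of cases (nonempty).
#' @param neg_scores Scores of non-cases (nonempty).
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' empirical_auc(c(2, 3), 1)        # 1
#' empirical_auc(c(1, 2, 3), 2)     # 0.5
empirical_auc <- function(pos_scores, neg_scores) {
  np <- as.numeric(length(pos_scores))
  nn <- as.numeric(length(neg_scores))
  if (np == 0 || nn == 0) {
    stop("both score classes must be nonempty")
  }
  r <- rank(c(pos_scores, neg_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Configuration of a synthetic evidence base
#'
#' Defaults mirror the size and mix of a moderate/severe-TBI prediction-model
#' evidence base: 18 models clustered in studies of up to two models, about
#' 245 validation records in total, risk-of-bias class frequencies of
#' roughly 20/60/20 (low/high/unclear), development optimism increasing with
#' risk of bias, a discrimination penalty for cohort-developed models
#' validated in trials, and relatedness-flag frequencies that put about two
#' thirds of validations in the distantly related class. All magnitudes are
#' scenario parameters of the generator, not estimates.
#'
#' @param n_models Number of prediction models.
#' @param models_per_study Models per development study (last study takes the
#'   remainder).
#' @param validations_per_model External validations per model (scalar or
#'   vector of length `n_models`).
#' @param true_auc_range Range of true validation-population AUCs.
#' @param rob_probs Named probabilities over `L`, `H`, `U` for a study's
#'   overall risk of bias.
#' @param optimism_by_rob Named AUC inflation at development per class.
#' @param dev_noise_sd SD of development-AUC reporting noise.
#' @param casemix_shift Named AUC shift per design transition.
#' @param within_model_sd SD of AUC-scale heterogeneity between validations
#'   of one model.
#' @param n_pos,n_neg Cases and non-cases per validation cohort.
#' @param p_dev_trial,p_val_trial Probability a development study / a
#'   validation is a trial rather than a cohort.
#' @param p_setting_match,p_inclusion_match,p_outcome_match Probabilities the
#'   relatedness-rubric domains are met.
#' @param seed Mandatory integer master seed.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(n_models = 18L,
                              models_per_study = 2L,
                              validations_per_model = 14L,
                              true_auc_range = c(0.65, 0.85),
                              rob_probs = c(L = 0.2, H = 0.6, U = 0.2),
                              optimism_by_rob = c(L = -0.02, H = 0.06,
                                                  U = 0.015),
                              dev_noise_sd = 0.01,
                              casemix_shift = c(similar = 0,
                                                cohort_to_trial = -0.03,
                                                trial_to_cohort = 0.005),
                              within_model_sd = 0.02,
                              n_pos = 150L, n_neg = 350L,
                              p_dev_trial = 0.3, p_val_trial = 0.3,
                              p_setting_match = 0.42,
                              p_inclusion_match = 0.57,
                              p_outcome_match = 0.58,
                              seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  stopifnot(n_models >= 1L, models_per_study >= 1L,
            all(validations_per_model >= 1L),
            length(true_auc_range) == 2L,
            true_auc_range[1] > 0.5, true_auc_range[2] < 1,
            true_auc_range[1] <= true_auc_range[2],
            n_pos >= 2L, n_neg >= 2L,
            dev_noise_sd >= 0, within_model_sd >= 0)
  if (!setequal(names(rob_probs), .judgment_levels) ||
      abs(sum(rob_probs) - 1) > 1e-8) {
    stop("rob_probs must be named L/H/U probabilities summing to 1")
  }
  if (!setequal(names(optimism_by_rob), .judgment_levels)) {
    stop("optimism_by_rob must be named over L/H/U")
  }
  if (!setequal(names(casemix_shift), .similarity_levels)) {
    stop("casemix_shift must be named over ",
         paste(.similarity_levels, collapse = "/"))
  }
  hi <- max(true_auc_range[2] + max(optimism_by_rob), true_auc_range[2])
  if (hi >= 1) stop("true_auc_range plus optimism leaves no AUC headroom")
  structure(list(n_models = as.integer(n_models),
                 models_per_study = as.integer(models_per_study),
                 validations_per_model =
                   rep_len(as.integer(validations_per_model), n_models),
                 true_auc_range = true_auc_range,
                 rob_probs = rob_probs[.judgment_levels],
                 optimism_by_rob = optimism_by_rob[.judgment_levels],
                 dev_noise_sd = dev_noise_sd,
                 casemix_shift = casemix_shift[.similarity_levels],
                 within_model_sd = within_model_sd,
                 n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 p_dev_trial = p_dev_trial, p_val_trial = p_val_trial,
                 p_setting_match = p_setting_match,
                 p_inclusion_match = p_inclusion_match,
                 p_outcome_match = p_outcome_match,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.clamp_auc <- function(x) pmin(pmax(x, 0.51), 0.99)

#' Simulate percent-dAUC records with known regression effects
#'
#' Direct regression-level generator for parameter-recovery experiments:
#' risk-of-bias class is drawn per cluster (model), design transition per
#' record, and the percent change in discrimination is the linear predictor
#' under the named effects plus a cluster-level random intercept (SD
#' `sigma_u`) and record noise (SD `sigma_e`), giving an exchangeable
#' within-cluster correlation of `sigma_u^2 / (sigma_u^2 + sigma_e^2)`.
#' The caller controls the random stream via [set.seed()].
#'
#' @param n_clusters Number of model clusters.
#' @param cluster_size Validations per model.
#' @param beta Named true effects for `intercept`, `rob_high`,
#'   `rob_unclear`, `design_cohort_to_trial`, `design_trial_to_cohort`.
#' @param sigma_u,sigma_e Cluster and record noise SDs (percent scale).
#' @param rob_probs Probabilities over `L`, `H`, `U` for the cluster class.
#' @param design_probs Probabilities over the three design transitions.
#' @return A list: `y`, `X`, `clusters`, plus `records` in the derived
#'   validation schema (for [gee_dauc()]).
#' @export
simulate_dauc_effects <- function(n_clusters, cluster_size, beta,
                                  sigma_u = 5, sigma_e = 10,
                                  rob_probs = c(L = 0.4, H = 0.3, U = 0.3),
                                  design_probs = c(similar = 0.6,
                                                   cohort_to_trial = 0.2,
                                                   trial_to_cohort = 0.2)) {
  stopifnot(setequal(names(beta), .gee_terms))
  n <- n_clusters * cluster_size
  cl <- rep(seq_len(n_clusters), each = cluster_size)
  rob <- sample(.judgment_levels, n_clusters, replace = TRUE,
                prob = rob_probs[.judgment_levels])[cl]
  des <- sample(.similarity_levels, n, replace = TRUE,
                prob = design_probs[.similarity_levels])
  X <- cbind(intercept = 1,
             rob_high = as.numeric(rob == "H"),
             rob_unclear = as.numeric(rob == "U"),
             design_cohort_to_trial = as.numeric(des == "cohort_to_trial"),
             design_trial_to_cohort = as.numeric(des == "trial_to_cohort"))
  y <- drop(X %*% beta[.gee_terms]) + rnorm(n_clusters, sd = sigma_u)[cl] +
    rnorm(n, sd = sigma_e)
  records <- data.frame(validation_id = sprintf("v%05d", seq_len(n)),
                        model_id = sprintf("m%04d", cl),
                        overall_rob = rob, design_similarity = des,
                        dauc_pct = y, stringsAsFactors = FALSE)
  list(y = y, X = X, clusters = records$model_id, records = records)
}

# Signaling answers consistent with a study's risk-of-bias class: all yes for
# low risk; a "no" (high) or "no information" (unclear) on analysis item 4.1.
.answers_for_class <- function(study_id, rob, config = probast_config()) {
  ids <- names(config$question_catalogue)
  ans <- rep("Y", length(ids))
  if (rob == "H") ans[ids == "4.1"] <- "N"
  if (rob == "U") ans[ids == "4.1"] <- "NI"
  data.frame(study_id = study_id, question_id = ids, answer = ans,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic evidence base
#'
#' Model-level truth is drawn first, then each model's validation records
#' are generated from a per-model substream seeded up front, so increasing
#' `validations_per_model` never perturbs model-level draws. Development AUC
#' is the true AUC plus class-specific optimism plus reporting noise;
#' each validation AUC is the empirical Mann-Whitney AUC of binormal scores
#' drawn at the true AUC shifted by the design-transition case-mix effect and
#' within-model heterogeneity, truncated into `[0.51, 0.99]`. Risk-of-bias
#' classes are materialized as consistent domain judgments (and a signaling
#' answer table), so the PROBAST rollup reproduces them. Output is
#' byte-identical for a given `(config, seed)`.
#'
#' @param config A [simulation_config()].
#' @return A list: `studies` (development schema), `validations` (validation
#'   schema), `answers` (per-study signaling answers), `truth` (per-model and
#'   per-record generative values).
#' @export
generate_evidence_base <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nm <- config$n_models

  # study-level draws
  n_studies <- ceiling(nm / config$models_per_study)
  study_of_model <- rep(seq_len(n_studies),
                        each = config$models_per_study)[seq_len(nm)]
  study_ids <- sprintf("study%02d", seq_len(n_studies))
  study_rob <- sample(.judgment_levels, n_studies, replace = TRUE,
                      prob = config$rob_probs)
  study_design <- ifelse(runif(n_studies) < config$p_dev_trial,
                         "trial", "cohort")
  study_res <- runif(n_studies) < 0.4
  study_prac <- runif(n_studies) < 0.9

  # model-level draws
  model_ids <- sprintf("model%03d", seq_len(nm))
  true_auc <- runif(nm, config$true_auc_range[1], config$true_auc_range[2])
  outcome <- sample(.outcome_levels, nm, replace = TRUE)
  rob_m <- study_rob[study_of_model]
  dev_auc <- .clamp_auc(true_auc + config$optimism_by_rob[rob_m] +
                          rnorm(nm, 0, config$dev_noise_sd))
  record_seeds <- sample.int(.Machine$integer.max - 1L, nm)

  studies <- data.frame(
    study_id = study_ids[study_of_model],
    model_id = model_ids,
    design = study_design[study_of_model],
    outcome = outcome,
    dev_auc = round(dev_auc, 4),
    app_participants = "L", app_predictors = "L", app_outcome = "L",
    rob_participants = "L", rob_predictors = "L", rob_outcome = "L",
    rob_analysis = rob_m,
    usable_research = study_res[study_of_model],
    usable_practice = study_prac[study_of_model],
    stringsAsFactors = FALSE
  )
  answers <- do.call(rbind, lapply(seq_len(n_studies), function(s) {
    .answers_for_class(study_ids[s], study_rob[s])
  }))

  # record-level draws, one substream per model
  rec_list <- vector("list", nm)
  for (i in seq_len(nm)) {
    set.seed(record_seeds[i])
    nv <- config$validations_per_model[i]
    val_design <- ifelse(runif(nv) < config$p_val_trial, "trial", "cohort")
    transition <- design_similarity(studies$design[i], val_design)
    shift <- config$casemix_shift[transition] +
      rnorm(nv, 0, config$within_model_sd)
    auc_target <- .clamp_auc(true_auc[i] + shift)
    delta <- auc_to_delta(auc_target)
    val_auc <- vapply(seq_len(nv), function(v) {
      empirical_auc(rnorm(config$n_pos, delta[v], 1),
                    rnorm(config$n_neg, 0, 1))
    }, numeric(1))
    # empirical AUC can stray outside the schema's open interval at tiny n
    val_auc <- pmin(pmax(val_auc, 1 / (config$n_pos * config$n_neg)),
                    1 - 1 / (config$n_pos * config$n_neg))
    has_cal <- runif(nv) < 0.5
    rec_list[[i]] <- data.frame(
      validation_id = sprintf("%s_v%03d", model_ids[i], seq_len(nv)),
      model_id = model_ids[i],
      publication_id = sprintf("%s_pub%02d", model_ids[i],
                               ceiling(seq_len(nv) / 3)),
      design = val_design,
      setting_match = runif(nv) < config$p_setting_match,
      inclusion_match = runif(nv) < config$p_inclusion_match,
      outcome_match = runif(nv) < config$p_outcome_match,
      n = config$n_pos + config$n_neg,
      auc = round(val_auc, 4),
      cal_intercept = ifelse(has_cal, round(rnorm(nv, 0, 0.3), 3), NA_real_),
      cal_slope = ifelse(has_cal, round(rnorm(nv, 1, 0.2), 3), NA_real_),
      outcome = outcome[i],
      transition = transition,
      shift = shift,
      auc_target = auc_target,
      stringsAsFactors = FALSE
    )
  }
  records <- do.call(rbind, rec_list)
  rownames(records) <- NULL

  truth_models <- data.frame(
    model_id = model_ids, study_id = study_ids[study_of_model],
    rob = rob_m, true_auc = true_auc,
    optimism = unname(config$optimism_by_rob[rob_m]),
    dev_design = study_design[study_of_model], outcome = outcome,
    record_seed = record_seeds, stringsAsFactors = FALSE
  )
  truth_records <- records[, c("validation_id", "model_id", "transition",
                               "shift", "auc_target")]
  validations <- records[, setdiff(names(records),
                                   c("transition", "shift", "auc_target"))]

  studies <- validate_dev_table(studies)
  validations <- validate_val_table(validations)
  list(studies = studies, validations = validations, answers = answers,
       truth = list(models = truth_models, records = truth_records))
}
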