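# Pipeline stages chaining the modules, with run manifests recording
# provenance (input hashes, seed, per-stage counts, exclusions with
# reasons). A thin command-line shim over these functions ships in
# inst/cli/probastmeta.R.

#' Derive per-validation fields needed by the synthesis
#'
#' Joins each validation record to its development study/model, computes the
#' relatedness class, the design-similarity label, the development-study
#' overall risk of bias, and the absolute and percent change in
#' discrimination. dAUC pairs a validation AUC with the development AUC of
#' the same model and the same outcome; records that cannot be paired, or
#' whose development AUC is missing or at/below 0.5 (nonpositive
#' discrimination above chance), are excluded with a logged reason rather
#' than failing the pipeline.
#'
#' @param studies Development table (long schema); overall judgments are
#'   recomputed via [assess_overall()] if absent.
#' @param validations Validation table.
#' @return A list: `records` (derived validation records with `overall_rob`,
#'   `relatedness`, `design_similarity`, `dev_auc`, `dauc_abs`, `dauc_pct`)
#'   and `exclusions` (data frame of `validation_id`, `reason`).
#' @export
derive_validation_fields <- function(studies, validations) {
  studies <- validate_dev_table(studies)
  validations <- validate_val_table(validations)
  if (is.null(studies$overall_rob) || anyNA(studies$overall_rob)) {
    studies <- assess_overall(studies)
  }
  recs <- validations
  recs$relatedness <- if (nrow(recs)) {
    classify_relatedness(recs$setting_match, recs$inclusion_match,
                         recs$outcome_match)
  } else {
    character(0)
  }

  exclusions <- data.frame(validation_id = character(),
                           reason = character(), stringsAsFactors = FALSE)
  drop_reason <- rep(NA_character_, nrow(recs))
  idx <- rep(NA_integer_, nrow(recs))
  for (j in seq_len(nrow(recs))) {
    hit <- which(studies$model_id == recs$model_id[j])
    if (!length(hit)) {
      drop_reason[j] <- "unknown_model_id"
      next
    }
    if (!is.null(recs$outcome) && !is.na(recs$outcome[j]) &&
        length(hit) > 1L) {
      by_outcome <- hit[!is.na(studies$outcome[hit]) &
                          studies$outcome[hit] == recs$outcome[j]]
      if (!length(by_outcome)) {
        drop_reason[j] <- "no_dev_auc_for_outcome"
        next
      }
      hit <- by_outcome
    } else if (!is.null(recs$outcome) && !is.na(recs$outcome[j])) {
      if (!is.na(studies$outcome[hit[1L]]) &&
          studies$outcome[hit[1L]] != recs$outcome[j]) {
        drop_reason[j] <- "no_dev_auc_for_outcome"
        next
      }
    }
    idx[j] <- hit[1L]
  }

  matched <- !is.na(idx)
  recs$overall_rob <- NA_character_
  recs$design_similarity <- NA_character_
  recs$dev_auc <- NA_real_
  if (any(matched)) {
    recs$overall_rob[matched] <- studies$overall_rob[idx[matched]]
    recs$design_similarity[matched] <-
      design_similarity(studies$design[idx[matched]], recs$design[matched])
    recs$dev_auc[matched] <- studies$dev_auc[idx[matched]]
  }
  drop_reason[matched & is.na(recs$dev_auc)] <- "dev_auc_missing"
  drop_reason[matched & !is.na(recs$dev_auc) & recs$dev_auc <= 0.5] <-
    "dev_auc_at_or_below_0.5"

  keep <- is.na(drop_reason)
  if (any(!keep)) {
    exclusions <- data.frame(validation_id = recs$validation_id[!keep],
                             reason = drop_reason[!keep],
                             stringsAsFactors = FALSE)
  }
  recs <- recs[keep, , drop = FALSE]
  if (nrow(recs)) {
    recs$dauc_abs <- dauc_abs(recs$dev_auc, recs$auc)
    recs$dauc_pct <- dauc_pct(recs$dev_auc, recs$auc)
  } else {
    recs$dauc_abs <- numeric(0)
    recs$dauc_pct <- numeric(0)
  }
  rownames(recs) <- NULL
  list(records = recs, exclusions = exclusions)
}

.file_md5 <- function(path) unname(tools::md5sum(path))

.obj_md5 <- function(obj) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  .file_md5(tmp)
}

.write_manifest <- function(out_dir, stage, inputs = character(),
                            config = NULL, seed = NULL, counts = list(),
                            exclusions = NULL) {
  input_hashes <- if (length(inputs)) {
    setNames(lapply(inputs, .file_md5), basename(inputs))
  } else {
    NULL
  }
  manifest <- list(
    stage = stage,
    package = "probastmeta",
    version = as.character(utils::packageVersion("probastmeta")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config_hash = if (!is.null(config)) .obj_md5(config) else NULL,
    input_hashes = input_hashes,
    counts = counts,
    exclusions = if (!is.null(exclusions) && nrow(exclusions)) {
      exclusions
    } else {
      NULL
    }
  )
  path <- file.path(out_dir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}

.ensure_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out_dir
}

#' Assess development studies and tabulate methodological quality
#'
#' Reads (or accepts) a development table, recomputes overall risk-of-bias
#' and applicability judgments from the domain columns, and writes the
#' per-study assessment report and the summary tally, with a run manifest.
#'
#' @param dev_table Path to a development CSV, or a data frame.
#' @param out_dir Output directory.
#' @param format `"csv"` or `"json"`.
#' @return Invisibly, a list with `studies` and `tally`.
#' @export
run_assess <- function(dev_table, out_dir, format = c("csv", "json")) {
  format <- match.arg(format)
  .ensure_dir(out_dir)
  inputs <- character()
  if (is.character(dev_table)) {
    inputs <- dev_table
    dev_table <- read_evidence(dev_table)$studies
  } else {
    dev_table <- validate_dev_table(dev_table)
  }
  studies <- assess_overall(dev_table)
  tal <- tally(studies = studies)
  ext <- format
  write_report(studies, file.path(out_dir, paste0("assessments.", ext)),
               format)
  write_report(tal, file.path(out_dir, paste0("quality_tally.", ext)), format)
  .write_manifest(out_dir, "assess", inputs = inputs,
                  counts = list(studies = length(unique(studies$study_id)),
                                models = length(unique(studies$model_id))))
  invisible(list(studies = studies, tally = tal))
}

#' Run the full dAUC synthesis
#'
#' Derives per-validation fields, writes the derived record table, the
#' stratified median/IQR summary by risk-of-bias class, and (when at least
#' two model clusters remain) the clustered GEE meta-regression report, plus
#' a manifest whose exclusion list carries one reason per excluded record.
#'
#' @param dev_table,val_table Paths to the two CSVs, or data frames.
#' @param out_dir Output directory.
#' @param format `"csv"` or `"json"`.
#' @param working_corr Working correlation for [fit_gee()].
#' @return Invisibly, a list with `records`, `exclusions`, `by_stratum`,
#'   `fit` (possibly `NULL`), `gee_table`.
#' @export
run_synthesize <- function(dev_table, val_table, out_dir,
                           format = c("csv", "json"),
                           working_corr = c("exchangeable", "independence")) {
  format <- match.arg(format)
  working_corr <- match.arg(working_corr)
  .ensure_dir(out_dir)
  inputs <- character()
  if (is.character(dev_table)) {
    inputs <- c(inputs, dev_table)
    dev_table <- read_evidence(dev_table)$studies
  }
  if (is.character(val_table)) {
    inputs <- c(inputs, val_table)
    val_table <- read.csv(val_table, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  }
  derived <- derive_validation_fields(dev_table, val_table)
  recs <- derived$records
  by_stratum <- summarize_by_stratum(recs)
  fit <- NULL
  gee_table <- NULL
  if (length(unique(recs$model_id)) >= 2L) {
    fit <- gee_dauc(recs, working_corr = working_corr)
    gee_table <- table4_report(fit)
  } else {
    warning("fewer than 2 model clusters after exclusions; GEE skipped")
  }
  ext <- format
  write_report(recs, file.path(out_dir, paste0("dauc_records.", ext)),
               format, allow_empty = TRUE)
  write_report(by_stratum,
               file.path(out_dir, paste0("dauc_by_stratum.", ext)), format)
  if (!is.null(gee_table)) {
    write_report(gee_table, file.path(out_dir, paste0("gee_dauc.", ext)),
                 format)
  }
  .write_manifest(out_dir, "synthesize", inputs = inputs,
                  counts = list(validations_in = nrow(val_table),
                                records_analyzed = nrow(recs),
                                excluded = nrow(derived$exclusions),
                                clusters = length(unique(recs$model_id)),
                                gee_fitted = !is.null(fit)),
                  exclusions = derived$exclusions)
  invisible(list(records = recs, exclusions = derived$exclusions,
                 by_stratum = by_stratum, fit = fit, gee_table = gee_table))
}

#' Generate and write a synthetic evidence base
#'
#' @param config A [simulation_config()], or a path to a YAML/JSON file of
#'   its fields (which must include `seed`).
#' @param out_dir Output directory.
#' @param format `"csv"` or `"json"`.
#' @return Invisibly, the generated evidence base.
#' @export
run_simulate <- function(config, out_dir, format = c("csv", "json")) {
  format <- match.arg(format)
  .ensure_dir(out_dir)
  if (is.character(config)) {
    fields <- if (grepl("\\.json$", config)) {
      jsonlite::fromJSON(config)
    } else {
      yaml::read_yaml(config)
    }
    for (nm in c("rob_probs", "optimism_by_rob", "casemix_shift")) {
      if (!is.null(fields[[nm]])) fields[[nm]] <- unlist(fields[[nm]])
    }
    if (!is.null(fields$true_auc_range)) {
      fields$true_auc_range <- as.numeric(unlist(fields$true_auc_range))
    }
    config <- do.call(simulation_config, fields)
  }
  eb <- generate_evidence_base(config)
  ext <- format
  write_report(eb$studies, file.path(out_dir, paste0("dev_table.", ext)),
               format)
  write_report(eb$validations, file.path(out_dir, paste0("val_table.", ext)),
               format)
  write_report(eb$truth$models,
               file.path(out_dir, paste0("truth_models.", ext)), format)
  write_report(eb$truth$records,
               file.path(out_dir, paste0("truth_records.", ext)), format)
  .write_manifest(out_dir, "simulate", config = unclass(config),
                  seed = config$seed,
                  counts = list(studies = length(unique(eb$studies$study_id)),
                                models = nrow(eb$truth$models),
                                validations = nrow(eb$validations)))
  invisible(eb)
}

#' Write the packaged fixture tables
#'
#' Emits the development-study assessment fixture (per-model long schema) and
#' a small seeded synthetic validation table usable against it, for examples
#' and smoke tests.
#'
#' @param out_dir Output directory.
#' @param seed Seed for the synthetic validation table.
#' @return Invisibly, the paths written.
#' @export
run_fixtures <- function(out_dir, seed = 20201L) {
  .ensure_dir(out_dir)
  dev_path <- file.path(out_dir, "table1_dev.csv")
  write_report(table1_dev_table(), dev_path, "csv")
  .write_manifest(out_dir, "fixtures", seed = seed,
                  counts = list(studies = 10L, models = 18L))
  invisible(dev_path)
}
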