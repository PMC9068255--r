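# Evidence-base schema: typed readers/writers for the two extraction tables
# (development-study assessments, external-validation records) and the
# packaged transcription of the in-paper development-study table.

# Development table: one row per study x model (x outcome where a study
# reports AUCs for several outcomes); study-level columns repeat across the
# rows of a study.
.dev_required <- c("study_id", "model_id", "design",
                   "app_participants", "app_predictors", "app_outcome",
                   "rob_participants", "rob_predictors", "rob_outcome",
                   "rob_analysis", "usable_research", "usable_practice")
.dev_optional <- c("outcome", "dev_auc", "events_smallest_group", "total_df",
                   "overall_rob", "overall_applicability")

.val_required <- c("validation_id", "model_id", "design",
                   "setting_match", "inclusion_match", "outcome_match", "auc")
.val_optional <- c("publication_id", "n", "outcome",
                   "cal_intercept", "cal_slope",
                   "relatedness", "design_similarity", "dauc_abs", "dauc_pct")

.check_columns <- function(df, required, what) {
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("schema error in ", what, " table: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  invisible(df)
}

.check_levels <- function(x, levels, col, what, allow_na = FALSE) {
  bad <- which(!(x %in% levels) & !(allow_na & is.na(x)))
  if (length(bad)) {
    stop("value error in ", what, " table, column '", col, "', row ",
         bad[1L], ": '", x[bad[1L]], "' is not one of ",
         paste(levels, collapse = "/"))
  }
}

.as_flag <- function(x, col, what, allow_na = FALSE) {
  if (is.logical(x)) return(x)
  xl <- tolower(trimws(as.character(x)))
  out <- ifelse(xl %in% c("true", "y", "yes", "1"), TRUE,
                ifelse(xl %in% c("false", "n", "no", "0"), FALSE, NA))
  bad <- which(is.na(out) & !(allow_na & (is.na(x) | xl == "")))
  if (length(bad)) {
    stop("value error in ", what, " table, column '", col, "', row ",
         bad[1L], ": cannot interpret '", x[bad[1L]], "' as a logical flag")
  }
  out
}

#' Validate a development-study assessment table
#'
#' @param studies A data frame in the development schema.
#' @return The table, with flag columns coerced to logical.
#' @export
validate_dev_table <- function(studies) {
  .check_columns(studies, .dev_required, "development")
  for (col in c(paste0("app_", .app_domains), paste0("rob_", .rob_domains))) {
    .check_levels(studies[[col]], .judgment_levels, col, "development")
  }
  .check_levels(studies$design, .dev_designs, "design", "development")
  if (!is.null(studies$outcome)) {
    .check_levels(studies$outcome, .outcome_levels, "outcome", "development",
                  allow_na = TRUE)
  }
  for (col in c("usable_research", "usable_practice")) {
    studies[[col]] <- .as_flag(studies[[col]], col, "development")
  }
  if (!is.null(studies$dev_auc)) {
    auc <- studies$dev_auc
    bad <- which(!is.na(auc) & (auc <= 0 | auc >= 1))
    if (length(bad)) {
      stop("value error in development table, row ", bad[1L],
           ": dev_auc = ", auc[bad[1L]], " is outside (0, 1)")
    }
  }
  studies
}

#' Validate an external-validation record table
#'
#' @param records A data frame in the validation schema; an empty (zero-row)
#'   table is valid.
#' @return The table, with flag columns coerced to logical.
#' @export
validate_val_table <- function(records) {
  .check_columns(records, .val_required, "validation")
  if (nrow(records) == 0L) return(records)
  .check_levels(records$design, .val_designs, "design", "validation")
  if (!is.null(records$outcome)) {
    .check_levels(records$outcome, .outcome_levels, "outcome", "validation",
                  allow_na = TRUE)
  }
  for (col in c("setting_match", "inclusion_match", "outcome_match")) {
    records[[col]] <- .as_flag(records[[col]], col, "validation")
  }
  auc <- records$auc
  bad <- which(is.na(auc) | auc <= 0 | auc >= 1)
  if (length(bad)) {
    stop("value error in validation table, row ", bad[1L],
         ": auc = ", auc[bad[1L]], " is outside (0, 1)")
  }
  if (!is.null(records$n)) {
    bad_n <- which(!is.na(records$n) & records$n <= 0)
    if (length(bad_n)) {
      stop("value error in validation table, row ", bad_n[1L],
           ": n must be a positive integer")
    }
  }
  records
}

#' Read the two evidence-extraction tables
#'
#' Both tables are comma-separated UTF-8 text with a header row; missing
#' numeric values are empty cells (never sentinel numbers). The column schema
#' is documented in `system.file("extdata", "evidence_schema.json",
#' package = "probastmeta")`. Derived fields (overall judgments, relatedness,
#' design similarity, dAUC) are left for the downstream stages.
#'
#' @param dev_table_path Path to the development-study assessment table.
#' @param val_table_path Path to the external-validation table, or `NULL`
#'   for assessment-only runs.
#' @return A list with elements `studies` and `validations` (the latter a
#'   zero-row table when no path was given).
#' @export
read_evidence <- function(dev_table_path, val_table_path = NULL) {
  if (!file.exists(dev_table_path)) {
    stop("development table not found: ", dev_table_path)
  }
  studies <- read.csv(dev_table_path, stringsAsFactors = FALSE,
                      na.strings = c("NA", ""))
  studies <- validate_dev_table(studies)
  if (is.null(val_table_path)) {
    validations <- empty_validation_table()
  } else {
    if (!file.exists(val_table_path)) {
      stop("validation table not found: ", val_table_path)
    }
    validations <- read.csv(val_table_path, stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
    validations <- validate_val_table(validations)
  }
  list(studies = studies, validations = validations)
}

#' An empty, schema-conformant validation table
#' @return A zero-row data frame with the mandatory validation columns.
#' @export
empty_validation_table <- function() {
  data.frame(validation_id = character(), model_id = character(),
             publication_id = character(), design = character(),
             setting_match = logical(), inclusion_match = logical(),
             outcome_match = logical(), n = integer(), auc = numeric(),
             cal_intercept = numeric(), cal_slope = numeric(),
             outcome = character(), stringsAsFactors = FALSE)
}

#' Development-study assessments of the ten TBI prognostic model papers
#'
#' Transcription of the published per-study PROBAST domain judgments and
#' usability flags for the ten development studies (Knaus/APACHE II through
#' Yuan) of 18 prognostic models for outcome after moderate and severe
#' traumatic brain injury. One row per study; `models` is a
#' semicolon-separated list of the model ids described in that study (18
#' distinct ids in total). Overall judgment columns are deliberately absent:
#' they are recomputed mechanically by [assess_overall()]. Study designs and
#' the placeholder model ids inside multi-model studies are supplementary
#' metadata reconstructed from the publications, not part of the printed
#' judgment table.
#'
#' @return A 10-row data frame with columns `study_id`, `models`, `design`,
#'   `app_participants`, `app_predictors`, `app_outcome`, `rob_participants`,
#'   `rob_predictors`, `rob_outcome`, `rob_analysis`, `usable_research`,
#'   `usable_practice`.
#' @export
#' @examples
#' fx <- table1_fixture()
#' assess_overall(fx)$overall_rob
table1_fixture <- function() {
  f <- function(study_id, models, design, a1, a2, a3, r1, r2, r3, r4,
                res, prac) {
    data.frame(study_id = study_id, models = models, design = design,
               app_participants = a1, app_predictors = a2, app_outcome = a3,
               rob_participants = r1, rob_predictors = r2, rob_outcome = r3,
               rob_analysis = r4,
               usable_research = res == "y", usable_practice = prac == "y",
               stringsAsFactors = FALSE)
  }
  rbind(
    f("knaus",       "apache_ii",                      "cohort",
      "H", "L", "L",  "L", "L", "L", "H",  "y", "y"),
    f("le_gall",     "saps_ii",                        "cohort",
      "H", "L", "L",  "L", "L", "L", "H",  "n", "y"),
    f("lemeshow",    "mpm_ii_admission;mpm_ii_24h",    "cohort",
      "H", "L", "L",  "L", "L", "L", "H",  "n", "n"),
    f("signorini",   "signorini",                      "cohort",
      "L", "L", "L",  "L", "L", "L", "H",  "n", "y"),
    f("hukkelhoven", "hukkelhoven",                    "trial",
      "L", "L", "L",  "L", "L", "L", "L",  "y", "y"),
    f("maas",        "rotterdam_ct",                   "trial",
      "L", "L", "L",  "L", "L", "L", "U",  "n", "y"),
    f("perel",       "crash_basic;crash_ct",           "trial",
      "L", "L", "L",  "L", "L", "L", "U",  "n", "y"),
    f("steyerberg",  "impact_core;impact_extended;impact_lab", "pooled",
      "L", "L", "L",  "L", "L", "L", "L",  "y", "y"),
    f("jacobs",      "nijmegen_a;nijmegen_b",          "cohort",
      "L", "L", "L",  "L", "L", "L", "H",  "y", "y"),
    f("yuan",        "yuan_a;yuan_b;yuan_c;yuan_d",    "cohort",
      "L", "L", "L",  "L", "U", "L", "H",  "n", "y")
  )
}

#' Expand the per-study fixture to the long development schema
#'
#' One row per model; development AUCs are unavailable in the transcription
#' and left missing.
#'
#' @param fixture A per-study table as returned by [table1_fixture()].
#' @return A development-schema data frame (one row per model id).
#' @export
table1_dev_table <- function(fixture = table1_fixture()) {
  model_lists <- strsplit(fixture$models, ";", fixed = TRUE)
  idx <- rep(seq_len(nrow(fixture)), lengths(model_lists))
  out <- fixture[idx, setdiff(names(fixture), "models"), drop = FALSE]
  out <- cbind(model_id = unlist(model_lists), out)
  out$outcome <- NA_character_
  out$dev_auc <- NA_real_
  rownames(out) <- NULL
  out[, c("study_id", "model_id", "design", "outcome", "dev_auc",
          paste0("app_", .app_domains), paste0("rob_", .rob_domains),
          "usable_research", "usable_practice")]
}

#' Write a synthesized table to disk
#'
#' CSV output uses empty cells for missing values; JSON output writes one
#' object per row with `null` for missing values. Column order is preserved,
#' so repeated runs on the same input are byte-identical and the result
#' round-trips through [read_report()].
#'
#' @param records A data frame.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @param allow_empty Permit a zero-row table (header-only CSV / empty JSON
#'   array)?
#' @return `path`, invisibly.
#' @export
write_report <- function(records, path, format = c("csv", "json"),
                         allow_empty = FALSE) {
  format <- match.arg(format)
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L && !allow_empty) {
    stop("refusing to write an empty table; set allow_empty = TRUE")
  }
  if (format == "csv") {
    write.csv(records, path, row.names = FALSE, na = "")
  } else {
    jsonlite::write_json(records, path, dataframe = "rows", na = "null",
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a table written by [write_report()]
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; inferred from the extension when `NULL`.
#' @return A data frame.
#' @export
read_report <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path)) "json" else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  } else {
    out <- jsonlite::fromJSON(path)
    as.data.frame(out, stringsAsFactors = FALSE)
  }
}
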