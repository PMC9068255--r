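# Bespoke classification rubrics: relatedness of a validation cohort to the
# derivation cohort, model usability, development-to-validation design
# similarity, and the summary tally.

#' Classify relatedness of a validation study to the development study
#'
#' Three-domain rubric: setting (unit/country), inclusion criteria, and
#' outcome assessment and timing. A validation meeting all three domains is
#' `related`; meeting inclusion criteria and outcome but not setting is
#' `moderately` related; failing inclusion criteria and/or outcome is
#' `distantly` related regardless of setting. An upstream "setting not
#' specified" should be resolved conservatively to `setting_match = FALSE`
#' before calling.
#'
#' @param setting_match,inclusion_match,outcome_match Logical vectors
#'   (recycled to a common length); `NA` is not allowed.
#' @return Character vector: `"related"`, `"moderately"` or `"distantly"`.
#' @export
#' @examples
#' classify_relatedness(TRUE, TRUE, TRUE)    # related
#' classify_relatedness(FALSE, TRUE, TRUE)   # moderately
#' classify_relatedness(TRUE, FALSE, TRUE)   # distantly
classify_relatedness <- function(setting_match, inclusion_match,
                                 outcome_match) {
  n <- max(length(setting_match), length(inclusion_match),
           length(outcome_match))
  setting_match <- rep_len(setting_match, n)
  inclusion_match <- rep_len(inclusion_match, n)
  outcome_match <- rep_len(outcome_match, n)
  if (anyNA(setting_match) || anyNA(inclusion_match) || anyNA(outcome_match)) {
    stop("relatedness inputs must be TRUE/FALSE; resolve unknowns upstream")
  }
  ifelse(!(inclusion_match & outcome_match), "distantly",
         ifelse(setting_match, "related", "moderately"))
}

#' Usability of a model for research
#'
#' A model is usable in research when the full model equation, or enough
#' information to extract the intercept and the individual predictor
#' coefficients, is reported. The rule is an identity on the extracted flag;
#' it exists so the criterion is named, documented and testable in one place.
#'
#' @param full_equation_reported Logical vector.
#' @return Logical vector.
#' @export
usable_research <- function(full_equation_reported) {
  stopifnot(is.logical(full_equation_reported))
  full_equation_reported
}

#' Usability of a model in clinical practice
#'
#' A model is usable in practice when the paper includes at least one
#' alternative presentation: a nomogram, score chart, web calculator, or
#' another simplified format.
#'
#' @param presentations A character vector of presentation tokens for one
#'   model, or a list of such vectors for several models.
#' @return Logical vector: `TRUE` iff the presentation set is nonempty.
#' @export
#' @examples
#' usable_practice(c("score_chart"))                # TRUE
#' usable_practice(character())                     # FALSE
#' usable_practice(list(c("nomogram", "web_calculator"), character()))
usable_practice <- function(presentations) {
  if (!is.list(presentations)) presentations <- list(presentations)
  vapply(presentations, function(p) {
    p <- as.character(p)
    bad <- setdiff(p, .presentation_levels)
    if (length(bad)) {
      stop("unknown presentation token(s): ", paste(bad, collapse = ", "))
    }
    length(p) > 0L
  }, logical(1))
}

#' Design similarity between development and validation study
#'
#' Labels the design transition from development to validation. A model
#' developed on pooled cohort-and-trial data is treated as design-similar to
#' either validation design, since both designs contributed to derivation.
#'
#' @param dev_design `"cohort"`, `"trial"` or `"pooled"` (vectorized).
#' @param val_design `"cohort"` or `"trial"` (vectorized).
#' @return Character vector: `"similar"`, `"cohort_to_trial"` or
#'   `"trial_to_cohort"`.
#' @export
design_similarity <- function(dev_design, val_design) {
  n <- max(length(dev_design), length(val_design))
  dev_design <- rep_len(as.character(dev_design), n)
  val_design <- rep_len(as.character(val_design), n)
  .check_levels(dev_design, .dev_designs, "dev_design", "design-similarity")
  .check_levels(val_design, .val_designs, "val_design", "design-similarity")
  ifelse(dev_design == "pooled" | dev_design == val_design, "similar",
         ifelse(dev_design == "cohort", "cohort_to_trial", "trial_to_cohort"))
}

.tally_section <- function(x, section, levels) {
  x <- x[!is.na(x)]
  counts <- table(factor(x, levels = levels))
  denom <- sum(counts)
  pct <- if (denom > 0) round(100 * as.integer(counts) / denom) else
    rep(NA_integer_, length(levels))
  data.frame(section = section, level = levels, n = as.integer(counts),
             pct = as.integer(pct), stringsAsFactors = FALSE)
}

#' Tabulate risk of bias, applicability, usability and validation rubrics
#'
#' Study-level sections (overall risk of bias, overall applicability,
#' usability in research and in practice) count one row per distinct
#' development study. Validation-level sections (design similarity,
#' relatedness) count validation records; records whose rubric field is
#' missing (unclassifiable) are excluded from the denominator and reported
#' in a separate `not_classified` row. Percentages are rounded to whole
#' percent.
#'
#' @param studies Development-study table with `overall_rob`,
#'   `overall_applicability`, `usable_research`, `usable_practice` populated
#'   (see [assess_overall()]); may be `NULL`.
#' @param records Validation-record table with `design_similarity` and
#'   `relatedness` populated (see [derive_validation_fields()]); may be
#'   `NULL` or empty.
#' @return A data frame with columns `section`, `level`, `n`, `pct`.
#' @export
tally <- function(studies = NULL, records = NULL) {
  out <- list()
  if (!is.null(studies) && nrow(studies) > 0L) {
    per_study <- studies[!duplicated(studies$study_id), , drop = FALSE]
    out$rob <- .tally_section(per_study$overall_rob, "overall_rob",
                              c("H", "L", "U"))
    out$app <- .tally_section(per_study$overall_applicability,
                              "overall_applicability", c("H", "L", "U"))
    out$res <- .tally_section(ifelse(per_study$usable_research, "yes", "no"),
                              "usable_research", c("yes", "no"))
    out$prac <- .tally_section(ifelse(per_study$usable_practice, "yes", "no"),
                               "usable_practice", c("yes", "no"))
  }
  if (!is.null(records) && nrow(records) > 0L) {
    for (fld in c("design_similarity", "relatedness")) {
      lv <- if (fld == "relatedness") .relatedness_levels else
        .similarity_levels
      sec <- .tally_section(records[[fld]], fld, lv)
      n_na <- sum(is.na(records[[fld]]))
      if (n_na > 0L) {
        sec <- rbind(sec, data.frame(section = fld, level = "not_classified",
                                     n = n_na, pct = NA_integer_,
                                     stringsAsFactors = FALSE))
      }
      out[[fld]] <- sec
    }
  }
  if (!length(out)) {
    return(data.frame(section = character(), level = character(),
                      n = integer(), pct = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
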