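# PROBAST rollup: signaling answers -> domain judgments -> overall judgment,
# plus the 8-item short form and the events-per-parameter (EPP) rule.

#' PROBAST configuration
#'
#' The question catalogue maps each of the 20 signaling questions to its
#' risk-of-bias domain (participant selection 1.1-1.2, predictors 2.1-2.3,
#' outcome 3.1-3.6, analysis 4.1-4.9). The short form is a configurable
#' 8-question subset used to screen for high risk of bias; the default subset
#' covers participant selection, predictor/outcome comparability and blinding,
#' and the analysis items that dominate high-risk judgments in practice
#' (events per parameter, continuous-predictor handling, participant
#' exclusions, overfitting/optimism, coherence of the final model).
#'
#' @param question_catalogue Named character vector mapping question id
#'   (e.g. `"4.1"`) to domain (`"participants"`, `"predictors"`, `"outcome"`,
#'   `"analysis"`).
#' @param short_form_ids Character vector of 8 question ids, a subset of the
#'   catalogue.
#' @param epp_threshold Positive number of events per parameter regarded as
#'   adequate; the conventional rule is 10 or more.
#' @return A list of class `probast_config`.
#' @export
#' @examples
#' cfg <- probast_config()
#' length(cfg$question_catalogue)  # 20
probast_config <- function(question_catalogue = NULL,
                           short_form_ids = c("1.1", "2.3", "3.5", "4.1",
                                              "4.2", "4.3", "4.8", "4.9"),
                           epp_threshold = 10) {
  if (is.null(question_catalogue)) {
    question_catalogue <- c(
      "1.1" = "participants", "1.2" = "participants",
      "2.1" = "predictors", "2.2" = "predictors", "2.3" = "predictors",
      "3.1" = "outcome", "3.2" = "outcome", "3.3" = "outcome",
      "3.4" = "outcome", "3.5" = "outcome", "3.6" = "outcome",
      "4.1" = "analysis", "4.2" = "analysis", "4.3" = "analysis",
      "4.4" = "analysis", "4.5" = "analysis", "4.6" = "analysis",
      "4.7" = "analysis", "4.8" = "analysis", "4.9" = "analysis"
    )
  }
  if (!all(question_catalogue %in% .rob_domains)) {
    stop("question_catalogue domains must be one of: ",
         paste(.rob_domains, collapse = ", "))
  }
  if (!all(short_form_ids %in% names(question_catalogue))) {
    stop("short_form_ids must be a subset of the question catalogue")
  }
  stopifnot(is.numeric(epp_threshold), length(epp_threshold) == 1L,
            epp_threshold > 0)
  structure(list(question_catalogue = question_catalogue,
                 short_form_ids = short_form_ids,
                 epp_threshold = epp_threshold),
            class = "probast_config")
}

#' Construct signaling answers
#'
#' @param question_id Character vector of question ids from the catalogue.
#' @param answer Character vector of answers: `Y`, `PY`, `PN`, `N`, `NI`
#'   (yes, probably yes, probably no, no, no information).
#' @param config A [probast_config()].
#' @return A data frame with columns `question_id`, `answer`, `domain`.
#' @export
signaling_answers <- function(question_id, answer, config = probast_config()) {
  question_id <- as.character(question_id)
  answer <- as.character(answer)
  stopifnot(length(question_id) == length(answer))
  unknown <- setdiff(question_id, names(config$question_catalogue))
  if (length(unknown)) {
    stop("unknown question id(s): ", paste(unknown, collapse = ", "))
  }
  bad <- setdiff(answer, .answer_levels)
  if (length(bad)) {
    stop("answers must be one of ", paste(.answer_levels, collapse = "/"),
         "; got: ", paste(bad, collapse = ", "))
  }
  data.frame(question_id = question_id, answer = answer,
             domain = unname(config$question_catalogue[question_id]),
             stringsAsFactors = FALSE)
}

#' Judge one PROBAST domain from its signaling answers
#'
#' Mechanical rule: any `N`/`PN` answer gives a high-risk judgment; otherwise
#' any `NI` gives unclear; otherwise low. A reviewer override, when supplied,
#' wins and is recorded with `source = "reviewer_override"` so that mechanical
#' and human judgments stay distinguishable.
#'
#' @param answers A data frame as returned by [signaling_answers()], all rows
#'   from a single domain.
#' @param override Optional `"L"`, `"H"` or `"U"` reviewer judgment.
#' @param config A [probast_config()].
#' @return A one-row data frame: `domain`, `judgment`, `source`.
#' @export
#' @examples
#' judge_domain(signaling_answers(c("4.1", "4.2"), c("Y", "NI")))
judge_domain <- function(answers, override = NULL, config = probast_config()) {
  if (!is.data.frame(answers) || nrow(answers) == 0L) {
    stop("answers must be a nonempty data frame of signaling answers")
  }
  if (is.null(answers$domain)) {
    answers <- signaling_answers(answers$question_id, answers$answer, config)
  }
  domains <- unique(answers$domain)
  if (length(domains) != 1L) {
    stop("judge_domain() expects answers from a single domain; got: ",
         paste(domains, collapse = ", "))
  }
  judgment <- if (any(answers$answer %in% c("N", "PN"))) {
    "H"
  } else if (any(answers$answer == "NI")) {
    "U"
  } else {
    "L"
  }
  source <- "mechanical"
  if (!is.null(override)) {
    override <- match.arg(override, .judgment_levels)
    judgment <- override
    source <- "reviewer_override"
  }
  data.frame(domain = domains, judgment = judgment, source = source,
             stringsAsFactors = FALSE)
}

# shared precedence rule: any H -> H, else any U -> U, else L
.rollup <- function(judgments) {
  bad <- setdiff(judgments, .judgment_levels)
  if (length(bad)) {
    stop("judgments must be L/H/U; got: ", paste(bad, collapse = ", "))
  }
  if (any(judgments == "H")) "H" else if (any(judgments == "U")) "U" else "L"
}

#' Overall risk-of-bias judgment from the four domain judgments
#'
#' Summative rule: any high-risk domain makes the overall judgment high;
#' otherwise any unclear domain makes it unclear; otherwise low.
#'
#' @param domains Character vector of four `L`/`H`/`U` judgments; if named,
#'   names must be `participants`, `predictors`, `outcome`, `analysis`.
#' @return `"L"`, `"H"` or `"U"`.
#' @export
#' @examples
#' overall_rob(c(participants = "L", predictors = "L",
#'               outcome = "L", analysis = "H"))  # "H"
overall_rob <- function(domains) {
  if (length(domains) != 4L) {
    stop("overall_rob() requires exactly the four risk-of-bias domains (",
         paste(.rob_domains, collapse = ", "), ")")
  }
  if (!is.null(names(domains)) && !setequal(names(domains), .rob_domains)) {
    stop("domain names must be: ", paste(.rob_domains, collapse = ", "))
  }
  .rollup(as.character(domains))
}

#' Overall applicability judgment from the three applicability domains
#'
#' Same precedence rule as [overall_rob()]; the analysis domain is not part
#' of applicability and is rejected.
#'
#' @param domains Character vector of three `L`/`H`/`U` judgments; if named,
#'   names must be `participants`, `predictors`, `outcome`.
#' @return `"L"`, `"H"` or `"U"`.
#' @export
overall_applicability <- function(domains) {
  if (length(domains) != 3L) {
    stop("overall_applicability() requires exactly three domains (",
         paste(.app_domains, collapse = ", "), ")")
  }
  if (!is.null(names(domains))) {
    if ("analysis" %in% names(domains)) {
      stop("the analysis domain is not an applicability domain")
    }
    if (!setequal(names(domains), .app_domains)) {
      stop("domain names must be: ", paste(.app_domains, collapse = ", "))
    }
  }
  .rollup(as.character(domains))
}

#' Short-form risk-of-bias screen
#'
#' Applies the mechanical domain rule to the configured 8-question subset
#' only, then rolls up over the domains those questions touch. Because the
#' short form sees fewer questions, an unclear full-form study whose
#' no-information answers fall outside the subset can screen as low risk.
#'
#' @param answers A data frame of signaling answers covering (at least) every
#'   configured short-form question; `NI` answers are allowed, unanswered
#'   short-form questions are an error.
#' @param config A [probast_config()].
#' @return `"L"`, `"H"` or `"U"`.
#' @export
short_form_rob <- function(answers, config = probast_config()) {
  if (is.null(answers$domain)) {
    answers <- signaling_answers(answers$question_id, answers$answer, config)
  }
  missing_q <- setdiff(config$short_form_ids, answers$question_id)
  if (length(missing_q)) {
    stop("unanswered short-form question(s): ",
         paste(missing_q, collapse = ", "))
  }
  short <- answers[answers$question_id %in% config$short_form_ids, ,
                   drop = FALSE]
  per_domain <- vapply(split(short, short$domain),
                       function(d) judge_domain(d, config = config)$judgment,
                       character(1))
  .rollup(per_domain)
}

#' Predictor specifications
#'
#' @param name Character vector of predictor names.
#' @param kind `"continuous"` or `"categorical"`, recycled as needed.
#' @param n_categories Integer number of categories (at least 2); required for
#'   categorical predictors, must be `NA` for continuous ones.
#' @return A data frame with one row per candidate predictor.
#' @export
predictor_spec <- function(name, kind, n_categories = NA_integer_) {
  kind <- rep_len(as.character(kind), length(name))
  n_categories <- rep_len(as.integer(n_categories), length(name))
  bad <- setdiff(kind, c("continuous", "categorical"))
  if (length(bad)) stop("kind must be continuous or categorical")
  cat_rows <- kind == "categorical"
  if (any(cat_rows & (is.na(n_categories) | n_categories < 2L))) {
    stop("categorical predictors require n_categories >= 2")
  }
  if (any(!cat_rows & !is.na(n_categories))) {
    stop("n_categories must be NA for continuous predictors")
  }
  data.frame(name = as.character(name), kind = kind,
             n_categories = n_categories, stringsAsFactors = FALSE)
}

#' Total degrees of freedom consumed by the candidate predictors
#'
#' Continuous predictors contribute one degree of freedom each. Under the
#' default `"categories"` convention a categorical predictor contributes its
#' number of categories; `"categories_minus_one"` is the dummy-coding
#' alternative. All candidate predictors count, including those dropped later
#' by univariable screening or stepwise selection.
#'
#' @param predictors A data frame from [predictor_spec()].
#' @param convention `"categories"` (default) or `"categories_minus_one"`.
#' @return A positive integer.
#' @export
#' @examples
#' p <- predictor_spec(c("age", "gcs", "pupils"), "continuous")
#' p <- rbind(p, predictor_spec("ct_class", "categorical", 4))
#' total_df(p)                                   # 7
#' total_df(p, "categories_minus_one")           # 6
total_df <- function(predictors, convention = c("categories",
                                                "categories_minus_one")) {
  convention <- match.arg(convention)
  if (!is.data.frame(predictors) || nrow(predictors) == 0L) {
    stop("predictors must be a nonempty data frame")
  }
  per_cat <- if (convention == "categories") {
    predictors$n_categories
  } else {
    predictors$n_categories - 1L
  }
  df <- ifelse(predictors$kind == "continuous", 1L, per_cat)
  as.integer(sum(df))
}

#' Events per parameter
#'
#' Events in the smaller outcome group divided by the total degrees of
#' freedom used during the whole modeling process; a ratio at or above the
#' threshold (inclusive) is taken as a reasonable number of outcome events.
#'
#' @param events_smallest_group Nonnegative count of events in the smaller
#'   outcome group.
#' @param df Positive total degrees of freedom, e.g. from [total_df()].
#' @param threshold Adequacy threshold; defaults to the configured value (10).
#' @param config A [probast_config()].
#' @return A list with `ratio` and `reasonable`.
#' @export
#' @examples
#' epp(100, 10)  # ratio 10, reasonable (boundary is inclusive)
epp <- function(events_smallest_group, df, threshold = NULL,
                config = probast_config()) {
  threshold <- threshold %||% config$epp_threshold
  stopifnot(is.numeric(events_smallest_group), events_smallest_group >= 0)
  if (!is.numeric(df) || df < 1) {
    stop("df must be a positive integer (at least 1)")
  }
  ratio <- events_smallest_group / df
  list(ratio = ratio, reasonable = ratio >= threshold)
}

#' Recompute overall judgments for a table of study assessments
#'
#' Applies [overall_rob()] and [overall_applicability()] row-wise to the
#' `rob_*` and `app_*` domain columns, filling `overall_rob` and
#' `overall_applicability`.
#'
#' @param studies A development-study assessment table (see
#'   [read_evidence()] for the schema).
#' @return The table with overall columns populated.
#' @export
assess_overall <- function(studies) {
  stopifnot(is.data.frame(studies))
  studies$overall_rob <- apply(
    studies[, paste0("rob_", .rob_domains)], 1L,
    function(r) overall_rob(as.character(r))
  )
  studies$overall_applicability <- apply(
    studies[, paste0("app_", .app_domains)], 1L,
    function(r) overall_applicability(as.character(r))
  )
  studies
}
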