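# Change in discriminative performance between derivation and external
# validation: the percent change in discrimination (dAUC) and its stratified
# median/IQR summary by risk-of-bias class.

#' Percent change in discrimination between development and validation
#'
#' Discrimination above chance is `AUC - 0.5`; the percent change is the
#' change in that quantity relative to its value at derivation:
#' \deqn{100 \times \frac{(AUC_{val} - 0.5) - (AUC_{dev} - 0.5)}
#'                       {AUC_{dev} - 0.5}}
#' A value of -100 means validation performance fell to chance; values below
#' -100 occur when the validation AUC is below 0.5. A development AUC at or
#' below 0.5 leaves the denominator nonpositive and is a domain error; in the
#' pipeline such records are excluded with a logged reason before this is
#' called.
#'
#' @param auc_dev Development AUC(s), strictly above 0.5.
#' @param auc_val Validation AUC(s) in (0, 1).
#' @return Numeric vector of percent changes.
#' @export
#' @examples
#' dauc_pct(0.70, 0.60)  # -50: a 0.10 drop from 0.70 halves the
#'                       # discrimination above chance
dauc_pct <- function(auc_dev, auc_val) {
  stopifnot(is.numeric(auc_dev), is.numeric(auc_val))
  if (any(is.na(auc_dev)) || any(auc_dev <= 0.5)) {
    stop("dauc_pct() requires development AUC strictly above 0.5 ",
         "(the denominator is dev AUC - 0.5)")
  }
  if (any(is.na(auc_val)) || any(auc_val <= 0) || any(auc_val >= 1)) {
    stop("validation AUC must lie in (0, 1)")
  }
  100 * ((auc_val - 0.5) - (auc_dev - 0.5)) / (auc_dev - 0.5)
}

#' Absolute change in AUC between development and validation
#'
#' @param auc_dev,auc_val AUCs in (0, 1).
#' @return `auc_val - auc_dev`.
#' @export
dauc_abs <- function(auc_dev, auc_val) {
  stopifnot(is.numeric(auc_dev), is.numeric(auc_val))
  auc_val - auc_dev
}

.q_summary <- function(x, type) {
  if (length(x) == 0L) {
    return(c(median = NA_real_, q1 = NA_real_, q3 = NA_real_))
  }
  q <- quantile(x, probs = c(0.5, 0.25, 0.75), type = type, names = FALSE)
  c(median = q[1L], q1 = q[2L], q3 = q[3L])
}

#' Median and IQR of AUCs and dAUC by risk-of-bias stratum
#'
#' One summary row per overall risk-of-bias class, in the fixed order low,
#' high, unclear, each with the number of contributing validation records and
#' the median and interquartile range of the development AUC, validation AUC,
#' absolute AUC change, and percent change in discrimination. The quartile
#' convention defaults to linear interpolation (R quantile type 7) and is
#' switchable since published tables rarely state it.
#'
#' @param records Validation records carrying `overall_rob`, `dev_auc`,
#'   `auc`, `dauc_abs`, `dauc_pct` (see [derive_validation_fields()]).
#' @param quartile_type Quantile algorithm type passed to
#'   [stats::quantile()]; default 7 (linear interpolation).
#' @return A data frame with one row per stratum (`L`, `H`, `U`), `n`, and
#'   `median`/`q1`/`q3` columns for each of the four statistics. Empty strata
#'   keep their row with `n = 0` and missing statistics.
#' @export
summarize_by_stratum <- function(records, quartile_type = 7) {
  stopifnot(is.data.frame(records))
  needed <- c("overall_rob", "dev_auc", "auc", "dauc_abs", "dauc_pct")
  .check_columns(records, needed, "derived validation")
  strata <- c("L", "H", "U")
  rows <- lapply(strata, function(s) {
    sub <- records[!is.na(records$overall_rob) & records$overall_rob == s, ,
                   drop = FALSE]
    stats <- c(
      setNames(.q_summary(sub$dev_auc, quartile_type),
               c("median_dev_auc", "q1_dev_auc", "q3_dev_auc")),
      setNames(.q_summary(sub$auc, quartile_type),
               c("median_val_auc", "q1_val_auc", "q3_val_auc")),
      setNames(.q_summary(sub$dauc_abs, quartile_type),
               c("median_dauc_abs", "q1_dauc_abs", "q3_dauc_abs")),
      setNames(.q_summary(sub$dauc_pct, quartile_type),
               c("median_dauc_pct", "q1_dauc_pct", "q3_dauc_pct"))
    )
    cbind(data.frame(stratum = s, n = nrow(sub), stringsAsFactors = FALSE),
          as.data.frame(as.list(stats)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
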