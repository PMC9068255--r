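# Clustered meta-regression of the percent change in discrimination on
# risk-of-bias class and design similarity: Gaussian generalized estimating
# equations (identity link) with an independence or exchangeable working
# correlation, clustering validations of the same model, and robust
# cluster-sandwich variance.

.gee_terms <- c("intercept", "rob_high", "rob_unclear",
                "design_cohort_to_trial", "design_trial_to_cohort")

#' Build the dAUC meta-regression design
#'
#' Indicator coding with reference levels low risk of bias and similar study
#' design, so the intercept is the expected percent change in discrimination
#' for a low-risk-of-bias model validated in a design-similar study.
#' Clusters are prediction models (`model_id`): validations of the same model
#' are correlated. Covariate levels absent from the data drop their column
#' with a warning so the design stays full rank.
#'
#' @param records Validation records carrying `dauc_pct`, `overall_rob`
#'   (`L`/`H`/`U`), `design_similarity` and `model_id`, with no missing
#'   values in those fields.
#' @return A list: `y` (response vector, percent scale), `X` (design
#'   matrix), `clusters` (cluster id per record).
#' @export
build_design <- function(records) {
  stopifnot(is.data.frame(records))
  needed <- c("dauc_pct", "overall_rob", "design_similarity", "model_id")
  .check_columns(records, needed, "meta-regression input")
  if (anyNA(records[, needed])) {
    stop("meta-regression input has missing covariates or response; ",
         "exclude those records first")
  }
  .check_levels(records$overall_rob, .judgment_levels, "overall_rob",
                "meta-regression input")
  .check_levels(records$design_similarity, .similarity_levels,
                "design_similarity", "meta-regression input")
  if (length(unique(records$model_id)) < 2L) {
    stop("at least 2 clusters (models) are required")
  }
  X <- cbind(
    intercept = 1,
    rob_high = as.numeric(records$overall_rob == "H"),
    rob_unclear = as.numeric(records$overall_rob == "U"),
    design_cohort_to_trial =
      as.numeric(records$design_similarity == "cohort_to_trial"),
    design_trial_to_cohort =
      as.numeric(records$design_similarity == "trial_to_cohort")
  )
  empty <- colnames(X)[-1L][colSums(X[, -1L, drop = FALSE]) == 0]
  if (length(empty)) {
    warning("dropping absent covariate level(s): ",
            paste(empty, collapse = ", "))
    X <- X[, setdiff(colnames(X), empty), drop = FALSE]
  }
  list(y = records$dauc_pct, X = X, clusters = as.character(records$model_id))
}

#' Fit Gaussian generalized estimating equations with cluster-robust variance
#'
#' Identity-link, Gaussian-type estimating equations. The algorithm
#' alternates (1) a weighted estimating-equation solve for the coefficients
#' given the working correlation with (2) a moment update of the exchangeable
#' correlation from standardized within-cluster residual cross-products,
#' until the largest coefficient change falls below `tol`. Variance is the
#' cluster-sandwich (robust) estimator; 95% confidence intervals are
#' z-based (estimate +/- 1.96 robust SE). With one record per cluster, or an
#' independence working correlation and a single iteration, the coefficients
#' coincide with ordinary least squares.
#'
#' @param y Numeric response (percent-scale dAUC in the intended use).
#' @param X Design matrix (see [build_design()]).
#' @param clusters Cluster id per record (model id in the intended use).
#' @param working_corr `"exchangeable"` (default) or `"independence"`.
#' @param tol Convergence tolerance on the maximum coefficient change.
#' @param max_iter Maximum number of iterations; non-convergence returns a
#'   fit flagged `converged = FALSE` with a warning, never silently.
#' @return An object of class `gee_fit`: `coefficients`, `robust_se`,
#'   `ci95` (two-column matrix), `vcov`, `n_records`, `n_clusters`,
#'   `working_corr`, `alpha_hat`, `dispersion`, `converged`, `n_iter`.
#' @export
#' @examples
#' set.seed(1)
#' X <- cbind(intercept = 1, x = rnorm(40))
#' y <- 2 + 3 * X[, "x"] + rnorm(40)
#' fit_gee(y, X, clusters = rep(1:20, each = 2))
fit_gee <- function(y, X, clusters,
                    working_corr = c("exchangeable", "independence"),
                    tol = 1e-8, max_iter = 100L) {
  working_corr <- match.arg(working_corr)
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), length(clusters) == nrow(X))
  n <- nrow(X)
  p <- ncol(X)
  f <- factor(clusters, levels = unique(clusters))
  cl_sizes <- as.integer(table(f)[levels(f)])
  m <- length(cl_sizes)
  if (m < 2L) stop("at least 2 clusters are required")
  if (m < 10L) {
    warning("only ", m, " clusters: the sandwich variance estimator is ",
            "unreliable with so few clusters")
  }

  qrX <- qr(X)
  if (qrX$rank < p) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("design matrix is singular; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(qrX, y)

  alpha <- 0
  n_pairs <- sum(cl_sizes * (cl_sizes - 1) / 2)
  converged <- FALSE
  iter <- 0L
  phi <- NA_real_

  # Exchangeable working correlation R = (1-a)I + aJ has the closed-form
  # inverse (1/(1-a)) * (I - c J) with c = a / (1 + (n_i - 1) a), so all
  # cluster solves reduce to column sums; the scalar factors cancel in both
  # the coefficient solve and the sandwich.
  repeat {
    iter <- iter + 1L
    e <- as.numeric(y - X %*% beta)
    phi <- sum(e^2) / (n - p)
    if (working_corr == "exchangeable" && n_pairs > 0) {
      cl_sum_e <- rowsum(e, f, reorder = FALSE)[, 1L]
      cl_sum_e2 <- rowsum(e^2, f, reorder = FALSE)[, 1L]
      num <- sum((cl_sum_e^2 - cl_sum_e2) / 2)
      denom <- phi * max(n_pairs - p, 1)
      alpha <- min(max(num / denom, 0), 0.99)
    } else {
      alpha <- 0
    }
    cc <- alpha / (1 + (cl_sizes - 1) * alpha)   # per-cluster shrink factor
    S <- rowsum(X, f, reorder = FALSE)           # per-cluster column sums
    u <- rowsum(y, f, reorder = FALSE)[, 1L]
    A <- crossprod(X) - crossprod(S, cc * S)
    b <- crossprod(X, y) - crossprod(S, cc * u)
    beta_new <- drop(solve(A, b))
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  if (!converged) {
    warning("GEE did not converge in ", max_iter, " iterations ",
            "(last max coefficient change ", format(delta), ")")
  }

  e <- as.numeric(y - X %*% beta)
  cc <- alpha / (1 + (cl_sizes - 1) * alpha)
  S <- rowsum(X, f, reorder = FALSE)
  u_e <- rowsum(e, f, reorder = FALSE)[, 1L]
  A <- crossprod(X) - crossprod(S, cc * S)
  # G[i, ] = X_i' V_i^{-1} e_i (up to the cancelling scalar factors)
  G <- rowsum(X * e, f, reorder = FALSE) - (cc * u_e) * S
  meat <- crossprod(G)
  bread <- solve(A)
  V <- bread %*% meat %*% bread
  V <- (V + t(V)) / 2

  se <- sqrt(pmax(diag(V), 0))
  names(beta) <- names(se) <- colnames(X)
  ci <- cbind(lo = beta - 1.96 * se, hi = beta + 1.96 * se)
  rownames(ci) <- colnames(X)

  structure(list(coefficients = beta, robust_se = se, ci95 = ci, vcov = V,
                 n_records = n, n_clusters = m, working_corr = working_corr,
                 alpha_hat = if (working_corr == "exchangeable") alpha
                             else NA_real_,
                 dispersion = phi, converged = converged, n_iter = iter),
            class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  cat("Gaussian GEE (", x$working_corr, " working correlation)\n", sep = "")
  cat(x$n_records, "records in", x$n_clusters, "clusters")
  if (!is.na(x$alpha_hat)) {
    cat("; alpha_hat =", formatC(x$alpha_hat, digits = 3, format = "f"))
  }
  cat("\n")
  if (!x$converged) cat("WARNING: fit did not converge\n")
  tab <- data.frame(estimate = x$coefficients, robust_se = x$robust_se,
                    ci_lo = x$ci95[, "lo"], ci_hi = x$ci95[, "hi"])
  print(round(tab, 3))
  invisible(x)
}

#' Fit the dAUC meta-regression on derived validation records
#'
#' Convenience wrapper: [build_design()] then [fit_gee()].
#'
#' @param records See [build_design()].
#' @param ... Passed to [fit_gee()] (`working_corr`, `tol`, `max_iter`).
#' @return A `gee_fit`.
#' @export
gee_dauc <- function(records, ...) {
  d <- build_design(records)
  fit_gee(d$y, d$X, d$clusters, ...)
}

#' Format a GEE fit as a term/estimate/CI report table
#'
#' Percent-scale estimates with 95% confidence intervals, annotated with the
#' reference level each indicator is contrasted against. An unconverged fit
#' carries a visible warning column.
#'
#' @param fit A `gee_fit`.
#' @return A data frame with columns `term`, `estimate`, `ci_lo`, `ci_hi`,
#'   `reference`, and `warning` when the fit did not converge.
#' @export
table4_report <- function(fit) {
  stopifnot(inherits(fit, "gee_fit"))
  refs <- c(intercept = "low RoB, similar design",
            rob_high = "vs low RoB", rob_unclear = "vs low RoB",
            design_cohort_to_trial = "vs similar design",
            design_trial_to_cohort = "vs similar design")
  terms <- names(fit$coefficients)
  out <- data.frame(term = terms,
                    estimate = unname(fit$coefficients),
                    ci_lo = unname(fit$ci95[, "lo"]),
                    ci_hi = unname(fit$ci95[, "hi"]),
                    reference = unname(refs[terms]),
                    stringsAsFactors = FALSE)
  if (!fit$converged) {
    out$warning <- "fit did not converge; estimates unreliable"
  }
  out
}
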