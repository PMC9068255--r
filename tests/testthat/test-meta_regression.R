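test_that("design building codes indicators against low/similar references", {
  recs <- make_derived_records(3, dauc_pct = c(1, 2, 3),
                               model_id = c("a", "b", "c"))
  d <- suppressWarnings(build_design(recs))
  expect_equal(colnames(d$X), "intercept")  # all low/similar collapses

  recs2 <- make_derived_records(4, dauc_pct = 1:4,
                                overall_rob = c("L", "H", "L", "L"),
                                design_similarity = c("similar", "similar",
                                                      "cohort_to_trial",
                                                      "trial_to_cohort"),
                                model_id = letters[1:4])
  d2 <- suppressWarnings(build_design(recs2))
  expect_equal(ncol(d2$X), 4L)  # rob_unclear absent, dropped with warning
  expect_equal(unname(d2$X[2, "rob_high"]), 1)
  expect_equal(sum(d2$X[, "rob_high"]), 1)
  expect_warning(build_design(recs2), "rob_unclear")

  recs3 <- make_derived_records(
    10, dauc_pct = rnorm(10),
    overall_rob = rep(c("L", "H", "U", "L", "H"), 2),
    design_similarity = rep(c("similar", "cohort_to_trial",
                              "trial_to_cohort", "trial_to_cohort",
                              "similar"), 2),
    model_id = rep(letters[1:5], 2))
  d3 <- build_design(recs3)
  expect_equal(ncol(d3$X), 5L)
  expect_equal(qr(d3$X)$rank, 5L)

  bad <- recs3
  bad$dauc_pct[1] <- NA
  expect_error(build_design(bad), "missing")
})

test_that("with one record per cluster the GEE equals ordinary least squares", {
  set.seed(101)
  n <- 60
  X <- cbind(intercept = 1, x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
  y <- drop(X %*% c(2, -1.5, 0.7)) + rnorm(n)
  ols <- qr.coef(qr(X), y)
  for (wc in c("independence", "exchangeable")) {
    fit <- fit_gee(y, X, clusters = seq_len(n), working_corr = wc)
    expect_true(fit$converged)
    expect_equal(fit$coefficients, ols, tolerance = 1e-8)
  }
})

test_that("balanced one-factor data recovers the closed-form group-mean difference", {
  set.seed(102)
  g <- rep(c(0, 1), each = 25)
  y <- 3 + 5 * g + rnorm(50)
  X <- cbind(intercept = 1, grp = g)
  fit <- fit_gee(y, X, clusters = seq_along(y),
                 working_corr = "independence")
  expect_equal(unname(fit$coefficients["grp"]),
               mean(y[g == 1]) - mean(y[g == 0]), tolerance = 1e-10)
})

test_that("robust variance matches the reference cluster-sandwich on independence fits", {
  skip_if_not_installed("sandwich")
  set.seed(103)
  cl <- rep(1:25, times = sample(1:6, 25, replace = TRUE))
  n <- length(cl)
  X <- cbind(intercept = 1, x = rnorm(n))
  y <- 1 + 0.5 * X[, "x"] + rnorm(25)[cl] + rnorm(n)
  fit <- fit_gee(y, X, cl, working_corr = "independence")
  m <- stats::lm(y ~ x, data = data.frame(y = y, x = X[, "x"]))
  V_ref <- sandwich::vcovCL(m, cluster = cl, type = "HC0", cadjust = FALSE)
  expect_equal(unname(fit$coefficients), unname(coef(m)), tolerance = 1e-10)
  expect_equal(unname(fit$vcov), unname(V_ref), tolerance = 1e-8)
})

test_that("sandwich diagonal is nonnegative and fits ignore record order", {
  set.seed(104)
  for (rep in 1:5) {
    cl <- sample(1:12, 60, replace = TRUE)
    X <- cbind(intercept = 1, x = rnorm(60), z = rbinom(60, 1, 0.5))
    y <- drop(X %*% c(1, 2, -1)) + rnorm(12, sd = 2)[cl] + rnorm(60)
    fit <- fit_gee(y, X, cl)
    expect_true(all(diag(fit$vcov) >= 0))
    perm <- sample(60)
    fit_p <- fit_gee(y[perm], X[perm, ], cl[perm])
    expect_equal(fit_p$coefficients, fit$coefficients, tolerance = 1e-6)
    expect_equal(fit_p$robust_se, fit$robust_se, tolerance = 1e-6)
    expect_equal(fit_p$alpha_hat, fit$alpha_hat, tolerance = 1e-6)
  }
})

test_that("confidence intervals are estimate plus/minus 1.96 robust SE", {
  set.seed(105)
  X <- cbind(intercept = 1, x = rnorm(40))
  y <- 1 + X[, "x"] + rnorm(40)
  fit <- fit_gee(y, X, rep(1:20, each = 2))
  expect_equal(fit$ci95[, "lo"], fit$coefficients - 1.96 * fit$robust_se)
  expect_equal(fit$ci95[, "hi"], fit$coefficients + 1.96 * fit$robust_se)
  expect_true(fit$alpha_hat >= 0 && fit$alpha_hat < 1)
  expect_lte(fit$n_clusters, fit$n_records)
})

test_that("singular designs are rejected naming the collinear columns", {
  set.seed(106)
  X <- cbind(intercept = 1, a = rep(1:0, 10), b = rep(1:0, 10))
  y <- rnorm(20)
  expect_error(fit_gee(y, X, rep(1:10, each = 2)), "collinear.*b")
})

test_that("few clusters trigger a reliability warning", {
  set.seed(107)
  X <- cbind(intercept = 1, x = rnorm(12))
  y <- rnorm(12)
  expect_warning(fit_gee(y, X, rep(1:4, each = 3)), "clusters")
})

test_that("exchangeable correlation is recovered from correlated clusters", {
  set.seed(108)
  m <- 300
  size <- 5
  rho <- 0.4
  sd_tot <- 8
  cl <- rep(seq_len(m), each = size)
  X <- cbind(intercept = 1, x = rnorm(m * size))
  u <- rnorm(m, sd = sd_tot * sqrt(rho))[cl]
  y <- drop(X %*% c(2, 1)) + u + rnorm(m * size, sd = sd_tot * sqrt(1 - rho))
  fit <- fit_gee(y, X, cl, working_corr = "exchangeable")
  expect_true(fit$converged)
  expect_equal(fit$alpha_hat, rho, tolerance = 0.06)
})

test_that("coefficient bias shrinks as the number of clusters grows", {
  truth <- c(intercept = 9, rob_high = -30, rob_unclear = -13,
             design_cohort_to_trial = -18, design_trial_to_cohort = 0)
  bias_at <- function(m, reps, seed) {
    set.seed(seed)
    est <- replicate(reps, {
      sim <- simulate_dauc_effects(n_clusters = m, cluster_size = 6,
                                   beta = truth, sigma_u = 5, sigma_e = 10)
      fit_gee(sim$y, sim$X, sim$clusters)$coefficients["rob_high"]
    })
    abs(mean(est) - truth["rob_high"])
  }
  b <- c(bias_at(20, 40, 1), bias_at(80, 40, 2), bias_at(320, 40, 3))
  # consistent estimator: bias at 320 clusters well under the small-m noise
  expect_lt(b[3], 1.0)
  expect_lt(b[3], b[1] + 1.0)
})

test_that("the report table annotates references and flags non-convergence", {
  set.seed(110)
  recs <- make_derived_records(
    40, dauc_pct = rnorm(40, sd = 10),
    overall_rob = sample(c("L", "H", "U"), 40, TRUE),
    design_similarity = sample(c("similar", "cohort_to_trial",
                                 "trial_to_cohort"), 40, TRUE),
    model_id = rep(sprintf("m%02d", 1:20), each = 2))
  fit <- gee_dauc(recs)
  tab <- table4_report(fit)
  expect_equal(tab$term[1], "intercept")
  expect_equal(tab$reference[tab$term == "rob_high"], "vs low RoB")
  expect_null(tab$warning)
  unconv <- fit
  unconv$converged <- FALSE
  expect_match(table4_report(unconv)$warning[1], "not converge")
})
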