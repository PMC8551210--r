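test_that("the intercept-only median fit returns the sample median minimizer", {
  des <- list(X = matrix(1, 3, 1, dimnames = list(NULL, "(Intercept)")),
              y = c(1, 2, 10))
  fit <- fit_quantile(des, taus = 0.5)
  expect_identical(unname(fit$coefficients[1, 1]), 2)
})

test_that("exact linear data are interpolated at every quantile with zero loss", {
  x <- c(-2, -1, 0, 1, 2, 3)
  des <- list(X = cbind(`(Intercept)` = 1, x = x), y = 3 + 2 * x)
  fit <- fit_quantile(des, taus = c(0.1, 0.3, 0.5, 0.7, 0.9))
  for (k in seq_along(fit$taus)) {
    expect_equal(unname(fit$coefficients[, k]), c(3, 2), tolerance = 1e-9)
  }
  expect_equal(max(fit$loss), 0, tolerance = 1e-9)
  ols <- fit_ols_reference(des)
  expect_equal(ols$estimate, c(3, 2), tolerance = 1e-10)
})

test_that("fitted check loss matches the brute-force subset oracle on small problems", {
  set.seed(10)
  worst <- 0
  for (i in 1:40) {
    n <- sample(6:12, 1)
    p <- sample(1:3, 1)
    X <- cbind(1, matrix(stats::rnorm(n * 2), n))[, seq_len(p), drop = FALSE]
    y <- stats::rnorm(n)
    tau <- sample(c(0.1, 0.25, 0.5, 0.75, 0.9), 1)
    fit <- mobflow:::fit_one_tau(X, y, tau)
    worst <- max(worst, abs(fit$loss - oracle_quantile_loss(X, y, tau)))
  }
  expect_lt(worst, 1e-6)
})

test_that("coefficients scale with the response (equivariance)", {
  set.seed(11)
  X <- cbind(1, stats::rnorm(40))
  y <- stats::rnorm(40)
  f1 <- mobflow:::fit_one_tau(X, y, 0.3)
  f2 <- mobflow:::fit_one_tau(X, 5 * y, 0.3)
  expect_equal(f2$coefficients, 5 * f1$coefficients, tolerance = 1e-7)
})

test_that("intercept-only fitted values are non-decreasing in tau", {
  set.seed(12)
  y <- stats::rnorm(37)
  des <- list(X = matrix(1, 37, 1), y = y)
  fit <- fit_quantile(des, taus = c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9))
  expect_true(all(diff(fit$coefficients[1, ]) >= -1e-10))
})

test_that("the regression design has the documented block structure", {
  sc <- generate_scenario(scenario_config(n_llms = 150, seed = 5),
                          components = "socioeconomic")
  std <- standardize_features(assemble_features(sc))
  ind <- simulate_linear_indicator(std$std, c(income_per_capita = 0.2),
                                   seed = 1)
  des <- build_design(std$std, ind, indicator_col = "indicator")
  expect_identical(ncol(des$X), 59L)
  expect_identical(colnames(des$X)[1], "(Intercept)")
  # reference-area rows carry zero dummies and zero interactions
  ft <- merge(std$std, data.table::as.data.table(ind), by = "llm_id")
  data.table::setkey(ft, NULL)
  ref_rows <- which(ft$macroarea[match(des$llm_id, ft$llm_id)] == "north_west")
  zcols <- grep("^area_", colnames(des$X))
  expect_true(all(des$X[ref_rows, zcols] == 0))
  # dummy column sums equal the per-area observation counts
  counts <- table(ft$macroarea[match(des$llm_id, ft$llm_id)])
  for (a in setdiff(names(counts), "north_west")) {
    expect_identical(sum(des$X[, paste0("area_", a)]), as.numeric(counts[[a]]))
  }
  # interaction columns are products of their parents
  s1 <- des$interaction_sectors[1]
  a1 <- setdiff(names(counts), "north_west")[1]
  expect_equal(des$X[, paste0("area_", a1, ":rpe_", s1)],
               des$X[, paste0("area_", a1)] * des$X[, paste0("rpe_", s1)])
  expect_error(build_design(std$std, ind, indicator_col = "indicator",
                            interaction_sectors = c("S01", "S99")), "S99")
})

test_that("a duplicated column is reported as collinear", {
  set.seed(13)
  X <- cbind(`(Intercept)` = 1, a = stats::rnorm(30))
  X <- cbind(X, dup = X[, "a"])
  expect_error(fit_ols_reference(list(X = X, y = stats::rnorm(30))),
               "collinear")
})

test_that("wild bootstrap is deterministic, zero on exact fits, and near asymptotic SEs", {
  x <- stats::rnorm(20)
  des0 <- list(X = cbind(1, x = x), y = 1 + 2 * x)
  f0 <- fit_quantile(des0, taus = 0.5)
  b0 <- wild_bootstrap_se(f0, n_reps = 50, seed = 4)
  expect_lt(max(b0$se), 1e-10)

  set.seed(14)
  n <- 500
  X <- cbind(`(Intercept)` = 1, a = stats::rnorm(n), b = stats::rnorm(n),
             c = stats::rnorm(n))
  ratios <- c()
  for (seed in 1:10) {
    set.seed(seed + 100)
    y <- as.numeric(X %*% c(1, 0.5, -0.2, 0)) + stats::rnorm(n)
    des <- list(X = X, y = y)
    fit <- fit_quantile(des, taus = c(0.3, 0.7))
    bs <- wild_bootstrap_se(fit, n_reps = 200, seed = seed)
    bs2 <- wild_bootstrap_se(fit, n_reps = 200, seed = seed)
    expect_identical(bs$se, bs2$se)
    ratios <- c(ratios, as.numeric(bs$se / fit$se))
  }
  expect_lt(abs(mean(ratios) - 1), 0.25)
})

test_that("OLS matches the median slope under symmetric noise", {
  set.seed(15)
  n <- 800
  x <- stats::rnorm(n)
  y <- 1 + 0.7 * x + stats::rnorm(n)
  des <- list(X = cbind(`(Intercept)` = 1, x = x), y = y)
  fit <- fit_quantile(des, taus = 0.5)
  ols <- fit_ols_reference(des)
  expect_lt(abs(fit$coefficients["x", 1] - ols$estimate[2]),
            3 * ols$se[2])
})

test_that("working information criteria are finite and ordered by sample size", {
  set.seed(16)
  des <- list(X = cbind(1, stats::rnorm(60)), y = stats::rnorm(60))
  fit <- fit_quantile(des, taus = c(0.25, 0.75))
  expect_true(all(is.finite(fit$working_ic$aic)))
  expect_true(all(fit$working_ic$bic >= fit$working_ic$aic))
})
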