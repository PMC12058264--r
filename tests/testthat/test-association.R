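test_that("a perfect linear relationship is fit exactly", {
  res <- suppressWarnings(fit_ols(c(1, 2, 3), data.frame(x = c(1, 2, 3))))
  expect_equal(res$beta[res$term == "x"], 1, tolerance = 1e-12)
  expect_equal(res$beta[res$term == "(Intercept)"], 0, tolerance = 1e-12)
})

test_that("fit_ols matches the normal-equations oracle on random designs", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(10:50, 1)
    k <- sample(1:6, 1)
    X <- as.data.frame(matrix(rnorm(n * k), n, k))
    names(X) <- paste0("x", seq_len(k))
    y <- rnorm(n)
    got <- fit_ols(y, X)
    want <- ols_oracle(y, X)
    expect_equal(got$beta, want$beta, tolerance = 1e-10)
    expect_equal(got$se, want$se, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
    expect_equal(got$ci_low, want$ci_low, tolerance = 1e-10)
    expect_equal(got$ci_high, want$ci_high, tolerance = 1e-10)
  }

  # the specific 4-point example
  got <- fit_ols(c(1, 2, 2, 4), data.frame(x = c(1, 2, 3, 4)))
  want <- ols_oracle(c(1, 2, 2, 4), data.frame(x = c(1, 2, 3, 4)))
  expect_equal(got$beta, want$beta, tolerance = 1e-10)
  expect_equal(got$ci_low, want$ci_low, tolerance = 1e-10)
})

test_that("row order does not affect the fit and rank deficiency is named", {
  set.seed(7)
  X <- data.frame(x1 = rnorm(20), x2 = rnorm(20))
  y <- rnorm(20)
  perm <- sample(20)
  a <- fit_ols(y, X)
  b <- fit_ols(y[perm], X[perm, ])
  expect_equal(a, b, ignore_attr = TRUE)

  X$x3 <- 2 * X$x1  # exactly collinear
  expect_error(fit_ols(y, X), "collinear.*x3")
})

test_that("complete cases are used and reported as n", {
  set.seed(8)
  X <- data.frame(x = rnorm(30))
  y <- rnorm(30)
  y[c(2, 5)] <- NA
  X$x[9] <- NA
  res <- fit_ols(y, X)
  expect_equal(attr(res, "n"), 27)
  keep <- !(seq_len(30) %in% c(2, 5, 9))
  expect_equal(res$beta, fit_ols(y[keep], X[keep, , drop = FALSE])$beta)
})

test_that("90th-percentile dichotomization uses the type-7 quantile, strictly", {
  f <- dichotomize_at_percentile(1:100, 90)
  expect_equal(attr(f, "threshold"), 90.1)
  expect_equal(sum(f), 10)
  expect_true(all(which(f) == 91:100))

  f10 <- dichotomize_at_percentile(1:10, 90)
  expect_equal(attr(f10, "threshold"), 9.1)
  expect_equal(sum(f10), 1)

  expect_equal(sum(dichotomize_at_percentile(rep(3.3, 12), 90)), 0)

  x <- c(1:20, NA)
  fna <- dichotomize_at_percentile(x, 90)
  expect_true(is.na(fna[21]))

  expect_error(dichotomize_at_percentile(1:100, 0), "between")
  expect_error(dichotomize_at_percentile(1:100, 100), "between")
  expect_error(dichotomize_at_percentile(1:5, 90), "at least 10")
})

test_that("p90 flag rate sits near 10% on continuous scores", {
  set.seed(33)
  for (n in c(200, 1000)) {
    x <- rnorm(n)
    rate <- mean(dichotomize_at_percentile(x, 90))
    expect_gte(rate, 0.09)
    expect_lte(rate, 0.11)
  }
})

test_that("BED conversion follows the linear-quadratic closed form", {
  expect_equal(bed_convert(60, 30), 72)
  expect_equal(bed_convert(55, 20), 70.125)
  expect_equal(bed_convert(60, 30, alpha_beta = 1e9), 60, tolerance = 1e-6)
  expect_error(bed_convert(-5, 10))
  expect_error(bed_convert(50, 0))
})

test_that("Bonferroni thresholds reproduce the endpoint-family display values", {
  expect_equal(bonferroni_threshold(0.05, 14)$threshold, 0.05 / 14)
  expect_equal(bonferroni_threshold(0.05, 14)$display, ".004")
  expect_equal(bonferroni_threshold(0.05, 5)$threshold, 0.01)
  expect_equal(bonferroni_threshold(0.05, 5)$display, ".01")
  expect_equal(bonferroni_threshold(0.05, 7)$display, ".007")
  expect_equal(bonferroni_threshold(0.05, 1)$threshold, 0.05)
  expect_error(bonferroni_threshold(0.05, 0), "at least 1")
})

make_battery_inputs <- function(site, n = 120, seed = 19, gamma = 0) {
  cfg <- simulation_config(n_patients = n, site = site, effect_gamma = gamma,
                           master_seed = seed)
  co <- simulate_cohort(cfg)
  h <- harmonize_dosages(co$panel, co$model)
  scores <- compute_scores(h$panel, co$model)
  summ <- summarize_endpoints(co$records)
  stat <- suppressMessages(compute_stat_scores(summ, site))
  list(scores = scores, stat = stat, summ = summ, cov = co$covariates)
}

test_that("the battery emits the configured family structure per site", {
  inp <- make_battery_inputs("prostate")
  res <- suppressMessages(run_battery(inp$scores, inp$stat, inp$summ,
                                      inp$cov, "prostate"))
  stat_rows <- res[res$outcome == "STAT", ]
  ep_rows <- res[res$outcome != "STAT", ]
  expect_equal(nrow(stat_rows), 16)  # 2 timings x 2 predictors x 2 x 2
  expect_true(all(stat_rows$family_size == 1))
  expect_true(all(stat_rows$alpha_adjusted == 0.05))
  expect_equal(nrow(ep_rows), (14 + 5) * 4)
  expect_true(all(ep_rows$model == "multivariable"))
  acute_ep <- ep_rows[ep_rows$timing == "acute", ]
  expect_true(all(acute_ep$family_size == 14))
  expect_true(all(acute_ep$alpha_adjusted == 0.05 / 14))
  late_ep <- ep_rows[ep_rows$timing == "late", ]
  expect_true(all(late_ep$family_size == 5))
  expect_true(all(late_ep$alpha_adjusted == 0.01))

  # row-level invariants
  expect_true(all(res$ci_low <= res$beta & res$beta <= res$ci_high))
  expect_identical(res$significant, res$p < res$alpha_adjusted)
  expect_true(all(res$n <= 120 & res$n > 0))
})

test_that("the breast late family of 7 endpoints yields the .007 threshold", {
  inp <- make_battery_inputs("breast", seed = 23)
  res <- suppressMessages(run_battery(inp$scores, inp$stat, inp$summ,
                                      inp$cov, "breast"))
  late_ep <- res[res$outcome != "STAT" & res$timing == "late", ]
  expect_equal(sort(unique(late_ep$outcome)),
               sort(site_endpoints("breast", "late")))
  expect_true(all(late_ep$family_size == 7))
  expect_true(all(late_ep$alpha_adjusted == 0.05 / 7))
  expect_equal(bonferroni_threshold(0.05, 7)$display, ".007")
})

test_that("a patient_id mismatch that loses most of the cohort is an error", {
  inp <- make_battery_inputs("prostate", n = 60, seed = 31)
  cov_bad <- inp$cov
  cov_bad$patient_id <- paste0("X", cov_bad$patient_id)
  expect_error(suppressMessages(
    run_battery(inp$scores, inp$stat, inp$summ, cov_bad, "prostate")),
    "mismatch")
})

test_that("null cohorts produce no extreme STAT coefficients", {
  inp <- make_battery_inputs("prostate", n = 300, seed = 47, gamma = 0)
  res <- suppressMessages(run_battery(inp$scores, inp$stat, inp$summ,
                                      inp$cov, "prostate"))
  stat_rows <- res[res$outcome == "STAT", ]
  se <- (stat_rows$ci_high - stat_rows$ci_low) / (2 * 1.96)
  expect_true(all(abs(stat_rows$beta) < 4 * se))
})
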