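test_that("window maxima, baseline and deltas follow the scoring rules", {
  s <- summarize_endpoints(records_from(list(c(-3, 1), c(30, 3), c(200, 2))))
  expect_equal(s$baseline_grade, 1)
  expect_equal(s$acute_max, 3)
  expect_equal(s$late_max, 2)
  expect_equal(s$acute_delta, 2)
  expect_equal(s$late_delta, 1)
})

test_that("empty windows yield absent values, never zero", {
  s <- summarize_endpoints(records_from(list(c(400, 2))))
  expect_true(is.na(s$baseline_grade))
  expect_true(is.na(s$acute_max))
  expect_true(is.na(s$acute_delta))
  expect_equal(s$late_max, 2)
  expect_equal(s$late_delta, 2)  # no baseline: delta falls back to the max
})

test_that("deltas are floored at zero when toxicity improves", {
  s <- summarize_endpoints(records_from(list(c(-1, 2), c(20, 1))))
  expect_equal(s$acute_delta, 0)
})

test_that("the latest baseline record wins and grades outside 0-4 are refused", {
  s <- summarize_endpoints(records_from(list(c(-30, 2), c(-2, 1), c(10, 3))))
  expect_equal(s$baseline_grade, 1)

  bad <- records_from(list(c(10, 5)), patient = "p9", endpoint = "cough")
  expect_error(summarize_endpoints(bad), "p9.*cough.*grade 5")
})

test_that("acute and late windows partition follow-up days 1-730", {
  w <- tox_windows()
  days <- 1:730
  in_acute <- days >= w$acute[1] & days <= w$acute[2]
  in_late <- days >= w$late[1] & days <= w$late[2]
  expect_true(all(xor(in_acute, in_late)))

  # a boundary record lands in exactly one window
  s90 <- summarize_endpoints(records_from(list(c(90, 2))))
  expect_equal(s90$acute_max, 2)
  expect_true(is.na(s90$late_max))
  s91 <- summarize_endpoints(records_from(list(c(91, 2))))
  expect_true(is.na(s91$acute_max))
  expect_equal(s91$late_max, 2)
})

stat_from_grades <- function(grades) {
  # grades: patients x endpoints matrix of acute maxima (no baselines)
  recs <- do.call(rbind, lapply(seq_len(ncol(grades)), function(j) {
    data.frame(patient_id = rownames(grades),
               endpoint = paste0("e", j), day = 30,
               grade = grades[, j], stringsAsFactors = FALSE)
  }))
  summarize_endpoints(recs)
}

test_that("two-patient worked example: z-scores with n-1 sd, zero-variance drop", {
  grades <- matrix(c(2, 0, 1, 1), 2, 2,
                   dimnames = list(c("a", "b"), NULL))
  summ <- stat_from_grades(grades)
  stat <- suppressMessages(compute_stat(summ, c("e1", "e2"), "acute"))
  expect_equal(stat$stat, c(1 / sqrt(2), -1 / sqrt(2)), tolerance = 1e-10)
  expect_equal(attr(stat, "endpoints_dropped")$endpoint, "e2")
  expect_equal(attr(stat, "endpoints_dropped")$reason, "zero_variance")
  expect_equal(mean(stat$stat), 0, tolerance = 1e-10)
})

test_that("STAT averages available z-values per patient under missingness", {
  set.seed(5)
  grades <- matrix(rbinom(20, 4, 0.3), 10, 2,
                   dimnames = list(sprintf("p%02d", 1:10), NULL))
  summ <- stat_from_grades(grades)
  # patient p01 has no record for e2
  summ <- summ[!(summ$patient_id == "p01" & summ$endpoint == "e2"), ]
  stat <- compute_stat(summ, c("e1", "e2"), "acute")

  # independent recomputation from the raw grades
  v1 <- grades[, 1]
  v2 <- grades[-1, 2]
  z1 <- (v1 - mean(v1)) / sd(v1)
  z2 <- (v2 - mean(v2)) / sd(v2)
  expect_equal(stat$stat[stat$patient_id == "p01"], unname(z1["p01"]))
  expect_equal(stat$n_endpoints[stat$patient_id == "p01"], 1L)
  other <- sprintf("p%02d", 2:10)
  expect_equal(stat$stat[match(other, stat$patient_id)],
               unname((z1[other] + z2[other]) / 2))
})

test_that("cohort STAT mean is zero whenever nothing is missing or dropped", {
  set.seed(9)
  for (n in c(4, 25)) {
    grades <- matrix(rbinom(3 * n, 4, runif(1, 0.2, 0.5)), n, 3,
                     dimnames = list(sprintf("p%03d", 1:n), NULL))
    grades[1, ] <- 0
    grades[2, ] <- c(2, 3, 4)  # guarantee every endpoint has variance
    summ <- stat_from_grades(grades)
    stat <- compute_stat(summ, c("e1", "e2", "e3"), "acute")
    expect_equal(nrow(attr(stat, "endpoints_dropped")), 0)
    expect_equal(mean(stat$stat), 0, tolerance = 1e-10)
  }
})

test_that("STAT is invariant to shifting or rescaling one endpoint's values", {
  set.seed(13)
  grades <- matrix(rbinom(40, 3, 0.4), 20, 2,
                   dimnames = list(sprintf("p%02d", 1:20), NULL))
  grades[1, ] <- 3  # ensure variance
  summ <- stat_from_grades(grades)
  base <- compute_stat(summ, c("e1", "e2"), "acute")

  # translation: add 1 to every e1 grade (stay on the 0-4 scale via delta off)
  shifted <- summ
  shifted$acute_max[shifted$endpoint == "e1"] <-
    shifted$acute_max[shifted$endpoint == "e1"] + 1
  s1 <- compute_stat(shifted, c("e1", "e2"), "acute")
  expect_equal(s1$stat, base$stat, tolerance = 1e-12)

  # positive rescaling of one endpoint
  scaled <- summ
  scaled$acute_max[scaled$endpoint == "e2"] <-
    scaled$acute_max[scaled$endpoint == "e2"] * 2.5
  s2 <- compute_stat(scaled, c("e1", "e2"), "acute")
  expect_equal(s2$stat, base$stat, tolerance = 1e-12)
})

test_that("delta engagement requires 80% baseline availability", {
  set.seed(21)
  n <- 20
  recs <- do.call(rbind, lapply(sprintf("p%02d", 1:n), function(p) {
    rbind(records_from(list(c(-5, 1), c(30, sample(0:4, 1))), patient = p))
  }))
  # strip baselines from half the patients -> 50% availability
  half <- recs$day < 0 & recs$patient_id %in% sprintf("p%02d", 1:(n / 2))
  sparse <- recs[!half, ]
  summ <- summarize_endpoints(sparse)
  expect_warning(compute_stat(summ, "e1", "acute", use_delta = "auto"),
                 "baseline")
  stat_auto <- suppressWarnings(
    compute_stat(summ, "e1", "acute", use_delta = "auto"))
  stat_off <- compute_stat(summ, "e1", "acute", use_delta = "off")
  expect_equal(stat_auto$stat, stat_off$stat)

  # full baselines: auto engages the delta
  summ_full <- summarize_endpoints(recs)
  stat_on <- compute_stat(summ_full, "e1", "acute", use_delta = "on")
  stat_auto_full <- compute_stat(summ_full, "e1", "acute")
  expect_equal(stat_auto_full$stat, stat_on$stat)
})

test_that("default synthetic cohorts produce right-skewed STAT distributions", {
  cfg <- simulation_config(n_patients = 400, site = "prostate",
                           master_seed = 77)
  co <- simulate_cohort(cfg)
  summ <- summarize_endpoints(co$records)
  stat <- compute_stat_scores(summ, "prostate")
  skew <- function(x) mean((x - mean(x))^3) / sd(x)^3
  expect_gt(skew(stat$stat_acute), 0)
  expect_gt(skew(stat$stat_late), 0)
})
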