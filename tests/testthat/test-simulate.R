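test_that("generators are pure functions of their seeds", {
  m1 <- draw_risk_model(101, seed = 1)
  m2 <- draw_risk_model(101, seed = 1)
  expect_identical(m1, m2)
  expect_false(identical(m1, draw_risk_model(101, seed = 2)))
  expect_true(all(m1$odds_ratio > 0.6 & m1$odds_ratio < 1.7))
  expect_true(all(m1$eaf > 0.05 & m1$eaf < 0.95))
  expect_false(any(.complement[m1$risk_allele] == m1$other_allele))

  p1 <- draw_genotypes(m1, 50, imputation_noise_sd = 0.05, seed = 3)
  p2 <- draw_genotypes(m1, 50, imputation_noise_sd = 0.05, seed = 3)
  expect_identical(p1, p2)

  prs <- rnorm(10)
  r1 <- draw_toxicity(prs, draw_covariates("lung", 10, seed = 4),
                      simulation_config(n_patients = 10, site = "lung"),
                      seed = 5)
  r2 <- draw_toxicity(prs, draw_covariates("lung", 10, seed = 4),
                      simulation_config(n_patients = 10, site = "lung"),
                      seed = 5)
  expect_identical(r1, r2)

  c1 <- simulate_cohort(simulation_config(n_patients = 20, master_seed = 9))
  c2 <- simulate_cohort(simulation_config(n_patients = 20, master_seed = 10))
  expect_false(identical(c1$panel$dosage, c2$panel$dosage))
})

test_that("a single-variant model scores a homozygous carrier as 2", {
  m <- draw_risk_model(1, seed = 7)
  panel <- dosage_panel(matrix(2), data.frame(
    variant_id = m$variant_id, chrom = m$chrom, pos = m$pos,
    allele_a = m$other_allele, allele_b = m$risk_allele,
    stringsAsFactors = FALSE), sample_ids = "s1")
  s <- compute_scores(harmonize_dosages(panel, m)$panel, m)
  expect_equal(s$prs, 2)
})

test_that("odds ratios follow the configured lognormal effect-size scale", {
  set.seed(1)
  ors <- unlist(lapply(1:100, function(i) {
    draw_risk_model(101, seed = 1000 + i)$odds_ratio
  }))
  # lognormal mean: exp(mu + sigma^2/2) = exp(0.005)
  se <- sd(ors) / sqrt(length(ors))
  expect_lt(abs(mean(ors) - exp(0.005)), 4 * se)
})

test_that("genotypes respect Hardy-Weinberg expectations", {
  m <- risk_model(data.frame(
    variant_id = c("hi", "lo"), chrom = c("1", "2"), pos = c(1L, 2L),
    risk_allele = c("G", "A"), other_allele = c("T", "C"),
    odds_ratio = c(1, 1), eaf = c(0.5, 0.05), stringsAsFactors = FALSE))
  panel <- draw_genotypes(m, 10000, imputation_noise_sd = 0, seed = 11)
  g <- panel$dosage

  # mean dosage ~= 2 * eaf within 3 standard errors
  for (j in 1:2) {
    eaf <- m$eaf[j]
    se <- sqrt(2 * eaf * (1 - eaf) / 10000)
    expect_lt(abs(mean(g[, j]) - 2 * eaf), 3 * se)
  }

  # genotype frequencies match HWE proportions (chi-square, alpha = .01)
  counts <- table(factor(g[, 1], levels = 0:2))
  p_hwe <- c(0.25, 0.5, 0.25)
  expect_gt(stats::chisq.test(counts, p = p_hwe)$p.value, 0.01)

  # dosage noise stays inside [0, 2]
  noisy <- draw_genotypes(m, 1000, imputation_noise_sd = 0.2, seed = 12)
  expect_true(all(noisy$dosage >= 0 & noisy$dosage <= 2))
})

test_that("covariate tables carry each site's preselected schema", {
  p <- draw_covariates("prostate", 100, seed = 3)
  expect_true(all(c("patient_id", "age", "diabetes", "prior_surgery",
                    "hormone_therapy", "total_dose", "n_fractions") %in%
                    names(p)))
  expect_false(anyNA(p))

  l <- draw_covariates("lung", 50, seed = 3)
  expect_true(all(c("fev1", "v20_lungs", "v35_esophagus", "technique",
                    "copd") %in% names(l)))
  expect_gte(length(unique(l$technique)), 2)

  b <- draw_covariates("breast", 50, seed = 3)
  expect_true(all(c("bmi", "breast_volume", "postop_infection", "boost") %in%
                    names(b)))

  set.seed(1)
  miss <- draw_covariates("prostate", 2000, seed = 5, missingness = 0.1)
  rate <- mean(is.na(as.matrix(miss[, -1])))
  expect_gt(rate, 0.08)
  expect_lt(rate, 0.12)
})

test_that("toxicity grades are realistic and track a large planted effect", {
  cfg <- simulation_config(n_patients = 2000, site = "lung",
                           effect_gamma = 0, master_seed = 15)
  co <- simulate_cohort(cfg)
  acute <- co$records[co$records$day > 0 & co$records$day <= 90, ]
  expect_gt(mean(acute$grade <= 1), 0.5)
  expect_lt(mean(acute$grade >= 3), 0.05)

  cfg_big <- simulation_config(n_patients = 2000, site = "lung",
                               effect_gamma = 2, master_seed = 15)
  co_big <- simulate_cohort(cfg_big)
  summ <- summarize_endpoints(co_big$records)
  amax <- summ$acute_max[summ$endpoint == "cough"]
  ids <- summ$patient_id[summ$endpoint == "cough"]
  prs_std <- co_big$truth$prs_std[match(ids, co_big$truth$sample_id)]
  expect_gt(cor(prs_std, amax, method = "spearman"), 0.5)
})

test_that("VCF and TSV serializations score identically, and truth matches", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_patients = 40, n_variants = 25,
                           imputation_noise_sd = 0, master_seed = 21)
  co <- generate_cohort(cfg, dir)
  expect_true(all(file.exists(unlist(co$paths))))

  model <- suppressMessages(load_risk_model(co$paths$risk_model))
  p_vcf <- read_dosage_vcf(co$paths$genotypes_vcf)
  p_tsv <- read_dosage_tsv(co$paths$dosages, co$paths$dosage_alleles)
  s_vcf <- compute_scores(harmonize_dosages(p_vcf, model)$panel, model)
  s_tsv <- compute_scores(harmonize_dosages(p_tsv, model)$panel, model)
  expect_equal(s_vcf$prs, s_tsv$prs, tolerance = 1e-6)
  expect_equal(s_vcf$wprs, s_tsv$wprs, tolerance = 1e-6)

  truth <- jsonlite::read_json(co$paths$truth, simplifyVector = TRUE)
  expect_equal(s_tsv$prs, truth$prs, tolerance = 1e-6)
  expect_equal(s_tsv$wprs, truth$wprs, tolerance = 1e-6)
})

test_that("GT hard calls are summed to dosages when DS is absent", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "1\t100\trs1\tT\tG\t.\tPASS\t.\tGT\t0/1\t1|1",
    "2\t200\trs2\tC\tA\t.\tPASS\t.\tGT\t0/0\t./."
  ), vcf)
  panel <- read_dosage_vcf(vcf)
  expect_equal(unname(panel$dosage["s1", ]), c(1, 0))
  expect_equal(unname(panel$dosage["s2", "rs1"]), 2)
  expect_true(is.na(panel$dosage["s2", "rs2"]))
})
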