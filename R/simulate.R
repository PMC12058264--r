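#' Configuration for a synthetic radiotherapy cohort
#'
#' Bundles every knob of the synthetic-cohort generator. The defaults emulate
#' a mid-sized prospective radiotherapy cohort: 101 independent biallelic
#' risk variants in Hardy-Weinberg proportions, per-site preselected
#' covariates with plausible marginals, and longitudinal CTCAE grades driven
#' by a latent toxicity with right-skewed noise (Gaussian plus centered
#' Gamma), so that most patients score grade 0-1 and few reach grade 3+ and
#' the resulting STAT distributions are right-skewed. `effect_gamma` plants a
#' linear effect of the standardized weighted risk score on the latent
#' toxicity scale; 0 gives a null cohort.
#'
#' @param n_patients Cohort size (>= 2).
#' @param n_variants Number of risk variants (default 101).
#' @param site Treatment site.
#' @param effect_gamma Latent-scale effect per standardized wPRS unit.
#' @param covariate_effects Named numeric vector of latent-scale effects per
#'   standardized covariate column; `NULL` uses per-site defaults.
#' @param grade_thresholds Strictly increasing latent cutpoints mapping the
#'   latent toxicity to CTCAE grades 0-4.
#' @param imputation_noise_sd SD of the Gaussian noise added to hard
#'   genotypes to mimic imputed dosages (clamped to \[0, 2\]).
#' @param ambiguous_fraction Fraction of variants drawn with palindromic
#'   (A/T or C/G) allele pairs.
#' @param covariate_missingness Fraction of covariate cells masked to `NA`.
#' @param baseline_shift Latent intercept of pre-treatment assessments.
#' @param acute_shift,late_shift Latent intercepts of the follow-up windows
#'   (treatment effect on normal tissue).
#' @param master_seed Integer seed; every downstream draw is a pure function
#'   of it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_patients = 500, n_variants = 101,
                              site = c("prostate", "lung", "breast"),
                              effect_gamma = 0, covariate_effects = NULL,
                              grade_thresholds = c(1.0, 2.0, 3.2, 4.5),
                              imputation_noise_sd = 0.05,
                              ambiguous_fraction = 0,
                              covariate_missingness = 0,
                              baseline_shift = -0.8,
                              acute_shift = 0.3, late_shift = -0.1,
                              master_seed = 1) {
  site <- match.arg(site)
  stopifnot(n_patients >= 2, n_variants >= 1,
            all(diff(grade_thresholds) > 0),
            imputation_noise_sd >= 0,
            ambiguous_fraction >= 0, ambiguous_fraction <= 1,
            covariate_missingness >= 0, covariate_missingness < 1)
  if (is.null(covariate_effects)) {
    covariate_effects <- switch(site,
      prostate = c(age = 0.15, bed = 0.25, diabetes = 0.2,
                   hormone_therapy = 0.1),
      lung = c(age = 0.1, bed = 0.2, smoker = 0.2, copd = 0.25,
               v20_lungs = 0.2),
      breast = c(age = 0.1, bmi = 0.15, breast_volume = 0.2, boost = 0.2)
    )
  }
  structure(list(n_patients = as.integer(n_patients),
                 n_variants = as.integer(n_variants), site = site,
                 effect_gamma = effect_gamma,
                 covariate_effects = covariate_effects,
                 grade_thresholds = grade_thresholds,
                 imputation_noise_sd = imputation_noise_sd,
                 ambiguous_fraction = ambiguous_fraction,
                 covariate_missingness = covariate_missingness,
                 baseline_shift = baseline_shift,
                 acute_shift = acute_shift, late_shift = late_shift,
                 master_seed = as.integer(master_seed)),
            class = "simulation_config")
}

# Deterministic sub-seeds so each component draw is independently seeded
# from the master seed (all < 2^31).
derive_seeds <- function(master_seed, n = 4) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Draw a synthetic risk-variant model
#'
#' Generates a biallelic risk model with effect-allele frequencies uniform
#' on (0.05, 0.95) and log odds ratios Normal(0, 0.1) — so ORs concentrate
#' in roughly (0.7, 1.4), the effect-size scale typical of autoimmune GWAS
#' hits. Allele pairs avoid palindromic (A/T, C/G) combinations unless
#' `ambiguous_fraction > 0`.
#'
#' @param n_variants Number of variants (>= 1).
#' @param seed Integer seed; same seed, same model.
#' @param ambiguous_fraction Fraction of palindromic variants.
#' @return A [risk_model()].
#' @export
draw_risk_model <- function(n_variants, seed, ambiguous_fraction = 0) {
  stopifnot(n_variants >= 1)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  risk <- sample(bases, n_variants, replace = TRUE)
  ambiguous <- stats::runif(n_variants) < ambiguous_fraction
  other <- vapply(seq_len(n_variants), function(i) {
    if (ambiguous[i]) return(unname(.complement[risk[i]]))
    sample(setdiff(bases, c(risk[i], .complement[risk[i]])), 1)
  }, character(1))
  pos <- sample.int(1e8, n_variants)  # unique, so chrom:pos keys are unique
  model <- data.frame(
    variant_id = sprintf("rs9%07d", sample.int(9999999L, n_variants)),
    chrom = as.character(sample(1:22, n_variants, replace = TRUE)),
    pos = pos,
    risk_allele = risk,
    other_allele = other,
    odds_ratio = exp(stats::rnorm(n_variants, 0, 0.1)),
    eaf = stats::runif(n_variants, 0.05, 0.95),
    stringsAsFactors = FALSE
  )
  risk_model(model, source_label = sprintf("synthetic_%d_seed%d",
                                           n_variants, seed))
}

#' Draw Hardy-Weinberg genotype dosages for a cohort
#'
#' Hard genotypes at each variant are Binomial(2, eaf), independent across
#' variants (no linkage disequilibrium); imputation uncertainty is mimicked
#' by adding Gaussian noise and clamping to \[0, 2\]. The returned panel is
#' risk-allele oriented (`allele_b` = risk allele), so harmonization against
#' the generating model is the identity.
#'
#' @param model A [risk_model()].
#' @param n_patients Number of samples.
#' @param imputation_noise_sd Dosage noise SD (0 = hard calls).
#' @param seed Integer seed.
#' @param missing_rate Fraction of dosage cells masked to `NA`.
#' @return A [dosage_panel()].
#' @export
draw_genotypes <- function(model, n_patients, imputation_noise_sd = 0,
                           seed = 1, missing_rate = 0) {
  stopifnot(inherits(model, "risk_model"), n_patients >= 1)
  set.seed(seed)
  m <- nrow(model)
  g <- vapply(model$eaf, function(f) stats::rbinom(n_patients, 2, f),
              numeric(n_patients))
  g <- matrix(g, nrow = n_patients, ncol = m)
  if (imputation_noise_sd > 0) {
    g <- g + stats::rnorm(length(g), 0, imputation_noise_sd)
    g <- pmin(pmax(g, 0), 2)
  }
  if (missing_rate > 0) {
    g[stats::runif(length(g)) < missing_rate] <- NA_real_
  }
  variants <- data.frame(variant_id = model$variant_id, chrom = model$chrom,
                         pos = model$pos, allele_a = model$other_allele,
                         allele_b = model$risk_allele,
                         stringsAsFactors = FALSE)
  dosage_panel(g, variants,
               sample_ids = sprintf("P%05d", seq_len(n_patients)))
}

#' Draw per-site clinical covariates
#'
#' Generates every covariate in the site's preselected adjustment set (see
#' [covariate_spec()]) with plausible marginals: ages Normal around the
#' site's typical presentation age, binary comorbidities and treatment flags
#' Bernoulli, dosimetric variables Normal, and prescriptions drawn from a
#' small set of standard fractionation regimens (carried as `total_dose` and
#' `n_fractions` for downstream BED conversion).
#'
#' @param site Treatment site.
#' @param n_patients Number of patients.
#' @param seed Integer seed.
#' @param missingness Fraction of covariate cells masked to `NA`.
#' @return Data frame with `patient_id` and the site's covariates.
#' @export
draw_covariates <- function(site = c("prostate", "lung", "breast"),
                            n_patients, seed = 1, missingness = 0) {
  site <- match.arg(site)
  set.seed(seed)
  n <- n_patients
  pick_regimen <- function(regimens, probs) {
    k <- sample.int(length(regimens), n, replace = TRUE, prob = probs)
    data.frame(total_dose = vapply(regimens[k], `[`, numeric(1), 1),
               n_fractions = vapply(regimens[k], `[`, numeric(1), 2))
  }
  cov <- switch(site,
    prostate = {
      reg <- pick_regimen(list(c(74, 37), c(60, 20), c(36.25, 5)),
                          c(0.45, 0.45, 0.10))
      data.frame(age = round(stats::rnorm(n, 69, 8), 1),
                 diabetes = stats::rbinom(n, 1, 0.15),
                 prior_surgery = stats::rbinom(n, 1, 0.10),
                 hormone_therapy = stats::rbinom(n, 1, 0.50),
                 reg)
    },
    lung = {
      reg <- pick_regimen(list(c(60, 30), c(55, 20), c(66, 33)),
                          c(0.5, 0.3, 0.2))
      data.frame(sex = stats::rbinom(n, 1, 0.6),
                 age = round(stats::rnorm(n, 68, 8), 1),
                 smoker = stats::rbinom(n, 1, 0.7),
                 technique = sample(c("conformal_3d", "arc", "imrt",
                                      "tomotherapy", "sbrt"),
                                    n, replace = TRUE,
                                    prob = c(0.35, 0.25, 0.25, 0.10, 0.05)),
                 fev1 = round(stats::rnorm(n, 65, 15), 1),
                 v20_lungs = round(pmax(stats::rnorm(n, 20, 6), 0), 1),
                 v35_esophagus = round(pmax(stats::rnorm(n, 30, 12), 0), 1),
                 reg,
                 copd = stats::rbinom(n, 1, 0.3))
    },
    breast = {
      reg <- pick_regimen(list(c(40.05, 15), c(50, 25)), c(0.6, 0.4))
      data.frame(age = round(stats::rnorm(n, 60, 9), 1),
                 smoker = stats::rbinom(n, 1, 0.25),
                 cardiovascular_disease = stats::rbinom(n, 1, 0.10),
                 bmi = round(stats::rnorm(n, 27, 5), 1),
                 breast_volume = round(pmax(stats::rnorm(n, 800, 300), 100)),
                 diabetes = stats::rbinom(n, 1, 0.08),
                 postop_infection = stats::rbinom(n, 1, 0.05),
                 boost = stats::rbinom(n, 1, 0.4),
                 reg)
    }
  )
  if (missingness > 0) {
    for (col in names(cov)) {
      cov[[col]][stats::runif(n) < missingness] <- NA
    }
  }
  cbind(patient_id = sprintf("P%05d", seq_len(n)), cov,
        stringsAsFactors = FALSE)
}

# Latent-scale covariate contribution: named effects applied to empirically
# standardized design columns (missing values contribute 0 so a masked cell
# perturbs only that patient).
covariate_term <- function(design_cov, effects) {
  term <- numeric(nrow(design_cov))
  for (nm in names(effects)) {
    if (!nm %in% names(design_cov)) next
    v <- design_cov[[nm]]
    s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) next
    z <- (v - mean(v, na.rm = TRUE)) / s
    z[is.na(z)] <- 0
    term <- term + effects[[nm]] * z
  }
  term
}

#' Draw longitudinal CTCAE toxicity records
#'
#' For every patient, endpoint and scheduled assessment, a latent toxicity
#' \eqn{L = shift + covariate\ term + \gamma \cdot prs_{std} + \epsilon} is
#' drawn with right-skewed noise \eqn{\epsilon = N(0,1) +
#' \Gamma(2, 0.5) - 1} (mean 0), and the CTCAE grade is the number of
#' configured thresholds below L, capped at 4. Baseline assessments (day -7)
#' use `baseline_shift` and no genetic effect; acute visits fall on days 14,
#' 45 and 80 and late visits on days 180, 365, 540 and 720, a fixed schedule
#' that makes window maxima exactly predictable. Records cover the union of
#' the site's acute and late endpoint families.
#'
#' @param prs_std Standardized weighted risk score, one value per patient.
#' @param covariates Output of [draw_covariates()] for the same patients.
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return Long data frame of records (`patient_id`, `endpoint`, `day`,
#'   `grade`) with attribute `latent_acute`, the patients x endpoints matrix
#'   of day-14 latent toxicities (the clean linear readout used for effect-
#'   recovery checks).
#' @export
draw_toxicity <- function(prs_std, covariates, config, seed = 1) {
  stopifnot(inherits(config, "simulation_config"),
            length(prs_std) == nrow(covariates))
  set.seed(seed)
  n <- length(prs_std)
  endpoints <- site_endpoints(config$site)
  design_cov <- build_design(covariates, config$site)
  cov_term <- covariate_term(design_cov, config$covariate_effects)
  thr <- config$grade_thresholds
  days <- list(baseline = -7L, acute = c(14L, 45L, 80L),
               late = c(180L, 365L, 540L, 720L))
  shifts <- c(baseline = config$baseline_shift, acute = config$acute_shift,
              late = config$late_shift)
  gamma <- c(baseline = 0, acute = config$effect_gamma,
             late = config$effect_gamma)

  skew_noise <- function(k) {
    stats::rnorm(k) + stats::rgamma(k, shape = 2, scale = 0.5) - 1
  }

  recs <- vector("list", length(endpoints))
  latent_acute <- matrix(NA_real_, n, length(endpoints),
                         dimnames = list(covariates$patient_id, endpoints))
  for (e in seq_along(endpoints)) {
    per_window <- lapply(names(days), function(w) {
      d <- days[[w]]
      lat <- matrix(shifts[[w]] + cov_term + gamma[[w]] * prs_std,
                    n, length(d)) + skew_noise(n * length(d))
      list(days = d, latent = lat)
    })
    names(per_window) <- names(days)
    latent_acute[, e] <- per_window$acute$latent[, 1]
    ep_recs <- lapply(per_window, function(pw) {
      grade <- matrix(findInterval(pw$latent, thr), n, length(pw$days))
      data.frame(
        patient_id = rep(covariates$patient_id, times = length(pw$days)),
        endpoint = endpoints[e],
        day = rep(pw$days, each = n),
        grade = as.integer(grade),
        stringsAsFactors = FALSE
      )
    })
    recs[[e]] <- do.call(rbind, ep_recs)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  attr(out, "latent_acute") <- latent_acute
  out
}

#' Simulate a complete cohort in memory
#'
#' Draws a risk model, genotype dosages, covariates and toxicity records
#' from a [simulation_config()], computes the true per-sample scores, and
#' returns everything as one bundle. Component seeds are derived
#' deterministically from `master_seed`, so the whole cohort is a pure
#' function of the configuration.
#'
#' @param config A [simulation_config()].
#' @param model Optional pre-drawn [risk_model()] to reuse across cohorts
#'   (a study has one risk model; replicate simulations redraw only the
#'   cohort).
#' @return List: `config`, `model`, `panel`, `covariates`, `records`,
#'   `truth` (seeds, effect, true `prs`/`wprs`/`prs_std`, `latent_acute`).
#' @export
simulate_cohort <- function(config, model = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  seeds <- derive_seeds(config$master_seed, 4)
  if (is.null(model)) {
    model <- draw_risk_model(config$n_variants, seeds[1],
                             config$ambiguous_fraction)
  }
  panel <- draw_genotypes(model, config$n_patients,
                          config$imputation_noise_sd, seeds[2])
  covariates <- draw_covariates(config$site, config$n_patients, seeds[3],
                                config$covariate_missingness)
  stopifnot(identical(panel$sample_ids, covariates$patient_id))
  prs <- rowSums(panel$dosage)
  wprs <- as.numeric(panel$dosage %*% model$odds_ratio)
  prs_std <- as.numeric(scale(wprs))
  records <- draw_toxicity(prs_std, covariates, config, seeds[4])
  truth <- list(seeds = seeds, effect_gamma = config$effect_gamma,
                sample_id = panel$sample_ids, prs = prs, wprs = wprs,
                prs_std = prs_std,
                latent_acute = attr(records, "latent_acute"))
  attr(records, "latent_acute") <- NULL
  list(config = config, model = model, panel = panel,
       covariates = covariates, records = records, truth = truth)
}

#' Generate a cohort and write every pipeline input to disk
#'
#' Materializes a simulated cohort as the plain-text files the pipeline
#' consumes — risk model TSV, genotype dosages as both a VCF (DS FORMAT
#' field) and a TSV with an allele sidecar, long-format toxicity TSV,
#' covariate TSV — plus `truth.json` recording the component seeds, the
#' planted effect and the true per-sample scores.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the in-memory cohort bundle with a `paths` element.
#' @export
generate_cohort <- function(config, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory ", out_dir)
  }
  cohort <- simulate_cohort(config)
  paths <- list(
    risk_model = file.path(out_dir, "risk_model.tsv"),
    genotypes_vcf = file.path(out_dir, "genotypes.vcf"),
    dosages = file.path(out_dir, "dosages.tsv"),
    dosage_alleles = file.path(out_dir, "dosage_alleles.tsv"),
    toxicity = file.path(out_dir, "toxicity.tsv"),
    covariates = file.path(out_dir, "covariates.tsv"),
    truth = file.path(out_dir, "truth.json")
  )
  write_risk_model(cohort$model, paths$risk_model)
  write_dosage_vcf(cohort$panel, paths$genotypes_vcf)
  write_dosage_tsv(cohort$panel, paths$dosages, paths$dosage_alleles)
  utils::write.table(cohort$records, paths$toxicity, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$covariates, paths$covariates, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  truth$latent_acute <- as.data.frame(truth$latent_acute)
  jsonlite::write_json(truth, paths$truth, digits = NA, auto_unbox = TRUE)
  cohort$paths <- paths
  invisible(cohort)
}
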