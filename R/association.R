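#' Ordinary least-squares fit with per-term inference
#'
#' Fits `y` on the supplied predictors by ordinary least squares with an
#' intercept, after complete-case removal of rows with any missing value.
#' Per-term p-values use the t distribution on `n - k` residual degrees of
#' freedom and 95% confidence intervals are `beta +/- t_{0.975, n-k} * se`.
#'
#' @param y Numeric response vector.
#' @param design Data frame (or matrix) of named predictor columns; the
#'   intercept is added automatically.
#' @return Data frame with one row per term (`term`, `beta`, `se`, `t`, `p`,
#'   `ci_low`, `ci_high`), attributes `n` (rows used) and `df_residual`.
#' @export
fit_ols <- function(y, design) {
  design <- as.data.frame(design)
  stopifnot(length(y) == nrow(design))
  dat <- cbind(.y = y, design)
  cc <- stats::complete.cases(dat)
  dat <- dat[cc, , drop = FALSE]
  n <- nrow(dat)
  if (n <= ncol(design) + 1) {
    stop("too few complete cases (", n, ") for ", ncol(design) + 1,
         " model terms")
  }
  fit <- stats::lm(.y ~ ., data = dat)
  coefs <- stats::coef(fit)
  if (anyNA(coefs)) {
    stop("rank-deficient design; collinear term(s): ",
         paste(names(coefs)[is.na(coefs)], collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit, level = 0.95)
  out <- data.frame(
    term = rownames(sm),
    beta = sm[, "Estimate"],
    se = sm[, "Std. Error"],
    t = sm[, "t value"],
    p = sm[, "Pr(>|t|)"],
    ci_low = ci[rownames(sm), 1],
    ci_high = ci[rownames(sm), 2],
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "n") <- n
  attr(out, "df_residual") <- fit$df.residual
  out
}

#' Flag scores above a percentile cutoff
#'
#' Dichotomizes a score vector at its q-th percentile (default 90th, the
#' "highest genetic risk" cutoff) using the linearly interpolated (type 7)
#' sample quantile; a score is flagged only when strictly greater than the
#' threshold. Missing scores yield missing flags.
#'
#' @param scores Numeric vector with at least 10 non-missing values.
#' @param q Percentile in (0, 100), exclusive.
#' @return Logical vector with attribute `threshold`.
#' @export
dichotomize_at_percentile <- function(scores, q = 90) {
  if (length(q) != 1 || !is.finite(q) || q <= 0 || q >= 100) {
    stop("q must lie strictly between 0 and 100")
  }
  if (sum(!is.na(scores)) < 10) {
    stop("need at least 10 non-missing scores to estimate a percentile")
  }
  thr <- unname(stats::quantile(scores, q / 100, na.rm = TRUE, type = 7))
  structure(scores > thr, threshold = thr)
}

#' Biologically effective dose of a fractionated prescription
#'
#' Converts a prescription (total dose D over n equal fractions of d = D/n)
#' to the biologically effective dose of the linear-quadratic model,
#' \deqn{BED = D \left(1 + \frac{d}{\alpha/\beta}\right)}
#' with the acute-responding tissue default alpha/beta = 10 Gy. As
#' alpha/beta grows the fractionation term vanishes and BED approaches D.
#'
#' @param total_dose Total prescribed dose in Gy (> 0); vectorized.
#' @param n_fractions Number of fractions (>= 1); vectorized.
#' @param alpha_beta Alpha/beta ratio in Gy (> 0).
#' @return BED in Gy.
#' @export
#' @examples
#' bed_convert(60, 30)      # 2 Gy/fraction -> 72 Gy
#' bed_convert(55, 20)      # 2.75 Gy/fraction -> 70.125 Gy
bed_convert <- function(total_dose, n_fractions, alpha_beta = 10) {
  stopifnot(all(total_dose > 0), all(n_fractions >= 1),
            all(alpha_beta > 0))
  total_dose * (1 + (total_dose / n_fractions) / alpha_beta)
}

#' Bonferroni-adjusted significance threshold
#'
#' Family-wise error control by dividing the significance level by the
#' number of tests in the endpoint family. The unrounded threshold is used
#' in all comparisons; `display` carries the 3-decimal display form used in
#' reporting (e.g., family sizes 14, 5 and 7 at alpha = .05 display as
#' ".004", ".01" and ".007").
#'
#' @param alpha Family-wise significance level in (0, 1).
#' @param m Family size (number of tests, >= 1).
#' @return List with `threshold` (alpha/m, full precision) and `display`
#'   (3-decimal string, leading zero and trailing zeros stripped).
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  stopifnot(length(alpha) == 1, alpha > 0, alpha < 1)
  if (length(m) != 1 || is.na(m) || m < 1) {
    stop("family size m must be at least 1")
  }
  thr <- alpha / m
  disp <- sprintf("%.3f", thr)
  disp <- sub("0+$", "", disp)
  disp <- sub("^0", "", disp)
  list(threshold = thr, display = disp)
}

# Expand a raw covariate table into numeric model columns per the site's
# preselected adjustment set: dose prescriptions become BED (alpha/beta 10),
# categoricals become reference-coded indicators with the most frequent
# level as reference, binaries become 0/1.
build_design <- function(covariates, site, alpha_beta = 10) {
  spec <- covariate_spec(site)
  out <- data.frame(row.names = seq_len(nrow(covariates)))
  for (i in seq_len(nrow(spec))) {
    nm <- spec$name[i]
    kind <- spec$kind[i]
    if (kind == "dose") {
      need <- c("total_dose", "n_fractions")
      if (!all(need %in% names(covariates))) {
        stop("covariate table lacks ", paste(need, collapse = "/"),
             " needed for the BED covariate")
      }
      out$bed <- bed_convert(covariates$total_dose, covariates$n_fractions,
                             alpha_beta)
    } else if (!nm %in% names(covariates)) {
      stop("covariate table lacks preselected covariate '", nm, "' for site ",
           site)
    } else if (kind == "categorical") {
      v <- as.character(covariates[[nm]])
      tab <- sort(table(v), decreasing = TRUE)
      ref <- names(tab)[1]
      for (lev in setdiff(names(tab), ref)) {
        out[[paste0(nm, "_", lev)]] <-
          ifelse(is.na(v), NA_real_, as.numeric(v == lev))
      }
    } else if (kind == "binary") {
      v <- covariates[[nm]]
      if (is.logical(v)) v <- as.numeric(v)
      if (is.character(v) || is.factor(v)) {
        v <- as.character(v)
        tab <- sort(table(v), decreasing = TRUE)
        v <- ifelse(is.na(v), NA_real_, as.numeric(v != names(tab)[1]))
      }
      if (!all(v[!is.na(v)] %in% 0:1)) {
        stop("binary covariate '", nm, "' is not codable as 0/1")
      }
      out[[nm]] <- as.numeric(v)
    } else {
      out[[nm]] <- as.numeric(covariates[[nm]])
    }
  }
  out
}

#' Run the per-site association battery
#'
#' Reproduces the study's analysis plan for one treatment site. STAT-acute
#' and STAT-late are each regressed on the polygenic risk score and the
#' weighted score, as continuous predictors and dichotomized above the 90th
#' percentile, in univariable models and in multivariable models adjusting
#' for the site's preselected covariates; these overall-toxicity analyses
#' are evaluated at `alpha` with family size 1. Each individual endpoint of
#' the site's acute and late families is then analyzed with multivariable
#' regression only, and its significance threshold is Bonferroni-adjusted by
#' the family size (e.g., 14 acute endpoints for prostate give .05/14).
#' All rows carry the complete-case `n` actually fitted.
#'
#' @param scores A `score_set` from [compute_scores()] (`sample_id` must
#'   match `patient_id` in the clinical tables).
#' @param stat Output of [compute_stat_scores()].
#' @param summaries Output of [summarize_endpoints()].
#' @param covariates Raw covariate table with a `patient_id` column and the
#'   site's preselected variables.
#' @param site Treatment site.
#' @param alpha Family-wise significance level (default .05).
#' @param use_delta Delta policy forwarded to endpoint value selection.
#' @param percentile Dichotomization percentile (default 90).
#' @param endpoints Optional list with `acute` and `late` character vectors
#'   overriding the site's configured endpoint families (and hence the
#'   Bonferroni family sizes).
#' @return Data frame with columns `site`, `outcome`, `timing`, `predictor`,
#'   `transform`, `model`, `n`, `beta`, `ci_low`, `ci_high`, `p`,
#'   `family_size`, `alpha_adjusted`, `significant`.
#' @export
run_battery <- function(scores, stat, summaries, covariates, site,
                        alpha = 0.05, use_delta = c("auto", "on", "off"),
                        percentile = 90, endpoints = NULL) {
  use_delta <- match.arg(use_delta)
  endpoints <- endpoints %||%
    list(acute = site_endpoints(site, "acute"),
         late = site_endpoints(site, "late"))
  if (length(endpoints$acute) == 0 || length(endpoints$late) == 0) {
    stop("endpoint families must be non-empty for site ", site)
  }
  stopifnot("patient_id" %in% names(covariates))
  ids <- scores$sample_id
  joined <- merge(
    merge(data.frame(patient_id = ids, prs = scores$prs,
                     wprs = scores$wprs, stringsAsFactors = FALSE),
          stat, by = "patient_id"),
    covariates, by = "patient_id")
  if (nrow(joined) < 0.5 * length(ids)) {
    stop("joining scores, STAT and covariates kept ", nrow(joined), " of ",
         length(ids), " patients; likely a patient_id mismatch")
  }
  design_cov <- build_design(joined, site)
  predictors <- list(
    prs = joined$prs,
    wprs = joined$wprs
  )
  transforms <- c("continuous", "p90")

  one_fit <- function(y, x, multiv, outcome, timing, pred_name, transform,
                      family_size) {
    design <- if (multiv) cbind(x = x, design_cov) else
      data.frame(x = x)
    res <- tryCatch(fit_ols(y, design), error = function(e) e)
    if (inherits(res, "error")) stop("fit for ", outcome, " (", pred_name,
                                     ", ", transform, ") failed: ",
                                     conditionMessage(res))
    row <- res[res$term == "x", ]
    thr <- bonferroni_threshold(alpha, family_size)$threshold
    data.frame(site = site, outcome = outcome, timing = timing,
               predictor = pred_name, transform = transform,
               model = if (multiv) "multivariable" else "univariable",
               n = attr(res, "n"), beta = row$beta, ci_low = row$ci_low,
               ci_high = row$ci_high, p = row$p,
               family_size = family_size, alpha_adjusted = thr,
               significant = row$p < thr, stringsAsFactors = FALSE)
  }

  rows <- list()
  # STAT analyses: all predictor x transform x model combinations, alpha-level
  for (timing in c("acute", "late")) {
    y <- joined[[paste0("stat_", timing)]]
    for (pred_name in names(predictors)) {
      x_cont <- predictors[[pred_name]]
      for (transform in transforms) {
        x <- if (transform == "p90") {
          as.numeric(dichotomize_at_percentile(x_cont, percentile))
        } else x_cont
        for (multiv in c(FALSE, TRUE)) {
          rows[[length(rows) + 1]] <-
            one_fit(y, x, multiv, "STAT", timing, pred_name, transform,
                    family_size = 1L)
        }
      }
    }
  }
  # Individual endpoints: multivariable only, Bonferroni by family size
  for (timing in c("acute", "late")) {
    family <- endpoints[[timing]]
    vals <- endpoint_values(summaries, family, timing, use_delta)
    vals <- vals[match(joined$patient_id, rownames(vals)), , drop = FALSE]
    for (ep in family) {
      y <- vals[, ep]
      for (pred_name in names(predictors)) {
        x_cont <- predictors[[pred_name]]
        for (transform in transforms) {
          x <- if (transform == "p90") {
            as.numeric(dichotomize_at_percentile(x_cont, percentile))
          } else x_cont
          rows[[length(rows) + 1]] <-
            one_fit(y, x, TRUE, ep, timing, pred_name, transform,
                    family_size = length(family))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write association results to TSV
#'
#' @param results Output of [run_battery()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
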