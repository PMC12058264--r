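#' Toxicity endpoint families per treatment site
#'
#' Returns the configured CTCAE endpoint vocabulary for a treatment site and
#' timing window. These families define the Bonferroni correction applied to
#' individual-endpoint association tests: the prostate acute family has 14
#' endpoints (family-wise threshold .05/14 = .004 at display precision), the
#' prostate and lung late families 5 (.01), and the breast late family 7
#' (.007).
#'
#' @param site One of `"prostate"`, `"lung"`, `"breast"`.
#' @param timing One of `"acute"`, `"late"`. If `NULL`, the union of both
#'   families is returned.
#' @return Character vector of endpoint names.
#' @export
#' @examples
#' site_endpoints("prostate", "acute")  # 14 endpoints
#' site_endpoints("breast", "late")     # 7 endpoints
site_endpoints <- function(site = c("prostate", "lung", "breast"),
                           timing = NULL) {
  site <- match.arg(site)
  fam <- .endpoint_families[[site]]
  if (is.null(timing)) {
    return(unique(c(fam$acute, fam$late)))
  }
  timing <- match.arg(timing, c("acute", "late"))
  fam[[timing]]
}

.endpoint_families <- list(
  prostate = list(
    acute = c("urinary_frequency", "nocturia", "urinary_urgency",
              "hematuria", "urinary_incontinence", "decreased_stream",
              "dysuria", "gi_incontinence", "diarrhea", "gi_urgency",
              "tenesmus", "gi_pain", "rectal_bleeding", "constipation"),
    late = c("proctitis", "rectal_bleeding", "hematuria",
             "urinary_frequency", "urinary_retention")
  ),
  lung = list(
    acute = c("cough", "dyspnea", "pneumonitis", "dysphagia", "esophagitis"),
    late = c("cough", "dyspnea", "pneumonitis", "dysphagia", "esophagitis")
  ),
  breast = list(
    acute = c("erythema", "ulceration"),
    late = c("telangiectasia", "telangiectasia_tumor_bed", "edema",
             "induration", "induration_tumor_bed", "pigmentation", "atrophy")
  )
)

#' Preselected multivariable adjustment variables per site
#'
#' Returns the preselected clinical covariate set entered into every
#' multivariable model for a site, with each covariate's kind. Covariates of
#' kind `"dose"` are supplied as a fractionation prescription (columns
#' `total_dose`, `n_fractions`) and converted to a biologically effective dose
#' with [bed_convert()] (alpha/beta = 10 Gy) before model entry. Categorical
#' covariates enter as reference-coded indicators with the most frequent level
#' as reference.
#'
#' @param site One of `"prostate"`, `"lung"`, `"breast"`.
#' @return A data frame with columns `name` and
#'   `kind` (`"continuous"`, `"binary"`, `"categorical"`, `"dose"`).
#' @export
covariate_spec <- function(site = c("prostate", "lung", "breast")) {
  site <- match.arg(site)
  spec <- switch(site,
    prostate = data.frame(
      name = c("age", "diabetes", "prior_surgery", "hormone_therapy", "dose"),
      kind = c("continuous", "binary", "binary", "binary", "dose")
    ),
    lung = data.frame(
      name = c("sex", "age", "smoker", "technique", "fev1", "v20_lungs",
               "v35_esophagus", "dose", "copd"),
      kind = c("binary", "continuous", "binary", "categorical", "continuous",
               "continuous", "continuous", "dose", "binary")
    ),
    breast = data.frame(
      name = c("age", "smoker", "cardiovascular_disease", "bmi",
               "breast_volume", "diabetes", "postop_infection", "boost"),
      kind = c("continuous", "binary", "binary", "continuous", "continuous",
               "binary", "binary", "binary")
    )
  )
  spec$site <- site
  spec
}
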