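#' Compute polygenic risk scores from harmonized dosages
#'
#' For each sample, the unweighted polygenic risk score is the sum of
#' risk-allele dosages over the model variants retained after harmonization,
#' and the weighted score additionally multiplies each dosage by the
#' variant's per-risk-allele weight:
#' \deqn{PRS_s = \sum_v d_{sv}, \qquad wPRS_s = \sum_v w_v d_{sv}}
#' with \eqn{w_v} the odds ratio itself under `weight_scheme = "or"` (the
#' default) or its natural logarithm under `"log_or"`.
#'
#' Missing dosages are imputed before summation — as `2 * eaf` when the model
#' supplies an effect-allele frequency for the variant, else as the cohort
#' mean dosage at that variant — and counted per sample in
#' `n_dosages_imputed`; the score is never silently rescaled to fewer
#' variants.
#'
#' @param panel A harmonized [dosage_panel()] (as returned by
#'   [harmonize_dosages()]).
#' @param model The [risk_model()] supplying weights (and `eaf` for
#'   imputation).
#' @param weight_scheme `"or"` (weight = odds ratio) or `"log_or"`
#'   (weight = ln odds ratio).
#' @return A `score_set` data frame: `sample_id`, `prs`, `wprs`,
#'   `n_variants_used`, `n_dosages_imputed`.
#' @export
compute_scores <- function(panel, model, weight_scheme = c("or", "log_or")) {
  weight_scheme <- match.arg(weight_scheme)
  stopifnot(inherits(panel, "dosage_panel"), inherits(model, "risk_model"))
  if (!isTRUE(attr(panel, "harmonized"))) {
    stop("panel is not harmonized; run harmonize_dosages() first")
  }
  keep <- match(panel$variants$variant_id, model$variant_id)
  if (anyNA(keep)) {
    stop("panel contains variants absent from the risk model: ",
         paste(panel$variants$variant_id[is.na(keep)], collapse = ", "))
  }
  m <- length(keep)
  if (m == 0) stop("zero retained variants; cannot compute scores")

  dos <- panel$dosage
  n_imputed <- rowSums(is.na(dos))
  if (any(n_imputed > 0)) {
    eaf <- model$eaf[keep]
    col_mean <- colMeans(dos, na.rm = TRUE)
    fill <- ifelse(is.na(eaf), col_mean, 2 * eaf)
    no_fill <- !is.finite(fill)
    if (any(no_fill & colSums(is.na(dos)) > 0)) {
      stop("cannot impute fully missing dosage column(s) without eaf: ",
           paste(panel$variants$variant_id[no_fill], collapse = ", "))
    }
    na_idx <- which(is.na(dos))
    dos[na_idx] <- fill[((na_idx - 1) %/% nrow(dos)) + 1]
  }

  w <- model$odds_ratio[keep]
  if (weight_scheme == "log_or") w <- log(w)
  scores <- data.frame(
    sample_id = panel$sample_ids,
    prs = as.numeric(rowSums(dos)),
    wprs = as.numeric(dos %*% w),
    n_variants_used = m,
    n_dosages_imputed = as.integer(n_imputed),
    stringsAsFactors = FALSE
  )
  structure(scores, class = c("score_set", "data.frame"),
            weight_scheme = weight_scheme)
}

#' Write a score set to TSV
#'
#' @param scores A `score_set` from [compute_scores()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  utils::write.table(as.data.frame(scores), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Compare risk scores between diagnosed and undiagnosed patients
#'
#' Two-sided Mann-Whitney U test of the polygenic risk score between patients
#' with and without a documented diagnosis (e.g., rheumatoid arthritis). The
#' p-value comes from exact enumeration when both groups have at most 8
#' observations and no ties are present, and otherwise from the normal
#' approximation with tie correction and continuity correction.
#'
#' @param scores A `score_set`, or a numeric vector of scores.
#' @param diagnosis Logical vector (one per sample): `TRUE` = diagnosed.
#' @param measure Which score column to test when `scores` is a `score_set`.
#' @return A list: `U` (the smaller of the two group statistics), `p`
#'   (two-sided), `n_diagnosed`, `n_undiagnosed`, `exact`.
#' @export
compare_by_diagnosis <- function(scores, diagnosis,
                                 measure = c("prs", "wprs")) {
  measure <- match.arg(measure)
  x <- if (inherits(scores, "score_set")) scores[[measure]] else
    as.numeric(scores)
  stopifnot(length(diagnosis) == length(x), is.logical(diagnosis))
  ok <- !is.na(x) & !is.na(diagnosis)
  x <- x[ok]; diagnosis <- diagnosis[ok]
  g1 <- x[diagnosis]
  g0 <- x[!diagnosis]
  if (length(g1) == 0 || length(g0) == 0) {
    stop("both diagnosis groups must be non-empty")
  }
  no_ties <- !any(duplicated(c(g0, g1)))
  exact <- length(g0) <= 8 && length(g1) <= 8 && no_ties
  wt <- stats::wilcox.test(g1, g0, alternative = "two.sided",
                           exact = exact, correct = TRUE)
  u1 <- unname(wt$statistic)
  u_min <- min(u1, length(g0) * length(g1) - u1)
  p <- unname(wt$p.value)
  if (is.nan(p)) p <- 1  # zero rank variance (all observations tied)
  list(U = u_min, p = p,
       n_diagnosed = length(g1), n_undiagnosed = length(g0),
       exact = exact)
}
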