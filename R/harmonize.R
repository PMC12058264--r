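#' Construct a sample-by-variant dosage panel
#'
#' A `dosage_panel` holds imputed genotype dosages for a cohort: a numeric
#' matrix with one row per sample and one column per variant, where each
#' value in \[0, 2\] is the expected count of `allele_b` copies and `NA`
#' marks a missing dosage. Values outside \[0, 2\] by at most `clamp_tol`
#' (float serialization noise) are clamped; larger excursions are an error.
#'
#' @param dosage Numeric matrix, samples x variants.
#' @param variants Data frame with columns `variant_id`, `chrom`, `pos`,
#'   `allele_a`, `allele_b` (dosage counts `allele_b`).
#' @param sample_ids Character vector of sample identifiers (defaults to the
#'   matrix rownames).
#' @param harmonized Logical; `TRUE` only when every column's dosage counts
#'   a risk-model risk allele (set by [harmonize_dosages()]).
#' @param clamp_tol Tolerance for clamping out-of-range dosages.
#' @return A `dosage_panel` object.
#' @export
dosage_panel <- function(dosage, variants, sample_ids = rownames(dosage),
                         harmonized = FALSE, clamp_tol = 1e-6) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(sample_ids)) {
    stop("sample_ids are required (no rownames on the dosage matrix)")
  }
  stopifnot(length(sample_ids) == nrow(dosage),
            is.data.frame(variants),
            all(c("variant_id", "chrom", "pos", "allele_a", "allele_b") %in%
                  names(variants)),
            nrow(variants) == ncol(dosage))
  if (anyDuplicated(sample_ids)) stop("duplicate sample_ids in panel")
  low <- dosage < 0 & !is.na(dosage)
  high <- dosage > 2 & !is.na(dosage)
  if (any(dosage[low] < -clamp_tol) || any(dosage[high] > 2 + clamp_tol)) {
    stop("dosage values outside [0, 2] beyond tolerance ", clamp_tol,
         "; the input file looks corrupt")
  }
  dosage[low] <- 0
  dosage[high] <- 2
  dimnames(dosage) <- list(sample_ids, variants$variant_id)
  rownames(variants) <- NULL
  structure(list(dosage = dosage, variants = variants,
                 sample_ids = sample_ids),
            class = "dosage_panel", harmonized = isTRUE(harmonized))
}

#' @export
print.dosage_panel <- function(x, ...) {
  cat("dosage_panel: ", length(x$sample_ids), " samples x ",
      nrow(x$variants), " variants",
      if (isTRUE(attr(x, "harmonized"))) " (harmonized)", "\n", sep = "")
  cat("missing dosages: ", sum(is.na(x$dosage)), "\n", sep = "")
  invisible(x)
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

.is_palindromic <- function(a, b) .complement[a] == b

#' Harmonize genotype dosages to a risk model's risk alleles
#'
#' Reorients a dosage panel so that, for every retained model variant, the
#' dosage counts copies of the model's risk allele. Variants are matched to
#' the panel by `variant_id` first, falling back to `chrom:pos` (ambiguous
#' positional matches are dropped). Each model variant receives exactly one
#' status:
#'
#' * `direct` — panel counts the risk allele already;
#' * `swapped` — panel counts the other allele; dosage becomes `2 - d`;
#' * `strand_flipped` — panel alleles are the reverse complement, counted
#'   allele complements the risk allele; dosage kept;
#' * `strand_flipped_swapped` — reverse complement with alleles swapped;
#'   dosage becomes `2 - d`;
#' * `ambiguous_kept` — palindromic (A/T or C/G) variant retained by
#'   exact-label matching (imputed panels are assumed reference-strand);
#' * `ambiguous_dropped` — palindromic variant removed under
#'   `drop_ambiguous`;
#' * `unmatched_dropped` — absent from the panel or alleles irreconcilable.
#'
#' Dropped variants contribute nothing to downstream scores; all anomalies
#' are statuses and warnings, never errors.
#'
#' @param panel A [dosage_panel()].
#' @param model A [risk_model()].
#' @param drop_ambiguous Drop palindromic variants instead of keeping them by
#'   exact label match.
#' @return A list with `panel` (harmonized `dosage_panel`, columns in model
#'   order for retained variants) and `report` (data frame: `variant_id`,
#'   `status`, `n_missing` dosages among samples).
#' @export
harmonize_dosages <- function(panel, model, drop_ambiguous = FALSE) {
  stopifnot(inherits(panel, "dosage_panel"), inherits(model, "risk_model"))
  pv <- panel$variants
  pv_key <- paste(pv$chrom, pv$pos, sep = ":")
  model_key <- paste(model$chrom, model$pos, sep = ":")

  # panel column index for each model variant: id match, then chrom:pos
  idx <- match(model$variant_id, pv$variant_id)
  pos_idx <- match(model_key, pv_key)
  pos_dup <- model_key %in% pv_key[duplicated(pv_key)]
  use_pos <- is.na(idx) & !is.na(pos_idx) & !pos_dup
  idx[use_pos] <- pos_idx[use_pos]

  n_model <- nrow(model)
  status <- character(n_model)
  flip <- logical(n_model)    # dosage -> 2 - dosage
  comp <- .complement

  for (i in seq_len(n_model)) {
    j <- idx[i]
    if (is.na(j)) {
      status[i] <- "unmatched_dropped"
      next
    }
    risk <- model$risk_allele[i]
    other <- model$other_allele[i]
    a <- pv$allele_a[j]
    b <- pv$allele_b[j]
    if (.is_palindromic(risk, other)) {
      if (drop_ambiguous) {
        status[i] <- "ambiguous_dropped"
      } else if (a == other && b == risk) {
        status[i] <- "ambiguous_kept"
      } else if (a == risk && b == other) {
        status[i] <- "ambiguous_kept"
        flip[i] <- TRUE
      } else {
        status[i] <- "unmatched_dropped"
      }
    } else if (a == other && b == risk) {
      status[i] <- "direct"
    } else if (a == risk && b == other) {
      status[i] <- "swapped"
      flip[i] <- TRUE
    } else if (a == comp[other] && b == comp[risk]) {
      status[i] <- "strand_flipped"
    } else if (a == comp[risk] && b == comp[other]) {
      status[i] <- "strand_flipped_swapped"
      flip[i] <- TRUE
    } else {
      status[i] <- "unmatched_dropped"
    }
  }

  keep <- !status %in% c("ambiguous_dropped", "unmatched_dropped")
  if (!all(keep)) {
    warning(sum(!keep), " of ", n_model,
            " model variants dropped during harmonization (",
            sum(status == "unmatched_dropped"), " unmatched, ",
            sum(status == "ambiguous_dropped"), " ambiguous)")
  }

  dos <- panel$dosage[, idx[keep], drop = FALSE]
  flip_keep <- flip[keep]
  if (any(flip_keep)) {
    dos[, flip_keep] <- 2 - dos[, flip_keep, drop = FALSE]
  }
  variants_out <- data.frame(
    variant_id = model$variant_id[keep],
    chrom = model$chrom[keep],
    pos = model$pos[keep],
    allele_a = model$other_allele[keep],
    allele_b = model$risk_allele[keep],
    stringsAsFactors = FALSE
  )
  out_panel <- dosage_panel(dos, variants_out, sample_ids = panel$sample_ids,
                            harmonized = TRUE)
  n_missing <- integer(n_model)
  n_missing[keep] <- colSums(is.na(dos))
  report <- data.frame(variant_id = model$variant_id, status = status,
                       n_missing = n_missing, stringsAsFactors = FALSE)
  list(panel = out_panel, report = report)
}
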