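#' Load a polygenic risk-variant model from TSV
#'
#' Reads a tab-separated risk-variant table (one row per locus) into a
#' `risk_model` object. The model defines, for each variant, the risk allele
#' whose dosage is summed into the polygenic risk score (PRS) and the
#' per-risk-allele odds ratio used to weight the dosage in the weighted score
#' (wPRS). The packaged 101-variant rheumatoid-arthritis model is available
#' via `system.file("extdata", "ra_synthetic_101.tsv", package = "radiotox")`;
#' it is a synthetic stand-in with the published model's dimensions and
#' effect-size scale.
#'
#' Required columns: `variant_id`, `chrom`, `pos`, `risk_allele`,
#' `other_allele`, `odds_ratio`; optional `eaf` (effect-allele frequency,
#' used to impute sporadically missing dosages as `2 * eaf`).
#'
#' @param path Path to the TSV file (header required).
#' @param source_label Optional label stored on the model.
#' @return A `risk_model`: a data frame of validated variants, in file order.
#' @export
load_risk_model <- function(path, source_label = basename(path)) {
  if (!file.exists(path)) {
    stop("risk model file not found: ", path)
  }
  # read everything as character: allele "T" must never become logical TRUE
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("variant_id", "chrom", "pos", "risk_allele", "other_allele",
                "odds_ratio")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("risk model is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"eaf" %in% names(tab)) tab$eaf <- NA_character_
  tab$pos <- as.integer(tab$pos)
  tab$odds_ratio <- suppressWarnings(as.numeric(tab$odds_ratio))
  tab$eaf <- suppressWarnings(as.numeric(tab$eaf))
  model <- risk_model(tab[c(required, "eaf")], source_label = source_label)
  message("loaded risk model '", source_label, "': ",
          nrow(model), " variants")
  model
}

#' Construct and validate a risk model
#'
#' @param variants Data frame with the columns documented in
#'   [load_risk_model()].
#' @param source_label Label describing the model's origin.
#' @return A validated `risk_model` data frame.
#' @export
risk_model <- function(variants, source_label = "risk_model") {
  stopifnot(is.data.frame(variants))
  if (nrow(variants) == 0) {
    stop("a risk model must contain at least one variant")
  }
  dup <- variants$variant_id[duplicated(variants$variant_id)]
  if (length(dup) > 0) {
    stop("duplicate variant_id in risk model: ",
         paste(unique(dup), collapse = ", "))
  }
  for (col in c("risk_allele", "other_allele")) {
    bad <- !variants[[col]] %in% c("A", "C", "G", "T")
    if (any(bad)) {
      stop("malformed ", col, " (must be one of A/C/G/T) for variant(s): ",
           paste(variants$variant_id[bad], collapse = ", "))
    }
  }
  same <- variants$risk_allele == variants$other_allele
  if (any(same)) {
    stop("risk_allele equals other_allele for variant(s): ",
         paste(variants$variant_id[same], collapse = ", "))
  }
  bad_or <- !is.finite(variants$odds_ratio) | variants$odds_ratio <= 0
  if (any(bad_or)) {
    stop("odds_ratio must be a positive number; offending variant(s): ",
         paste(variants$variant_id[bad_or], collapse = ", "))
  }
  bad_eaf <- !is.na(variants$eaf) &
    (variants$eaf <= 0 | variants$eaf >= 1)
  if (any(bad_eaf)) {
    stop("eaf must lie in (0, 1); offending variant(s): ",
         paste(variants$variant_id[bad_eaf], collapse = ", "))
  }
  rownames(variants) <- NULL
  structure(variants, class = c("risk_model", "data.frame"),
            source_label = source_label)
}

#' Write a risk model back to TSV
#'
#' Inverse of [load_risk_model()]: writes the model's variant table with the
#' canonical column order so a valid table round-trips identically.
#'
#' @param model A `risk_model`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_risk_model <- function(model, path) {
  cols <- c("variant_id", "chrom", "pos", "risk_allele", "other_allele",
            "odds_ratio")
  if (any(!is.na(model$eaf))) cols <- c(cols, "eaf")
  utils::write.table(as.data.frame(model)[cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.risk_model <- function(x, ...) {
  cat("risk_model '", attr(x, "source_label"), "': ", nrow(x),
      " variants\n", sep = "")
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("... and", nrow(x) - 6, "more variants\n")
  invisible(x)
}

#' Path to the packaged rheumatoid-arthritis risk model
#'
#' Convenience accessor for the packaged 101-variant RA risk model fixture
#' (synthetic stand-in; see [load_risk_model()]).
#'
#' @return File path to the TSV fixture.
#' @export
ra_model_path <- function() {
  system.file("extdata", "ra_synthetic_101.tsv", package = "radiotox",
              mustWork = TRUE)
}
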