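#' Write a dosage panel as a VCF with per-sample dosages
#'
#' Emits a minimal VCF v4.2 with one biallelic record per variant
#' (REF = `allele_a`, ALT = `allele_b`) and the expected ALT-allele dosage
#' in the per-sample `DS` FORMAT field; missing dosages are written as `.`.
#'
#' @param panel A [dosage_panel()].
#' @param path Output path (`.vcf`).
#' @return `path`, invisibly.
#' @export
write_dosage_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "dosage_panel"))
  v <- panel$variants
  ds <- t(panel$dosage)  # variants x samples
  ds_chr <- matrix(sprintf("%.6g", ds), nrow(ds), ncol(ds))
  ds_chr[is.na(ds)] <- "."
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated ALT allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$sample_ids), collapse = "\t")
  )
  body <- paste(v$chrom, v$pos, v$variant_id, v$allele_a, v$allele_b,
                ".", "PASS", ".", "DS",
                apply(ds_chr, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotype dosages from a VCF
#'
#' Reads per-sample dosages from the `DS` FORMAT field of a (plain or
#' bgzipped) VCF. When no `DS` field is present, hard genotype calls (`GT`)
#' are summed to ALT-allele dosages as a fallback. The returned panel counts
#' copies of the ALT allele (`allele_a` = REF, `allele_b` = ALT).
#'
#' @param path Path to the VCF.
#' @return A [dosage_panel()].
#' @export
read_dosage_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- matrix(fix, ncol = ncol(fix), dimnames = dimnames(fix))
  fmt_keys <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":", fixed = TRUE)))
  if ("DS" %in% fmt_keys) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else if ("GT" %in% fmt_keys) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    ds <- apply(gt, 2, function(col) {
      vapply(strsplit(col, "[/|]"), function(a) {
        if (length(a) == 0 || anyNA(a) || any(a == ".")) return(NA_real_)
        sum(a != "0")
      }, numeric(1))
    })
    ds <- matrix(ds, nrow = nrow(gt), dimnames = dimnames(gt))
  } else {
    stop("VCF carries neither DS dosages nor GT genotypes: ", path)
  }
  variants <- data.frame(
    variant_id = unname(fix[, "ID"]),
    chrom = unname(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    allele_a = unname(fix[, "REF"]),
    allele_b = unname(fix[, "ALT"]),
    stringsAsFactors = FALSE
  )
  multi <- grepl(",", variants$allele_b, fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) dropped from ", path)
    variants <- variants[!multi, , drop = FALSE]
    ds <- ds[!multi, , drop = FALSE]
  }
  dosage_panel(t(ds), variants, sample_ids = colnames(ds))
}

#' Write a dosage panel as TSV plus allele sidecar
#'
#' The main table has `sample_id` followed by one column per variant; the
#' sidecar records each variant's `chrom`, `pos`, `allele_a` and `allele_b`
#' (dosages count `allele_b`).
#'
#' @param panel A [dosage_panel()].
#' @param path Dosage TSV path.
#' @param alleles_path Sidecar TSV path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(panel, path, alleles_path) {
  stopifnot(inherits(panel, "dosage_panel"))
  tab <- data.frame(sample_id = panel$sample_ids, panel$dosage,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(panel$variants, alleles_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a dosage panel from TSV plus allele sidecar
#'
#' @param path Dosage TSV (first column `sample_id`).
#' @param alleles_path Sidecar TSV with `variant_id`, `chrom`, `pos`,
#'   `allele_a`, `allele_b`.
#' @return A [dosage_panel()].
#' @export
read_dosage_tsv <- function(path, alleles_path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "sample_id") {
    stop("dosage TSV must have sample_id as its first column: ", path)
  }
  variants <- utils::read.delim(alleles_path, stringsAsFactors = FALSE,
                                colClasses = c(variant_id = "character",
                                               chrom = "character"))
  ids <- setdiff(names(tab), "sample_id")
  if (!setequal(ids, variants$variant_id)) {
    stop("dosage TSV columns and allele sidecar disagree on variant ids")
  }
  variants <- variants[match(ids, variants$variant_id), , drop = FALSE]
  dosage_panel(as.matrix(tab[ids]), variants, sample_ids = tab$sample_id)
}

#' Read long-format toxicity records from TSV
#'
#' @param path TSV with columns `patient_id`, `endpoint`, `day`, `grade`.
#' @return Data frame of toxicity records.
#' @export
read_toxicity_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(patient_id = "character"))
  need <- c("patient_id", "endpoint", "day", "grade")
  if (!all(need %in% names(tab))) {
    stop("toxicity TSV must have columns ", paste(need, collapse = ", "))
  }
  tab
}

#' Read a covariate table from TSV
#'
#' @param path TSV with a `patient_id` column.
#' @return Data frame of covariates.
#' @export
read_covariates_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(patient_id = "character"))
  if (!"patient_id" %in% names(tab)) {
    stop("covariate TSV must have a patient_id column: ", path)
  }
  tab
}
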