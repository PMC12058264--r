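#' Run the full simulate/score/STAT/associate pipeline
#'
#' Executes every stage of the analysis in order — input loading (or cohort
#' simulation), dosage harmonization, score computation, endpoint
#' summarization, STAT scoring and the association battery — and writes the
#' result tables plus a run manifest sufficient to reproduce the run
#' bit-identically.
#'
#' `config` is a list (or path to a YAML file) with fields:
#' \describe{
#'   \item{site}{Treatment site.}
#'   \item{alpha}{Family-wise significance level (default .05).}
#'   \item{weight_scheme}{`"or"` or `"log_or"`.}
#'   \item{use_delta}{`"auto"`, `"on"` or `"off"`.}
#'   \item{drop_ambiguous}{Drop palindromic variants (default `FALSE`).}
#'   \item{simulate}{Optional list of [simulation_config()] arguments; when
#'     present the cohort is simulated and written under `out_dir/inputs`.}
#'   \item{inputs}{Otherwise, paths: `risk_model`, `genotypes` (VCF) or
#'     `dosages` + `dosage_alleles` (TSV), `toxicity`, `covariates`.}
#' }
#'
#' @param config List or YAML path as described above.
#' @param out_dir Output directory.
#' @param seed Optional integer overriding the simulation master seed.
#' @return Invisibly, a list with the results table, STAT table,
#'   harmonization report, scores and the manifest.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  site <- match.arg(config$site, c("prostate", "lung", "breast"))
  alpha <- config$alpha %||% 0.05
  weight_scheme <- config$weight_scheme %||% "or"
  use_delta <- config$use_delta %||% "auto"
  drop_ambiguous <- isTRUE(config$drop_ambiguous)
  endpoints <- config$endpoints %||%
    list(acute = site_endpoints(site, "acute"),
         late = site_endpoints(site, "late"))
  if (length(endpoints$acute) == 0 || length(endpoints$late) == 0) {
    stop("stage config: acute and late endpoint families must be non-empty")
  }
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory ", out_dir)
  }
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  say <- function(...) {
    line <- paste0(...)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  counts <- list()

  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$site <- sim_args$site %||% site
    if (!is.null(seed)) sim_args$master_seed <- seed
    sim_config <- do.call(simulation_config, sim_args)
    say("stage simulate: n_patients=", sim_config$n_patients,
        " n_variants=", sim_config$n_variants,
        " effect_gamma=", sim_config$effect_gamma,
        " master_seed=", sim_config$master_seed)
    cohort <- generate_cohort(sim_config, file.path(out_dir, "inputs"))
    model <- cohort$model
    panel <- cohort$panel
    records <- cohort$records
    covariates <- cohort$covariates
  } else {
    inp <- config$inputs
    if (is.null(inp)) stop("config needs either 'simulate' or 'inputs'")
    for (f in unlist(inp)) {
      if (!file.exists(f)) stop("stage load: input file not found: ", f)
    }
    model <- load_risk_model(inp$risk_model)
    panel <- if (!is.null(inp$genotypes)) {
      read_dosage_vcf(inp$genotypes)
    } else {
      read_dosage_tsv(inp$dosages, inp$dosage_alleles)
    }
    records <- read_toxicity_tsv(inp$toxicity)
    covariates <- read_covariates_tsv(inp$covariates)
    say("stage load: ", nrow(model), " model variants, ",
        length(panel$sample_ids), " samples, ", nrow(records),
        " toxicity records, ", nrow(covariates), " covariate rows")
  }
  counts$model_variants <- nrow(model)
  counts$samples <- length(panel$sample_ids)
  counts$toxicity_records <- nrow(records)

  harm <- harmonize_dosages(panel, model, drop_ambiguous = drop_ambiguous)
  counts$variants_retained <- nrow(harm$panel$variants)
  say("stage harmonize: ", counts$variants_retained, " of ", nrow(model),
      " variants retained (", sum(harm$report$status != "direct"),
      " non-direct)")

  scores <- compute_scores(harm$panel, model, weight_scheme = weight_scheme)
  say("stage score: ", nrow(scores), " samples scored (",
      sum(scores$n_dosages_imputed), " dosages imputed)")

  summaries <- summarize_endpoints(records)
  counts$endpoint_summaries <- nrow(summaries)
  stat <- compute_stat_scores(summaries, site, use_delta = use_delta,
                              endpoints = endpoints)
  say("stage stat: STAT computed for ", sum(!is.na(stat$stat_acute)),
      " (acute) / ", sum(!is.na(stat$stat_late)), " (late) patients")

  results <- run_battery(scores, stat, summaries, covariates, site,
                         alpha = alpha, use_delta = use_delta,
                         endpoints = endpoints)
  counts$result_rows <- nrow(results)
  say("stage associate: ", nrow(results), " result rows (",
      sum(results$significant), " significant at adjusted thresholds)")

  write_results(results, file.path(out_dir, "results.tsv"))
  write_scores(scores, file.path(out_dir, "scores.tsv"))
  utils::write.table(stat, file.path(out_dir, "stat.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(harm$report, file.path(out_dir, "harmonization.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config, cfg_file)
  manifest <- list(
    package_version = as.character(utils::packageVersion("radiotox")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = config,
    config_md5 = unname(tools::md5sum(cfg_file)),
    seed = seed,
    site = site,
    counts = counts
  )
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, log_path)
  invisible(list(results = results, scores = scores, stat = stat,
                 harmonization = harm$report, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
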