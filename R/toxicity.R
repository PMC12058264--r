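#' Time-window configuration for toxicity scoring
#'
#' Day 0 is anchored at the last radiotherapy fraction. Baseline records are
#' those at or before day 0; acute toxicity is the maximum reported grade
#' within 3 months of radiotherapy (days 1-90) and late toxicity the maximum
#' reported after 3 months up to 2 years (days 91-730). The two follow-up
#' windows partition days 1-730, so no record is counted twice.
#'
#' @param acute_end Last day of the acute window.
#' @param late_end Last day of the late window.
#' @return A list with `baseline_max`, `acute`, `late` ranges.
#' @export
tox_windows <- function(acute_end = 90L, late_end = 730L) {
  stopifnot(acute_end >= 1, late_end > acute_end)
  list(baseline_max = 0L,
       acute = c(1L, as.integer(acute_end)),
       late = c(as.integer(acute_end) + 1L, as.integer(late_end)))
}

#' Summarize longitudinal CTCAE records per patient and endpoint
#'
#' Collapses long-format toxicity records (one row per patient, endpoint and
#' assessment day, CTCAE grade 0-4) into per-patient-endpoint summaries:
#' baseline grade (the latest record at or before day 0), acute and late
#' window maxima, and baseline-adjusted deltas. The delta is the increase in
#' reported toxicity attributed to radiotherapy,
#' `max(window_max - baseline, 0)`, floored at zero so improvements below
#' baseline are not scored as negative toxicity; when no baseline record
#' exists the delta falls back to the raw window maximum. Windows with no
#' record yield `NA`, never 0.
#'
#' @param records Data frame with columns `patient_id`, `endpoint`, `day`
#'   (integer days relative to the end of radiotherapy), `grade` (0-4).
#' @param windows A [tox_windows()] configuration.
#' @return Data frame with one row per observed patient x endpoint:
#'   `patient_id`, `endpoint`, `baseline_grade`, `acute_max`, `late_max`,
#'   `acute_delta`, `late_delta`.
#' @export
summarize_endpoints <- function(records, windows = tox_windows()) {
  stopifnot(is.data.frame(records),
            all(c("patient_id", "endpoint", "day", "grade") %in%
                  names(records)))
  if (nrow(records) == 0) stop("no toxicity records supplied")
  bad <- which(!records$grade %in% 0:4)
  if (length(bad) > 0) {
    b <- bad[1]
    stop("grade outside 0-4 in record (patient ", records$patient_id[b],
         ", endpoint ", records$endpoint[b], ", day ", records$day[b],
         ", grade ", records$grade[b], ")")
  }
  patient_id <- endpoint <- day <- grade <- NULL # data.table NSE
  dt <- data.table::as.data.table(
    records[c("patient_id", "endpoint", "day", "grade")])

  grouped <- function(sub, j_fun, col) {
    if (nrow(sub) == 0) {
      out <- data.table::data.table(patient_id = character(0),
                                    endpoint = character(0),
                                    v = integer(0))
    } else {
      out <- sub[, .(v = j_fun(day, grade)), by = .(patient_id, endpoint)]
    }
    data.table::setnames(out, "v", col)
  }
  base <- grouped(dt[day <= windows$baseline_max],
                  function(d, g) g[d == max(d)][which.max(g[d == max(d)])],
                  "baseline_grade")
  acute <- grouped(dt[day >= windows$acute[1] & day <= windows$acute[2]],
                   function(d, g) max(g), "acute_max")
  late <- grouped(dt[day >= windows$late[1] & day <= windows$late[2]],
                  function(d, g) max(g), "late_max")

  out <- unique(dt[, .(patient_id, endpoint)])
  out <- merge(out, base, by = c("patient_id", "endpoint"), all.x = TRUE)
  out <- merge(out, acute, by = c("patient_id", "endpoint"), all.x = TRUE)
  out <- merge(out, late, by = c("patient_id", "endpoint"), all.x = TRUE)
  delta <- function(mx, bl) {
    ifelse(is.na(mx), NA_integer_,
           ifelse(is.na(bl), mx, pmax(mx - bl, 0L)))
  }
  out[, c("acute_delta", "late_delta") := .(
    delta(acute_max, baseline_grade), delta(late_max, baseline_grade))]
  data.table::setorder(out, patient_id, endpoint)
  data.table::setDF(out)
  out
}

# Per-endpoint analysis values: delta when engaged, else raw window maximum.
# "auto" engages the delta for an endpoint only when at least `baseline_frac`
# of its patients have a baseline record; otherwise the raw maximum is used
# with a warning.
endpoint_values <- function(summaries, endpoints, timing = c("acute", "late"),
                            use_delta = c("auto", "on", "off"),
                            baseline_frac = 0.8) {
  timing <- match.arg(timing)
  use_delta <- match.arg(use_delta)
  max_col <- paste0(timing, "_max")
  delta_col <- paste0(timing, "_delta")
  patients <- sort(unique(summaries$patient_id))
  mat <- matrix(NA_real_, length(patients), length(endpoints),
                dimnames = list(patients, endpoints))
  for (ep in endpoints) {
    rows <- summaries[summaries$endpoint == ep, , drop = FALSE]
    if (nrow(rows) == 0) next
    use <- switch(use_delta,
      on = delta_col,
      off = max_col,
      auto = {
        frac <- mean(!is.na(rows$baseline_grade))
        if (frac >= baseline_frac) delta_col else {
          if (frac > 0) {
            warning("endpoint '", ep, "': only ", round(100 * frac),
                    "% of patients have a baseline; using raw ", timing,
                    " maxima instead of deltas")
          }
          max_col
        }
      })
    mat[match(rows$patient_id, patients), ep] <- rows[[use]]
  }
  mat
}

#' Standardized Total Average Toxicity (STAT) scores
#'
#' Pools several toxicity endpoints into one per-patient measure of overall
#' toxicity: each endpoint's chosen grade (baseline-adjusted delta where
#' baselines are sufficiently available, else the raw window maximum) is
#' z-standardized across the cohort using the mean and sample (n-1) standard
#' deviation of patients with a non-missing value, and a patient's STAT is
#' the mean of their available z-values. Endpoints observed in too few
#' patients or with zero variance are dropped with a recorded reason;
#' patients with no available endpoint get `NA`. When no value is missing
#' and no endpoint is dropped, STAT has cohort mean zero by construction.
#'
#' @param summaries Output of [summarize_endpoints()].
#' @param endpoints Character vector: the endpoint family to pool (see
#'   [site_endpoints()]).
#' @param timing `"acute"` or `"late"`.
#' @param use_delta `"auto"` (delta when >= 80% of the endpoint's patients
#'   have a baseline), `"on"`, or `"off"`.
#' @param baseline_frac Baseline availability fraction required by `"auto"`.
#' @return Data frame `patient_id`, `stat`, `n_endpoints` with attributes
#'   `endpoints_dropped` (data frame of endpoint/reason) and `timing`.
#' @export
compute_stat <- function(summaries, endpoints, timing = c("acute", "late"),
                         use_delta = c("auto", "on", "off"),
                         baseline_frac = 0.8) {
  timing <- match.arg(timing)
  use_delta <- match.arg(use_delta)
  stopifnot(length(endpoints) > 0)
  if (length(unique(summaries$patient_id)) < 2) {
    stop("STAT requires at least 2 patients")
  }
  mat <- endpoint_values(summaries, endpoints, timing, use_delta,
                         baseline_frac)
  dropped <- data.frame(endpoint = character(0), reason = character(0))
  z <- matrix(NA_real_, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  for (ep in colnames(mat)) {
    v <- mat[, ep]
    n_obs <- sum(!is.na(v))
    if (n_obs == 0) {
      dropped <- rbind(dropped, data.frame(endpoint = ep,
                                           reason = "not_observed"))
    } else if (n_obs < 2) {
      dropped <- rbind(dropped, data.frame(endpoint = ep,
                                           reason = "insufficient_data"))
    } else if (stats::sd(v, na.rm = TRUE) == 0) {
      dropped <- rbind(dropped, data.frame(endpoint = ep,
                                           reason = "zero_variance"))
    } else {
      z[, ep] <- (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
    }
  }
  kept <- setdiff(colnames(mat), dropped$endpoint)
  if (length(kept) == 0) {
    stop("all endpoints dropped (", paste(unique(dropped$reason),
                                          collapse = ", "),
         "); cannot compute STAT")
  }
  if (nrow(dropped) > 0) {
    message("STAT-", timing, ": dropped endpoint(s) ",
            paste0(dropped$endpoint, " [", dropped$reason, "]",
                   collapse = ", "))
  }
  zk <- z[, kept, drop = FALSE]
  n_avail <- rowSums(!is.na(zk))
  stat <- rowMeans(zk, na.rm = TRUE)
  stat[n_avail == 0] <- NA_real_
  out <- data.frame(patient_id = rownames(mat), stat = stat,
                    n_endpoints = as.integer(n_avail),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "endpoints_dropped") <- dropped
  attr(out, "timing") <- timing
  out
}

#' STAT-acute and STAT-late for a treatment site
#'
#' Convenience wrapper computing both STAT scores from one summary table
#' using the site's configured acute and late endpoint families.
#'
#' @inheritParams compute_stat
#' @param site Treatment site (see [site_endpoints()]).
#' @param endpoints Optional list with `acute` and `late` character vectors
#'   overriding the site's configured endpoint families.
#' @return Data frame `patient_id`, `stat_acute`, `stat_late`,
#'   `n_endpoints_acute`, `n_endpoints_late`.
#' @export
compute_stat_scores <- function(summaries, site,
                                use_delta = c("auto", "on", "off"),
                                baseline_frac = 0.8, endpoints = NULL) {
  use_delta <- match.arg(use_delta)
  endpoints <- endpoints %||%
    list(acute = site_endpoints(site, "acute"),
         late = site_endpoints(site, "late"))
  a <- compute_stat(summaries, endpoints$acute, "acute",
                    use_delta, baseline_frac)
  l <- compute_stat(summaries, endpoints$late, "late",
                    use_delta, baseline_frac)
  names(a)[2:3] <- c("stat_acute", "n_endpoints_acute")
  names(l)[2:3] <- c("stat_late", "n_endpoints_late")
  merge(a, l, by = "patient_id", all = TRUE)
}
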