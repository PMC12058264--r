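# In-code fixtures shared across test files.

# A tiny hand-specified risk model (non-palindromic unless asked otherwise).
tiny_model <- function(or = c(1.2, 1.5, 0.8)) {
  risk_model(data.frame(
    variant_id = paste0("v", seq_along(or)),
    chrom = as.character(seq_along(or)),
    pos = 100L * seq_along(or),
    risk_allele = rep(c("G", "A", "C"), length.out = length(or)),
    other_allele = rep(c("T", "C", "T"), length.out = length(or)),
    odds_ratio = or,
    eaf = rep(NA_real_, length(or)),
    stringsAsFactors = FALSE
  ), source_label = "tiny")
}

# A panel already oriented to the model's risk alleles (status 'direct').
oriented_panel <- function(model, dosage) {
  dosage <- matrix(dosage, ncol = nrow(model))
  dosage_panel(
    dosage,
    data.frame(variant_id = model$variant_id, chrom = model$chrom,
               pos = model$pos, allele_a = model$other_allele,
               allele_b = model$risk_allele, stringsAsFactors = FALSE),
    sample_ids = paste0("S", seq_len(nrow(dosage)))
  )
}

# Long-format toxicity records from (day, grade) pairs for one
# patient/endpoint.
records_from <- function(pairs, patient = "p1", endpoint = "e1") {
  data.frame(patient_id = patient, endpoint = endpoint,
             day = vapply(pairs, `[`, numeric(1), 1),
             grade = vapply(pairs, `[`, numeric(1), 2),
             stringsAsFactors = FALSE)
}

# Independent normal-equations OLS oracle (kept free of fit_ols internals).
ols_oracle <- function(y, X) {
  X <- cbind(`(Intercept)` = 1, as.matrix(X))
  cc <- stats::complete.cases(cbind(y, X))
  y <- y[cc]; X <- X[cc, , drop = FALSE]
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  resid <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(resid^2) / df
  se <- sqrt(diag(xtx_inv) * s2)
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  tcrit <- stats::qt(0.975, df)
  data.frame(term = colnames(X), beta = as.numeric(beta), se = se,
             p = as.numeric(p), ci_low = as.numeric(beta - tcrit * se),
             ci_high = as.numeric(beta + tcrit * se),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
mw_enumerate_p <- function(g1, g0) {
  pooled <- c(g1, g0)
  n1 <- length(g1)
  u_stat <- function(a, b) sum(outer(a, b, ">"))
  u_obs <- min(u_stat(g1, g0), u_stat(g0, g1))
  idx <- utils::combn(length(pooled), n1)
  us <- apply(idx, 2, function(i) {
    min(u_stat(pooled[i], pooled[-i]), u_stat(pooled[-i], pooled[i]))
  })
  mean(us <= u_obs)
}
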