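# Fixture builders and independent oracles shared across the test files.

make_readings <- function(times, values, type = "SBP", source = "NIBP",
                          valid = TRUE, patient = "P1", proc = "PR1") {
  data.frame(patient_id = patient, procedure_id = proc,
             timestamp = times, bp_type = type, value = values,
             source = source, valid = valid, stringsAsFactors = FALSE)
}

make_bolus <- function(timestamp, dose = 100, patient = "P1", proc = "PR1",
                       drug = "phenylephrine") {
  data.frame(patient_id = patient, procedure_id = proc, drug = drug,
             dose = dose, timestamp = timestamp, stringsAsFactors = FALSE)
}

# Naive full-scan oracle for the window response: loops over every reading
# and every bp_type, no vectorization shared with the implementation.
brute_force_response <- function(readings, t0, window_s) {
  out <- list()
  for (type in c("SBP", "MAP", "DBP")) {
    before <- c(); after <- c()
    for (i in seq_len(nrow(readings))) {
      r <- readings[i, ]
      if (r$bp_type != type) next
      if (!is.null(readings$valid) && !r$valid) next
      if (r$timestamp >= t0 - window_s && r$timestamp < t0)
        before <- c(before, r$value)
      if (r$timestamp > t0 && r$timestamp <= t0 + window_s)
        after <- c(after, r$value)
    }
    out[[tolower(type)]] <-
      if (length(before) && length(after)) max(after) - min(before) else NA_real_
  }
  out
}

# Random vitals fixture around a bolus at t0 = 0.
random_response_fixture <- function(n = 60) {
  data.frame(patient_id = "P1", procedure_id = "PR1",
             timestamp = round(runif(n, -600, 600)),
             bp_type = sample(c("SBP", "MAP", "DBP"), n, replace = TRUE),
             value = round(runif(n, 40, 200), 1),
             source = sample(c("NIBP", "ARTERIAL"), n, replace = TRUE),
             valid = runif(n) < 0.9,
             stringsAsFactors = FALSE)
}

# Small noiseless simulator configuration for controlled recovery checks.
quiet_sim_config <- function(...) {
  args <- list(...)
  defaults <- list(n_patients = 100, n_variants = 50,
                   causal_common = NULL, nonresponder_variants = NULL,
                   pd_amplitude_sd = 0, noise_sd_mmHg = 0,
                   baseline_walk_sd = 0, baseline_drift_mmHg_per_hr = 0,
                   propofol_rate = 0, pd_bolus_jitter_sd = 0,
                   ancestry_effects = c(AA = 0, EA = 0, HA = 0),
                   covariate_effects = c(age_z = 0),
                   exclusion_rates = c(canceled = 0, short_procedure = 0,
                                       emergency = 0, transfusion = 0,
                                       fluid_over_cap = 0, bmi_extreme = 0,
                                       asa5 = 0),
                   mean_boluses_per_case = 1, mean_cases_per_patient = 1,
                   mean_procedure_min = 60, seed = 99L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# GRM built from independent binomial genotypes, plus a polygenic phenotype
# drawn with known variance components (uses the eigendecomposition of K).
polygenic_fixture <- function(n, m, h2, sigma2 = 1, X = NULL) {
  G <- matrix(rbinom(n * m, 2, 0.3), n, m)
  K <- compute_grm(G)
  e <- eigen(K, symmetric = TRUE)
  g <- e$vectors %*% (sqrt(pmax(e$values, 0) * h2 * sigma2) * rnorm(n))
  if (is.null(X)) X <- cbind(1, rnorm(n))
  beta <- rep(1, ncol(X))
  y <- as.numeric(X %*% beta + g + rnorm(n, 0, sqrt((1 - h2) * sigma2)))
  list(y = y, X = X, K = K, G = G)
}

# Dense independent evaluation of the profiled restricted log-likelihood at
# a given heritability ratio, written with plain solve()/determinant() so it
# shares no code path with fit_lmm_null().
dense_reml_loglik <- function(y, X, K, h2) {
  n <- length(y); p <- ncol(X)
  V <- h2 * K + (1 - h2) * diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  s2 <- as.numeric(t(r) %*% Vi %*% r) / (n - p)
  as.numeric(-0.5 * ((n - p) * (1 + log(2 * pi * s2)) +
                       determinant(V, logarithm = TRUE)$modulus +
                       determinant(XtViX, logarithm = TRUE)$modulus))
}
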