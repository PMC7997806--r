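#' Simulate a complete perioperative + genomic cohort with ground truth
#'
#' Generates all five pipeline input tables (patients, procedures, vitals,
#' medications, genotypes + variant table) plus a ground-truth record, under
#' a single RNG seed. Patients receive demographics with ancestry-specific
#' means, a per-patient systolic response amplitude composed of the
#' configured base amplitude, ancestry shifts, centered covariate effects,
#' common-variant allele effects, Gaussian between-patient noise, and the
#' multiplicative carrier factor of any configured non-responder variant.
#' Procedures carry exclusion flags at the configured marginal rates,
#' phenylephrine boluses with a median dose of 100 ug, and (at rate
#' `propofol_rate`) a confounding propofol bolus at induction.
#'
#' Determinism: identical configurations (including the seed) produce
#' identical bundles.
#'
#' @param config a [sim_config()] object.
#' @return A list of class `perioperative_cohort` with elements `patients`,
#'   `procedures`, `vitals`, `medications`, `genotypes`, `variants`,
#'   `ground_truth` (list: `amplitude`, `carrier`, `causal_effects`,
#'   `boluses` with per-bolus injected peak delta-BP), and `config`.
#'   Timestamps are epoch seconds.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients

  gen <- simulate_genotypes(config)
  ancestry <- gen$ancestry
  patient_id <- rownames(gen$genotypes)

  patients <- simulate_patients(patient_id, ancestry, config)
  procedures <- simulate_procedures(patients, config)
  medications <- simulate_boluses(procedures, config)

  # per-patient amplitude: base + ancestry + centered patient covariates +
  # common causal allele effects + between-patient noise, then the carrier
  # multiplier of every non-responder variant carried
  eff <- config$covariate_effects
  age_z <- as.numeric(scale(patients$age))
  base <- rep(config$pd_amplitude_mean, n) +
    unname(config$ancestry_effects[ancestry]) +
    get0_effect(eff, "age_z") * age_z +
    get0_effect(eff, "bmi") * (patients$bmi - mean(patients$bmi))
  causal_effects <- numeric(config$n_variants)
  if (!is.null(config$causal_common) && nrow(config$causal_common)) {
    cc <- config$causal_common
    causal_effects[cc$index] <- cc$effect
    base <- base + as.numeric(gen$genotypes[, cc$index, drop = FALSE] %*% cc$effect)
  }
  if (config$pd_amplitude_sd > 0) base <- base + rnorm(n, 0, config$pd_amplitude_sd)

  nr <- config$nonresponder_variants
  multiplier <- rep(1, n)
  carrier <- NULL
  if (!is.null(nr) && nrow(nr)) {
    carrier <- gen$genotypes[, nr$index, drop = FALSE] >= 1L
    colnames(carrier) <- gen$variants$id[nr$index]
    for (i in seq_len(nrow(nr)))
      multiplier <- multiplier * ifelse(carrier[, i], nr$multiplier[i], 1)
  }
  amplitude <- base * multiplier

  # procedure-level covariate contributions (centered), scaled by the same
  # carrier multiplier so non-response is complete for multiplier-0 carriers
  idx <- match(procedures$patient_id, patient_id)
  proc_contrib <-
    get0_effect(eff, "asa") * (procedures$asa - mean(procedures$asa)) +
    get0_effect(eff, "mac") * (procedures$mac - mean(procedures$mac)) +
    get0_effect(eff, "crystalloid_ml") *
      (procedures$crystalloid_ml - mean(procedures$crystalloid_ml))
  proc_amplitude <- (base[idx] + proc_contrib) * multiplier[idx]

  vitals <- simulate_all_traces(procedures, medications, proc_amplitude, config)

  pe <- medications[medications$drug == "phenylephrine", , drop = FALSE]
  pidx <- match(pe$procedure_id, procedures$procedure_id)
  gt_boluses <- data.frame(patient_id = pe$patient_id,
                           procedure_id = pe$procedure_id,
                           timestamp = pe$timestamp,
                           dose = pe$dose,
                           injected_delta_bp = proc_amplitude[pidx] * pe$dose / 100,
                           stringsAsFactors = FALSE)

  genotyped <- patient_id
  geno <- gen$genotypes
  if (config$genotyped_fraction < 1) {
    keep <- sort(sample.int(n, round(n * config$genotyped_fraction)))
    geno <- geno[keep, , drop = FALSE]
  }

  out <- list(patients = patients,
              procedures = procedures,
              vitals = vitals,
              medications = medications,
              genotypes = geno,
              variants = gen$variants,
              ground_truth = list(amplitude = setNames(amplitude, patient_id),
                                  carrier = carrier,
                                  causal_effects = causal_effects,
                                  boluses = gt_boluses,
                                  freq = gen$freq),
              config = config)
  class(out) <- "perioperative_cohort"
  out
}

get0_effect <- function(effects, name) {
  if (is.null(effects) || !(name %in% names(effects))) return(0)
  v <- unname(effects[[name]])
  if (is.na(v)) 0 else v
}

simulate_patients <- function(patient_id, ancestry, config) {
  n <- length(patient_id)
  age_mean <- c(AA = 54.8, EA = 61, HA = 54.9)[ancestry]
  age_mean[is.na(age_mean)] <- 56.8
  age <- pmin(pmax(rnorm(n, age_mean, 14), 18), 95)
  female_p <- c(AA = 0.66, EA = 0.45, HA = 0.67)[ancestry]
  female_p[is.na(female_p)] <- 0.6
  sex <- ifelse(rbinom(n, 1, female_p) == 1, "F", "M")
  bmi_mean <- c(AA = 31, EA = 27.9, HA = 30.3)[ancestry]
  bmi_mean[is.na(bmi_mean)] <- 29.7
  bmi <- pmin(pmax(rnorm(n, bmi_mean, 8), 15), 60)
  extreme <- runif(n) < config$exclusion_rates[["bmi_extreme"]]
  bmi[extreme] <- runif(sum(extreme), 101, 140)
  data.frame(patient_id = patient_id,
             age = round(age, 1),
             sex = sex,
             bmi = round(bmi, 1),
             ancestry = ancestry,
             cci = rpois(n, 1.5),
             hypertension = runif(n) < 0.26,
             diabetes = runif(n) < 0.17,
             chf = runif(n) < 0.10,
             stringsAsFactors = FALSE)
}

simulate_procedures <- function(patients, config) {
  n <- nrow(patients)
  n_cases <- 1L + rpois(n, max(config$mean_cases_per_patient - 1, 0))
  pid <- rep(patients$patient_id, n_cases)
  case_no <- sequence(n_cases)
  np <- length(pid)
  rates <- config$exclusion_rates

  # schedule: per-patient base date, successive cases >= 30 days apart so
  # procedures of one patient never overlap
  base_day <- rep(floor(runif(n, 0, 365)), n_cases)
  start <- as.numeric(as.POSIXct("2014-01-01", tz = "UTC")) +
    (base_day + (case_no - 1) * 30) * 86400 + floor(runif(np, 7, 17)) * 3600
  duration <- pmax(rgamma(np, shape = 4, scale = config$mean_procedure_min / 4), 30) * 60
  end <- start + round(duration)

  category_pool <- c("cardiovascular", "musculoskeletal", "digestive",
                     "genitourinary", "nervous", "integumentary")
  category <- sample(category_pool, np, replace = TRUE)
  short <- runif(np) < rates[["short_procedure"]]
  category[short] <- sample(c("colonoscopy", "endoscopy"), sum(short), replace = TRUE)

  crystalloid <- pmin(rlnorm(np, log(850), 0.7), 4800)
  over <- runif(np) < rates[["fluid_over_cap"]]
  crystalloid[over] <- runif(sum(over), 5001, 9000)

  asa <- sample(1:4, np, replace = TRUE, prob = c(0.23, 0.32, 0.38, 0.07))
  asa[runif(np) < rates[["asa5"]]] <- 5L

  data.frame(procedure_id = sprintf("PR%06d", seq_len(np)),
             patient_id = pid,
             start = start,
             end = end,
             category = category,
             emergency = runif(np) < rates[["emergency"]],
             transfusion = runif(np) < rates[["transfusion"]],
             crystalloid_ml = round(crystalloid),
             anesthesia_type = sample(c("general", "mac", "regional"), np,
                                      replace = TRUE, prob = c(0.65, 0.21, 0.14)),
             mac = round(pmin(pmax(rnorm(np, 1, 0.3), 0), 2), 2),
             asa = as.integer(asa),
             canceled_or_manual = runif(np) < rates[["canceled"]],
             monitoring = ifelse(runif(np) < config$arterial_fraction,
                                 "ARTERIAL", "NIBP"),
             stringsAsFactors = FALSE)
}

simulate_boluses <- function(procedures, config) {
  np <- nrow(procedures)
  n_bol <- 1L + rpois(np, max(config$mean_boluses_per_case - 1, 0))
  rows <- rep(seq_len(np), n_bol)
  nb <- length(rows)
  dose <- if (length(config$dose_levels) == 1) rep(config$dose_levels, nb)
          else sample(config$dose_levels, nb, replace = TRUE,
                      prob = config$dose_probs)
  span_lo <- procedures$start[rows] + 300
  span_hi <- pmax(procedures$end[rows] - 300, span_lo + 60)
  ts <- floor(runif(nb, span_lo, span_hi))
  med <- data.frame(patient_id = procedures$patient_id[rows],
                    procedure_id = procedures$procedure_id[rows],
                    drug = "phenylephrine",
                    dose = dose,
                    timestamp = ts,
                    stringsAsFactors = FALSE)
  has_prop <- runif(np) < config$propofol_rate
  if (any(has_prop)) {
    pr <- data.frame(patient_id = procedures$patient_id[has_prop],
                     procedure_id = procedures$procedure_id[has_prop],
                     drug = "propofol",
                     dose = round(runif(sum(has_prop), 50, 200)),
                     timestamp = procedures$start[has_prop] + 120,
                     stringsAsFactors = FALSE)
    med <- rbind(med, pr)
  }
  med[order(med$procedure_id, med$timestamp), , drop = FALSE]
}

simulate_all_traces <- function(procedures, medications, proc_amplitude, config) {
  check_no_overlap(procedures)
  med_by_proc <- split(medications, medications$procedure_id)
  sbp0 <- rnorm(nrow(procedures), 125, 10)
  dbp0 <- rnorm(nrow(procedures), 70, 8)
  traces <- vector("list", nrow(procedures))
  for (i in seq_len(nrow(procedures))) {
    traces[[i]] <- simulate_bp_trace(
      procedures$patient_id[i], procedures$procedure_id[i],
      procedures$start[i], procedures$end[i],
      med_by_proc[[procedures$procedure_id[i]]],
      config,
      amplitude = proc_amplitude[i],
      monitoring = procedures$monitoring[i],
      sbp0 = sbp0[i], dbp0 = dbp0[i])
  }
  out <- do.call(rbind, traces)
  out$value <- round(out$value, 2)
  rownames(out) <- NULL
  out
}

check_no_overlap <- function(procedures) {
  for (pid in unique(procedures$patient_id[duplicated(procedures$patient_id)])) {
    p <- procedures[procedures$patient_id == pid, , drop = FALSE]
    p <- p[order(p$start), , drop = FALSE]
    if (any(p$start[-1] < p$end[-nrow(p)]))
      stop("overlapping procedures for patient ", pid)
  }
  invisible(TRUE)
}

#' @export
print.perioperative_cohort <- function(x, ...) {
  cat("Synthetic perioperative cohort\n")
  cat(sprintf("  %d patients, %d procedures, %d vitals readings, %d boluses\n",
              nrow(x$patients), nrow(x$procedures), nrow(x$vitals),
              nrow(x$medications)))
  if (!is.null(x$genotypes))
    cat(sprintf("  genotypes: %d samples x %d variants\n",
                nrow(x$genotypes), ncol(x$genotypes)))
  tab <- table(x$patients$ancestry)
  cat(sprintf("  ancestry: %s\n",
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}
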