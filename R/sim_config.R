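#' Synthetic cohort configuration
#'
#' Builds the configuration object consumed by [simulate_cohort()],
#' [simulate_genotypes()] and [simulate_bp_trace()]. Defaults emulate the
#' structure of a multi-ancestry perioperative biobank cohort: three
#' self-reported ancestry groups with Balding-Nichols allele-frequency
#' structure, a phenylephrine pharmacodynamic bolus response with a
#' 15-20 minute elimination half-life, rare ancestry-specific
#' "non-responder" variants at ~1% minor allele frequency, confounding
#' propofol boluses, NIBP (minutes) versus arterial-line (15 s) sampling
#' cadence, and procedure-level exclusion flags at realistic rates.
#'
#' @param n_patients number of patients.
#' @param ancestry_proportions named fractions per ancestry label, summing
#'   to 1 (default AA/EA/HA at the proportions of a 4317-patient
#'   perioperative cohort: 0.282/0.321/0.397).
#' @param n_variants number of simulated bi-allelic variants.
#' @param fst named per-ancestry Balding-Nichols drift parameters in
#'   \[0, 0.2\].
#' @param causal_common data.frame with columns `index` (variant column) and
#'   `effect` (mmHg per allele added to the response amplitude), or NULL for
#'   none. Left unspecified, two variants at 20% and 40% of the index range
#'   get effects +0.9 and -1.1 mmHg/allele.
#' @param nonresponder_variants data.frame with columns `index`, `ancestry`
#'   (target group), `maf` (frequency in the target group, ~0.01) and
#'   `multiplier` (carrier response multiplier in \[0, 1\]; 0 = complete
#'   non-response), or NULL for none. Variants are absent outside the
#'   target group. Left unspecified, the last two variants are planted as
#'   an EA and an AA complete non-responder at 1% MAF.
#' @param pd_amplitude_mean mean systolic response amplitude, mmHg per
#'   100 ug bolus.
#' @param pd_amplitude_sd between-patient SD of the amplitude, mmHg.
#' @param pd_half_life_min elimination half-life of the bolus effect,
#'   minutes; physiologic range is 15-20.
#' @param pd_time_to_peak_s linear onset time to peak effect, seconds.
#' @param pd_bolus_jitter_sd per-bolus multiplicative jitter SD on the
#'   amplitude (0 disables; within-patient repeat-bolus variability is not
#'   characterized by the source data, so the default is off).
#' @param dbp_ratio diastolic response amplitude as a fraction of systolic.
#' @param propofol_drop_mmHg depth of the systolic dip after a propofol
#'   bolus, mmHg.
#' @param propofol_duration_min duration of the propofol dip, minutes.
#' @param propofol_rate fraction of procedures receiving a propofol bolus
#'   at induction.
#' @param nibp_interval_s NIBP cuff cycle time, seconds (60-300).
#' @param art_interval_s arterial-line recording interval, seconds.
#' @param arterial_fraction fraction of procedures monitored by arterial
#'   line (the rest use NIBP).
#' @param noise_sd_mmHg per-reading Gaussian measurement noise, mmHg.
#' @param baseline_drift_mmHg_per_hr slow intraoperative hypotension drift.
#' @param baseline_walk_sd random-walk innovation SD, mmHg per sqrt(min).
#' @param ancestry_effects named mmHg shifts of the response amplitude per
#'   ancestry (default: EA +5 mmHg, HA +1 mmHg relative to AA).
#' @param covariate_effects named mmHg-per-unit effects injected into the
#'   amplitude for `age_z`, `bmi`, `asa`, `mac`, `crystalloid_ml`
#'   (covariates are centered before injection, so the mean amplitude stays
#'   at `pd_amplitude_mean`).
#' @param exclusion_rates named fractions of procedures flagged for each
#'   exclusion criterion: `canceled`, `short_procedure`, `emergency`,
#'   `transfusion`, `fluid_over_cap`, `bmi_extreme`, `asa5`.
#' @param genotyped_fraction fraction of patients with genotype data.
#' @param mean_cases_per_patient,mean_boluses_per_case,mean_procedure_min
#'   cohort-shape parameters (defaults 1.4 cases/patient, 4.4
#'   boluses/case, 150 min procedures).
#' @param dose_levels,dose_probs phenylephrine bolus dose levels (ug) and
#'   their sampling probabilities; the default mix has median 100 ug.
#' @param chrom_lengths named integer vector of synthetic chromosome
#'   lengths in bp; default 22 autosomes with hg19-proportional lengths.
#' @param seed integer RNG seed.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 2000,
                       ancestry_proportions = c(AA = 0.282, EA = 0.321, HA = 0.397),
                       n_variants = 5000,
                       fst = c(AA = 0.1, EA = 0.1, HA = 0.1),
                       causal_common = NULL,
                       nonresponder_variants = NULL,
                       pd_amplitude_mean = 15,
                       pd_amplitude_sd = 6,
                       pd_half_life_min = 17.5,
                       pd_time_to_peak_s = 60,
                       pd_bolus_jitter_sd = 0,
                       dbp_ratio = 0.65,
                       propofol_drop_mmHg = 15,
                       propofol_duration_min = 10,
                       propofol_rate = 0.25,
                       nibp_interval_s = 180,
                       art_interval_s = 15,
                       arterial_fraction = 0.4,
                       noise_sd_mmHg = 3,
                       baseline_drift_mmHg_per_hr = -5,
                       baseline_walk_sd = 1,
                       ancestry_effects = c(AA = 0, EA = 5, HA = 1),
                       covariate_effects = c(age_z = -2, bmi = -0.1, asa = -1.5,
                                             mac = -3, crystalloid_ml = -0.002),
                       exclusion_rates = c(canceled = 0.02, short_procedure = 0.05,
                                           emergency = 0.01, transfusion = 0.02,
                                           fluid_over_cap = 0.02, bmi_extreme = 0.002,
                                           asa5 = 0.002),
                       genotyped_fraction = 1,
                       mean_cases_per_patient = 1.4,
                       mean_boluses_per_case = 4.4,
                       mean_procedure_min = 150,
                       dose_levels = c(50, 100, 150, 200),
                       dose_probs = c(0.20, 0.55, 0.15, 0.10),
                       chrom_lengths = NULL,
                       seed = 1L) {
  if (is.null(chrom_lengths)) chrom_lengths <- hg19_autosome_lengths()
  # planted-variant defaults: two common causal variants (columns 1001 and
  # 2002 of the reference 5000-variant panel, or 20%/40% of the index range
  # when the panel is too small to hold them) and one EA plus one AA
  # non-responder variant at the top of the index range
  if (missing(causal_common) && n_variants >= 8) {
    idx <- c(1001L, 2002L)
    if (n_variants < 2002L)
      idx <- as.integer(round(n_variants * c(0.2, 0.4)))
    causal_common <- data.frame(index = idx, effect = c(0.9, -1.1))
  }
  if (missing(nonresponder_variants) && n_variants >= 8) {
    nonresponder_variants <- data.frame(index = as.integer(n_variants - c(1L, 0L)),
                                        ancestry = c("EA", "AA"),
                                        maf = c(0.01, 0.01),
                                        multiplier = c(0, 0))
    nonresponder_variants <- nonresponder_variants[
      nonresponder_variants$ancestry %in% names(ancestry_proportions), ,
      drop = FALSE]
    if (!nrow(nonresponder_variants)) nonresponder_variants <- NULL
  }
  cfg <- list(n_patients = as.integer(n_patients),
              ancestry_proportions = ancestry_proportions,
              n_variants = as.integer(n_variants),
              fst = fst,
              causal_common = causal_common,
              nonresponder_variants = nonresponder_variants,
              pd_amplitude_mean = pd_amplitude_mean,
              pd_amplitude_sd = pd_amplitude_sd,
              pd_half_life_min = pd_half_life_min,
              pd_time_to_peak_s = pd_time_to_peak_s,
              pd_bolus_jitter_sd = pd_bolus_jitter_sd,
              dbp_ratio = dbp_ratio,
              propofol_drop_mmHg = propofol_drop_mmHg,
              propofol_duration_min = propofol_duration_min,
              propofol_rate = propofol_rate,
              nibp_interval_s = nibp_interval_s,
              art_interval_s = art_interval_s,
              arterial_fraction = arterial_fraction,
              noise_sd_mmHg = noise_sd_mmHg,
              baseline_drift_mmHg_per_hr = baseline_drift_mmHg_per_hr,
              baseline_walk_sd = baseline_walk_sd,
              ancestry_effects = ancestry_effects,
              covariate_effects = covariate_effects,
              exclusion_rates = exclusion_rates,
              genotyped_fraction = genotyped_fraction,
              mean_cases_per_patient = mean_cases_per_patient,
              mean_boluses_per_case = mean_boluses_per_case,
              mean_procedure_min = mean_procedure_min,
              dose_levels = dose_levels,
              dose_probs = dose_probs,
              chrom_lengths = chrom_lengths,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 2, cfg$n_variants >= 1)
  if (abs(sum(cfg$ancestry_proportions) - 1) > 1e-9)
    stop("ancestry_proportions must sum to 1 (within 1e-9)")
  if (is.null(names(cfg$ancestry_proportions)))
    stop("ancestry_proportions must be named")
  fracs <- c(cfg$ancestry_proportions, cfg$arterial_fraction,
             cfg$genotyped_fraction, cfg$propofol_rate, cfg$exclusion_rates)
  if (any(fracs < 0 | fracs > 1)) stop("all fractions must lie in [0, 1]")
  if (any(cfg$fst < 0 | cfg$fst > 0.2))
    stop("fst drift parameters must lie in [0, 0.2]")
  if (cfg$pd_half_life_min < 15 || cfg$pd_half_life_min > 20)
    warning("pd_half_life_min outside the physiologic 15-20 min range")
  if (cfg$nibp_interval_s < 60 || cfg$nibp_interval_s > 300)
    warning("nibp_interval_s outside the typical 60-300 s cuff cycle range")
  if (!is.null(cfg$nonresponder_variants)) {
    nr <- cfg$nonresponder_variants
    stopifnot(all(c("index", "ancestry", "maf", "multiplier") %in% names(nr)))
    if (any(nr$multiplier < 0 | nr$multiplier > 1))
      stop("non-responder multipliers must lie in [0, 1]")
    if (!all(nr$ancestry %in% names(cfg$ancestry_proportions)))
      stop("non-responder target ancestry not among ancestry_proportions")
  }
  invisible(cfg)
}

#' hg19-proportional autosome lengths
#'
#' Lengths (bp) of the 22 human autosomes under the hg19 assembly, used as
#' the default synthetic genome so that region sampling operates over a
#' realistic coordinate space. Coordinates throughout the package are
#' 1-based inclusive.
#'
#' @return Named integer-valued numeric vector (`chr1` ... `chr22`).
#' @export
hg19_autosome_lengths <- function() {
  c(chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
    chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
    chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
    chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
    chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
    chr21 = 48129895, chr22 = 51304566)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic perioperative cohort configuration\n")
  cat(sprintf("  patients: %d   variants: %d   seed: %d\n",
              x$n_patients, x$n_variants, x$seed))
  cat(sprintf("  ancestry: %s\n",
              paste(sprintf("%s=%.3f", names(x$ancestry_proportions),
                            x$ancestry_proportions), collapse = ", ")))
  cat(sprintf("  PD: %.1f mmHg/100ug, half-life %.1f min, peak %.0f s\n",
              x$pd_amplitude_mean, x$pd_half_life_min, x$pd_time_to_peak_s))
  nnr <- if (is.null(x$nonresponder_variants)) 0 else nrow(x$nonresponder_variants)
  cat(sprintf("  non-responder variants: %d   causal common variants: %d\n",
              nnr, if (is.null(x$causal_common)) 0 else nrow(x$causal_common)))
  invisible(x)
}
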