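#' Phenylephrine bolus effect kernel
#'
#' Unitless pharmacodynamic shape of a single intravenous phenylephrine
#' bolus: zero before administration, linear rise to 1 at
#' `time_to_peak_s`, then exponential decay with elimination half-life
#' `half_life_min`. The shape is the simplest one consistent with a very
#' rapid onset and a 15-20 minute half-life; the full effect of a bolus of
#' dose `d` ug on a patient with amplitude `A` is `A * (d / 100) * g(t)`.
#'
#' @param t time since bolus administration, seconds (vectorized).
#' @param time_to_peak_s onset time to peak, seconds.
#' @param half_life_min elimination half-life, minutes.
#' @return Numeric vector in \[0, 1\].
#' @export
bolus_effect_kernel <- function(t, time_to_peak_s = 60, half_life_min = 17.5) {
  g <- numeric(length(t))
  rising <- t > 0 & t <= time_to_peak_s
  decaying <- t > time_to_peak_s
  g[rising] <- t[rising] / time_to_peak_s
  g[decaying] <- exp(-log(2) * (t[decaying] - time_to_peak_s) /
                       (half_life_min * 60))
  g
}

# Propofol dip kernel: full depth (boxcar) for duration_min, then an
# exponential tail with a fixed 2 min half-life. Onset is immediate.
propofol_kernel <- function(t, duration_min = 10) {
  dur <- duration_min * 60
  p <- numeric(length(t))
  box <- t > 0 & t <= dur
  tail <- t > dur
  p[box] <- 1
  p[tail] <- exp(-log(2) * (t[tail] - dur) / 120)
  p
}

#' Simulate an intraoperative blood-pressure trace
#'
#' Generates SBP/DBP/MAP readings for one procedure on the monitoring grid
#' (arterial line at `art_interval_s` or NIBP cuff at `nibp_interval_s`).
#' The systolic signal is a baseline with a slow hypotension drift and a
#' Gaussian random walk, plus the summed effects of all phenylephrine
#' boluses (amplitude `amplitude` mmHg per 100 ug, shape
#' [bolus_effect_kernel()]) minus a dip of depth `propofol_drop_mmHg` after
#' each propofol bolus. The diastolic signal receives `dbp_ratio` times the
#' same effects; MAP is written as `DBP + (SBP - DBP) / 3` before
#' independent per-reading Gaussian noise is added to all three series.
#'
#' @param patient_id,procedure_id identifiers stamped on the readings.
#' @param start,end procedure start/end, epoch seconds.
#' @param boluses data.frame with columns `drug`, `dose`, `timestamp`
#'   (epoch seconds); rows with `drug == "phenylephrine"` raise BP, rows
#'   with `drug == "propofol"` lower it, other drugs are inert.
#' @param config a [sim_config()] object.
#' @param amplitude patient systolic response amplitude, mmHg per 100 ug.
#' @param monitoring `"ARTERIAL"` or `"NIBP"`.
#' @param sbp0,dbp0 baseline systolic/diastolic pressure, mmHg.
#'
#' @return data.frame of readings: patient_id, procedure_id, timestamp,
#'   bp_type, value, source.
#' @export
simulate_bp_trace <- function(patient_id, procedure_id, start, end, boluses,
                              config, amplitude = config$pd_amplitude_mean,
                              monitoring = c("ARTERIAL", "NIBP"),
                              sbp0 = 120, dbp0 = 70) {
  monitoring <- match.arg(monitoring)
  stopifnot(end > start)
  interval <- if (monitoring == "ARTERIAL") config$art_interval_s else config$nibp_interval_s
  times <- seq(start, end, by = interval)
  nt <- length(times)

  drift <- config$baseline_drift_mmHg_per_hr * (times - start) / 3600
  walk_sd <- config$baseline_walk_sd * sqrt(interval / 60)
  walk_s <- if (walk_sd > 0) cumsum(rnorm(nt, 0, walk_sd)) else numeric(nt)
  walk_d <- if (walk_sd > 0) cumsum(rnorm(nt, 0, walk_sd)) else numeric(nt)

  eff <- numeric(nt)
  if (!is.null(boluses) && nrow(boluses)) {
    pe <- boluses[boluses$drug == "phenylephrine", , drop = FALSE]
    if (nrow(pe)) {
      jit <- if (config$pd_bolus_jitter_sd > 0)
        rnorm(nrow(pe), 1, config$pd_bolus_jitter_sd) else rep(1, nrow(pe))
      for (b in seq_len(nrow(pe))) {
        eff <- eff + amplitude * jit[b] * (pe$dose[b] / 100) *
          bolus_effect_kernel(times - pe$timestamp[b],
                              config$pd_time_to_peak_s,
                              config$pd_half_life_min)
      }
    }
    pro <- boluses[boluses$drug == "propofol", , drop = FALSE]
    for (b in seq_len(nrow(pro))) {
      eff <- eff - config$propofol_drop_mmHg *
        propofol_kernel(times - pro$timestamp[b], config$propofol_duration_min)
    }
  }

  sbp <- sbp0 + drift + walk_s + eff
  dbp <- dbp0 + config$dbp_ratio * (drift + eff) + walk_d
  map <- dbp + (sbp - dbp) / 3
  if (config$noise_sd_mmHg > 0) {
    sbp <- sbp + rnorm(nt, 0, config$noise_sd_mmHg)
    dbp <- dbp + rnorm(nt, 0, config$noise_sd_mmHg)
    map <- map + rnorm(nt, 0, config$noise_sd_mmHg)
  }

  data.frame(patient_id = patient_id,
             procedure_id = procedure_id,
             timestamp = rep(times, 3),
             bp_type = rep(c("SBP", "DBP", "MAP"), each = nt),
             value = c(sbp, dbp, map),
             source = monitoring,
             stringsAsFactors = FALSE)
}
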