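#' Flag physiologically valid blood-pressure readings
#'
#' Marks each reading valid iff its value lies inside the inclusive
#' physiological range for its type (defaults: 60-240 mmHg systolic,
#' 30-120 diastolic, 30-130 mean arterial). Out-of-range readings likely
#' represent measurement artifacts; they are retained in the table but
#' never used downstream. Bounds are inclusive at both ends.
#'
#' @param readings vitals data.frame with columns `bp_type` and `value`.
#' @param config a [pipeline_config()] (only `validity_ranges` is used).
#' @return `readings` with a logical `valid` column (re)set.
#' @export
flag_validity <- function(readings, config = pipeline_config()) {
  ranges <- config$validity_ranges
  unknown <- setdiff(unique(readings$bp_type), names(ranges))
  if (length(unknown))
    stop("unknown bp_type: ", paste(unknown, collapse = ", "))
  lo <- vapply(ranges, `[`, 0, 1)[readings$bp_type]
  hi <- vapply(ranges, `[`, 0, 2)[readings$bp_type]
  readings$valid <- is.finite(readings$value) &
    readings$value >= lo & readings$value <= hi
  readings
}

#' Extract the rapid bolus-response phenotype for one bolus
#'
#' The response is the difference between the maximum valid BP in the
#' `window_s` seconds after the bolus and the minimum valid BP in the
#' `window_s` seconds before it, computed independently per bp_type with
#' no smoothing. The before-window is `[t0 - window_s, t0)` and the
#' after-window `(t0, t0 + window_s]`; a reading exactly at the bolus
#' timestamp belongs to neither. NIBP and arterial readings are pooled
#' without precedence. A delta is `NA` whenever either window contains no
#' valid reading of that type (that is data, not an error).
#'
#' @param readings vitals for the bolus's procedure, after
#'   [flag_validity()] (if no `valid` column is present all readings are
#'   treated as valid).
#' @param bolus one-row data.frame with `timestamp` and `dose` (and
#'   optionally patient/procedure ids, copied through).
#' @param window_s window width in seconds (default 300).
#' @return One-row data.frame: patient_id, procedure_id, bolus_time, dose,
#'   delta_sbp/delta_map/delta_dbp, per-type before/after reading counts,
#'   and the monitoring source(s) used.
#' @export
extract_response <- function(readings, bolus, window_s = 300) {
  stopifnot(nrow(bolus) == 1, window_s > 0)
  t0 <- bolus$timestamp
  if (is.null(readings$valid)) readings$valid <- TRUE
  before <- readings$valid & readings$timestamp >= t0 - window_s &
    readings$timestamp < t0
  after <- readings$valid & readings$timestamp > t0 &
    readings$timestamp <= t0 + window_s

  one <- function(type) {
    b <- readings$value[before & readings$bp_type == type]
    a <- readings$value[after & readings$bp_type == type]
    c(delta = if (length(a) && length(b)) max(a) - min(b) else NA_real_,
      n_before = length(b), n_after = length(a))
  }
  sbp <- one("SBP"); map <- one("MAP"); dbp <- one("DBP")
  used <- unique(readings$source[(before | after)])
  data.frame(patient_id = bolus$patient_id %||% NA_character_,
             procedure_id = bolus$procedure_id %||% NA_character_,
             bolus_time = t0,
             dose = bolus$dose %||% NA_real_,
             delta_sbp = sbp[["delta"]],
             delta_map = map[["delta"]],
             delta_dbp = dbp[["delta"]],
             n_before_sbp = sbp[["n_before"]], n_after_sbp = sbp[["n_after"]],
             n_before_map = map[["n_before"]], n_after_map = map[["n_after"]],
             n_before_dbp = dbp[["n_before"]], n_after_dbp = dbp[["n_after"]],
             source = if (length(used) == 0) NA_character_
                      else if (length(used) == 1) used else "MIXED",
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flag phenylephrine boluses proximal to a propofol bolus
#'
#' A phenylephrine bolus is excluded when any propofol bolus in the same
#' procedure lies within `window_min` minutes of it. The window is applied
#' symmetrically (before or after the phenylephrine bolus), since propofol
#' has an immediate onset and a ~10 minute duration.
#'
#' @param boluses phenylephrine bolus rows (procedure_id, timestamp).
#' @param medications full medication table (used for `drug == "propofol"`).
#' @param window_min exclusion radius in minutes.
#' @return logical vector along `boluses` rows; TRUE = propofol-proximal.
#' @export
propofol_proximal <- function(boluses, medications, window_min = 10) {
  prop <- medications[medications$drug == "propofol", , drop = FALSE]
  if (!nrow(prop) || !nrow(boluses)) return(rep(FALSE, nrow(boluses)))
  out <- rep(FALSE, nrow(boluses))
  prop_by_proc <- split(prop$timestamp, prop$procedure_id)
  for (proc in intersect(unique(boluses$procedure_id), names(prop_by_proc))) {
    rows <- which(boluses$procedure_id == proc)
    pts <- prop_by_proc[[proc]]
    for (i in rows)
      out[i] <- any(abs(boluses$timestamp[i] - pts) <= window_min * 60)
  }
  out
}

#' Select the index bolus: first retained case, first retained bolus
#'
#' For each patient, restricts to phenylephrine boluses that are not
#' propofol-proximal, keeps only the chronologically first retained
#' procedure, and within it the earliest retained bolus. Patients with no
#' retained bolus drop out.
#'
#' @param boluses phenylephrine bolus rows (patient_id, procedure_id,
#'   dose, timestamp).
#' @param procedures procedure table (for chronological ordering by start).
#' @param medications full medication table (propofol lookup).
#' @param propofol_exclusion_min exclusion radius, minutes.
#' @return data.frame with one bolus row per retained patient.
#' @export
select_index_bolus <- function(boluses, procedures, medications,
                               propofol_exclusion_min = 10) {
  pe <- if ("drug" %in% names(boluses))
    boluses[boluses$drug == "phenylephrine", , drop = FALSE] else boluses
  keep <- !propofol_proximal(pe, medications, propofol_exclusion_min)
  pe <- pe[keep, , drop = FALSE]
  if (!nrow(pe)) return(pe)
  pe$.start <- procedures$start[match(pe$procedure_id, procedures$procedure_id)]
  pe <- pe[order(pe$patient_id, pe$.start, pe$timestamp), , drop = FALSE]
  first_proc <- !duplicated(pe$patient_id)
  index_proc <- pe$procedure_id[first_proc]
  names(index_proc) <- pe$patient_id[first_proc]
  pe <- pe[pe$procedure_id == index_proc[pe$patient_id], , drop = FALSE]
  pe <- pe[!duplicated(pe$patient_id), , drop = FALSE]
  pe$.start <- NULL
  rownames(pe) <- NULL
  pe
}

#' Derive per-patient bolus-response phenotypes
#'
#' End-to-end phenotype derivation: validity-flags the vitals, applies the
#' exclusion cascade (see [apply_cascade()]), and extracts the
#' delta-SBP/MAP/DBP response for each patient's index bolus.
#'
#' @param bundle a `perioperative_cohort`.
#' @param config a [pipeline_config()].
#' @return list of class `derived_phenotypes`: `phenotypes` (one row per
#'   retained patient, joined with ancestry), `attrition` (the cascade's
#'   attrition table), and `cascade` (the full cascade result).
#' @export
derive_phenotypes <- function(bundle, config = pipeline_config()) {
  bundle$vitals <- flag_validity(bundle$vitals, config)
  cascade <- apply_cascade(bundle, config)
  idx <- cascade$index_boluses
  vit_by_proc <- split(bundle$vitals, bundle$vitals$procedure_id)
  rows <- vector("list", nrow(idx))
  for (i in seq_len(nrow(idx))) {
    rows[[i]] <- extract_response(vit_by_proc[[idx$procedure_id[i]]],
                                  idx[i, , drop = FALSE], config$window_s)
  }
  phen <- do.call(rbind, rows)
  phen$ancestry <- bundle$patients$ancestry[
    match(phen$patient_id, bundle$patients$patient_id)]
  out <- list(phenotypes = phen, attrition = cascade$attrition,
              cascade = cascade)
  class(out) <- "derived_phenotypes"
  out
}

#' @export
print.derived_phenotypes <- function(x, ...) {
  p <- x$phenotypes
  cat(sprintf("Derived bolus-response phenotypes: %d patients\n", nrow(p)))
  for (v in c("delta_sbp", "delta_map", "delta_dbp"))
    cat(sprintf("  %s: mean %.1f mmHg (SD %.1f), %d defined\n", v,
                mean(p[[v]], na.rm = TRUE), sd(p[[v]], na.rm = TRUE),
                sum(!is.na(p[[v]]))))
  invisible(x)
}
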