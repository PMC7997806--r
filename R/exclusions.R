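#' Apply the sequential inclusion/exclusion cascade
#'
#' Applies the study's filtering steps in their stated order and records a
#' complete attrition table. The order is part of the contract — the table
#' is only valid for this sequence:
#'
#' 0. include only procedures with at least one phenylephrine bolus;
#' 1. drop canceled or manually charted procedures (no automated vitals);
#' 2. drop short-duration/rapid-turnover categories (default colonoscopy,
#'    endoscopy; optionally also procedures shorter than
#'    `min_procedure_min`);
#' 3. drop emergency procedures;
#' 4. drop procedures with any blood transfusion;
#' 5. drop procedures with crystalloid volume strictly over `fluid_cap_ml`;
#' 6. drop phenylephrine boluses within `propofol_exclusion_min` minutes of
#'    a propofol bolus, and procedures left with no bolus;
#' 7. keep only each patient's chronologically first retained procedure;
#' 8. keep only the first retained bolus within it;
#' 9. drop patients with BMI strictly over `bmi_cap` (data-entry artifact);
#' 10. drop procedures with ASA physical status 5.
#'
#' BMI and ASA are applied last, mirroring the prose order of the source
#' criteria.
#'
#' @param bundle a `perioperative_cohort`.
#' @param config a [pipeline_config()].
#' @return list of class `exclusion_cascade`: `index_boluses` (one retained
#'   phenylephrine bolus per patient), `procedures` (retained index
#'   procedures), and `attrition` (class `attrition_table`).
#' @export
apply_cascade <- function(bundle, config = pipeline_config()) {
  pr <- bundle$procedures
  me <- bundle$medications
  pe <- me[me$drug == "phenylephrine", , drop = FALSE]

  unknown <- setdiff(config$short_procedure_categories, unique(pr$category))
  if (length(unknown))
    warning("short-procedure categories not present in data: ",
            paste(unknown, collapse = ", "))

  steps <- list()
  live <- pr[pr$procedure_id %in% unique(pe$procedure_id), , drop = FALSE]
  steps[["has phenylephrine bolus"]] <-
    list(before = pr, after = live,
         note = "inclusion: >=1 phenylephrine bolus")

  drop_step <- function(live, name, drop_idx) {
    after <- live[!drop_idx, , drop = FALSE]
    steps[[name]] <<- list(before = live, after = after)
    after
  }

  live <- drop_step(live, "canceled or manually charted", live$canceled_or_manual)
  short <- live$category %in% config$short_procedure_categories
  if (config$min_procedure_min > 0)
    short <- short | (live$end - live$start) < config$min_procedure_min * 60
  live <- drop_step(live, "short-duration category", short)
  live <- drop_step(live, "emergency procedure", live$emergency)
  live <- drop_step(live, "blood transfusion", live$transfusion)
  live <- drop_step(live, "crystalloid > cap",
                    live$crystalloid_ml > config$fluid_cap_ml)

  # step 6: bolus-level propofol proximity; procedures left bolus-less drop
  pe_live <- pe[pe$procedure_id %in% live$procedure_id, , drop = FALSE]
  prox <- propofol_proximal(pe_live, me, config$propofol_exclusion_min)
  pe_live <- pe_live[!prox, , drop = FALSE]
  live <- drop_step(live, "propofol within exclusion window",
                    !(live$procedure_id %in% unique(pe_live$procedure_id)))

  # steps 7-8: first retained case, first retained bolus per patient
  idx <- select_index_bolus(pe_live, live, me, 0)  # proximity already applied
  first_proc <- live$procedure_id %in% idx$procedure_id
  live <- drop_step(live, "first procedure per patient", !first_proc)
  steps[["first bolus per patient"]] <- list(before = live, after = live)

  bmi <- bundle$patients$bmi[match(live$patient_id, bundle$patients$patient_id)]
  live <- drop_step(live, "BMI > cap", bmi > config$bmi_cap)
  live <- drop_step(live, "ASA 5", live$asa == 5)

  idx <- idx[idx$procedure_id %in% live$procedure_id, , drop = FALSE]
  rownames(idx) <- NULL
  out <- list(index_boluses = idx,
              procedures = live,
              attrition = build_attrition(steps))
  class(out) <- "exclusion_cascade"
  out
}

build_attrition <- function(steps) {
  rows <- lapply(names(steps), function(nm) {
    s <- steps[[nm]]
    data.frame(step = nm,
               n_patients_in = length(unique(s$before$patient_id)),
               n_procedures_in = nrow(s$before),
               n_procedures_excluded = nrow(s$before) - nrow(s$after),
               n_patients_excluded = length(unique(s$before$patient_id)) -
                 length(unique(s$after$patient_id)),
               n_procedures_out = nrow(s$after),
               n_patients_out = length(unique(s$after$patient_id)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("attrition_table", "data.frame")
  out
}

#' @export
print.attrition_table <- function(x, ...) {
  cat("Attrition table (procedures / patients)\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-38s %6d -> %6d proc (-%d) | %6d -> %6d pat (-%d)\n",
                x$step[i], x$n_procedures_in[i], x$n_procedures_out[i],
                x$n_procedures_excluded[i], x$n_patients_in[i],
                x$n_patients_out[i], x$n_patients_excluded[i]))
  invisible(x)
}

#' @export
print.exclusion_cascade <- function(x, ...) {
  print(x$attrition)
  cat(sprintf("Retained: %d patients with an index bolus\n",
              nrow(x$index_boluses)))
  invisible(x)
}
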