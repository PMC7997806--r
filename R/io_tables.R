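#' Write a cohort bundle to a directory of plain-text files
#'
#' Writes patients, procedures, vitals and medications as UTF-8 CSV with
#' ISO-8601 UTC timestamps, genotypes as minimal VCFv4.2 (plus a
#' dosage-matrix TSV alternative), and the ground truth (if present) as a
#' separate CSV that the pipeline never reads.
#'
#' @param bundle a `perioperative_cohort` or a compatible list of tables.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pr <- bundle$procedures
  pr$start <- iso8601(pr$start)
  pr$end <- iso8601(pr$end)
  vi <- bundle$vitals
  vi$valid <- NULL  # validity is assigned by the filter, never stored
  vi$timestamp <- iso8601(vi$timestamp)
  me <- bundle$medications
  me$timestamp <- iso8601(me$timestamp)
  write.csv(bundle$patients, file.path(dir, "patients.csv"), row.names = FALSE)
  write.csv(pr, file.path(dir, "procedures.csv"), row.names = FALSE)
  write.csv(vi, file.path(dir, "vitals.csv"), row.names = FALSE)
  write.csv(me, file.path(dir, "medications.csv"), row.names = FALSE)
  if (!is.null(bundle$genotypes)) {
    write_vcf(bundle$genotypes, bundle$variants, file.path(dir, "genotypes.vcf"))
    write_dosage_matrix(bundle$genotypes, bundle$variants,
                        file.path(dir, "dosages.tsv"))
  }
  gt <- bundle$ground_truth
  if (!is.null(gt)) {
    amp <- data.frame(patient_id = names(gt$amplitude),
                      amplitude = unname(gt$amplitude))
    if (!is.null(gt$carrier)) amp <- cbind(amp, gt$carrier)
    write.csv(amp, file.path(dir, "ground_truth_patients.csv"), row.names = FALSE)
    write.csv(gt$boluses, file.path(dir, "ground_truth_boluses.csv"),
              row.names = FALSE)
  }
  invisible(dir)
}

#' Read a cohort bundle from a directory
#'
#' Reads the four tabular CSV files (and `genotypes.vcf` if present), parses
#' ISO-8601 timestamps to epoch seconds, and checks referential integrity:
#' every vitals and medication row must point to an existing procedure and
#' patient, and every procedure to an existing patient. Readers never
#' mutate values: no unit conversion, no imputation, and no validity
#' flagging (see [flag_validity()]).
#'
#' @param dir directory written by [write_cohort()] (or hand-assembled with
#'   the same headers).
#' @return A list of class `perioperative_cohort`.
#' @export
read_cohort <- function(dir) {
  patients <- read_table_checked(file.path(dir, "patients.csv"),
                                 c("patient_id", "age", "sex", "bmi", "ancestry"))
  procedures <- read_table_checked(file.path(dir, "procedures.csv"),
                                   c("procedure_id", "patient_id", "start", "end",
                                     "category", "emergency", "transfusion",
                                     "crystalloid_ml", "anesthesia_type", "mac",
                                     "asa", "canceled_or_manual"))
  vitals <- read_table_checked(file.path(dir, "vitals.csv"),
                               c("patient_id", "procedure_id", "timestamp",
                                 "bp_type", "value", "source"))
  medications <- read_table_checked(file.path(dir, "medications.csv"),
                                    c("patient_id", "procedure_id", "drug",
                                      "dose", "timestamp"))
  procedures$start <- parse_iso8601(procedures$start, "procedures.csv")
  procedures$end <- parse_iso8601(procedures$end, "procedures.csv")
  vitals$timestamp <- parse_iso8601(vitals$timestamp, "vitals.csv")
  medications$timestamp <- parse_iso8601(medications$timestamp, "medications.csv")

  check_integrity(procedures$patient_id, patients$patient_id,
                  "procedures.csv", "patient_id")
  check_integrity(vitals$patient_id, patients$patient_id, "vitals.csv", "patient_id")
  check_integrity(vitals$procedure_id, procedures$procedure_id,
                  "vitals.csv", "procedure_id")
  check_integrity(medications$patient_id, patients$patient_id,
                  "medications.csv", "patient_id")
  check_integrity(medications$procedure_id, procedures$procedure_id,
                  "medications.csv", "procedure_id")

  geno <- NULL; variants <- NULL
  vcf_path <- file.path(dir, "genotypes.vcf")
  if (file.exists(vcf_path)) {
    g <- read_genotypes(vcf_path)
    geno <- g$genotypes
    variants <- g$variants
  }
  out <- list(patients = patients, procedures = procedures, vitals = vitals,
              medications = medications, genotypes = geno, variants = variants,
              ground_truth = NULL, config = NULL)
  class(out) <- "perioperative_cohort"
  out
}

read_table_checked <- function(path, required) {
  if (!file.exists(path)) stop("missing input file: ", path)
  x <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop(sprintf("%s: missing column(s) %s", basename(path),
                 paste(missing, collapse = ", ")))
  x
}

check_integrity <- function(keys, universe, file, field) {
  bad <- which(!(keys %in% universe))
  if (length(bad))
    stop(sprintf("%s: dangling %s '%s' at row %d", file, field,
                 keys[bad[1]], bad[1]))
  invisible(TRUE)
}

iso8601 <- function(t) {
  format(as.POSIXct(t, origin = "1970-01-01", tz = "UTC"), "%Y-%m-%dT%H:%M:%SZ")
}

parse_iso8601 <- function(s, file) {
  t <- as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  bad <- which(is.na(t) & !is.na(s))
  if (length(bad))
    stop(sprintf("%s: unparseable timestamp '%s' at row %d", file, s[bad[1]], bad[1]))
  as.numeric(t)
}
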