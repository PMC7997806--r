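#' Pipeline analysis configuration
#'
#' Parameters for phenotype derivation, the exclusion cascade, covariate
#' adjustment, the mixed-model scan and the enrichment test. Defaults are
#' the study values: 5 minute response windows; validity ranges 60-240 mmHg
#' (SBP), 30-120 (DBP), 30-130 (MAP); phenylephrine boluses within 10 min
#' of a propofol bolus excluded; procedures with more than 5 L of charted
#' crystalloid excluded; BMI cap 100; short-duration categories
#' colonoscopy/endoscopy; ten principal components; genome-wide and
#' suggestive significance at 5e-8 and 1e-5; region enrichment at p < 1e-3
#' with 1000 size-matched random draws.
#'
#' @param window_s response window half-width, seconds (5 min before and
#'   after the bolus).
#' @param validity_ranges named list of inclusive \[lo, hi\] mmHg ranges per
#'   bp_type.
#' @param propofol_exclusion_min exclusion radius around propofol boluses,
#'   minutes (applied symmetrically).
#' @param fluid_cap_ml crystalloid volume cap; strictly greater values are
#'   excluded.
#' @param bmi_cap BMI cap; strictly greater values are excluded.
#' @param short_procedure_categories category labels treated as
#'   short-duration/rapid-turnover.
#' @param min_procedure_min optional minimum procedure duration in minutes
#'   (0 disables; the category rule is the primary mechanism).
#' @param covariates covariate columns entered in adjusted models.
#' @param n_pcs number of principal components used as covariates.
#' @param p_genome_wide,p_suggestive significance thresholds flagged in
#'   the association output.
#' @param enrichment_p_threshold per-variant p threshold defining a region
#'   "hit".
#' @param enrichment_n_perm number of random region draws.
#' @param enrichment_flank_bp half-width of template regions built around
#'   index variants (regions span index position +/- this, 1 Mb total).
#' @param seed integer seed for the stochastic stages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(window_s = 300,
                            validity_ranges = list(SBP = c(60, 240),
                                                   DBP = c(30, 120),
                                                   MAP = c(30, 130)),
                            propofol_exclusion_min = 10,
                            fluid_cap_ml = 5000,
                            bmi_cap = 100,
                            short_procedure_categories = c("colonoscopy", "endoscopy"),
                            min_procedure_min = 0,
                            covariates = c("age_z", "sex", "bmi", "asa", "mac",
                                           "dose", "crystalloid_ml"),
                            n_pcs = 10,
                            p_genome_wide = 5e-8,
                            p_suggestive = 1e-5,
                            enrichment_p_threshold = 1e-3,
                            enrichment_n_perm = 1000,
                            enrichment_flank_bp = 5e5,
                            seed = 1L) {
  cfg <- list(window_s = window_s,
              validity_ranges = validity_ranges,
              propofol_exclusion_min = propofol_exclusion_min,
              fluid_cap_ml = fluid_cap_ml,
              bmi_cap = bmi_cap,
              short_procedure_categories = short_procedure_categories,
              min_procedure_min = min_procedure_min,
              covariates = covariates,
              n_pcs = as.integer(n_pcs),
              p_genome_wide = p_genome_wide,
              p_suggestive = p_suggestive,
              enrichment_p_threshold = enrichment_p_threshold,
              enrichment_n_perm = as.integer(enrichment_n_perm),
              enrichment_flank_bp = enrichment_flank_bp,
              seed = as.integer(seed))
  thresholds <- c(cfg$window_s, cfg$propofol_exclusion_min, cfg$fluid_cap_ml,
                  cfg$bmi_cap, cfg$p_genome_wide, cfg$p_suggestive,
                  cfg$enrichment_p_threshold, cfg$enrichment_n_perm)
  if (any(thresholds <= 0)) stop("all thresholds must be positive")
  stopifnot(all(c("SBP", "DBP", "MAP") %in% names(cfg$validity_ranges)))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML mapping whose keys are [pipeline_config()] arguments;
#' unspecified keys keep their defaults.
#'
#' @param path a YAML file.
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    warning("ignoring unknown config key(s): ", paste(unknown, collapse = ", "))
  y <- y[intersect(names(y), known)]
  if (!is.null(y$validity_ranges))
    y$validity_ranges <- lapply(y$validity_ranges, as.numeric)
  do.call(pipeline_config, y)
}
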