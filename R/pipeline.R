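#' Run the full analysis pipeline on a cohort bundle
#'
#' Derives the bolus-response phenotype (validity filter, exclusion
#' cascade, index-bolus extraction), compares ancestry groups (Mann-Whitney
#' and covariate-adjusted contrasts), runs the mixed-model association scan
#' per stratum, and tests enrichment of the scan's signal in a set of
#' candidate regions. When `regions` is NULL and the bundle carries a
#' simulator ground truth, templates are built around the configured causal
#' and non-responder variants plus randomly chosen variants, up to
#' `n_regions`; enrichment is skipped when no regions can be formed.
#'
#' @param bundle a `perioperative_cohort`, e.g. from [simulate_cohort()] or
#'   [read_cohort()].
#' @param config a [pipeline_config()].
#' @param phenotype phenotype column scanned (default `"delta_sbp"`, the
#'   measure with the largest between-group differences).
#' @param regions optional candidate regions for the enrichment stage
#'   (chrom, start, end); see [read_bed()].
#' @param n_regions number of template regions to synthesize when `regions`
#'   is NULL (default 50).
#' @return list of class `pressor_pipeline` with elements `phenotypes`,
#'   `attrition`, `comparison`, `gwas`, `enrichment` (possibly NULL), and
#'   the configs used.
#' @export
run_pipeline <- function(bundle, config = pipeline_config(),
                         phenotype = "delta_sbp", regions = NULL,
                         n_regions = 50) {
  derived <- derive_phenotypes(bundle, config)
  phen <- derived$phenotypes
  covars <- covariate_table(bundle, phen)
  comparison <- compare_ancestry_groups(
    cbind(phen[c("patient_id", "delta_sbp", "delta_map", "delta_dbp")],
          covars[setdiff(names(covars), "patient_id")]),
    phenotype = phenotype,
    covariates = config$covariates)

  scan <- NULL
  if (!is.null(bundle$genotypes))
    scan <- run_gwas(bundle, phen, config, phenotype = phenotype)

  enrichment <- NULL
  if (!is.null(scan)) {
    set.seed(config$seed)
    if (is.null(regions))
      regions <- default_template_regions(bundle, config, n_regions)
    if (!is.null(regions) && nrow(regions)) {
      chrom_lengths <- bundle$config$chrom_lengths %||%
        hg19_autosome_lengths()
      enrichment <- permutation_enrichment(
        scan$results[["ALL"]], regions, chrom_lengths,
        n_perm = config$enrichment_n_perm,
        p_threshold = config$enrichment_p_threshold)
    }
  }
  out <- list(phenotypes = phen, attrition = derived$attrition,
              comparison = comparison, gwas = scan, enrichment = enrichment,
              config = config)
  class(out) <- "pressor_pipeline"
  out
}

# Template regions around the simulator's planted variants, padded with
# randomly chosen variants to n_regions; NULL without a variant table.
default_template_regions <- function(bundle, config, n_regions) {
  if (is.null(bundle$variants)) return(NULL)
  planted <- integer(0)
  sc <- bundle$config
  if (!is.null(sc)) {
    if (!is.null(sc$causal_common)) planted <- c(planted, sc$causal_common$index)
    if (!is.null(sc$nonresponder_variants))
      planted <- c(planted, sc$nonresponder_variants$index)
  }
  extra <- setdiff(seq_len(nrow(bundle$variants)), planted)
  n_extra <- max(n_regions - length(planted), 0)
  idx <- c(planted, sample(extra, min(n_extra, length(extra))))
  chrom_lengths <- sc$chrom_lengths %||% hg19_autosome_lengths()
  make_loci_regions(bundle$variants, idx, chrom_lengths,
                    config$enrichment_flank_bp)
}

#' @export
print.pressor_pipeline <- function(x, ...) {
  cat("== Attrition ==\n"); print(x$attrition)
  cat("\n== Ancestry comparison ==\n"); print(x$comparison)
  if (!is.null(x$gwas)) { cat("\n== Association scan ==\n"); print(x$gwas) }
  if (!is.null(x$enrichment)) { cat("\n== Region enrichment ==\n"); print(x$enrichment) }
  invisible(x)
}
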