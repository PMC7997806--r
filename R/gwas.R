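#' Build the covariate table for adjusted models and the mixed-model scan
#'
#' One row per phenotyped patient: age z-score, sex, BMI, and the index
#' procedure's ASA status, depth of anesthesia (MAC), index bolus dose and
#' total crystalloid volume.
#'
#' @param bundle a `perioperative_cohort`.
#' @param phenotypes the phenotype table from [derive_phenotypes()] (its
#'   `phenotypes` element), carrying patient_id, procedure_id and dose.
#' @return data.frame keyed by patient_id.
#' @export
covariate_table <- function(bundle, phenotypes) {
  pa <- bundle$patients[match(phenotypes$patient_id, bundle$patients$patient_id), ]
  pr <- bundle$procedures[match(phenotypes$procedure_id,
                                bundle$procedures$procedure_id), ]
  data.frame(patient_id = phenotypes$patient_id,
             age_z = age_zscore(pa$age),
             sex = pa$sex,
             bmi = pa$bmi,
             asa = pr$asa,
             mac = pr$mac,
             dose = phenotypes$dose,
             crystalloid_ml = pr$crystalloid_ml,
             ancestry = pa$ancestry,
             stringsAsFactors = FALSE)
}

#' Mixed-model genome-wide association scan
#'
#' For each population stratum (the whole cohort plus each ancestry group
#' with at least `min_stratum_n` genotyped, phenotyped samples): compute
#' the stratum GRM, its top principal components, fit the REML polygenic
#' null model with the configured covariates plus PCs, and score-test every
#' variant. Principal components are recomputed within each stratum.
#' Variants are flagged at the genome-wide (`p < 5e-8`) and suggestive
#' (`p < 1e-5`) thresholds; no MAF filter is applied, but variants with
#' minor-allele count below 3 are flagged unstable. The genomic inflation
#' factor is reported per stratum, and the mean phenotype of carriers
#' (dosage >= 1) is recorded for flagged variants.
#'
#' @param bundle a `perioperative_cohort` (genotypes required).
#' @param phenotypes phenotype table from [derive_phenotypes()].
#' @param config a [pipeline_config()].
#' @param phenotype phenotype column to scan (default `"delta_sbp"`).
#' @param strata stratum labels; `"ALL"` plus ancestry labels by default.
#' @param min_stratum_n strata smaller than this are skipped with a
#'   warning (default 50).
#' @return An object of class `gwas_scan`: per-stratum summary-statistic
#'   data.frames (chrom, pos, id, maf, mac, beta, se, p, n, flags, carrier
#'   mean), per-stratum `lambda_gc`, and the fitted null models.
#' @export
run_gwas <- function(bundle, phenotypes, config = pipeline_config(),
                     phenotype = "delta_sbp", strata = NULL,
                     min_stratum_n = 50) {
  if (is.null(bundle$genotypes)) stop("bundle has no genotypes")
  covars <- covariate_table(bundle, phenotypes)
  y_all <- phenotypes[[phenotype]]
  ok <- !is.na(y_all) & phenotypes$patient_id %in% rownames(bundle$genotypes)
  if (is.null(strata)) strata <- c("ALL", sort(unique(covars$ancestry)))

  results <- list(); lambdas <- c(); nulls <- list()
  for (st in strata) {
    sel <- ok & (st == "ALL" | covars$ancestry == st)
    n_st <- sum(sel)
    if (n_st < min_stratum_n) {
      warning(sprintf("stratum %s skipped: %d samples < %d", st, n_st,
                      min_stratum_n))
      next
    }
    y <- y_all[sel]
    G <- bundle$genotypes[phenotypes$patient_id[sel], , drop = FALSE]
    K <- compute_grm(G)
    pcs <- compute_pcs(K, min(config$n_pcs, n_st - 1))
    cv <- covars[sel, intersect(config$covariates, names(covars)), drop = FALSE]
    X <- model.matrix(~ ., data = cbind(cv, as.data.frame(pcs)))
    null <- fit_lmm_null(y, X, K)
    res <- score_test(null, G)
    res <- cbind(bundle$variants[match(res$id, bundle$variants$id),
                                 c("chrom", "pos")], res)
    res$genome_wide <- !is.na(res$p) & res$p < config$p_genome_wide
    res$suggestive <- !is.na(res$p) & res$p < config$p_suggestive
    res$unstable <- res$mac < 3
    res$carrier_mean <- NA_real_
    flag <- which(res$genome_wide | res$suggestive)
    for (i in flag) {
      carriers <- G[, res$id[i]] >= 1
      if (any(carriers, na.rm = TRUE))
        res$carrier_mean[i] <- mean(y[carriers], na.rm = TRUE)
    }
    rownames(res) <- NULL
    results[[st]] <- res
    lambdas[st] <- genomic_inflation(res$p)
    nulls[[st]] <- null
  }
  out <- list(results = results, lambda_gc = lambdas, null_models = nulls,
              phenotype = phenotype,
              n = vapply(results, function(r) r$n[1], 0))
  class(out) <- "gwas_scan"
  out
}

#' Write per-stratum summary statistics as TSV
#'
#' One file per stratum, columns chrom, pos, id, maf, beta, se, p (one row
#' per tested variant).
#'
#' @param scan a `gwas_scan`.
#' @param dir output directory.
#' @return the file paths, invisibly.
#' @export
write_summary_stats <- function(scan, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (st in names(scan$results)) {
    path <- file.path(dir, sprintf("gwas_%s_%s.tsv", scan$phenotype, st))
    write.table(scan$results[[st]][, c("chrom", "pos", "id", "maf", "beta",
                                       "se", "p")],
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' @export
print.gwas_scan <- function(x, ...) {
  cat(sprintf("Mixed-model association scan of %s\n", x$phenotype))
  for (st in names(x$results)) {
    r <- x$results[[st]]
    cat(sprintf("  %s: n=%d, %d variants tested, %d genome-wide, %d suggestive, lambda_gc=%.4f\n",
                st, r$n[1], sum(is.na(r$skipped)), sum(r$genome_wide),
                sum(r$suggestive), x$lambda_gc[st]))
  }
  invisible(x)
}

#' Manhattan-style plot of a scan stratum
#'
#' Minimal base-graphics Manhattan plot with the genome-wide (5e-8) and
#' suggestive (1e-5) thresholds drawn.
#'
#' @param x a `gwas_scan`.
#' @param stratum stratum to plot (default the first).
#' @param ... passed to [plot()].
#' @export
plot.gwas_scan <- function(x, stratum = names(x$results)[1], ...) {
  r <- x$results[[stratum]]
  r <- r[!is.na(r$p), ]
  chrom <- factor(r$chrom, levels = unique(r$chrom[order(r$chrom)]))
  offs <- c(0, cumsum(tapply(r$pos, chrom, max)))
  xpos <- r$pos + offs[as.integer(chrom)]
  plot(xpos, -log10(r$p), pch = 20, cex = 0.5,
       col = c("grey30", "steelblue")[1 + as.integer(chrom) %% 2],
       xlab = "genome position", ylab = expression(-log[10](p)),
       main = sprintf("%s (%s)", x$phenotype, stratum), ...)
  abline(h = -log10(5e-8), col = "red", lty = 2)
  abline(h = -log10(1e-5), col = "blue", lty = 3)
  invisible(x)
}
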