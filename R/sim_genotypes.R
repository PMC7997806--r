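#' Simulate genotype dosages under Balding-Nichols population structure
#'
#' Draws bi-allelic dosages in \{0, 1, 2\} for a multi-ancestry cohort. Each
#' variant has an ancestral allele frequency `p ~ Uniform(0.05, 0.95)`; each
#' ancestry group draws its own frequency from
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)` with drift parameter `F` (the
#' Balding-Nichols model), so Hardy-Weinberg holds within groups while
#' allele frequencies drift between them. Configured non-responder variants
#' are forced to their target minor allele frequency in the target ancestry
#' and are absent elsewhere. Variants are placed uniformly on the synthetic
#' genome (chromosome chosen with probability proportional to length,
#' position uniform; 1-based coordinates).
#'
#' @param config a [sim_config()] object.
#' @param ancestry optional character vector of per-patient ancestry labels;
#'   by default labels are allocated proportionally to
#'   `config$ancestry_proportions` and shuffled.
#'
#' @return A list with `genotypes` (n x m integer matrix, rownames patient
#'   ids), `variants` (data.frame: chrom, pos, id, ref, alt), `ancestry`
#'   (character vector), and `freq` (m x K matrix of the true per-ancestry
#'   allele frequencies, for parameter-recovery checks; not consumed by the
#'   pipeline).
#' @export
simulate_genotypes <- function(config, ancestry = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_patients
  m <- config$n_variants
  labels <- names(config$ancestry_proportions)

  if (is.null(ancestry)) {
    ancestry <- allocate_ancestry(n, config$ancestry_proportions)
  }
  stopifnot(length(ancestry) == n, all(ancestry %in% labels))

  p_anc <- runif(m, 0.05, 0.95)
  freq <- matrix(NA_real_, m, length(labels), dimnames = list(NULL, labels))
  for (k in labels) {
    f <- config$fst[[k]]
    if (is.null(f) || f == 0) {
      freq[, k] <- p_anc
    } else {
      shape <- (1 - f) / f
      freq[, k] <- rbeta(m, p_anc * shape, (1 - p_anc) * shape)
    }
  }

  nr <- config$nonresponder_variants
  if (!is.null(nr) && nrow(nr)) {
    for (i in seq_len(nrow(nr))) {
      idx <- nr$index[i]
      if (idx > m) stop("non-responder variant index exceeds n_variants")
      freq[idx, ] <- 0
      freq[idx, nr$ancestry[i]] <- nr$maf[i]
      n_target <- sum(ancestry == nr$ancestry[i])
      if (nr$maf[i] * n_target < 1)
        warning(sprintf(
          "non-responder variant %d: expected carriers < 1 (MAF %.4f x n %d)",
          idx, nr$maf[i], n_target))
    }
  }

  geno <- matrix(0L, n, m)
  for (k in labels) {
    rows <- which(ancestry == k)
    if (!length(rows)) next
    pk <- freq[, k]
    draws <- rbinom(length(rows) * m, 2L, rep(pk, each = length(rows)))
    geno[rows, ] <- matrix(as.integer(draws), length(rows), m)
  }
  rownames(geno) <- sprintf("P%05d", seq_len(n))

  variants <- place_variants(m, config$chrom_lengths)
  colnames(geno) <- variants$id
  list(genotypes = geno, variants = variants, ancestry = ancestry, freq = freq)
}

# Proportional allocation of ancestry labels (largest-remainder), shuffled.
allocate_ancestry <- function(n, proportions) {
  counts <- floor(n * proportions)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- n * proportions - counts
    extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  sample(rep(names(proportions), counts))
}

place_variants <- function(m, chrom_lengths) {
  ch <- sample.int(length(chrom_lengths), m, replace = TRUE,
                   prob = chrom_lengths)
  pos <- floor(runif(m, 1, chrom_lengths[ch] + 1))
  data.frame(chrom = names(chrom_lengths)[ch],
             pos = as.numeric(pos),
             id = sprintf("var%05d", seq_len(m)),
             ref = "A", alt = "G",
             stringsAsFactors = FALSE)
}
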