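#' Compute the genetic relationship matrix
#'
#' Allele-frequency-standardized (VanRaden) GRM:
#' `K[i, j] = (1 / M) * sum_m (g_im - 2 p_m)(g_jm - 2 p_m) / (2 p_m (1 - p_m))`
#' over the M polymorphic variants, with `p_m` the sample allele frequency.
#' Missing dosages are mean-imputed per variant before standardization;
#' monomorphic variants are skipped and counted.
#'
#' @param genotypes n x m dosage matrix (0/1/2, `NA` allowed).
#' @return symmetric n x n matrix with attributes `n_variants` (variants
#'   used) and `n_skipped` (monomorphic variants skipped).
#' @export
compute_grm <- function(genotypes) {
  stopifnot(nrow(genotypes) >= 2, ncol(genotypes) >= 1)
  G <- mean_impute(genotypes)
  p <- colMeans(G) / 2
  poly <- p > 0 & p < 1 & (colMeans(G^2) - colMeans(G)^2) > 0
  if (!any(poly)) stop("all variants are monomorphic")
  G <- G[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(G, 2, 2 * p, `-`)
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), `/`)
  K <- tcrossprod(Z) / ncol(Z)
  dimnames(K) <- list(rownames(genotypes), rownames(genotypes))
  attr(K, "n_variants") <- ncol(Z)
  attr(K, "n_skipped") <- sum(!poly)
  K
}

mean_impute <- function(G) {
  if (!anyNA(G)) return(G)
  storage.mode(G) <- "double"
  mu <- colMeans(G, na.rm = TRUE)
  na_idx <- which(is.na(G), arr.ind = TRUE)
  G[na_idx] <- mu[na_idx[, 2]]
  G
}

#' Principal components of a genetic relationship matrix
#'
#' Top-k eigenvectors of the GRM scaled by the square root of their
#' eigenvalues. Sign convention: each component is flipped so its
#' largest-magnitude loading is positive, making the output deterministic.
#'
#' @param K symmetric GRM from [compute_grm()].
#' @param k number of components (default 10); must be below `nrow(K)`.
#' @return n x k matrix of PC scores (columns `PC1` ... `PCk`), with the
#'   eigenvalues in attribute `eigenvalues`.
#' @export
compute_pcs <- function(K, k = 10) {
  n <- nrow(K)
  if (k >= n) stop("k must be smaller than the number of samples")
  e <- eigen(K, symmetric = TRUE)
  vals <- pmax(e$values[seq_len(k)], 0)
  scores <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(vals), k)
  for (j in seq_len(k)) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(K)
  attr(scores, "eigenvalues") <- e$values[seq_len(k)]
  scores
}
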