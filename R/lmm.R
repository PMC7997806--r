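#' Fit the polygenic null model by REML
#'
#' Fits `y = X beta + g + e` with `g ~ N(0, sigma2_g K)` and
#' `e ~ N(0, sigma2_e I)`, where `K` is a genetic relationship matrix.
#' After one eigendecomposition of `K` the restricted likelihood is a
#' one-dimensional function of the heritability ratio
#' `h2 = sigma2_g / (sigma2_g + sigma2_e)`, maximized over
#' `[0, 1 - 1e-6]` by golden-section search (tolerance 1e-6) with the
#' boundary candidates checked explicitly, so a data set with no polygenic
#' signal lands exactly on `h2 = 0` and the fixed effects reduce to OLS.
#' The total variance is profiled out analytically.
#'
#' @param y numeric phenotype vector (no missing values).
#' @param X fixed-effect design matrix (include the intercept column);
#'   must be full rank.
#' @param K genetic relationship matrix, positive semi-definite (smallest
#'   eigenvalue above -1e-8).
#' @param tol convergence tolerance on h2.
#' @return An object of class `lmm_null` with components `beta` (named
#'   fixed-effect estimates), `se`, `sigma2_g`, `sigma2_e`, `h2`, `logLik`
#'   (restricted), `n`, `p`, and the rotated quantities used by
#'   [score_test()].
#' @seealso [score_test()], [compute_grm()]
#' @export
fit_lmm_null <- function(y, X, K, tol = 1e-6) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(K) == n, ncol(K) == n)
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design matrix is rank deficient")
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) < -1e-8)
    stop("K is not positive semi-definite (smallest eigenvalue ",
         format(min(e$values)), ")")
  lambda <- pmax(e$values, 0)
  U <- e$vectors
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)
  p <- ncol(X)

  reml <- function(h2) {
    v <- h2 * lambda + (1 - h2)
    w <- 1 / v
    XtWX <- crossprod(Xt, Xt * w)
    XtWy <- crossprod(Xt, yt * w)
    beta <- solve(XtWX, XtWy)
    r <- yt - Xt %*% beta
    rss <- sum(r^2 * w)
    s2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * (1 + log(2 * pi * s2)) + sum(log(v)) +
                    determinant(XtWX, logarithm = TRUE)$modulus)
    list(ll = as.numeric(ll), beta = beta, s2 = s2, w = w, r = r, XtWX = XtWX)
  }

  upper <- 1 - 1e-6
  opt <- optimize(function(h) reml(h)$ll, c(0, upper), maximum = TRUE, tol = tol)
  cand <- c(0, opt$maximum, upper)
  lls <- vapply(cand, function(h) reml(h)$ll, 0)
  h2 <- cand[which.max(lls)]
  fit <- reml(h2)

  sigma2 <- fit$s2
  XtWX_inv <- solve(fit$XtWX)
  out <- list(beta = setNames(as.numeric(fit$beta), colnames(X)),
              se = sqrt(diag(XtWX_inv) * sigma2),
              sigma2_g = h2 * sigma2,
              sigma2_e = (1 - h2) * sigma2,
              h2 = h2,
              logLik = fit$ll,
              n = n, p = p,
              # rotated-space quantities for the score test:
              U = U, lambda = lambda,
              w = fit$w / sigma2,          # diagonal of V^{-1} in rotated space
              r = as.numeric(fit$r),       # rotated residual y~ - X~ beta
              Xt = Xt,
              XtVX_inv = XtWX_inv * sigma2,
              y = y, X = X)
  class(out) <- "lmm_null"
  out
}

#' Score test of candidate variants against a fitted null model
#'
#' Efficient score test for adding one dosage vector at a time to a fitted
#' [fit_lmm_null()] model, without refitting: with projection
#' `P = V^{-1} - V^{-1} X (X' V^{-1} X)^{-1} X' V^{-1}` evaluated at the
#' null variance components, the statistic is `(g' P y)^2 / (g' P g)`,
#' chi-square with 1 df; the effect estimate is `beta = g' P y / g' P g`
#' with `se = 1 / sqrt(g' P g)` (the variance is the null-model variance,
#' as usual for a score test). Missing dosages are mean-imputed per
#' variant; monomorphic variants are skipped with a reason. When
#' `sigma2_g = 0` the test reduces algebraically to OLS.
#'
#' @param null an `lmm_null` object.
#' @param genotypes dosage vector (length n) or n x m matrix.
#' @return data.frame with one row per variant: id, maf (folded), mac,
#'   beta, se, chisq, p, n, skipped (reason or NA).
#' @export
score_test <- function(null, genotypes) {
  stopifnot(inherits(null, "lmm_null"))
  G <- as.matrix(genotypes)
  if (nrow(G) != null$n && ncol(G) == null$n) G <- t(G)
  stopifnot(nrow(G) == null$n)
  ids <- colnames(G)
  if (is.null(ids)) ids <- paste0("v", seq_len(ncol(G)))
  G <- mean_impute(G)
  f <- colMeans(G) / 2
  maf <- pmin(f, 1 - f)
  mac <- round(2 * nrow(G) * maf)
  poly <- maf > 0

  beta <- se <- chisq <- p <- rep(NA_real_, ncol(G))
  if (any(poly)) {
    Gt <- crossprod(null$U, G[, poly, drop = FALSE])
    wr <- null$w * null$r
    s <- as.numeric(crossprod(Gt, wr))                     # g' P y
    A <- crossprod(null$Xt, Gt * null$w)                   # X~' W g~  (p x m)
    gPg <- colSums(Gt^2 * null$w) - colSums(A * (null$XtVX_inv %*% A))
    beta[poly] <- s / gPg
    se[poly] <- 1 / sqrt(gPg)
    chisq[poly] <- s^2 / gPg
    p[poly] <- pchisq(chisq[poly], 1, lower.tail = FALSE)
  }
  data.frame(id = ids, maf = maf, mac = mac, beta = beta, se = se,
             chisq = chisq, p = p, n = nrow(G),
             skipped = ifelse(poly, NA_character_, "monomorphic"),
             stringsAsFactors = FALSE)
}

#' Genomic inflation factor
#'
#' `lambda_GC = median(qchisq(1 - p, 1)) / 0.4549364`, the median
#' association chi-square divided by its expectation under the null.
#'
#' @param p vector of association p values (non-empty).
#' @return scalar lambda.
#' @export
genomic_inflation <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) stop("no p values supplied")
  median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
}

#' @export
print.lmm_null <- function(x, ...) {
  cat("Polygenic null model (REML)\n")
  cat(sprintf("  n = %d, fixed effects = %d\n", x$n, x$p))
  cat(sprintf("  sigma2_g = %.4f, sigma2_e = %.4f (h2 = %.3f)\n",
              x$sigma2_g, x$sigma2_e, x$h2))
  cat(sprintf("  restricted logLik = %.3f\n", x$logLik))
  invisible(x)
}

#' @export
summary.lmm_null <- function(object, ...) {
  z <- object$beta / object$se
  tab <- cbind(Estimate = object$beta, `Std. Error` = object$se,
               `z value` = z, `Pr(>|z|)` = 2 * pnorm(-abs(z)))
  out <- list(coefficients = tab, sigma2_g = object$sigma2_g,
              sigma2_e = object$sigma2_e, h2 = object$h2,
              logLik = object$logLik, n = object$n)
  class(out) <- "summary.lmm_null"
  out
}

#' @export
print.summary.lmm_null <- function(x, ...) {
  cat("Polygenic null model (REML)\n")
  cat(sprintf("  sigma2_g = %.4f, sigma2_e = %.4f (h2 = %.3f), n = %d\n\n",
              x$sigma2_g, x$sigma2_e, x$h2, x$n))
  printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
coef.lmm_null <- function(object, ...) object$beta

#' @export
logLik.lmm_null <- function(object, ...) {
  structure(object$logLik, df = object$p + 2, class = "logLik")
}

#' @export
residuals.lmm_null <- function(object, ...) {
  as.numeric(object$y - object$X %*% object$beta)
}
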