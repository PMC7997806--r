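#' Age z-score standardization
#'
#' Centers and scales age to cohort mean 0 and SD 1. Idempotent up to
#' floating tolerance (re-standardizing a z-score returns it unchanged).
#'
#' @param age numeric vector of ages in years.
#' @return numeric vector of z-scores.
#' @export
age_zscore <- function(age) {
  s <- sd(age)
  if (s == 0) stop("age has zero variance; cannot standardize")
  (age - mean(age)) / s
}

#' Univariate covariate screen
#'
#' Regresses the phenotype on each candidate covariate separately (simple
#' linear regression; factors enter with their full dummy coding and are
#' tested by the model F statistic) and selects covariates with p below
#' `alpha`. Zero-variance covariates are flagged and not tested. The
#' screen informs, but does not dictate, the final model covariate list —
#' a covariate can be retained on substantive grounds regardless of its
#' screening p value (bolus dose is the canonical example).
#'
#' @param y numeric phenotype vector.
#' @param covariates data.frame of candidate covariates (numeric or factor).
#' @param alpha selection threshold (default 0.05).
#' @return data.frame: covariate, p, selected, zero_variance.
#' @export
univariate_screen <- function(y, covariates, alpha = 0.05) {
  stopifnot(nrow(covariates) == length(y))
  rows <- lapply(names(covariates), function(nm) {
    x <- covariates[[nm]]
    ok <- complete.cases(x, y)
    if (sum(ok) < 3)
      stop("covariate ", nm, ": fewer than 3 complete observations")
    xv <- x[ok]
    if (length(unique(xv)) < 2)
      return(data.frame(covariate = nm, p = NA_real_, selected = FALSE,
                        zero_variance = TRUE))
    fit <- lm(y[ok] ~ xv)
    fs <- summary(fit)$fstatistic
    p <- pf_upper(fs[1], fs[2], fs[3])
    data.frame(covariate = nm, p = p, selected = p < alpha,
               zero_variance = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

pf_upper <- function(f, df1, df2) stats::pf(f, df1, df2, lower.tail = FALSE)

#' Mann-Whitney U test
#'
#' Rank-sum test with midrank tie handling. The U statistic counts pairs
#' where a group-A value exceeds a group-B value (ties count one half), so
#' `U` lies in `[0, n_A * n_B]`. The two-sided p value comes from exact
#' enumeration of the rank-sum distribution whenever the data are untied
#' and `n_A * n_B <= exact_limit`, and otherwise from the normal
#' approximation with tie correction and continuity correction. When every
#' value in both groups is identical the test is degenerate and p = 1.
#'
#' @param x,y numeric samples for groups A and B (both non-empty).
#' @param exact_limit use exact enumeration when `length(x) * length(y)`
#'   is at most this and there are no ties (default 400).
#' @return list with `U`, `p`, and `method` ("exact" or "normal").
#' @export
mann_whitney <- function(x, y, exact_limit = 400) {
  stopifnot(length(x) > 0, length(y) > 0, is.numeric(x), is.numeric(y))
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)

  if (all(c(x, y) == c(x, y)[1]))
    return(list(U = U, p = 1, method = "degenerate"))

  if (!has_ties && nx * ny <= exact_limit) {
    cdf <- wilcox_count_distribution(nx, ny)   # counts of U = 0..nx*ny
    total <- sum(cdf)
    p_le <- sum(cdf[seq_len(U + 1)]) / total
    p_ge <- sum(cdf[seq(U + 1, length(cdf))]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(U = U, p = p, method = "exact"))
  }

  n <- nx + ny
  mu <- nx * ny / 2
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- nx * ny / 12 * (n + 1 - tie_term)
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "degenerate"))
  z <- U - mu
  z <- sign(z) * max(abs(z) - 0.5, 0) / sqrt(sigma2)  # continuity correction
  list(U = U, p = min(1, 2 * pnorm(-abs(z))), method = "normal")
}

# Exact null distribution of the Mann-Whitney U statistic for untied data:
# number of size-nx subsets of ranks 1..(nx+ny) attaining each rank sum,
# built by subset-sum dynamic programming over the ranks. Returns counts
# indexed by U = 0..nx*ny. The distribution is symmetric in the two group
# sizes, so the smaller group is enumerated.
wilcox_count_distribution <- function(nx, ny) {
  if (nx > ny) { tmp <- nx; nx <- ny; ny <- tmp }
  n <- nx + ny
  # ways[k + 1, s + 1]: subsets of size k with rank sum s, over ranks seen so far
  smax <- sum((n - nx + 1):n)
  ways <- matrix(0, nx + 1, smax + 1)
  ways[1, 1] <- 1
  for (rank_val in seq_len(n)) {
    kmax <- min(rank_val, nx)
    for (k in kmax:1) {
      shifted <- c(rep(0, rank_val), ways[k, seq_len(smax + 1 - rank_val)])
      ways[k + 1, ] <- ways[k + 1, ] + shifted
    }
  }
  smin <- nx * (nx + 1) / 2
  counts <- ways[nx + 1, (smin:smax) + 1]
  names(counts) <- 0:(nx * ny)
  counts
}

#' Covariate-adjusted ancestry contrasts
#'
#' Ordinary least squares of the phenotype on ancestry indicators (with a
#' configurable reference group) plus covariates and, when provided,
#' principal components. Returns the coefficient, standard error and
#' two-sided p value of each non-reference ancestry: the adjusted mean
#' difference from the reference in mmHg.
#'
#' @param y numeric phenotype.
#' @param ancestry character/factor of group labels.
#' @param covariates data.frame of adjustment covariates (may have zero
#'   columns for an unadjusted contrast, which then equals the group-mean
#'   difference).
#' @param reference reference ancestry label (default `"EA"`).
#' @return data.frame: ancestry, estimate, se, p.
#' @export
adjusted_group_difference <- function(y, ancestry, covariates = NULL,
                                      reference = "EA") {
  ancestry <- factor(ancestry)
  stopifnot(reference %in% levels(ancestry))
  ancestry <- stats::relevel(ancestry, ref = reference)
  df <- data.frame(y = y, ancestry = ancestry)
  if (!is.null(covariates) && ncol(covariates)) df <- cbind(df, covariates)
  ok <- complete.cases(df)
  df <- df[ok, , drop = FALSE]
  X <- model.matrix(~ ., data = df[, -1, drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- lm(y ~ ., data = df)
  tab <- summary(fit)$coefficients
  rows <- grep("^ancestry", rownames(tab))
  data.frame(ancestry = sub("^ancestry", "", rownames(tab)[rows]),
             estimate = tab[rows, 1],
             se = tab[rows, 2],
             p = tab[rows, 4],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Ancestry-group comparison of the derived phenotype
#'
#' For each non-reference ancestry: group mean and standard error,
#' Mann-Whitney U and two-sided p versus the reference group, and the
#' covariate-adjusted contrast (mmHg) with its SE and p.
#'
#' @param phenotypes data.frame with the phenotype column, `ancestry`, and
#'   any covariate columns named in `covariates`.
#' @param phenotype phenotype column name (default `"delta_sbp"`).
#' @param covariates covariate column names for the adjusted model.
#' @param reference reference ancestry (default `"EA"`).
#' @return data.frame of class `ancestry_comparison`.
#' @export
compare_ancestry_groups <- function(phenotypes, phenotype = "delta_sbp",
                                    covariates = c("age_z", "sex", "bmi", "asa",
                                                   "mac", "dose", "crystalloid_ml"),
                                    reference = "EA") {
  covariates <- intersect(covariates, names(phenotypes))
  y <- phenotypes[[phenotype]]
  ok <- !is.na(y)
  y <- y[ok]
  anc <- phenotypes$ancestry[ok]
  cov_df <- phenotypes[ok, covariates, drop = FALSE]
  adj <- adjusted_group_difference(y, anc, cov_df, reference)

  ref_vals <- y[anc == reference]
  groups <- unique(anc)
  rows <- lapply(groups, function(g) {
    v <- y[anc == g]
    mw <- if (g == reference) list(U = NA_real_, p = NA_real_)
          else mann_whitney(v, ref_vals)
    a <- adj[adj$ancestry == g, , drop = FALSE]
    data.frame(ancestry = g, n = length(v),
               mean = mean(v), se = sd(v) / sqrt(length(v)),
               U = mw$U, p_mann_whitney = mw$p,
               adj_estimate = if (nrow(a)) a$estimate else NA_real_,
               adj_se = if (nrow(a)) a$se else NA_real_,
               adj_p = if (nrow(a)) a$p else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$ancestry != reference, out$ancestry), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "phenotype") <- phenotype
  attr(out, "reference") <- reference
  class(out) <- c("ancestry_comparison", "data.frame")
  out
}

#' @export
print.ancestry_comparison <- function(x, ...) {
  cat(sprintf("Ancestry comparison of %s (reference %s)\n",
              attr(x, "phenotype"), attr(x, "reference")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %s (n=%d): mean %.2f mmHg (SE %.2f)", x$ancestry[i],
                x$n[i], x$mean[i], x$se[i]))
    if (!is.na(x$p_mann_whitney[i]))
      cat(sprintf("  MW p=%.3g  adjusted %.2f mmHg (SE %.2f, p=%.3g)",
                  x$p_mann_whitney[i], x$adj_estimate[i], x$adj_se[i],
                  x$adj_p[i]))
    cat("\n")
  }
  invisible(x)
}
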