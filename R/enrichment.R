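#' Count candidate regions containing an association signal
#'
#' A region is "hit" when at least one tested variant inside it (1-based
#' inclusive coordinates) has `p < p_threshold`. Overlapping regions are
#' counted independently. Regions on chromosomes absent from the summary
#' statistics are counted as not hit, with a warning.
#'
#' @param stats summary statistics with columns chrom, pos, p.
#' @param regions data.frame with chrom, start, end (1-based inclusive).
#' @param p_threshold per-variant significance threshold (default 1e-3).
#' @return integer count of hit regions.
#' @export
region_hit_count <- function(stats, regions, p_threshold = 1e-3) {
  missing_chr <- setdiff(unique(regions$chrom), unique(stats$chrom))
  if (length(missing_chr))
    warning("region chromosome(s) absent from summary stats: ",
            paste(missing_chr, collapse = ", "))
  idx <- sig_position_index(stats, p_threshold)
  sum(regions_hit(regions$chrom, regions$start, regions$end, idx))
}

# Sorted significant-variant positions, globally offset so one findInterval
# serves all chromosomes.
sig_position_index <- function(stats, p_threshold) {
  chroms <- unique(stats$chrom)
  offsets <- setNames((seq_along(chroms) - 1) * 2^40, chroms)
  sig <- !is.na(stats$p) & stats$p < p_threshold
  list(offsets = offsets,
       pos = sort(stats$pos[sig] + offsets[stats$chrom[sig]]))
}

regions_hit <- function(chrom, start, end, idx) {
  off <- idx$offsets[chrom]
  gs <- start + off
  ge <- end + off
  known <- !is.na(off)
  hit <- rep(FALSE, length(chrom))
  hit[known] <- findInterval(ge[known], idx$pos) -
    findInterval(gs[known] - 1, idx$pos) > 0
  hit
}

#' Sample size-matched random regions
#'
#' Draws one random region per template region with exactly the same
#' length: a chromosome is chosen with probability proportional to its
#' length among chromosomes long enough to hold the region, and the start
#' uniformly over positions where the region fits. Regions within one draw
#' are non-overlapping (overlapping draws are resolved by resampling only
#' the offending regions, preserving the marginal distribution); random
#' regions may overlap the template regions.
#'
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param template data.frame with chrom, start, end; only the lengths
#'   (end - start + 1) are used.
#' @param seed optional integer seed.
#' @param max_iter resampling passes before giving up.
#' @return data.frame with chrom, start, end, label; same length multiset
#'   as the template.
#' @export
sample_random_regions <- function(chrom_lengths, template, seed = NULL,
                                  max_iter = 200) {
  if (!is.null(seed)) set.seed(seed)
  lens <- template$end - template$start + 1
  if (any(lens > max(chrom_lengths)))
    stop("a template region is longer than every chromosome")
  offsets <- setNames(c(0, cumsum(as.numeric(chrom_lengths)))[seq_along(chrom_lengths)],
                      names(chrom_lengths))
  draw <- function(lens) {
    ch <- integer(length(lens)); st <- numeric(length(lens))
    for (L in unique(lens)) {
      i <- which(lens == L)
      fits <- which(chrom_lengths >= L)
      ch[i] <- fits[sample.int(length(fits), length(i), replace = TRUE,
                               prob = chrom_lengths[fits])]
      st[i] <- floor(runif(length(i), 1, chrom_lengths[ch[i]] - L + 2))
    }
    list(ch = ch, st = st)
  }
  d <- draw(lens)
  gs <- d$st + offsets[d$ch]
  for (iter in seq_len(max_iter)) {
    o <- order(gs)
    overlap <- which(gs[o][-1] <= gs[o][-length(gs)] + lens[o][-length(gs)] - 1)
    if (!length(overlap)) break
    redo <- o[overlap + 1]
    nd <- draw(lens[redo])
    d$ch[redo] <- nd$ch
    d$st[redo] <- nd$st
    gs[redo] <- nd$st + offsets[nd$ch]
    if (iter == max_iter)
      stop("could not place non-overlapping regions after ", max_iter,
           " resampling passes")
  }
  data.frame(chrom = names(chrom_lengths)[d$ch],
             start = d$st,
             end = d$st + lens - 1,
             label = sprintf("random%04d", seq_along(lens)),
             stringsAsFactors = FALSE)
}

#' Permutation enrichment of association signal in candidate regions
#'
#' Counts candidate regions hit at `p < p_threshold`, then builds a null
#' distribution from `n_perm` independent draws of size-matched random
#' region sets ([sample_random_regions()]). The empirical p value uses the
#' plus-one estimator `(1 + #\{null >= observed\}) / (1 + n_perm)` and is
#' therefore never zero.
#'
#' @param stats summary statistics (chrom, pos, p).
#' @param regions candidate regions (chrom, start, end, 1-based inclusive).
#' @param chrom_lengths named chromosome lengths defining the sampling
#'   space.
#' @param n_perm number of random draws (default 1000).
#' @param p_threshold per-variant hit threshold (default 1e-3).
#' @param seed optional integer seed.
#' @return An object of class `enrichment_result`: observed count, null
#'   counts, null mean and SD, empirical p, and the parameters used.
#' @export
permutation_enrichment <- function(stats, regions, chrom_lengths,
                                   n_perm = 1000, p_threshold = 1e-3,
                                   seed = NULL) {
  stopifnot(n_perm >= 1)
  if (!is.null(seed)) set.seed(seed)
  idx <- sig_position_index(stats, p_threshold)
  observed <- region_hit_count(stats, regions, p_threshold)
  lens <- regions$end - regions$start + 1
  null_counts <- vapply(seq_len(n_perm), function(i) {
    r <- sample_random_regions(chrom_lengths, regions)
    sum(regions_hit(r$chrom, r$start, r$end, idx))
  }, 0)
  out <- list(observed = observed,
              null_counts = null_counts,
              null_mean = mean(null_counts),
              null_sd = sd(null_counts),
              empirical_p = (1 + sum(null_counts >= observed)) / (1 + n_perm),
              p_threshold = p_threshold,
              n_regions = nrow(regions),
              n_perm = n_perm,
              seed = seed)
  class(out) <- "enrichment_result"
  out
}

#' Build template regions around index variants
#'
#' One region per index variant, spanning the variant position plus/minus
#' `flank_bp` (1 Mb total at the 5e5 default), truncated at chromosome
#' ends.
#'
#' @param variants variant table (chrom, pos, id).
#' @param indices row indices of the index variants.
#' @param chrom_lengths named chromosome lengths.
#' @param flank_bp half-width in bp.
#' @return data.frame with chrom, start, end, label.
#' @export
make_loci_regions <- function(variants, indices, chrom_lengths, flank_bp = 5e5) {
  v <- variants[indices, , drop = FALSE]
  data.frame(chrom = v$chrom,
             start = pmax(v$pos - flank_bp, 1),
             end = pmin(v$pos + flank_bp, chrom_lengths[v$chrom]),
             label = v$id,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Region enrichment test\n")
  cat(sprintf("  %d of %d regions hit at p < %g\n", x$observed, x$n_regions,
              x$p_threshold))
  cat(sprintf("  random regions: %.1f (+/-%.2f) over %d draws\n",
              x$null_mean, x$null_sd, x$n_perm))
  cat(sprintf("  empirical p = %.4g\n", x$empirical_p))
  invisible(x)
}

#' Histogram of the enrichment null distribution
#'
#' @param x an `enrichment_result`.
#' @param ... passed to [hist()].
#' @export
plot.enrichment_result <- function(x, ...) {
  hist(x$null_counts, breaks = 30, col = "grey80", border = "white",
       xlab = "regions hit in random draws", main = "Region enrichment", ...)
  abline(v = x$observed, col = "red", lwd = 2)
  legend("topright", legend = sprintf("observed = %d (p = %.3g)",
                                      x$observed, x$empirical_p),
         bty = "n")
  invisible(x)
}
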