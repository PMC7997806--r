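fake_stats <- function(chrom, pos, p) {
  data.frame(chrom = chrom, pos = pos, p = p, stringsAsFactors = FALSE)
}

test_that("region hit counting matches hand-countable fixtures", {
  regions <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                        start = c(100, 1000, 50),
                        end = c(500, 2000, 600),
                        label = c("A", "B", "C"), stringsAsFactors = FALSE)
  stats <- fake_stats(c("chr1", "chr1", "chr2", "chr2"),
                      c(200, 1500, 100, 400),
                      c(5e-4, 0.01, 9e-4, 0.2))
  expect_equal(region_hit_count(stats, regions, 1e-3), 2)   # A and C
  expect_equal(suppressWarnings(
    region_hit_count(fake_stats("chr1", 200, 1), regions, 1e-3)), 0)
})

test_that("region boundaries are 1-based inclusive", {
  regions <- data.frame(chrom = "chr1", start = 100, end = 200, label = "A")
  expect_equal(region_hit_count(fake_stats("chr1", 100, 1e-6), regions), 1)
  expect_equal(region_hit_count(fake_stats("chr1", 200, 1e-6), regions), 1)
  expect_equal(region_hit_count(fake_stats("chr1", 99, 1e-6), regions), 0)
  expect_equal(region_hit_count(fake_stats("chr1", 201, 1e-6), regions), 0)
})

test_that("hit counts equal a brute-force double loop on random fixtures", {
  set.seed(51)
  for (rep in 1:5) {
    m <- 2000
    stats <- fake_stats(sample(paste0("chr", 1:4), m, replace = TRUE),
                        sample.int(1e6, m, replace = TRUE), runif(m))
    regions <- data.frame(chrom = sample(paste0("chr", 1:4), 40, replace = TRUE),
                          start = st <- sample.int(9e5, 40), end = st + 5e4,
                          label = paste0("r", 1:40))
    thr <- sample(c(0.001, 0.01, 0.1), 1)
    oracle <- 0
    for (i in seq_len(nrow(regions))) {
      hit <- FALSE
      for (j in seq_len(m)) {
        if (stats$chrom[j] == regions$chrom[i] &&
            stats$pos[j] >= regions$start[i] &&
            stats$pos[j] <= regions$end[i] &&
            stats$p[j] < thr) { hit <- TRUE; break }
      }
      oracle <- oracle + hit
    }
    expect_equal(region_hit_count(stats, regions, thr), oracle)
    # invariant to row order
    expect_equal(region_hit_count(stats[sample(m), ],
                                  regions[sample(40), ], thr), oracle)
  }
})

test_that("regions on chromosomes absent from the stats warn and count as unhit", {
  regions <- data.frame(chrom = c("chr1", "chrX"), start = c(1, 1),
                        end = c(100, 100), label = c("a", "b"))
  stats <- fake_stats("chr1", 50, 1e-6)
  expect_warning(n <- region_hit_count(stats, regions), "chrX")
  expect_equal(n, 1)
})

test_that("lowering the threshold never increases a hit count", {
  set.seed(52)
  stats <- fake_stats("chr1", sample.int(1e6, 3000), runif(3000))
  regions <- data.frame(chrom = "chr1", start = st <- sample.int(9e5, 30),
                        end = st + 3e4, label = paste0("r", 1:30))
  counts <- vapply(c(0.1, 0.01, 0.001, 1e-4),
                   function(thr) suppressWarnings(
                     region_hit_count(stats, regions, thr)), 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("random regions match template lengths and respect forced placement", {
  # one chromosome exactly the template length: unique placement
  r <- sample_random_regions(c(chrA = 1000),
                             data.frame(chrom = "chrA", start = 1, end = 1000),
                             seed = 1)
  expect_equal(r$start, 1)
  expect_equal(r$end, 1000)

  # length multiset always preserved
  set.seed(53)
  template <- data.frame(chrom = "chr1",
                         start = c(1, 100, 5000, 9000),
                         end = c(400, 1099, 5499, 9299))
  lens <- sort(template$end - template$start + 1)
  genome <- c(chr1 = 5e5, chr2 = 3e5)
  for (i in 1:20) {
    r <- sample_random_regions(genome, template)
    expect_equal(sort(r$end - r$start + 1), lens)
    # non-overlapping within the draw
    for (ch in unique(r$chrom)) {
      rc <- r[r$chrom == ch, ]
      rc <- rc[order(rc$start), ]
      if (nrow(rc) > 1) expect_true(all(rc$start[-1] > rc$end[-nrow(rc)]))
    }
    expect_true(all(r$start >= 1 & r$end <= genome[r$chrom]))
  }

  # a template longer than every chromosome cannot be placed
  expect_error(sample_random_regions(c(chr1 = 100),
                                     data.frame(chrom = "chr1", start = 1, end = 500)),
               "longer than every chromosome")
})

test_that("start positions are uniform over the valid range", {
  set.seed(54)
  template <- data.frame(chrom = "chr1", start = 1, end = 10)
  genome <- c(chr1 = 1000)
  starts <- vapply(1:4000, function(i)
    sample_random_regions(genome, template)$start, 0)
  # valid starts are 1..991; chi-square goodness of fit over 10 bins
  bins <- cut(starts, breaks = seq(0.5, 991.5, length.out = 11))
  expect_gt(chisq.test(table(bins))$p.value, 0.01)
})

test_that("the empirical p uses the plus-one rule and is never zero", {
  genome <- c(chr1 = 1e6)
  regions <- data.frame(chrom = "chr1", start = 5e5, end = 5e5, label = "hit")
  stats <- fake_stats("chr1", 5e5, 1e-6)

  # a single permutation that misses: p = (1 + 0) / (1 + 1) = 1/2
  r1 <- permutation_enrichment(stats, regions, genome, n_perm = 1, seed = 3)
  expect_equal(r1$observed, 1)
  expect_equal(r1$null_counts < r1$observed, TRUE)
  expect_equal(r1$empirical_p, 1 / 2)

  # maximal planted signal: every true region hit, p = 1/(1 + n_perm)
  set.seed(55)
  m <- 500
  pos <- sample.int(1e6, m)
  regions2 <- data.frame(chrom = "chr1",
                         start = s <- seq(1, 9e5, length.out = 10),
                         end = s + 99, label = paste0("r", 1:10))
  pvals <- rep(1, m)
  planted <- fake_stats(rep("chr1", 10), regions2$start + 50, rep(1e-6, 10))
  stats2 <- rbind(fake_stats("chr1", pos, pvals), planted)
  r2 <- permutation_enrichment(stats2, regions2, genome, n_perm = 99, seed = 4)
  expect_equal(r2$observed, 10)
  expect_equal(r2$empirical_p, 1 / 100)
})

test_that("the empirical p stabilizes across seeds at large n_perm", {
  set.seed(56)
  genome <- c(chr1 = 2e6, chr2 = 2e6)
  m <- 4000
  stats <- fake_stats(sample(c("chr1", "chr2"), m, replace = TRUE),
                      sample.int(2e6, m, replace = TRUE), runif(m))
  regions <- data.frame(chrom = sample(c("chr1", "chr2"), 20, replace = TRUE),
                        start = st <- sample.int(1.8e6, 20), end = st + 2e4,
                        label = paste0("r", 1:20))
  # plant modest signal inside the candidate regions so the observed count
  # sits in the null tail, where the estimator's precision matters
  stats <- rbind(stats, fake_stats(regions$chrom[1:12],
                                   regions$start[1:12] + 100, rep(1e-4, 12)))
  p1 <- permutation_enrichment(stats, regions, genome, n_perm = 2000,
                               p_threshold = 0.01, seed = 100)$empirical_p
  p2 <- permutation_enrichment(stats, regions, genome, n_perm = 2000,
                               p_threshold = 0.01, seed = 200)$empirical_p
  expect_lt(abs(p1 - p2), 0.02)
})

test_that("template builders clip at chromosome ends", {
  variants <- data.frame(chrom = c("chr1", "chr1"), pos = c(100, 900),
                         id = c("a", "b"))
  reg <- make_loci_regions(variants, 1:2, c(chr1 = 1000), flank_bp = 200)
  expect_equal(reg$start, c(1, 700))
  expect_equal(reg$end, c(300, 1000))
})
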