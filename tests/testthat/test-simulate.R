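test_that("the bolus kernel has the stated shape", {
  g <- function(t) bolus_effect_kernel(t, time_to_peak_s = 60, half_life_min = 17.5)
  expect_equal(g(c(-10, 0)), c(0, 0))
  expect_equal(g(30), 0.5)           # linear rise
  expect_equal(g(60), 1)             # peak
  expect_equal(g(60 + 17.5 * 60), 0.5)  # one half-life past peak
  expect_equal(g(60 + 2 * 17.5 * 60), 0.25)
})

test_that("identical configurations give byte-identical cohorts", {
  cfg <- quiet_sim_config(n_patients = 40, n_variants = 30, noise_sd_mmHg = 2,
                          seed = 123L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$vitals, b$vitals)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$medications, b$medications)
  expect_identical(a$ground_truth$amplitude, b$ground_truth$amplitude)
})

test_that("empirical allele frequencies recover the configured ones", {
  set.seed(3)
  cfg <- quiet_sim_config(n_patients = 600, n_variants = 300,
                          fst = c(AA = 0.05, EA = 0.05, HA = 0.05))
  g <- simulate_genotypes(cfg)
  within3 <- 0; total <- 0
  for (k in colnames(g$freq)) {
    rows <- g$ancestry == k
    nk <- sum(rows)
    phat <- colMeans(g$genotypes[rows, , drop = FALSE]) / 2
    p <- g$freq[, k]
    se <- sqrt(p * (1 - p) / (2 * nk))
    within3 <- within3 + sum(abs(phat - p) <= 3 * pmax(se, 1e-12))
    total <- total + length(p)
  }
  expect_gte(within3 / total, 0.99)
})

test_that("no drift means no systematic frequency differences across groups", {
  set.seed(4)
  cfg <- quiet_sim_config(n_patients = 800, n_variants = 200,
                          fst = c(AA = 0, EA = 0, HA = 0))
  g <- simulate_genotypes(cfg)
  fa <- colMeans(g$genotypes[g$ancestry == "AA", ]) / 2
  fe <- colMeans(g$genotypes[g$ancestry == "EA", ]) / 2
  na <- sum(g$ancestry == "AA"); ne <- sum(g$ancestry == "EA")
  pooled <- (fa * na + fe * ne) / (na + ne)
  se <- sqrt(pooled * (1 - pooled) * (1 / (2 * na) + 1 / (2 * ne)))
  expect_gte(mean(abs(fa - fe) <= 4 * se), 0.99)
})

test_that("Hardy-Weinberg holds within each ancestry group", {
  set.seed(5)
  cfg <- quiet_sim_config(n_patients = 900, n_variants = 400)
  g <- simulate_genotypes(cfg)
  hwe_p <- function(geno) {
    n <- length(geno)
    p <- mean(geno) / 2
    if (p == 0 || p == 1) return(1)
    obs <- tabulate(geno + 1L, 3)
    expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    pchisq(sum((obs - expd)^2 / expd), df = 1, lower.tail = FALSE)
  }
  for (k in c("AA", "EA", "HA")) {
    gk <- g$genotypes[g$ancestry == k, ]
    ps <- apply(gk, 2, hwe_p)
    expect_gte(mean(ps > 0.001), 0.95)
  }
})

test_that("a 1% non-responder variant in 1100 target samples has ~22 carriers", {
  set.seed(6)
  cfg <- quiet_sim_config(
    n_patients = 2000, n_variants = 60,
    ancestry_proportions = c(AA = 0.225, EA = 0.55, HA = 0.225),
    nonresponder_variants = data.frame(index = 60L, ancestry = "EA",
                                       maf = 0.01, multiplier = 0))
  g <- simulate_genotypes(cfg)
  expect_equal(sum(g$ancestry == "EA"), 1100)
  carriers <- sum(g$genotypes[, 60] >= 1)
  # E[carriers] = 1100 * (1 - 0.99^2) ~ 21.9; allow +/- 3 binomial SD
  expect_gt(carriers, 22 - 3 * sqrt(22))
  expect_lt(carriers, 22 + 3 * sqrt(22))
  expect_equal(sum(g$genotypes[g$ancestry != "EA", 60]), 0)
  expect_true(all(sort(unique(as.vector(g$genotypes))) %in% 0:2))
})

test_that("an implausibly rare non-responder configuration warns", {
  cfg <- quiet_sim_config(n_patients = 30, n_variants = 10,
                          nonresponder_variants = data.frame(
                            index = 1L, ancestry = "EA", maf = 0.01,
                            multiplier = 0))
  expect_warning(simulate_genotypes(cfg), "expected carriers < 1")
})

test_that("noiseless dense traces reproduce the closed-form kernel", {
  cfg <- quiet_sim_config(art_interval_s = 5, pd_amplitude_mean = 20)
  boluses <- make_bolus(1000, dose = 100)
  tr <- simulate_bp_trace("P1", "PR1", 0, 3600, boluses, cfg,
                          amplitude = 20, monitoring = "ARTERIAL",
                          sbp0 = 120, dbp0 = 70)
  sbp <- tr[tr$bp_type == "SBP", ]
  # independent evaluation of the kernel on the same grid
  grid <- seq(0, 3600, by = 5)
  rel <- grid - 1000
  oracle <- ifelse(rel <= 0, 0,
                   ifelse(rel <= 60, rel / 60,
                          exp(-log(2) * (rel - 60) / (17.5 * 60))))
  expect_equal(sbp$value, 120 + 20 * oracle, tolerance = 1e-10)

  # the extracted phenotype recovers the injected amplitude on this grid
  res <- extract_response(flag_validity(tr, pipeline_config()),
                          make_bolus(1000, dose = 100), 300)
  expect_equal(res$delta_sbp, 20 * max(oracle[rel > 0 & rel <= 300]),
               tolerance = 1e-6)
  expect_equal(res$delta_sbp, 20, tolerance = 0.02)  # grid hits the peak

  # a zero-amplitude carrier has a flat trace: delta 0
  tr0 <- simulate_bp_trace("P1", "PR1", 0, 3600, boluses, cfg,
                           amplitude = 0, monitoring = "ARTERIAL")
  res0 <- extract_response(flag_validity(tr0, pipeline_config()),
                           make_bolus(1000, dose = 100), 300)
  expect_equal(res0$delta_sbp, 0)
})

test_that("MAP is one third of the way from DBP to SBP before noise", {
  cfg <- quiet_sim_config()
  tr <- simulate_bp_trace("P1", "PR1", 0, 1800, make_bolus(600), cfg,
                          amplitude = 15, monitoring = "ARTERIAL")
  wide <- reshape(tr[, c("timestamp", "bp_type", "value")],
                  idvar = "timestamp", timevar = "bp_type", direction = "wide")
  expect_equal(wide$value.MAP,
               wide$value.DBP + (wide$value.SBP - wide$value.DBP) / 3,
               tolerance = 1e-8)
})

test_that("propofol boluses depress the trace for their stated duration", {
  cfg <- quiet_sim_config(propofol_drop_mmHg = 15, propofol_duration_min = 10)
  prop <- make_bolus(600, dose = 100, drug = "propofol")
  tr <- simulate_bp_trace("P1", "PR1", 0, 3600, prop, cfg,
                          amplitude = 0, monitoring = "ARTERIAL", sbp0 = 120)
  sbp <- tr[tr$bp_type == "SBP", ]
  during <- sbp$value[sbp$timestamp > 600 & sbp$timestamp <= 600 + 600]
  before <- sbp$value[sbp$timestamp <= 600]
  late <- sbp$value[sbp$timestamp > 600 + 600 + 1200]
  expect_true(all(during == 105))
  expect_true(all(before == 120))
  expect_true(all(late > 105 & late <= 120))
})

test_that("default cohort marginals match the intended study-like shape", {
  b <- simulate_cohort(quiet_sim_config(n_patients = 400, noise_sd_mmHg = 3,
                                        mean_boluses_per_case = 4.4,
                                        seed = 21L))
  pe <- b$medications[b$medications$drug == "phenylephrine", ]
  expect_equal(median(pe$dose), 100)
  expect_true(all(b$patients$age >= 18))
  expect_equal(mean(b$patients$age), 56.8, tolerance = 0.05)
  expect_equal(mean(b$patients$bmi), 29.8, tolerance = 0.05)
})

test_that("overlapping procedures for one patient are rejected", {
  pr <- data.frame(procedure_id = c("PR1", "PR2"), patient_id = "P1",
                   start = c(0, 3000), end = c(7200, 9000),
                   monitoring = "NIBP", stringsAsFactors = FALSE)
  expect_error(pressor:::check_no_overlap(pr), "overlapping procedures")
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(ancestry_proportions = c(AA = 0.5, EA = 0.6)),
               "sum to 1")
  expect_error(sim_config(fst = c(AA = 0.5, EA = 0.1, HA = 0.1)), "fst")
  expect_warning(sim_config(pd_half_life_min = 5), "15-20")
  expect_error(sim_config(arterial_fraction = 1.4), "fractions")
})
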