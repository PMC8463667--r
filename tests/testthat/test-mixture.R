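test_that("pileup counts equal brute-force per-read tallies", {
  # plain mixture
  pair <- small_pair(len = 1200L, n_snps = 8L)
  sim <- simulate_reads(pair, read_sim_config(coverage = 40,
                                              mixture_fraction = 0.3,
                                              seed = 17))
  pos <- c(find_informative_snps(pair$donor, pair$recipient)$position,
           1L, 600L, 1200L)
  pu <- build_pileup(sim, pair$recipient, pos)
  bf <- brute_force_pileup(sim, pos)
  expect_equal(as.data.frame(pu), bf)

  # deletion-carrying mixture: junction-crossing and origin-wrapping reads
  del <- deletion_spec(500, 900, heteroplasmy = 0.6)
  paird <- small_pair(len = 1200L, n_snps = 8L, deletion = del)
  simd <- simulate_reads(paird, read_sim_config(coverage = 40,
                                                mixture_fraction = 0.2,
                                                seed = 19))
  posd <- c(1L, 450L, 499L, 700L, 901L, 950L, 1200L)
  expect_equal(as.data.frame(build_pileup(simd, paird$recipient, posd)),
               brute_force_pileup(simd, posd))
})

test_that("pileup honors depth-0 columns and base-quality filters", {
  pair <- small_pair(len = 1000L, n_snps = 4L)
  sim <- simulate_reads(pair, read_sim_config(coverage = 30,
                                              mixture_fraction = 0,
                                              seed = 23))
  # all simulated bases are Q30: a Q40 filter empties every column
  pu <- build_pileup(sim, pair$recipient, c(10L, 500L), min_baseq = 40)
  expect_true(all(pu$depth == 0L))
  expect_true(all(is.na(pu$mean_baseq)))
  # mapq above the simulated 60 likewise
  pu2 <- build_pileup(sim, pair$recipient, c(10L, 500L), min_mapq = 99)
  expect_true(all(pu2$depth == 0L))
})

test_that("snp_frequencies computes donor fractions and fail reasons", {
  cols <- data.frame(position = c(100L, 200L, 300L),
                     A = c(90L, 30L, 0L), C = c(0L, 0L, 0L),
                     G = c(10L, 10L, 150L), T = c(0L, 0L, 0L),
                     depth = c(100L, 40L, 150L),
                     mean_baseq = 30)
  snps <- data.frame(position = c(100L, 200L, 300L),
                     donor_allele = c("G", "G", "G"),
                     recipient_allele = c("A", "A", "A"),
                     pass = c(TRUE, TRUE, FALSE))
  fr <- snp_frequencies(cols, snps, min_depth = 100)
  expect_equal(fr$donor_freq, c(0.10, 0.25, 1.0))
  expect_identical(fr$passed, c(TRUE, FALSE, FALSE))
  expect_identical(fr$fail_reason, c(NA, "low_depth", "flagged_site"))
  # flagged sites can be restored
  fr2 <- snp_frequencies(cols, snps, min_depth = 100, use_flagged = TRUE)
  expect_identical(fr2$passed, c(TRUE, FALSE, TRUE))
  expect_error(snp_frequencies(cols, data.frame(position = 999L,
                                                donor_allele = "A",
                                                recipient_allele = "C")),
               "do not cover")
})

test_that("estimate_exogenous_fraction averages passing SNPs", {
  fr <- data.frame(position = c(1L, 2L), donor_allele = "G",
                   recipient_allele = "A", donor_freq = c(0.10, 0.20),
                   depth = 1000L, passed = TRUE, fail_reason = NA)
  est <- estimate_exogenous_fraction(fr)
  expect_equal(est$percent_exogenous, 15.0)
  expect_equal(est$n_snps_used, 2L)
  expect_equal(est$sem, 100 * sd(c(0.1, 0.2)) / sqrt(2))
  expect_equal(unname(coef(est)), 15.0)
  ci <- confint(est)
  expect_true(ci[1] <= 15 && 15 <= ci[2])

  fr0 <- transform(fr, donor_freq = 0)
  est0 <- estimate_exogenous_fraction(fr0)
  expect_equal(est0$percent_exogenous, 0)
  expect_equal(est0$sem, 0)

  none <- transform(fr, passed = FALSE, fail_reason = "low_depth")
  expect_error(estimate_exogenous_fraction(none), "no informative sites")
})

test_that("per-SNP frequencies scatter binomially around the truth", {
  pair <- derive_haplotypes(make_reference(16569, seed = 1), n_snps = 30,
                            seed = 5)
  f <- 0.145
  sim <- simulate_reads(pair, read_sim_config(coverage = 500,
                                              mixture_fraction = f,
                                              seed = 29))
  est <- fit_mixture(sim, pair)
  used <- est$per_snp[est$per_snp$passed, ]
  bound <- 4 * sqrt(f * (1 - f) / used$depth)
  expect_true(all(abs(used$donor_freq - f) < bound + 0.001))
})

test_that("estimates at the mixture boundaries respect the error floor", {
  pair <- derive_haplotypes(make_reference(16569, seed = 1), n_snps = 30,
                            seed = 5)
  e <- 0.001
  cov <- 800
  sim0 <- simulate_reads(pair, read_sim_config(coverage = cov,
                                               error_rate = e,
                                               mixture_fraction = 0,
                                               seed = 41))
  est0 <- fit_mixture(sim0, pair)
  se0 <- 100 * sqrt((e / 3) / (30 * cov))
  expect_lte(est0$percent_exogenous, 100 * e / 3 + 4 * se0)

  sim1 <- simulate_reads(pair, read_sim_config(coverage = cov,
                                               error_rate = e,
                                               mixture_fraction = 1,
                                               seed = 43))
  est1 <- fit_mixture(sim1, pair)
  se1 <- 100 * sqrt(e / (30 * cov))
  expect_gte(est1$percent_exogenous, 100 - (100 * e + 4 * se1))
})

test_that("the estimator is unbiased and dose-monotone", {
  pair <- derive_haplotypes(make_reference(16569, seed = 1), n_snps = 30,
                            seed = 5)
  fracs <- c(0.00625, 0.054, 0.145)
  n_rep <- 8
  means <- ses <- numeric(length(fracs))
  for (i in seq_along(fracs)) {
    ests <- vapply(seq_len(n_rep), function(r) {
      cfg <- read_sim_config(coverage = 600, mixture_fraction = fracs[i],
                             seed = derive_seed(77, "unbias", i * 100 + r))
      fit_mixture(simulate_reads(pair, cfg), pair)$percent_exogenous
    }, numeric(1))
    means[i] <- mean(ests)
    ses[i] <- sd(ests) / sqrt(n_rep)
  }
  # expected value includes the (documented, uncorrected) error shift
  expected <- 100 * (fracs * 0.999 + (1 - fracs) * 0.001 / 3)
  expect_true(all(abs(means - expected) < pmax(2 * ses, 0.05)))
  expect_true(all(diff(means) > 0))
})

test_that("amplification modes agree on the same truth mixture", {
  pair <- derive_haplotypes(make_reference(16569, seed = 1), n_snps = 30,
                            seed = 5)
  f <- 0.10
  est_pair <- function(seed, ratio) {
    rca <- read_sim_config(coverage = 500, mixture_fraction = f,
                           seed = seed)
    pcr <- read_sim_config(coverage = 500, mixture_fraction = f,
                           amplification_mode = "pcr_two_amplicon",
                           amplicon_ratio = ratio, seed = seed + 1)
    list(a = fit_mixture(simulate_reads(pair, rca), pair),
         b = fit_mixture(simulate_reads(pair, pcr), pair))
  }
  same <- fit_mixture(simulate_reads(
    pair, read_sim_config(coverage = 300, mixture_fraction = f,
                          seed = 3)), pair)
  expect_equal(compare_amplification_modes(same, same)$difference_pp, 0)

  diffs <- pcr_means <- numeric(5)
  for (s in 1:5) {
    cmp <- est_pair(1000 + s, ratio = 1)
    diffs[s] <- compare_amplification_modes(cmp$a, cmp$b)$difference_pp
  }
  expect_lt(abs(mean(diffs)), 1)

  # strong per-amplicon depth imbalance leaves the unweighted mean unbiased
  for (s in 1:5) {
    cmp <- est_pair(2000 + s, ratio = 5)
    pcr_means[s] <- cmp$b$percent_exogenous
  }
  expect_lt(abs(mean(pcr_means) - 100 * f), 1)
})
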