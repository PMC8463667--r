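test_that("poisson_lambda matches the closed form and guards saturation", {
  expect_equal(poisson_lambda(0, 20000), 0)
  expect_equal(poisson_lambda(12642, 20000), -log(1 - 12642 / 20000))
  expect_lt(abs(poisson_lambda(12642, 20000) - 1.0), 1e-3)
  expect_error(poisson_lambda(20000, 20000), "saturation")
  expect_error(poisson_lambda(-1, 20000), "invalid parameter")
})

test_that("copies_per_ng converts counts with a valid Wilson CI", {
  # lambda ~= 0.005965 example geometry: 119 positives on a 20k chip, 2 ng
  cn <- copies_per_ng(partition_counts(119, 20000, ng_loaded = 2))
  expect_equal(cn$copies_per_ng, -log(1 - 119 / 20000) * 20000 / 2)
  expect_lt(abs(cn$copies_per_ng - 59.66), 0.2)
  expect_true(cn$ci95[1] <= cn$copies_per_ng &&
                cn$copies_per_ng <= cn$ci95[2])

  zero <- copies_per_ng(partition_counts(0, 20000, ng_loaded = 2))
  expect_equal(zero$copies_per_ng, 0)
  expect_equal(zero$ci95[1], 0)

  a <- copies_per_ng(partition_counts(500, 20000, ng_loaded = 1))
  b <- copies_per_ng(partition_counts(500, 20000, ng_loaded = 2))
  expect_equal(a$copies_per_ng, 2 * b$copies_per_ng)
})

test_that("deletion heteroplasmy is the full-length deficit", {
  # counts constructed to give ~16.5 and ~100 copies/ng
  fl <- copies_per_ng(partition_counts(33, 20000, ng_loaded = 2))
  tt <- copies_per_ng(partition_counts(199, 20000, ng_loaded = 2))
  h <- deletion_heteroplasmy(fl, tt)
  expect_lt(abs(h$percent - 83.5), 0.2)
  expect_false(h$clamped)

  same <- deletion_heteroplasmy(tt, tt)
  expect_equal(same$percent, 0)
  zero_fl <- copies_per_ng(partition_counts(0, 20000, ng_loaded = 2))
  expect_equal(deletion_heteroplasmy(zero_fl, tt)$percent, 100)
  expect_error(deletion_heteroplasmy(zero_fl, zero_fl), "undefined")
  # sampling noise: FL > Total clamps to zero with a warning
  expect_warning(neg <- deletion_heteroplasmy(tt, fl), "clamped")
  expect_equal(neg$percent, 0)
  expect_true(neg$clamped)
})

test_that("dual-probe fractions recover allele shares", {
  a <- partition_counts(500, 20000)
  expect_equal(dual_probe_fraction(a, a), 0.5)
  zero <- partition_counts(0, 20000)
  expect_equal(dual_probe_fraction(a, zero), 0)
  expect_error(dual_probe_fraction(zero, zero), "undefined")

  fr <- vapply(1:20, function(s) {
    ca <- simulate_dpcr(900, ng_loaded = 2, seed = derive_seed(s, "chA"))
    cb <- simulate_dpcr(100, ng_loaded = 2, seed = derive_seed(s, "chB"))
    dual_probe_fraction(ca, cb)
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.10), 0.01)
})

test_that("copy-number recovery error shrinks with partition count", {
  # the chip readout estimates the molecules actually loaded; finer
  # partitioning must converge on that realized count (the remaining
  # gap to the nominal concentration is irreducible Poisson loading noise)
  true_cn <- 1500  # copies/ng, 2 ng
  err <- vapply(c(2000L, 20000L, 200000L), function(np) {
    rel <- vapply(1:30, function(s) {
      ch <- simulate_dpcr(true_cn, ng_loaded = 2, n_partitions = np,
                          seed = derive_seed(s, paste0("cons", np)))
      abs(copies_per_ng(ch)$copies_per_chip - ch$true_molecules) /
        ch$true_molecules
    }, numeric(1))
    mean(rel)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 0.01)
})

test_that("occupancy round trip is accurate across the dynamic range", {
  for (lam in c(0.01, 0.1, 1, 3)) {
    est <- vapply(1:20, function(s) {
      ch <- simulate_dpcr(lam * 20000 / 2, ng_loaded = 2,
                          seed = derive_seed(s, paste0("rt", lam)))
      poisson_lambda(ch$n_positive, ch$n_valid)
    }, numeric(1))
    expect_lt(abs(mean(est) - lam) / lam, 0.03)
  }
})

test_that("heteroplasmy recovery is within a point across the range", {
  for (h in c(0, 0.5, 0.835, 1)) {
    est <- vapply(1:20, function(s) {
      chips <- simulate_dpcr_heteroplasmy(1527, h, ng_loaded = 6.55,
                                          seed = derive_seed(s, "hrec"))
      fl <- copies_per_ng(chips$full_length)
      tt <- copies_per_ng(chips$total)
      suppressWarnings(deletion_heteroplasmy(fl, tt)$percent)
    }, numeric(1))
    expect_lt(abs(mean(est) - 100 * h), 1)
  }
})

test_that("partition-count tables round trip through TSV", {
  counts <- list(partition_counts(119, 20000, 2, "b2m"),
                 partition_counts(33, 19500, 6.55, "full_length"))
  path <- tempfile(fileext = ".tsv")
  write_partition_counts(counts, path)
  back <- read_partition_counts(path)
  expect_equal(back[[1]]$n_positive, 119L)
  expect_equal(back[[2]]$n_valid, 19500L)
  expect_equal(back[[2]]$ng_loaded, 6.55)
  expect_equal(back[[1]]$assay, "b2m")
})
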