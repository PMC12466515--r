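test_that("Balding-Nichols draws have the model's moments", {
  set.seed(1)
  f <- balding_nichols_freqs(rep(0.3, 10000), fst = 0.2, n_pops = 1)
  se_mean <- sqrt(0.2 * 0.3 * 0.7 / 10000)
  expect_lt(abs(mean(f) - 0.3), 3 * se_mean)
  expect_lt(abs(stats::var(as.vector(f)) - 0.2 * 0.3 * 0.7),
            3 * 0.042 / sqrt(5000))  # generous SE bound on the variance
  # vanishing drift: frequencies collapse onto the ancestral value
  f0 <- balding_nichols_freqs(rep(0.3, 100), fst = 1e-9, n_pops = 2)
  expect_true(all(abs(f0 - 0.3) < 1e-3))
  f1 <- balding_nichols_freqs(rep(0.4, 50), 0.1, 2, seed = 5)
  f2 <- balding_nichols_freqs(rep(0.4, 50), 0.1, 2, seed = 5)
  expect_identical(f1, f2)
  expect_error(balding_nichols_freqs(c(0.3, 1), 0.1, 2), "inside")
})

test_that("noiseless cohorts equal their truth and respect HWE", {
  cfg <- sim_config(n_loci = 200, n_per_pop = c(x = 10, y = 10),
                    missing_rate = 0, error_rate = 0, seed = 3)
  sim <- simulate_cohort(cfg)
  expect_identical(sim$genotypes$dosage, sim$truth_genotypes$dosage)
  expect_equal(nrow(sim$truth), 200)
  expect_identical(sim$truth$id, sim$genotypes$loci$id)

  # HWE class fractions at one frequency, large n
  set.seed(4)
  p <- 0.3; n <- 20000
  g <- stats::rbinom(n, 2, p)
  fr <- tabulate(g + 1L, 3) / n
  expect_lt(abs(fr[1] - (1 - p)^2), 3 * sqrt((1 - p)^2 / n))
  expect_lt(abs(fr[2] - 2 * p * (1 - p)), 3 * sqrt(2 * p * (1 - p) / n))
  expect_lt(abs(fr[3] - p^2), 3 * sqrt(p^2 / n))
})

test_that("missingness and error rates are realized within binomial tolerance", {
  cfg <- sim_config(n_loci = 500, n_per_pop = c(a = 20, b = 20),
                    missing_rate = 0.1, error_rate = 0, seed = 6)
  sim <- simulate_cohort(cfg)
  m <- mean(is.na(sim$genotypes$dosage))
  n_cells <- length(sim$genotypes$dosage)
  expect_lt(abs(m - 0.1), 3 * sqrt(0.1 * 0.9 / n_cells))

  cfg2 <- sim_config(n_loci = 500, n_per_pop = c(a = 20, b = 20),
                     missing_rate = 0, error_rate = 0.05, seed = 7)
  sim2 <- simulate_cohort(cfg2)
  disc <- mean(sim2$genotypes$dosage != sim2$truth_genotypes$dosage)
  expect_lt(abs(disc - 0.05), 3 * sqrt(0.05 * 0.95 / n_cells))
})

test_that("truth frequencies agree with the empirical VCF frequencies", {
  cfg <- sim_config(n_loci = 300, n_per_pop = c(t = 50, o = 50),
                    missing_rate = 0, error_rate = 0, seed = 8)
  sim <- simulate_cohort(cfg)
  s <- summarize_loci(sim$genotypes,
                      groups = stats::setNames(sim$groups, names(sim$groups)))
  emp <- s$alt_freq_t
  tru <- sim$truth$freq_t
  se <- sqrt(tru * (1 - tru) / (2 * 50))
  expect_gt(mean(abs(emp - tru) < 3 * se + 1e-9), 0.98)
})

test_that("cohort files round-trip through the standard formats", {
  cfg <- sim_config(n_loci = 50, n_per_pop = c(t = 4, o = 5),
                    missing_rate = 0.05, error_rate = 0.01, seed = 9)
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(cfg, dir = dir)
  gm <- read_vcf(sim$paths$vcf)
  expect_identical(gm$dosage, sim$genotypes$dosage)
  groups <- read_sample_groups(sim$paths$groups)
  expect_identical(groups, sim$groups)
})

test_that("exact-discordance mode flips exactly k calls and nothing else", {
  truth <- make_gm(matrix(rep(0L, 5062), nrow = 1), pos = seq_len(5062))
  chip <- simulate_chip_readout(truth, seed = 10, exact_discordant = 5)
  r <- duplicate_concordance(truth$dosage[1, ], chip$dosage[1, ])
  expect_equal(r$n_discordant, 5)
  expect_equal(r$concordance_rate, 99.90)
  expect_equal(sum(is.na(chip$dosage)), 0)
  ident <- simulate_chip_readout(truth, seed = 11)
  expect_identical(ident$dosage, truth$dosage)
  expect_error(simulate_chip_readout(truth, seed = 1, exact_discordant = 9999),
               "exceeds")
})

test_that("reference simulation is seed-reproducible with known duplications", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- simulate_reference(c(chr1 = 30000), n_duplications = 3, seed = 13,
                           dir = d1)
  r2 <- simulate_reference(c(chr1 = 30000), n_duplications = 3, seed = 13,
                           dir = d2)
  expect_identical(readLines(r1$paths$fasta), readLines(r2$paths$fasta))
  expect_equal(nrow(r1$dup_sites), 3)
  probe <- extract_region(r1$genome, "chr1", r1$dup_source$start,
                          r1$dup_source$end)
  expect_equal(homology_count(probe, r1$genome), 4L)  # 3 copies + self
  expect_error(simulate_reference(c(chr1 = 500), seed = 1), "1000 bp")
})
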