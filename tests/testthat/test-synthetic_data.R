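test_that("simulation config validates its parameters", {
  expect_error(simulation_config(genome_length = 500), "genome_length")
  expect_error(simulation_config(mu = 2), "0, 1")
  expect_error(simulation_config(reference_bias = 0.6), "reference_bias")
  expect_error(simulation_config(spectrum_weights = c(a = 1)), "six classes")
  w <- simulation_config()$spectrum_weights
  expect_equal(sum(w), 1, tolerance = 1e-12)
  # default weights encode Ti/Tv 3.2 and C>T/T>C 4.4
  expect_equal((w[["C>T"]] + w[["T>C"]]) / (1 - w[["C>T"]] - w[["T>C"]]), 3.2,
               tolerance = 1e-9)
  expect_equal(w[["C>T"]] / w[["T>C"]], 4.4, tolerance = 1e-9)
})

test_that("truth generation is deterministic and respects the rate model", {
  cfg <- simulation_config(n_trios = 6, genome_length = 1e5, mu = 1e-5,
                           seed = 101)
  t1 <- simulate_truth(cfg)
  t2 <- simulate_truth(cfg)
  expect_identical(t1$events, t2$events)
  expect_identical(t1$G, t2$G)

  none <- simulate_truth(simulation_config(n_trios = 4, mu = 0,
                                           mosaic_rate = 0, seed = 5))
  expect_equal(sum(none$events$type == "germline_dnm"), 0)

  # Poisson mean 2 L mu per offspring, checked over many offspring
  cfg2 <- simulation_config(n_trios = 200, genome_length = 1e5, mu = 5e-6,
                            background_snp_density = 0, mosaic_rate = 0,
                            seed = 103)
  tr <- simulate_truth(cfg2)
  counts <- table(factor(tr$events$sample_id,
                         levels = grep("^P", tr$samples, value = TRUE)))
  expect_equal(mean(counts), 2 * 1e5 * 5e-6,
               tolerance = 4 / sqrt(200))  # 4 SE of a Poisson(1) mean
  # planted germline events are het in the proband, hom-ref in the parents
  g <- tr$events[tr$events$type == "germline_dnm", ]
  i <- match(g$pos, tr$variants$pos)
  expect_true(all(tr$G[cbind(i, match(g$sample_id, tr$samples))] == 1L))
  ped_tr <- trios(tr$pedigree)
  sires <- ped_tr$sire[match(g$sample_id, ped_tr$proband)]
  expect_true(all(tr$G[cbind(i, match(sires, tr$samples))] == 0L))
  expect_true(!anyDuplicated(tr$variants$pos))
})

test_that("rendered allele fractions show the configured reference bias", {
  cfg <- simulation_config(n_trios = 30, genome_length = 2e5, mu = 1e-4,
                           background_snp_density = 0, mosaic_rate = 0,
                           reference_bias = 0.025, seed = 107)
  sim <- simulate_cohort(cfg)
  ev <- sim$truth$events
  i <- match(ev$pos, sim$cohort$sites$pos)
  j <- match(ev$sample_id, sim$cohort$samples)
  af <- sim$cohort$ad_alt[cbind(i, j)] / sim$cohort$dp[cbind(i, j)]
  expect_gt(length(af), 1000)
  expect_lt(abs(mean(af) - 0.475), 4 * stats::sd(af) / sqrt(length(af)))
  # and the one-sample t test detects the departure from 0.5
  expect_lt(one_sample_t_test(af, 0.5)$p_value, 0.01)
})

test_that("zero-noise rendering gives parents zero alt reads at DNM sites", {
  cfg <- simulation_config(n_trios = 8, genome_length = 1e5, mu = 5e-5,
                           background_snp_density = 0, mosaic_rate = 0,
                           seq_error_rate = 0, seed = 109)
  sim <- simulate_cohort(cfg)
  ev <- sim$truth$events
  tr <- trios(sim$truth$pedigree)
  i <- match(ev$pos, sim$cohort$sites$pos)
  for (col in c("sire", "dam")) {
    j <- match(tr[[col]][match(ev$sample_id, tr$proband)], sim$cohort$samples)
    expect_true(all(sim$cohort$ad_alt[cbind(i, j)] == 0L))
  }
})

test_that("low-fraction mosaics mostly fail the allele-balance rule downstream", {
  cfg <- simulation_config(n_trios = 40, genome_length = 5e5, mu = 0,
                           background_snp_density = 0, mosaic_rate = 8,
                           mosaic_fraction = 0.1, fixed_depth = TRUE,
                           depth_mean = 30, seq_error_rate = 0, seed = 113)
  sim <- simulate_cohort(cfg)
  n_mosaic <- sum(sim$truth$events$type == "mosaic")
  expect_gt(n_mosaic, 200)
  calls <- call_candidates(sim$cohort)
  # binomial tail: P(Bin(30, 0.1) > 6) ~ 0.026, so only a few ~ survive
  expect_lt(nrow(calls$candidates) / n_mosaic, 0.08)
})

test_that("end-to-end sensitivity at default noise and 30X depth is >= 0.95", {
  cfg <- simulation_config(n_trios = 46, genome_length = 2e6, mu = 1e-6,
                           seed = 127)
  sim <- simulate_cohort(cfg)
  truth <- sim$truth$events[sim$truth$events$type == "germline_dnm", ]
  calls <- call_candidates(sim$cohort, ledger = FALSE)
  got <- paste(calls$candidates$pos, calls$candidates$proband)
  want <- paste(truth$pos, truth$sample_id)
  expect_gt(nrow(truth), 100)
  expect_gte(mean(want %in% got), 0.95)
})

test_that("the written reference FASTA agrees with the truth ledger contexts", {
  cfg <- simulation_config(n_trios = 5, genome_length = 5e4, mu = 2e-5,
                           background_snp_density = 1e-3, seed = 131)
  truth <- simulate_truth(cfg)
  fa <- withr::local_tempfile(fileext = ".fa")
  write_reference_fasta(truth, fa)
  ev <- truth$events
  ctx <- contexts_for_variants(ev[, c("chrom", "pos", "ref", "alt")], fa)
  expect_equal(ctx$context, ev$context)
  expect_equal(ctx$is_cpg, ev$is_cpg)
  expect_equal(ctx$collapsed_class, ev$collapsed_class)
})
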