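good_site <- function(...) {
  site_record("chrT", 100, "C", "T", qd = 10, fs = 5, mq = 60,
              mq_rank_sum = 0, read_pos_rank_sum = 0, ...)
}
trio3 <- function(gq = 50, dp = 30) {
  lapply(1:3, function(i) sample_call("hom_ref", dp, 0, dp, gq))
}

test_that("site quality cascade fails on boundary values, passes absent annotations", {
  th <- filter_thresholds()
  expect_true(site_quality_pass(good_site(), trio3(), th)$pass)

  # boundary semantics follow the exclusion expression: <= fails for MQ/QD
  mq40 <- site_record("chrT", 1, "C", "T", qd = 10, fs = 5, mq = 40)
  r <- site_quality_pass(mq40, trio3(), th)
  expect_false(r$pass); expect_equal(r$reasons, "MQ")
  qd4 <- site_record("chrT", 1, "C", "T", qd = 4.0, fs = 5, mq = 60)
  expect_equal(site_quality_pass(qd4, trio3(), th)$reasons, "QD")
  fs60 <- site_record("chrT", 1, "C", "T", qd = 10, fs = 60.0, mq = 60)
  expect_equal(site_quality_pass(fs60, trio3(), th)$reasons, "FS")

  # one member below the depth window fails DP
  calls <- trio3(); calls[[2]] <- sample_call("hom_ref", 8, 0, 8, 50)
  r <- site_quality_pass(good_site(), calls, th)
  expect_false(r$pass); expect_equal(r$reasons, "DP")

  # absent rank-sum annotations never fail
  no_rs <- site_record("chrT", 1, "C", "T", qd = 10, fs = 5, mq = 60,
                       mq_rank_sum = NA, read_pos_rank_sum = NA)
  expect_true(site_quality_pass(no_rs, trio3(), th)$pass)
  # but present failing ones do
  bad_rs <- site_record("chrT", 1, "C", "T", qd = 10, fs = 5, mq = 60,
                        mq_rank_sum = -2, read_pos_rank_sum = -8.0)
  expect_setequal(site_quality_pass(bad_rs, trio3(), th)$reasons,
                  c("MQRankSum", "ReadPosRankSum"))
})

test_that("trio genotype test enforces configuration, allele balance and parental reads", {
  th <- filter_thresholds()
  hr <- function(alt = 0) sample_call("hom_ref", 30 - alt, alt, 30, 40)
  het <- function(ref = 15, alt = 13) sample_call("het", ref, alt, ref + alt, 50)

  expect_true(trio_genotype_test(het(), hr(), hr(), th)$pass)

  # alt fraction must be strictly > 20%
  r <- trio_genotype_test(sample_call("het", 25, 5, 30, 50), hr(), hr(), th)
  expect_false(r$pass); expect_equal(r$reasons, "alt_fraction")
  expect_equal(r$alt_fraction, 5 / 30, tolerance = 1e-12)
  exact20 <- trio_genotype_test(sample_call("het", 24, 6, 30, 50), hr(), hr(), th)
  expect_equal(exact20$reasons, "alt_fraction")

  # a single parental alt read is disqualifying
  r <- trio_genotype_test(het(), hr(), hr(alt = 1), th)
  expect_false(r$pass); expect_equal(r$reasons, "parent_alt_reads")

  # proband must be heterozygous
  r <- trio_genotype_test(sample_call("hom_alt", 0, 30, 30, 50), hr(), hr(), th)
  expect_false(r$pass); expect_true("genotype_config" %in% r$reasons)

  # missing genotype is a reason code, not an exception
  r <- trio_genotype_test(het(), sample_call("missing"), hr(), th)
  expect_false(r$pass); expect_equal(r$reasons, "missing_genotype")

  # parental GQ/DP bounds
  r <- trio_genotype_test(het(), sample_call("hom_ref", 30, 0, 30, 10), hr(), th)
  expect_equal(r$reasons, "parent_gq")
  r <- trio_genotype_test(het(), sample_call("hom_ref", 120, 0, 120, 50), hr(), th)
  expect_equal(r$reasons, "parent_dp")
})

test_that("population screen applies the AC cap and half-sib/offspring exemptions", {
  th <- filter_thresholds()
  ped <- toy_ped()
  mk_calls <- function(p2_gt = "hom_ref", p2_alt = 0L, u1_gt = "hom_ref",
                       u1_alt = 0L) {
    list(P1 = sample_call("het", 15, 15, 30, 50),
         P2 = sample_call(p2_gt, 30L - p2_alt, p2_alt, 30, 50),
         U1 = sample_call(u1_gt, 30L - u1_alt, u1_alt, 30, 50),
         S1 = sample_call("hom_ref", 30, 0, 30, 50),
         D1 = sample_call("hom_ref", 30, 0, 30, 50))
  }
  rec <- function(calls, ac = 1L)
    site_record("chrT", 100, "C", "T", allele_count = ac, calls = calls)

  expect_true(population_screen(rec(mk_calls()), "P1", ped, 135, th)$pass)

  # unrelated carrier (het call) fails
  r <- population_screen(rec(mk_calls(u1_gt = "het", u1_alt = 15L), ac = 2L),
                         "P1", ped, 135, th)
  expect_false(r$pass); expect_equal(r$reasons, "population_carrier")

  # a single stray alt read in an unrelated sample also fails
  r <- population_screen(rec(mk_calls(u1_alt = 1L)), "P1", ped, 135, th)
  expect_equal(r$reasons, "population_carrier")

  # the same allele in a half-sib is exempt
  expect_true(population_screen(rec(mk_calls(p2_gt = "het", p2_alt = 14L),
                                    ac = 2L), "P1", ped, 135, th)$pass)

  # AC cap: with 135 samples the cap is max(4, ceil(0.135)) = 4
  expect_false(population_screen(rec(mk_calls(), ac = 5L),
                                 "P1", ped, 135, th)$pass)
  expect_false(population_screen(rec(mk_calls(), ac = 4L),
                                 "P1", ped, 135, th)$pass)
  expect_true(population_screen(rec(mk_calls(), ac = 3L),
                                "P1", ped, 135, th)$pass)
})

test_that("call_candidates matches the brute-force oracle on constructed cohorts", {
  samples <- c("S1", "S2", "D1", "D2", "P1", "P2", "U1")
  # sites exercising: clean DNM, parental read, unrelated carrier, half-sib
  # sharing, alt-fraction failure, bad INFO, missing genotype
  gt <- cm(samples,
           c(0L, 0L, 0L, 0L, 1L, 0L, 0L),   # clean DNM in P1
           c(0L, 0L, 0L, 0L, 1L, 0L, 0L),   # parental alt read (S1)
           c(0L, 0L, 0L, 0L, 1L, 0L, 1L),   # unrelated carrier U1
           c(0L, 0L, 0L, 0L, 1L, 1L, 0L),   # shared with half-sib P2
           c(0L, 0L, 0L, 0L, 1L, 0L, 0L),   # low alt fraction
           c(0L, 0L, 0L, 0L, 1L, 0L, 0L),   # MQ at boundary
           c(0L, 0L, 0L, NA, 1L, 0L, 0L))   # missing dam genotype (P2 trio ok)
  ad <- cm(samples,
           c(0L, 0L, 0L, 0L, 14L, 0L, 0L),
           c(1L, 0L, 0L, 0L, 14L, 0L, 0L),
           c(0L, 0L, 0L, 0L, 14L, 0L, 15L),
           c(0L, 0L, 0L, 0L, 14L, 13L, 0L),
           c(0L, 0L, 0L, 0L, 5L, 0L, 0L),
           c(0L, 0L, 0L, 0L, 14L, 0L, 0L),
           c(0L, 0L, 0L, 0L, 14L, 0L, 0L))
  cohort <- build_cohort(pos = (1:7) * 100, ref = "C", alt = "T",
                         gt = gt, ad_alt = ad,
                         mq = c(60, 60, 60, 60, 60, 40, 60))
  calls <- call_candidates(cohort)
  oracle <- oracle_candidates(cohort)
  got <- calls$candidates[, c("pos", "proband")]
  rownames(got) <- NULL
  expect_equal(got[order(got$pos, got$proband), ],
               oracle[order(oracle$pos, oracle$proband), ])
  # survivors: the clean DNM, the half-sib-shared site (both probands), and
  # site 700 for trio P1 (only P2's trio has the missing dam genotype)
  expect_setequal(paste(calls$candidates$pos, calls$candidates$proband),
                  c("100 P1", "400 P1", "400 P2", "700 P1"))
  led <- calls$ledger
  # the sire's stray read fails both the parental-read rule and the cohort
  # screen (parents are not in the exemption set)
  expect_equal(led$reasons[led$pos == 200 & led$proband == "P1"],
               "parent_alt_reads;population_carrier")
  expect_equal(led$reasons[led$pos == 300 & led$proband == "P1"],
               "population_carrier")
  expect_equal(led$reasons[led$pos == 500 & led$proband == "P1"],
               "alt_fraction")
  expect_equal(led$reasons[led$pos == 600 & led$proband == "P1"], "MQ")
  expect_equal(led$reasons[led$pos == 700 & led$proband == "P2"],
               "missing_genotype")
  # every evaluated pair appears in the ledger; candidates have no reasons
  expect_equal(nrow(led), 7 * 2)
  expect_true(all((led$status == "candidate") == (led$reasons == "")))
})

test_that("call_candidates agrees with the oracle on a small simulated cohort", {
  cfg <- simulation_config(n_trios = 6, genome_length = 1e4, mu = 5e-5,
                           background_snp_density = 5e-3, seq_error_rate = 2e-3,
                           info_fail_rate = 0.1, seed = 19)
  sim <- simulate_cohort(cfg)
  calls <- call_candidates(sim$cohort)
  oracle <- oracle_candidates(sim$cohort)
  got <- calls$candidates[, c("pos", "proband")]
  expect_equal(got[order(got$pos, got$proband), ],
               oracle[order(oracle$pos, oracle$proband), ],
               ignore_attr = TRUE)
})

test_that("empty cohorts yield zero candidates without error", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  ped <- withr::local_tempfile(fileext = ".ped")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="g">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="a">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="d">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="q">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "D1", "P1"), collapse = "\t")), vcf)
  writeLines(c("F1\tS1\t0\t0\t1\t0", "F1\tD1\t0\t0\t2\t0",
               "F1\tP1\tS1\tD1\t1\t0"), ped)
  cohort <- read_cohort(vcf, ped)
  expect_equal(nrow(call_candidates(cohort)$candidates), 0)
})

test_that("tightening any single threshold never increases the candidate count", {
  cfg <- simulation_config(n_trios = 8, genome_length = 5e4, mu = 5e-5,
                           background_snp_density = 3e-3, seq_error_rate = 1e-3,
                           seed = 23)
  sim <- simulate_cohort(cfg)
  base_th <- filter_thresholds()
  n_base <- nrow(call_candidates(sim$cohort, base_th)$candidates)
  tighter <- list(
    list(min_gq = 40), list(min_dp = 20L), list(max_dp = 40L),
    list(min_qd = 20), list(max_fs = 6), list(min_mq = 59),
    list(min_mq_rank_sum = -0.5), list(min_read_pos_rank_sum = -0.5),
    list(min_proband_alt_fraction = 0.45), list(ac_cap_floor = 2L))
  for (delta in tighter) {
    th <- do.call(filter_thresholds, delta)
    n <- nrow(call_candidates(sim$cohort, th)$candidates)
    expect_lte(n, n_base)
  }
})

test_that("zero-noise deep-coverage simulation is recovered perfectly", {
  cfg <- simulation_config(n_trios = 12, genome_length = 5e5, mu = 2e-5,
                           background_snp_density = 1e-3, seq_error_rate = 0,
                           reference_bias = 0, fixed_depth = TRUE,
                           depth_mean = 50, mosaic_rate = 0, seed = 31)
  sim <- simulate_cohort(cfg)
  truth <- sim$truth$events[sim$truth$events$type == "germline_dnm", ]
  calls <- call_candidates(sim$cohort)
  got <- paste(calls$candidates$pos, calls$candidates$proband)
  want <- paste(truth$pos, truth$sample_id)
  expect_gt(nrow(truth), 50)  # enough planted events to be meaningful
  expect_setequal(got, want)  # sensitivity 1, FDR 0
})
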