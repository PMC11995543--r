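test_that("panel classification matches the germline/somatic definitions", {
  nc <- "non_carrier"
  expect_equal(classify_validation("carrier", nc, nc,
                                   c("carrier", nc, nc, nc, nc)), "germline")
  expect_equal(classify_validation("carrier", nc, nc, c(nc, nc, nc)),
               "possible_somatic")
  expect_equal(classify_validation("carrier", nc, nc, nc), "inconclusive")
  expect_equal(classify_validation("failed", nc, nc, c("carrier")),
               "assay_failed")
  expect_equal(classify_validation(nc, nc, nc, c("carrier")), "not_validated")
  # a carrier parent means inherited, even with carrier offspring
  expect_equal(classify_validation("carrier", "carrier", nc, c("carrier")),
               "not_validated")
  # a failed parent blocks the germline call
  expect_equal(classify_validation("carrier", "failed", nc, c("carrier")),
               "inconclusive")
  # failed offspring do not count as genotyped
  expect_equal(classify_validation("carrier", nc, nc, c("failed", nc)),
               "inconclusive")
})

test_that("every panel configuration maps to exactly one class", {
  calls <- c("carrier", "non_carrier", "failed")
  grid <- expand.grid(p = calls, s = calls, d = calls, o1 = calls, o2 = calls,
                      stringsAsFactors = FALSE)
  classes <- c("germline", "possible_somatic", "not_validated",
               "inconclusive", "assay_failed")
  for (i in seq_len(nrow(grid))) {
    cl <- classify_validation(grid$p[i], grid$s[i], grid$d[i],
                              c(grid$o1[i], grid$o2[i]))
    expect_length(cl, 1)
    expect_true(cl %in% classes)
  }
})

test_that("classify_panel aggregates a table and reports the validation rate", {
  tabs <- synthetic_supplementary_tables(seed = 3)
  val <- classify_panel(tabs$panel)
  expect_equal(sum(val$class == "germline"), 395)
  expect_equal(sum(val$class == "possible_somatic"), 9)
  expect_equal(sum(val$class == "assay_failed"), 73)
  expect_equal(attr(val, "validation_rate"), 404 / 602, tolerance = 1e-12)
})

test_that("transmission tracing assigns generations and loss correctly", {
  chain <- as_pedigree(data.frame(
    fam = "F1", id = c("P", "M1", "A", "M2", "B"),
    sire = c(NA, NA, "P", NA, "A"), dam = c(NA, NA, "M1", NA, "M2"),
    sex = c("1", "2", "1", "2", "1"), phenotype = "0"))
  # one carrier per generation: segregating
  tr <- trace_transmission(chain, "P", genotyped = c("A", "B"),
                           carriers = c("A", "B"))
  expect_equal(unname(tr$generation_counts), c(1, 1, 1))
  expect_equal(tr$status, "segregating")
  # no genotyped descendant carries: lost at generation 2
  tr2 <- trace_transmission(chain, "P", genotyped = c("A", "B"),
                            carriers = character(0))
  expect_equal(tr2$lost_generation, 2)
  expect_equal(tr2$status, "lost")
  # proband with no genotyped descendants at all: lost at generation 2
  tr3 <- trace_transmission(chain, "B", genotyped = character(0),
                            carriers = character(0))
  expect_equal(tr3$lost_generation, 2)
  # carrier outside the descendant lineage triggers a warning
  expect_warning(trace_transmission(chain, "A", genotyped = c("B", "M1"),
                                    carriers = c("M1")), "outside")
})

test_that("neutral transmission matches the 1 - 0.5^k survival law", {
  k <- 5
  cfg <- simulation_config(n_trios = 20, genome_length = 2e5, mu = 2e-4,
                           background_snp_density = 0, mosaic_rate = 0,
                           panel_offspring = k, panel_fail_rate = 0, seed = 59)
  truth <- simulate_truth(cfg)
  panel <- simulate_panel(truth, cfg)
  val <- classify_panel(panel)
  n <- nrow(val)
  expect_gt(n, 1000)
  p_hat <- mean(val$class == "germline")
  p_true <- 1 - 0.5^k
  expect_lt(abs(p_hat - p_true), 4 * sqrt(p_true * (1 - p_true) / n))
  # closed form agrees with direct binomial evaluation
  expect_equal(p_true, 1 - stats::dbinom(0, k, 0.5), tolerance = 1e-12)
})

test_that("chip-het concordance excludes missing calls from the denominator", {
  chip <- c("het", "het", "het", "hom_ref", "het", "het")
  wgs <- c("het", "hom_ref", "het", "het", NA, "het")
  cc <- het_concordance(chip, wgs)
  expect_equal(as.numeric(cc), 3 / 4)
  expect_equal(attr(cc, "n_excluded_missing"), 1)
  expect_equal(het_concordance(rep("het", 5), rep("het", 5)),
               1, ignore_attr = TRUE)
  expect_error(het_concordance("het", NA_character_), "no overlapping")
})

test_that("class retention reports removed fractions per genotype class", {
  pre <- c(Hom_RR = 100, Het_RA = 200, Hom_AA = 0)
  post <- c(Hom_RR = 95, Het_RA = 196, Hom_AA = 0)
  rem <- class_retention(pre, post)
  expect_equal(unname(rem["Hom_RR"]), 0.05)
  expect_equal(unname(rem["Het_RA"]), 0.02)
  expect_true(is.na(rem["Hom_AA"]))
  expect_equal(unname(class_retention(c(Hom_RR = 10, Het_RA = 10, Hom_AA = 10),
                                      c(Hom_RR = 10, Het_RA = 10, Hom_AA = 10))),
               c(0, 0, 0))
  expect_error(class_retention(pre, c(Hom_RR = 101, Het_RA = 1, Hom_AA = 0)),
               "exceeds")
})
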