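## Shared fixture builders: hand-rolled toy cohorts, an independent
## brute-force re-implementation of the filter cascade, and a synthetic
## reconstruction of published-style summary tables.

## A 2-sire / 2-dam pedigree with half-sib probands P1, P2 (shared sire S1)
## and an unrelated genotyped sample U1.
toy_ped <- function() {
  as_pedigree(data.frame(
    fam = "F1",
    id = c("S1", "S2", "D1", "D2", "P1", "P2", "U1"),
    sire = c(NA, NA, NA, NA, "S1", "S1", NA),
    dam = c(NA, NA, NA, NA, "D1", "D2", NA),
    sex = c("1", "1", "2", "2", "1", "2", "1"),
    phenotype = "0", stringsAsFactors = FALSE))
}

## Build a cohort from explicit matrices; defaults put every value deep in
## the pass region so single deviations isolate single rules.
build_cohort <- function(pos, ref, alt, gt, ad_alt, dp = NULL, gq = NULL,
                         qd = 25, fs = 5, mq = 60, mq_rank_sum = 0,
                         read_pos_rank_sum = 0, ped = toy_ped()) {
  n <- length(pos)
  samples <- colnames(gt)
  if (is.null(dp)) dp <- matrix(30L, n, ncol(gt), dimnames = dimnames(gt))
  if (is.null(gq)) gq <- matrix(50, n, ncol(gt), dimnames = dimnames(gt))
  rec <- function(x) if (length(x) == 1) rep(x, n) else x
  sites <- data.frame(chrom = "chrT", pos = as.integer(pos), ref = ref,
                      alt = alt, qd = rec(qd), fs = rec(fs), mq = rec(mq),
                      mq_rank_sum = rec(mq_rank_sum),
                      read_pos_rank_sum = rec(read_pos_rank_sum),
                      allele_count = as.integer(rowSums(gt, na.rm = TRUE)),
                      stringsAsFactors = FALSE)
  new_cohort(sites, gt, dp - ad_alt, ad_alt, dp, gq, pedigree = ped)
}

## Matrix constructor: one row per site, named columns.
cm <- function(samples, ..., default = 0L) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  colnames(m) <- samples
  m
}

## Independent brute-force evaluator of every calling rule, written as plain
## per-site conditionals straight from the filter definitions; used as the
## oracle for call_candidates().
oracle_candidates <- function(cohort, th = filter_thresholds()) {
  ped <- cohort$pedigree
  trs <- trios(ped)
  trs <- trs[trs$proband %in% cohort$samples, , drop = FALSE]
  cap <- max(th$ac_cap_floor,
             ceiling(th$ac_cap_sample_frac * length(cohort$samples)))
  out <- list()
  for (i in seq_len(nrow(cohort$sites))) {
    s <- cohort$sites[i, ]
    for (k in seq_len(nrow(trs))) {
      p <- trs$proband[k]; si <- trs$sire[k]; dm <- trs$dam[k]
      gt <- function(sm) cohort$gt[i, sm]
      aa <- function(sm) { v <- cohort$ad_alt[i, sm]; if (is.na(v)) 0 else v }
      d <- function(sm) { v <- cohort$dp[i, sm]; if (is.na(v)) 0 else v }
      q <- function(sm) { v <- cohort$gq[i, sm]; if (is.na(v)) 0 else v }
      ok <- TRUE
      if (!is.na(s$qd) && s$qd <= th$min_qd) ok <- FALSE
      if (!is.na(s$fs) && s$fs >= th$max_fs) ok <- FALSE
      if (!is.na(s$mq) && s$mq <= th$min_mq) ok <- FALSE
      if (!is.na(s$mq_rank_sum) && s$mq_rank_sum <= th$min_mq_rank_sum)
        ok <- FALSE
      if (!is.na(s$read_pos_rank_sum) &&
          s$read_pos_rank_sum <= th$min_read_pos_rank_sum) ok <- FALSE
      for (sm in c(p, si, dm))
        if (q(sm) < th$min_gq || d(sm) < th$min_dp || d(sm) > th$max_dp)
          ok <- FALSE
      if (is.na(gt(p)) || is.na(gt(si)) || is.na(gt(dm))) ok <- FALSE
      else if (!(gt(p) == 1 && gt(si) == 0 && gt(dm) == 0)) ok <- FALSE
      if (d(p) == 0 || aa(p) / d(p) <= th$min_proband_alt_fraction) ok <- FALSE
      if (aa(si) > th$max_parent_alt_reads ||
          aa(dm) > th$max_parent_alt_reads) ok <- FALSE
      if (s$allele_count >= cap) ok <- FALSE
      exempt <- c(p, half_sibs(ped, p), offspring_of(ped, p))
      for (sm in setdiff(cohort$samples, exempt)) {
        g <- cohort$gt[i, sm]
        if ((!is.na(g) && g >= 1) || aa(sm) >= 1) ok <- FALSE
      }
      if (ok) out[[length(out) + 1]] <-
          data.frame(pos = s$pos, proband = p, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(pos = integer(0), proband = character(0))
}

## Synthetic reconstruction of published-style per-DNM and validation
## tables, built from marginal counts only (404 mutations: 251 C>T of which
## 88 CpG, 57 T>C, 24 each of the four transversion classes; 675 assayed
## DNM: 73 failures, 395 germline, 9 possible somatic, 198 not validated;
## alt-read fractions centred at 0.475). Stands in for restricted data.
synthetic_supplementary_tables <- function(seed = 1) {
  set.seed(seed)
  classes <- c(rep("C>T", 251), rep("T>C", 57),
               rep("C>A", 24), rep("C>G", 24), rep("T>A", 24), rep("T>G", 24))
  is_cpg <- c(rep(TRUE, 88), rep(FALSE, 251 - 88), rep(NA, 404 - 251))
  is_cpg[is.na(is_cpg)] <- FALSE
  context <- ifelse(classes == "C>T" & is_cpg, "A[C>T]G",
                    sprintf("A[%s]T", classes))
  af <- stats::rnorm(404, 0.475, 0.05)
  af <- af - mean(af) + 0.475  # centre exactly at the target mean
  dnm_table <- data.frame(dnm_id = sprintf("dnm%03d", 1:404),
                          collapsed_class = classes, context = context,
                          is_cpg = is_cpg, alt_fraction = af,
                          stringsAsFactors = FALSE)
  one <- function(id, proband, sire, dam, off) {
    data.frame(dnm_id = id,
               individual_id = c("p", "s", "d", paste0("o", seq_along(off))),
               role = c("proband", "sire", "dam", rep("offspring", length(off))),
               call = c(proband, sire, dam, off), stringsAsFactors = FALSE)
  }
  rows <- list()
  add <- function(n, maker) {
    start <- length(rows)
    for (j in seq_len(n))
      rows[[start + j]] <<- maker(sprintf("v%03d", start + j))
  }
  add(395, function(id) one(id, "carrier", "non_carrier", "non_carrier",
                            c("carrier", "non_carrier")))
  add(9, function(id) one(id, "carrier", "non_carrier", "non_carrier",
                          c("non_carrier", "non_carrier")))
  add(198, function(id) one(id, "non_carrier", "non_carrier", "non_carrier",
                            c("non_carrier", "non_carrier")))
  add(73, function(id) one(id, "failed", "failed", "failed",
                           c("failed", "failed")))
  panel <- do.call(rbind, rows)
  list(dnm_table = dnm_table, panel = panel)
}
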