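#' Filter thresholds for candidate DNM calling
#'
#' Defaults reproduce the published filter cascade: sites are excluded when
#' the minimum trio GQ < 20, minimum trio DP < 10, maximum trio DP > 100,
#' QD <= 4.0, FS >= 60.0, MQ <= 40, MQRankSum <= -2 or
#' ReadPosRankSum <= -8.0; the proband must carry the alternative allele on
#' strictly more than 20% of its reads, parents may carry no reads supporting
#' it, and the cohort allele count must stay below max(4, 0.1% of samples).
#' Where the inequality direction could be read two ways, the executable
#' exclusion expression (the `bcftools filter -e` form) is followed: QD, MQ
#' and the rank sums fail on equality, GQ/DP bounds are inclusive.
#'
#' @param min_gq Minimum Phred genotype quality per trio member.
#' @param min_dp,max_dp Inclusive per-member read-depth window.
#' @param min_qd Sites with QD at or below this fail.
#' @param max_fs Sites with FS at or above this fail.
#' @param min_mq Sites with MQ at or below this fail.
#' @param min_mq_rank_sum,min_read_pos_rank_sum Sites at or below these fail;
#'   absent annotations never fail.
#' @param min_proband_alt_fraction Proband alt reads / depth must exceed this
#'   (strict).
#' @param max_parent_alt_reads Maximum alt reads allowed in each parent.
#' @param ac_cap_floor,ac_cap_sample_frac Cohort allele-count cap:
#'   candidates need AC < max(floor, ceiling(frac x n_samples)).
#' @return A `filter_thresholds` object.
#' @export
filter_thresholds <- function(min_gq = 20, min_dp = 10L, max_dp = 100L,
                              min_qd = 4.0, max_fs = 60.0, min_mq = 40,
                              min_mq_rank_sum = -2,
                              min_read_pos_rank_sum = -8.0,
                              min_proband_alt_fraction = 0.20,
                              max_parent_alt_reads = 0L,
                              ac_cap_floor = 4L, ac_cap_sample_frac = 0.001) {
  if (min_dp >= max_dp) .stopf("min_dp must be < max_dp")
  if (min_proband_alt_fraction < 0 || min_proband_alt_fraction > 1)
    .stopf("min_proband_alt_fraction must lie in [0, 1]")
  structure(list(min_gq = min_gq, min_dp = min_dp, max_dp = max_dp,
                 min_qd = min_qd, max_fs = max_fs, min_mq = min_mq,
                 min_mq_rank_sum = min_mq_rank_sum,
                 min_read_pos_rank_sum = min_read_pos_rank_sum,
                 min_proband_alt_fraction = min_proband_alt_fraction,
                 max_parent_alt_reads = max_parent_alt_reads,
                 ac_cap_floor = ac_cap_floor,
                 ac_cap_sample_frac = ac_cap_sample_frac),
            class = "filter_thresholds")
}

.ac_cap <- function(thresholds, n_samples) {
  max(thresholds$ac_cap_floor,
      ceiling(thresholds$ac_cap_sample_frac * n_samples))
}

#' Site-level quality filter over a trio
#'
#' Evaluates the INFO-annotation cascade plus the per-member GQ/DP window,
#' with MIN/MAX taken over the three trio members. Absent (`NA`) INFO
#' annotations never cause a failure.
#'
#' @param record A [site_record()].
#' @param trio_calls List of the three trio members' [sample_call()]s.
#' @param thresholds A [filter_thresholds()].
#' @return List with `pass` (logical) and `reasons` (character vector of
#'   failed checks among `GQ`, `DP`, `QD`, `FS`, `MQ`, `MQRankSum`,
#'   `ReadPosRankSum`).
#' @export
site_quality_pass <- function(record, trio_calls,
                              thresholds = filter_thresholds()) {
  th <- thresholds
  gq <- vapply(trio_calls, function(x) x$genotype_quality, numeric(1))
  dp <- vapply(trio_calls, function(x) x$depth, numeric(1))
  reasons <- character(0)
  if (min(gq) < th$min_gq) reasons <- c(reasons, "GQ")
  if (min(dp) < th$min_dp || max(dp) > th$max_dp) reasons <- c(reasons, "DP")
  fail_info <- function(v, bad) !is.na(v) && bad
  if (fail_info(record$qd, record$qd <= th$min_qd)) reasons <- c(reasons, "QD")
  if (fail_info(record$fs, record$fs >= th$max_fs)) reasons <- c(reasons, "FS")
  if (fail_info(record$mq, record$mq <= th$min_mq)) reasons <- c(reasons, "MQ")
  if (fail_info(record$mq_rank_sum, record$mq_rank_sum <= th$min_mq_rank_sum))
    reasons <- c(reasons, "MQRankSum")
  if (fail_info(record$read_pos_rank_sum,
                record$read_pos_rank_sum <= th$min_read_pos_rank_sum))
    reasons <- c(reasons, "ReadPosRankSum")
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Mendelian genotype-configuration test for one trio at one site
#'
#' A candidate DNM requires the proband heterozygous with both parents
#' homozygous reference; the proband must satisfy GQ and depth bounds and
#' carry the alternative allele on strictly more than
#' `min_proband_alt_fraction` of its reads; each parent must satisfy GQ and
#' depth bounds and have at most `max_parent_alt_reads` reads supporting the
#' alternative allele.
#'
#' @param proband,sire,dam [sample_call()]s for the three trio members.
#' @param thresholds A [filter_thresholds()].
#' @return List with `pass`, `reasons` (subset of `missing_genotype`,
#'   `genotype_config`, `proband_gq`, `proband_dp`, `alt_fraction`,
#'   `parent_gq`, `parent_dp`, `parent_alt_reads`) and `alt_fraction`.
#' @export
trio_genotype_test <- function(proband, sire, dam,
                               thresholds = filter_thresholds()) {
  th <- thresholds
  af <- if (proband$depth > 0) proband$alt_reads / proband$depth else NA_real_
  gts <- c(proband$genotype, sire$genotype, dam$genotype)
  if (any(gts == "missing"))
    return(list(pass = FALSE, reasons = "missing_genotype", alt_fraction = af))
  reasons <- character(0)
  if (!(proband$genotype == "het" && sire$genotype == "hom_ref" &&
        dam$genotype == "hom_ref"))
    reasons <- c(reasons, "genotype_config")
  if (proband$genotype_quality < th$min_gq) reasons <- c(reasons, "proband_gq")
  if (proband$depth < th$min_dp || proband$depth > th$max_dp)
    reasons <- c(reasons, "proband_dp")
  if (is.na(af) || af <= th$min_proband_alt_fraction)
    reasons <- c(reasons, "alt_fraction")
  for (p in list(sire, dam)) {
    if (p$genotype_quality < th$min_gq) reasons <- c(reasons, "parent_gq")
    if (p$depth < th$min_dp || p$depth > th$max_dp)
      reasons <- c(reasons, "parent_dp")
    if (p$alt_reads > th$max_parent_alt_reads)
      reasons <- c(reasons, "parent_alt_reads")
  }
  reasons <- unique(reasons)
  list(pass = length(reasons) == 0L, reasons = reasons, alt_fraction = af)
}

#' Cohort-uniqueness screen for a candidate DNM
#'
#' A candidate fails when the cohort allele count reaches
#' max(`ac_cap_floor`, ceiling(`ac_cap_sample_frac` x n_samples)), or when any
#' cohort sample outside the proband, its half-sibs (sharing at least one
#' parent) and its offspring shows evidence of the alternative allele — a het
#' or hom-alt call, or one or more alt-supporting reads. Half-sibs and
#' offspring are exempt because they can legitimately share a parental-mosaic
#' or transmitted de novo allele.
#'
#' @param record A [site_record()] whose `calls` cover the cohort samples.
#' @param proband Proband id.
#' @param ped A `dnm_pedigree`.
#' @param n_samples Number of samples in the cohort (for the AC cap).
#' @param thresholds A [filter_thresholds()].
#' @return List with `pass` and `reasons` (subset of `ac_cap`,
#'   `population_carrier`).
#' @export
population_screen <- function(record, proband, ped,
                              n_samples = length(record$calls),
                              thresholds = filter_thresholds()) {
  reasons <- character(0)
  if (record$allele_count >= .ac_cap(thresholds, n_samples))
    reasons <- c(reasons, "ac_cap")
  rel <- derive_relatives(ped, proband)
  exempt <- c(proband, rel$half_sibs, rel$offspring)
  others <- setdiff(names(record$calls), exempt)
  carrier <- vapply(record$calls[others], function(cl) {
    cl$genotype %in% c("het", "hom_alt") || cl$alt_reads >= 1L
  }, logical(1))
  if (any(carrier)) reasons <- c(reasons, "population_carrier")
  list(pass = length(reasons) == 0L, reasons = reasons)
}

## Vectorised filter cascade for one trio over all sites of a cohort.
## Returns a character vector of ";"-joined reason codes ("" = candidate).
.trio_reasons <- function(cohort, proband, sire, dam, exempt, carrier_mat,
                          th, ac_cap) {
  s <- cohort$sites
  n <- nrow(s)
  idx <- match(c(proband, sire, dam), cohort$samples)
  gt <- cohort$gt[, idx, drop = FALSE]
  dp <- cohort$dp[, idx, drop = FALSE]
  gq <- cohort$gq[, idx, drop = FALSE]
  ad_alt <- cohort$ad_alt[, idx, drop = FALSE]
  dp0 <- dp; dp0[is.na(dp0)] <- 0L
  gq0 <- gq; gq0[is.na(gq0)] <- 0
  aa0 <- ad_alt; aa0[is.na(aa0)] <- 0L

  flags <- list()
  ## site-level cascade (MIN/MAX over the three trio members)
  min3 <- function(m) pmin(m[, 1], m[, 2], m[, 3])
  max3 <- function(m) pmax(m[, 1], m[, 2], m[, 3])
  flags$GQ <- min3(gq0) < th$min_gq
  flags$DP <- min3(dp0) < th$min_dp | max3(dp0) > th$max_dp
  flags$QD <- !is.na(s$qd) & s$qd <= th$min_qd
  flags$FS <- !is.na(s$fs) & s$fs >= th$max_fs
  flags$MQ <- !is.na(s$mq) & s$mq <= th$min_mq
  flags$MQRankSum <- !is.na(s$mq_rank_sum) & s$mq_rank_sum <= th$min_mq_rank_sum
  flags$ReadPosRankSum <- !is.na(s$read_pos_rank_sum) &
    s$read_pos_rank_sum <= th$min_read_pos_rank_sum

  ## trio genotype configuration
  miss <- is.na(gt[, 1]) | is.na(gt[, 2]) | is.na(gt[, 3])
  flags$missing_genotype <- miss
  flags$genotype_config <- !miss &
    !(gt[, 1] == 1L & gt[, 2] == 0L & gt[, 3] == 0L)
  flags$proband_gq <- !miss & gq0[, 1] < th$min_gq
  flags$proband_dp <- !miss & (dp0[, 1] < th$min_dp | dp0[, 1] > th$max_dp)
  af <- ifelse(dp0[, 1] > 0, aa0[, 1] / dp0[, 1], NA_real_)
  flags$alt_fraction <- !miss & (is.na(af) | af <= th$min_proband_alt_fraction)
  flags$parent_gq <- !miss & (gq0[, 2] < th$min_gq | gq0[, 3] < th$min_gq)
  flags$parent_dp <- !miss &
    (dp0[, 2] < th$min_dp | dp0[, 2] > th$max_dp |
     dp0[, 3] < th$min_dp | dp0[, 3] > th$max_dp)
  flags$parent_alt_reads <- !miss &
    (aa0[, 2] > th$max_parent_alt_reads | aa0[, 3] > th$max_parent_alt_reads)

  ## population-uniqueness screen
  flags$ac_cap <- s$allele_count >= ac_cap
  others <- setdiff(cohort$samples, exempt)
  flags$population_carrier <- if (length(others))
    rowSums(carrier_mat[, others, drop = FALSE]) > 0 else rep(FALSE, n)

  ## trio-level flags after a missing genotype are unreliable; report only
  ## missing_genotype for those sites (matches trio_genotype_test semantics)
  trio_level <- c("genotype_config", "proband_gq", "proband_dp",
                  "alt_fraction", "parent_gq", "parent_dp", "parent_alt_reads")
  for (f in trio_level) flags[[f]][miss] <- FALSE

  reason_mat <- do.call(cbind, flags)
  reasons <- apply(reason_mat, 1, function(r)
    paste(colnames(reason_mat)[r], collapse = ";"))
  list(reasons = reasons, alt_fraction = af)
}

#' Call candidate de novo mutations across all trios of a cohort
#'
#' Applies the full filter cascade — site-level quality, trio genotype
#' configuration, and cohort-uniqueness screen — to every (site, proband)
#' pair. A pair is a candidate iff all three stages pass; the rejection
#' ledger records every evaluated pair with its reason codes.
#'
#' @param cohort A `dnm_cohort` carrying a pedigree.
#' @param thresholds A [filter_thresholds()].
#' @param ledger Keep the full per-pair rejection ledger (set `FALSE` to save
#'   memory on large cohorts).
#' @return A `dnm_calls` object: list with `candidates` (data.frame `chrom`,
#'   `pos`, `ref`, `alt`, `trio_id`, `proband`, `alt_fraction`, `status`,
#'   `reasons`), `ledger` (same columns, every evaluated pair, or `NULL`),
#'   `thresholds`, `n_samples` and `ac_cap`. Rows are ordered by
#'   (chrom, pos, proband).
#' @export
call_candidates <- function(cohort, thresholds = filter_thresholds(),
                            ledger = TRUE) {
  if (is.null(cohort$pedigree)) .stopf("cohort carries no pedigree")
  th <- thresholds
  tr <- trios(cohort$pedigree)
  tr <- tr[tr$proband %in% cohort$samples, , drop = FALSE]
  n_samples <- length(cohort$samples)
  ac_cap <- .ac_cap(th, n_samples)
  s <- cohort$sites

  carrier_mat <- (!is.na(cohort$gt) & cohort$gt >= 1L) |
    (!is.na(cohort$ad_alt) & cohort$ad_alt >= 1L)
  colnames(carrier_mat) <- cohort$samples

  per_trio <- lapply(seq_len(nrow(tr)), function(k) {
    p <- tr$proband[k]
    rel <- derive_relatives(cohort$pedigree, p)
    out <- .trio_reasons(cohort, p, tr$sire[k], tr$dam[k],
                         exempt = c(p, rel$half_sibs, rel$offspring),
                         carrier_mat = carrier_mat, th = th, ac_cap = ac_cap)
    data.frame(chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
               trio_id = rep(tr$trio_id[k], nrow(s)),
               proband = rep(p, nrow(s)),
               alt_fraction = out$alt_fraction,
               status = ifelse(out$reasons == "", "candidate", "rejected"),
               reasons = out$reasons, stringsAsFactors = FALSE)
  })
  all_pairs <- if (length(per_trio)) do.call(rbind, per_trio) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), trio_id = character(0),
               proband = character(0), alt_fraction = numeric(0),
               status = character(0), reasons = character(0))
  ord <- order(all_pairs$chrom, all_pairs$pos, all_pairs$proband)
  all_pairs <- all_pairs[ord, , drop = FALSE]
  rownames(all_pairs) <- NULL
  structure(list(
    candidates = all_pairs[all_pairs$status == "candidate", , drop = FALSE],
    ledger = if (ledger) all_pairs else NULL,
    thresholds = th, n_samples = n_samples, ac_cap = ac_cap,
    trios = tr), class = "dnm_calls")
}

#' @export
print.dnm_calls <- function(x, ...) {
  cat(sprintf("dnm_calls: %d candidate DNM over %d trios (%d samples, AC cap %d)\n",
              nrow(x$candidates), nrow(x$trios), x$n_samples, x$ac_cap))
  invisible(x)
}

#' Candidate DNM counts per trio
#'
#' @param calls A `dnm_calls` object.
#' @return data.frame with `trio_id` and `n_dnm`, one row per trio evaluated
#'   (zero counts included).
#' @export
dnm_counts <- function(calls) {
  n <- table(factor(calls$candidates$trio_id, levels = calls$trios$trio_id))
  data.frame(trio_id = calls$trios$trio_id, n_dnm = as.integer(n),
             stringsAsFactors = FALSE)
}
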