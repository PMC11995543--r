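#' Callable proportion of the genome from SNP pass counts
#'
#' The fraction of assessed cohort SNPs passing all quality filters is used
#' as a proxy for the fraction of the genome in which a de novo mutation
#' could have been detected; it becomes the denominator correction of the
#' mutation-rate estimate.
#'
#' @param n_total Total SNPs assessed (> 0).
#' @param n_pass SNPs passing all filters (0 <= n_pass <= n_total).
#' @return A `callable_stats` list: `n_total_snps`, `n_pass_snps`,
#'   `proportion`.
#' @export
callable_proportion <- function(n_total, n_pass) {
  if (n_total <= 0) .stopf("n_total must be > 0 (undefined denominator)")
  if (n_pass < 0 || n_pass > n_total)
    .stopf("n_pass must lie in [0, n_total]")
  structure(list(n_total_snps = n_total, n_pass_snps = n_pass,
                 proportion = n_pass / n_total), class = "callable_stats")
}

#' Per-trio callable statistics from a cohort
#'
#' For each trio, the callable proportion is the fraction of cohort SNP sites
#' passing the site-level INFO cascade together with the trio's own GQ/DP
#' window (MIN/MAX over its three members).
#'
#' @param cohort A `dnm_cohort` carrying a pedigree.
#' @param thresholds A [filter_thresholds()].
#' @return data.frame with `trio_id`, `n_total`, `n_pass`, `proportion`.
#' @export
callable_stats <- function(cohort, thresholds = filter_thresholds()) {
  th <- thresholds
  s <- cohort$sites
  if (nrow(s) == 0) .stopf("cohort has no sites (undefined denominator)")
  info_pass <- !(
    (!is.na(s$qd) & s$qd <= th$min_qd) |
    (!is.na(s$fs) & s$fs >= th$max_fs) |
    (!is.na(s$mq) & s$mq <= th$min_mq) |
    (!is.na(s$mq_rank_sum) & s$mq_rank_sum <= th$min_mq_rank_sum) |
    (!is.na(s$read_pos_rank_sum) &
       s$read_pos_rank_sum <= th$min_read_pos_rank_sum))
  tr <- trios(cohort$pedigree)
  tr <- tr[tr$proband %in% cohort$samples, , drop = FALSE]
  rows <- lapply(seq_len(nrow(tr)), function(k) {
    idx <- match(c(tr$proband[k], tr$sire[k], tr$dam[k]), cohort$samples)
    dp <- cohort$dp[, idx, drop = FALSE]; dp[is.na(dp)] <- 0L
    gq <- cohort$gq[, idx, drop = FALSE]; gq[is.na(gq)] <- 0
    trio_pass <- pmin(gq[, 1], gq[, 2], gq[, 3]) >= th$min_gq &
      pmin(dp[, 1], dp[, 2], dp[, 3]) >= th$min_dp &
      pmax(dp[, 1], dp[, 2], dp[, 3]) <= th$max_dp
    n_pass <- sum(info_pass & trio_pass)
    data.frame(trio_id = tr$trio_id[k], n_total = nrow(s), n_pass = n_pass,
               proportion = n_pass / nrow(s), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-trio mutation-rate estimate
#'
#' The per-site per-gamete rate is n_dnm / (2 x autosome_length x
#' callable_proportion): the factor 2 accounts for the two gametes (one per
#' parental genome) in which each diploid offspring could have mutated, and
#' the callable proportion corrects the genome size down to the fraction
#' actually investigated.
#'
#' @param n_dnm Number of (validated) DNM in the trio offspring.
#' @param autosome_length Autosome length in bases (> 0).
#' @param proportion Callable proportion in (0, 1].
#' @param trio_id Label for the estimate.
#' @return One-row data.frame: `trio_id`, `n_dnm`, `autosome_length`,
#'   `callable_proportion`, `rate`.
#' @export
per_trio_rate <- function(n_dnm, autosome_length, proportion,
                          trio_id = "trio") {
  if (autosome_length <= 0) .stopf("autosome_length must be > 0")
  if (any(proportion <= 0) || any(proportion > 1))
    .stopf("callable proportion must lie in (0, 1] (undefined denominator at 0)")
  if (any(n_dnm < 0)) .stopf("n_dnm must be >= 0")
  data.frame(trio_id = trio_id, n_dnm = n_dnm,
             autosome_length = autosome_length,
             callable_proportion = proportion,
             rate = n_dnm / (2 * autosome_length * proportion),
             stringsAsFactors = FALSE)
}

#' Cohort mutation rate from per-trio estimates
#'
#' The cohort rate pools numerators and denominators:
#' sum(n_dnm) / sum(2 x L x p_i); the minimum and maximum are taken over the
#' per-trio rates.
#'
#' @param per_trio data.frame as returned by [per_trio_rate()] (one row per
#'   trio).
#' @return A `rate_summary` list: `cohort` (one-row data.frame with
#'   `trio_id = "cohort"`), `min_rate`, `max_rate`, `mean_dnm_per_proband`,
#'   `n_trios`, `per_trio`.
#' @export
cohort_rate <- function(per_trio) {
  if (is.null(per_trio) || nrow(per_trio) == 0)
    .stopf("cohort_rate needs at least one per-trio estimate")
  denom <- sum(2 * per_trio$autosome_length * per_trio$callable_proportion)
  rate <- sum(per_trio$n_dnm) / denom
  cohort <- data.frame(trio_id = "cohort", n_dnm = sum(per_trio$n_dnm),
                       autosome_length = sum(per_trio$autosome_length) /
                         nrow(per_trio),
                       callable_proportion = stats::weighted.mean(
                         per_trio$callable_proportion,
                         per_trio$autosome_length),
                       rate = rate, stringsAsFactors = FALSE)
  structure(list(cohort = cohort,
                 min_rate = min(per_trio$rate),
                 max_rate = max(per_trio$rate),
                 mean_dnm_per_proband = mean(per_trio$n_dnm),
                 n_trios = nrow(per_trio),
                 per_trio = per_trio), class = "rate_summary")
}

#' @export
print.rate_summary <- function(x, ...) {
  cat(sprintf("cohort mutation rate: %s per site per gamete (%d trios, %.1f DNM/proband)\n",
              format_rate(x$cohort$rate), x$n_trios, x$mean_dnm_per_proband))
  cat(sprintf("  per-trio range: %s - %s\n",
              format_rate(x$min_rate), format_rate(x$max_rate)))
  invisible(x)
}

#' Total autosome length from a FASTA file
#'
#' @param fasta Path to the reference FASTA.
#' @param contigs Optional contig whitelist (e.g. autosomes); default all.
#' @return Total length in bases.
#' @export
autosome_length_from_fasta <- function(fasta, contigs = NULL) {
  lens <- Biostrings::fasta.seqlengths(fasta)
  names(lens) <- sub("\\s.*$", "", names(lens))
  if (!is.null(contigs)) {
    miss <- setdiff(contigs, names(lens))
    if (length(miss)) .stopf("contig(s) not in FASTA: %s",
                             paste(miss, collapse = ", "))
    lens <- lens[contigs]
  }
  sum(as.numeric(lens))
}

#' Format a mutation rate in scientific notation (2 significant digits)
#'
#' @param x Numeric rate(s).
#' @return Character, e.g. `"6.3e-09"`; zero prints as `"0"`.
#' @export
format_rate <- function(x) {
  ifelse(x == 0, "0", formatC(x, format = "e", digits = 1))
}
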