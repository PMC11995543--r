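#' Per-sample genotype call at one site
#'
#' Lightweight record of one sample's call at one biallelic SNV site, as read
#' from the VCF FORMAT fields GT, AD, DP and GQ. `ref_reads + alt_reads` may be
#' smaller than `depth` (clipped or otherwise uninformative reads), but each
#' read count must not exceed the depth on its own.
#'
#' @param genotype One of `"hom_ref"`, `"het"`, `"hom_alt"`, `"missing"`.
#' @param ref_reads,alt_reads Reads supporting the reference / alternative
#'   allele (VCF AD field); non-negative integers.
#' @param depth Total read depth (VCF DP); non-negative integer.
#' @param genotype_quality Phred-scaled genotype quality (VCF GQ); ignored when
#'   the genotype is missing.
#' @return A `sample_call` object (named list).
#' @export
sample_call <- function(genotype = "missing", ref_reads = 0L, alt_reads = 0L,
                        depth = ref_reads + alt_reads, genotype_quality = 0) {
  genotype <- match.arg(genotype, c("hom_ref", "het", "hom_alt", "missing"))
  .check_count(ref_reads, "ref_reads"); .check_count(alt_reads, "alt_reads")
  .check_count(depth, "depth")
  if (ref_reads > depth || alt_reads > depth)
    .stopf("read counts (%d ref, %d alt) exceed depth %d",
           ref_reads, alt_reads, depth)
  structure(list(genotype = genotype, ref_reads = as.integer(ref_reads),
                 alt_reads = as.integer(alt_reads), depth = as.integer(depth),
                 genotype_quality = as.numeric(genotype_quality)),
            class = "sample_call")
}

#' One biallelic SNV site with INFO annotations and per-sample calls
#'
#' @param chrom Contig name.
#' @param pos 1-based position.
#' @param ref,alt Reference / alternative allele, single bases in A, C, G, T
#'   and distinct from each other.
#' @param qd,fs,mq,mq_rank_sum,read_pos_rank_sum Site INFO annotations
#'   (QD, FS, MQ, MQRankSum, ReadPosRankSum); `NA` when absent from the VCF.
#'   Rank-sum annotations are genuinely absent at sites without heterozygous
#'   reference-supporting reads, so absence is represented, never zero-filled.
#' @param allele_count Alternative allele count over all cohort samples.
#' @param calls Named list of [sample_call()] objects, keyed by sample id.
#' @return A `site_record` object.
#' @export
site_record <- function(chrom, pos, ref, alt,
                        qd = NA_real_, fs = NA_real_, mq = NA_real_,
                        mq_rank_sum = NA_real_, read_pos_rank_sum = NA_real_,
                        allele_count = 0L, calls = list()) {
  .check_base(ref, "ref allele"); .check_base(alt, "alt allele")
  if (ref == alt) .stopf("ref and alt allele must differ at %s:%d", chrom, pos)
  if (pos < 1) .stopf("position must be >= 1")
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = ref, alt = alt,
                 qd = as.numeric(qd), fs = as.numeric(fs), mq = as.numeric(mq),
                 mq_rank_sum = as.numeric(mq_rank_sum),
                 read_pos_rank_sum = as.numeric(read_pos_rank_sum),
                 allele_count = as.integer(allele_count), calls = calls),
            class = "site_record")
}

## integer genotype codes used in cohort matrices
.GT_CODES <- c(hom_ref = 0L, het = 1L, hom_alt = 2L)

.gt_label <- function(code) {
  out <- rep("missing", length(code))
  out[!is.na(code)] <- names(.GT_CODES)[match(code[!is.na(code)], .GT_CODES)]
  out
}

#' Assemble an in-memory trio cohort
#'
#' The cohort container used throughout the pipeline: a site table plus
#' per-sample call matrices (sites x samples), mirroring the layout of a
#' multi-sample VCF. Usually produced by [read_cohort()] or
#' [render_observations()] rather than called directly.
#'
#' @param sites `data.frame` with columns `chrom`, `pos`, `ref`, `alt`, `qd`,
#'   `fs`, `mq`, `mq_rank_sum`, `read_pos_rank_sum`, `allele_count`.
#' @param gt Integer matrix of genotype codes (0 hom-ref, 1 het, 2 hom-alt,
#'   `NA` missing), sites in rows, samples in columns.
#' @param ad_ref,ad_alt,dp,gq Matrices of the corresponding FORMAT values,
#'   dimensioned like `gt`.
#' @param pedigree A pedigree from [read_ped()] or [as_pedigree()], or `NULL`.
#' @param n_skipped Count of VCF records dropped as non-SNV or multi-allelic.
#' @return A `dnm_cohort` object.
#' @export
new_cohort <- function(sites, gt, ad_ref, ad_alt, dp, gq,
                       pedigree = NULL, n_skipped = 0L) {
  needed <- c("chrom", "pos", "ref", "alt", "qd", "fs", "mq",
              "mq_rank_sum", "read_pos_rank_sum", "allele_count")
  miss <- setdiff(needed, names(sites))
  if (length(miss)) .stopf("sites table lacks column(s): %s",
                           paste(miss, collapse = ", "))
  samples <- colnames(gt)
  if (is.null(samples)) .stopf("genotype matrix must have sample column names")
  for (m in list(ad_ref, ad_alt, dp, gq))
    if (!identical(dim(m), dim(gt))) .stopf("call matrices must share dimensions")
  if (nrow(gt) != nrow(sites)) .stopf("call matrices must have one row per site")
  structure(list(sites = sites, gt = gt, ad_ref = ad_ref, ad_alt = ad_alt,
                 dp = dp, gq = gq, samples = samples, pedigree = pedigree,
                 n_skipped = as.integer(n_skipped)),
            class = "dnm_cohort")
}

#' @export
print.dnm_cohort <- function(x, ...) {
  cat(sprintf("dnm_cohort: %d biallelic SNV sites x %d samples (%d records skipped)\n",
              nrow(x$sites), length(x$samples), x$n_skipped))
  if (!is.null(x$pedigree))
    cat(sprintf("  pedigree: %d individuals, %d trios\n",
                nrow(x$pedigree), nrow(trios(x$pedigree))))
  invisible(x)
}

## Extract one sample's call at site i as a sample_call object.
.call_at <- function(cohort, i, sample) {
  code <- cohort$gt[i, sample]
  sample_call(genotype = .gt_label(code),
              ref_reads = ifelse(is.na(cohort$ad_ref[i, sample]), 0L,
                                 cohort$ad_ref[i, sample]),
              alt_reads = ifelse(is.na(cohort$ad_alt[i, sample]), 0L,
                                 cohort$ad_alt[i, sample]),
              depth = ifelse(is.na(cohort$dp[i, sample]), 0L,
                             cohort$dp[i, sample]),
              genotype_quality = ifelse(is.na(cohort$gq[i, sample]), 0,
                                        cohort$gq[i, sample]))
}

#' Extract one site of a cohort as a site_record
#'
#' @param cohort A `dnm_cohort`.
#' @param i Site row index.
#' @param samples Samples to include as calls (default all).
#' @return A [site_record()].
#' @export
cohort_site <- function(cohort, i, samples = cohort$samples) {
  s <- cohort$sites[i, ]
  calls <- lapply(samples, function(sm) .call_at(cohort, i, sm))
  names(calls) <- samples
  site_record(s$chrom, s$pos, s$ref, s$alt, qd = s$qd, fs = s$fs, mq = s$mq,
              mq_rank_sum = s$mq_rank_sum,
              read_pos_rank_sum = s$read_pos_rank_sum,
              allele_count = s$allele_count, calls = calls)
}
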