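## VCF parsing is delegated to vcfR; this file maps a joint-called
## multi-sample VCF + PED pair onto the dnm_cohort container.

.GT_MAP <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)

.parse_gt <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  out <- unname(.GT_MAP[gt])
  dim(out) <- dim(gt); dimnames(out) <- dimnames(gt)
  out
}

#' Read a multi-sample VCF and pedigree into a cohort
#'
#' Loads biallelic SNV records (GT/AD/DP/GQ per sample; QD, FS, MQ, MQRankSum,
#' ReadPosRankSum site INFO annotations) from a VCF 4.x file and attaches the
#' pedigree. Multi-allelic and non-SNV records are skipped and counted.
#' Missing INFO annotations stay `NA`; they are genuinely absent at some
#' sites and never imputed to zero.
#'
#' @param vcf_path Path to a plain or bgzipped VCF.
#' @param ped_path Path to a 6-column PED file.
#' @param contigs Optional contig whitelist (e.g. the autosomes); records on
#'   other contigs are dropped.
#' @return A `dnm_cohort` (see [new_cohort()]).
#' @export
read_cohort <- function(vcf_path, ped_path, contigs = NULL) {
  if (!file.exists(vcf_path)) .stopf("VCF file not found: %s", vcf_path)
  ped <- read_ped(ped_path)
  vcf <- tryCatch(vcfR::read.vcfR(vcf_path, verbose = FALSE),
                  error = function(e) .stopf("malformed VCF %s: %s",
                                             vcf_path, conditionMessage(e)))
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    empty <- matrix(integer(0), nrow = 0, ncol = ncol(vcf@gt) - 1,
                    dimnames = list(NULL, colnames(vcf@gt)[-1]))
    sites <- data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        qd = numeric(0), fs = numeric(0), mq = numeric(0),
                        mq_rank_sum = numeric(0), read_pos_rank_sum = numeric(0),
                        allele_count = integer(0))
    return(new_cohort(sites, empty, empty, empty, empty, empty,
                      pedigree = ped, n_skipped = 0L))
  }

  is_snv <- !is.na(fix$ALT) & fix$REF %in% .BASES & fix$ALT %in% .BASES
  if (!is.null(contigs)) {
    off_contig <- !(fix$CHROM %in% contigs)
    keep <- is_snv & !off_contig
  } else keep <- is_snv
  n_skipped <- sum(!is_snv)

  info_num <- function(tag) {
    x <- suppressWarnings(
      vcfR::extract.info(vcf, element = tag, as.numeric = TRUE))
    if (is.null(x)) rep(NA_real_, nrow(fix)) else as.numeric(x)
  }
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  ad_raw <- vcfR::extract.gt(vcf, element = "AD")
  dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
  gq <- vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE)
  if (is.null(gt_raw) || is.null(ad_raw) || is.null(dp) || is.null(gq))
    .stopf("VCF %s lacks one of the required FORMAT fields GT, AD, DP, GQ",
           vcf_path)

  samples <- colnames(gt_raw)
  missing_members <- setdiff(
    unique(c(trios(ped)$proband, trios(ped)$sire, trios(ped)$dam)), samples)
  if (length(missing_members))
    .stopf("trio member(s) absent from VCF sample columns: %s",
           paste(missing_members, collapse = ", "))

  gt <- .parse_gt(gt_raw)
  ad_ref <- vcfR::masplit(ad_raw, record = 1, sort = FALSE)
  ad_alt <- vcfR::masplit(ad_raw, record = 2, sort = FALSE)
  storage.mode(ad_ref) <- "integer"; storage.mode(ad_alt) <- "integer"
  storage.mode(dp) <- "integer"

  gt <- gt[keep, , drop = FALSE]
  sites <- data.frame(
    chrom = fix$CHROM[keep], pos = as.integer(fix$POS[keep]),
    ref = fix$REF[keep], alt = fix$ALT[keep],
    qd = info_num("QD")[keep], fs = info_num("FS")[keep],
    mq = info_num("MQ")[keep],
    mq_rank_sum = info_num("MQRankSum")[keep],
    read_pos_rank_sum = info_num("ReadPosRankSum")[keep],
    allele_count = as.integer(rowSums(gt, na.rm = TRUE)),
    stringsAsFactors = FALSE)

  new_cohort(sites, gt,
             ad_ref[keep, , drop = FALSE], ad_alt[keep, , drop = FALSE],
             dp[keep, , drop = FALSE], gq[keep, , drop = FALSE],
             pedigree = ped, n_skipped = n_skipped)
}

#' Write a cohort back to a VCF file
#'
#' Emits a minimal VCF 4.2 with the INFO (AC, QD, FS, MQ, MQRankSum,
#' ReadPosRankSum) and FORMAT (GT:AD:DP:GQ) fields the pipeline consumes;
#' absent INFO annotations are omitted from the record, and `write_cohort()`
#' followed by [read_cohort()] round-trips all site and call values.
#'
#' @param cohort A `dnm_cohort`.
#' @param path Output path (plain-text `.vcf`).
#' @param contig_lengths Optional named vector of contig lengths for the
#'   header.
#' @return The path, invisibly.
#' @export
write_cohort <- function(cohort, path, contig_lengths = NULL) {
  s <- cohort$sites
  hdr <- c("##fileformat=VCFv4.2", "##source=trionovo")
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  hdr <- c(hdr,
    '##INFO=<ID=AC,Number=A,Type=Integer,Description="Allele count in genotypes">',
    '##INFO=<ID=QD,Number=1,Type=Float,Description="Variant quality by depth">',
    '##INFO=<ID=FS,Number=1,Type=Float,Description="Phred-scaled strand bias">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
    '##INFO=<ID=MQRankSum,Number=1,Type=Float,Description="Mapping quality rank sum">',
    '##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description="Read position rank sum">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$samples), collapse = "\t"))

  fmt_num <- function(x) formatC(x, format = "g", digits = 6)
  info_field <- function(i) {
    parts <- sprintf("AC=%d", s$allele_count[i])
    tags <- c(QD = "qd", FS = "fs", MQ = "mq", MQRankSum = "mq_rank_sum",
              ReadPosRankSum = "read_pos_rank_sum")
    for (k in names(tags)) {
      v <- s[[tags[[k]]]][i]
      if (!is.na(v)) parts <- c(parts, sprintf("%s=%s", k, fmt_num(v)))
    }
    paste(parts, collapse = ";")
  }

  gt_str <- matrix("./.:.,.:.:.", nrow = nrow(s), ncol = length(cohort$samples))
  known <- !is.na(cohort$gt)
  gt_sym <- c("0/0", "0/1", "1/1")[cohort$gt[known] + 1L]
  gt_str[known] <- sprintf("%s:%d,%d:%d:%d", gt_sym,
                           cohort$ad_ref[known], cohort$ad_alt[known],
                           cohort$dp[known], as.integer(round(cohort$gq[known])))

  body <- vapply(seq_len(nrow(s)), function(i) {
    paste(c(s$chrom[i], s$pos[i], ".", s$ref[i], s$alt[i], ".", "PASS",
            info_field(i), "GT:AD:DP:GQ", gt_str[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
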