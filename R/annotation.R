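## External deleteriousness annotations (pCADD scores, VEP consequence
## terms, SIFT labels) are consumed as a pre-computed table keyed by
## (chrom, pos, ref, alt) and joined onto called DNM.

#' Standard VEP consequence terms ordered from most to least severe
#' @export
vep_severity_order <- c(
  "transcript_ablation", "splice_acceptor_variant", "splice_donor_variant",
  "stop_gained", "frameshift_variant", "stop_lost", "start_lost",
  "missense_variant", "splice_region_variant", "synonymous_variant",
  "5_prime_UTR_variant", "3_prime_UTR_variant", "intron_variant",
  "upstream_gene_variant", "downstream_gene_variant", "intergenic_variant")

.CODING_SPLICE <- c("splice_acceptor_variant", "splice_donor_variant",
                    "stop_gained", "frameshift_variant", "stop_lost",
                    "start_lost", "missense_variant", "splice_region_variant",
                    "synonymous_variant")

#' Most severe consequence of a (possibly multi-valued) VEP term
#'
#' @param x Character vector; multiple consequences joined with `&`.
#' @return The most severe single term per element.
#' @export
most_severe_consequence <- function(x) {
  vapply(strsplit(x, "&", fixed = TRUE), function(terms) {
    r <- match(terms, vep_severity_order)
    if (all(is.na(r))) terms[1] else terms[which.min(r)]
  }, character(1))
}

#' Join an annotation table onto called DNM
#'
#' Left join by (chrom, pos, ref, alt): every DNM is kept; unmatched DNM
#' carry `NA` annotations and their count is attached as an attribute.
#' Duplicate annotation keys with conflicting values raise an error (exact
#' duplicate rows are collapsed).
#'
#' @param dnms data.frame with `chrom`, `pos`, `ref`, `alt` (plus any other
#'   columns, preserved).
#' @param annotation data.frame with `chrom`, `pos`, `ref`, `alt`, `pcadd`,
#'   `consequence`, `sift`, `gene`.
#' @return Annotated data.frame (same row count and order as `dnms`), with
#'   attribute `n_unmatched`.
#' @export
join_annotations <- function(dnms, annotation) {
  key_cols <- c("chrom", "pos", "ref", "alt")
  for (df in list(dnms, annotation)) {
    miss <- setdiff(key_cols, names(df))
    if (length(miss)) .stopf("missing key column(s): %s",
                             paste(miss, collapse = ", "))
  }
  annotation <- unique(annotation)
  key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  ak <- key(annotation)
  if (anyDuplicated(ak))
    .stopf("conflicting duplicate annotation rows for key(s): %s",
           paste(unique(ak[duplicated(ak)]), collapse = ", "))
  i <- match(key(dnms), ak)
  ann_cols <- setdiff(names(annotation), key_cols)
  out <- dnms
  for (col in ann_cols) out[[col]] <- annotation[[col]][i]
  attr(out, "n_unmatched") <- sum(is.na(i))
  out
}

#' Summarise annotated DNM by consequence class
#'
#' Groups by the most severe VEP consequence, reporting counts and mean
#' pCADD (absent scores are ignored; `NA` when no score is available for a
#' class). The high-impact list collects coding and splice variants with a
#' pCADD score above the threshold or a deleterious SIFT label; pCADD 10 and
#' 20 rank a substitution among the 10% and 1% most deleterious.
#'
#' @param annotated data.frame from [join_annotations()] (columns
#'   `consequence`, `pcadd`, optionally `sift`).
#' @param pcadd_threshold High-impact pCADD cutoff (default 10).
#' @return List with `by_consequence` (data.frame `consequence`, `n`,
#'   `mean_pcadd`) and `high_impact` (subset of the input rows).
#' @export
summarize_by_consequence <- function(annotated, pcadd_threshold = 10) {
  if (!nrow(annotated))
    return(list(by_consequence = data.frame(consequence = character(0),
                                            n = integer(0),
                                            mean_pcadd = numeric(0)),
                high_impact = annotated))
  cons <- most_severe_consequence(
    ifelse(is.na(annotated$consequence), "intergenic_variant",
           annotated$consequence))
  agg <- lapply(split(seq_along(cons), cons), function(idx) {
    sc <- annotated$pcadd[idx]
    data.frame(n = length(idx),
               mean_pcadd = if (all(is.na(sc))) NA_real_ else
                 mean(sc, na.rm = TRUE))
  })
  by_cons <- data.frame(consequence = names(agg),
                        n = vapply(agg, `[[`, 0, "n"),
                        mean_pcadd = vapply(agg, `[[`, 0, "mean_pcadd"),
                        row.names = NULL, stringsAsFactors = FALSE)
  r <- match(by_cons$consequence, vep_severity_order)
  by_cons <- by_cons[order(ifelse(is.na(r), length(vep_severity_order) + 1, r)), ]
  rownames(by_cons) <- NULL
  sift <- if (!is.null(annotated$sift)) annotated$sift else
    rep(NA_character_, nrow(annotated))
  hi <- cons %in% .CODING_SPLICE &
    ((!is.na(annotated$pcadd) & annotated$pcadd > pcadd_threshold) |
       (!is.na(sift) & sift == "deleterious"))
  list(by_consequence = by_cons,
       high_impact = annotated[hi, , drop = FALSE])
}
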