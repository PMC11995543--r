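## Mutational-spectrum classification: six pyrimidine-centred base-change
## classes, SBS96 trinucleotide contexts, Ti/Tv and CpG-deamination summaries.

#' Collapse a base change to its pyrimidine-centred class
#'
#' Substitutions are reported with a pyrimidine (C or T) reference, the
#' standard strand-collapse convention: a purine reference (A or G) and its
#' alternative are reverse-complemented, so e.g. G>A becomes C>T. Transitions
#' are the purine<->purine / pyrimidine<->pyrimidine changes, i.e. the
#' collapsed classes C>T and T>C.
#'
#' @param ref,alt Single bases in A, C, G, T (vectorised); `ref != alt`.
#' @return data.frame with `collapsed_class` (one of C>A, C>G, C>T, T>A,
#'   T>C, T>G) and `is_transition`.
#' @export
collapse_change <- function(ref, alt) {
  .check_base(ref, "ref"); .check_base(alt, "alt")
  if (any(ref == alt)) .stopf("ref and alt must differ")
  flip <- ref %in% .PURINES
  r <- ifelse(flip, unname(.COMP[ref]), ref)
  a <- ifelse(flip, unname(.COMP[alt]), alt)
  cls <- paste0(r, ">", a)
  data.frame(collapsed_class = cls, is_transition = cls %in% .TRANSITIONS,
             stringsAsFactors = FALSE)
}

#' Trinucleotide context of a substitution
#'
#' Extracts the bases flanking a substitution from the reference sequence and
#' reports the pyrimidine-centred context label (e.g. `"A[C>T]G"`). When the
#' reference base is a purine, both the change and its flanks are
#' reverse-complemented (and thereby swapped). A C>T (or C>A, C>G) change
#' with a downstream G is a CpG-site mutation, the signature of spontaneous
#' deamination of methylated cytosine.
#'
#' @param refseq Reference sequence of the contig (character string or
#'   `Biostrings::DNAString`).
#' @param pos 1-based position of the substitution within `refseq`.
#' @param ref,alt The substitution; `ref` must match `refseq` at `pos`.
#' @return List with `collapsed_class`, `upstream`, `downstream`, `context`
#'   (label, `NA` at contig edges), `is_cpg`.
#' @export
context_of <- function(refseq, pos, ref, alt) {
  refseq <- as.character(refseq)
  .check_base(ref, "ref"); .check_base(alt, "alt")
  n <- nchar(refseq)
  if (pos < 1 || pos > n) .stopf("position %d outside sequence (1..%d)", pos, n)
  at <- toupper(substr(refseq, pos, pos))
  if (at != ref)
    .stopf("reference mismatch at %d: sequence has %s, variant says %s",
           pos, at, ref)
  cls <- collapse_change(ref, alt)$collapsed_class
  if (pos == 1 || pos == n)
    return(list(collapsed_class = cls, upstream = NA_character_,
                downstream = NA_character_, context = NA_character_,
                is_cpg = NA))
  up <- toupper(substr(refseq, pos - 1, pos - 1))
  down <- toupper(substr(refseq, pos + 1, pos + 1))
  if (ref %in% .PURINES) {
    tmp <- up
    up <- unname(.COMP[down])
    down <- unname(.COMP[tmp])
  }
  list(collapsed_class = cls, upstream = up, downstream = down,
       context = sprintf("%s[%s]%s", up, cls, down),
       is_cpg = startsWith(cls, "C") && identical(down, "G"))
}

#' Contexts for a table of variants
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param fasta Path to the reference FASTA covering the variants' contigs.
#' @return `variants` with added columns `collapsed_class`, `is_transition`,
#'   `upstream`, `downstream`, `context`, `is_cpg`.
#' @export
contexts_for_variants <- function(variants, fasta) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  miss <- setdiff(unique(variants$chrom), names(seqs))
  if (length(miss)) .stopf("contig(s) not in FASTA: %s",
                           paste(miss, collapse = ", "))
  ctx <- lapply(seq_len(nrow(variants)), function(i) {
    context_of(seqs[[variants$chrom[i]]], variants$pos[i],
               variants$ref[i], variants$alt[i])
  })
  variants$collapsed_class <- vapply(ctx, `[[`, "", "collapsed_class")
  variants$is_transition <- variants$collapsed_class %in% .TRANSITIONS
  variants$upstream <- vapply(ctx, `[[`, "", "upstream")
  variants$downstream <- vapply(ctx, `[[`, "", "downstream")
  variants$context <- vapply(ctx, `[[`, "", "context")
  variants$is_cpg <- vapply(ctx, function(x) as.logical(x$is_cpg), NA)
  variants
}

.SBS96 <- local({
  g <- expand.grid(down = .BASES, cls = .CLASSES, up = .BASES,
                   stringsAsFactors = FALSE)
  sprintf("%s[%s]%s", g$up, g$cls, g$down)
})

#' Summarise a mutational spectrum
#'
#' Computes six-class counts and proportions, the 96-context matrix, the
#' transition/transversion ratio, the C>T / T>C ratio, and the fraction of
#' C>T mutations at CpG sites. Ratios with a zero denominator are reported as
#' `NA` (undefined), never as infinities.
#'
#' @param changes data.frame with at least `collapsed_class`; optionally
#'   `context` and `is_cpg` (as from [contexts_for_variants()]).
#' @return A `spectrum_summary` list: `counts`, `proportions` (named by
#'   class), `context_matrix` (16 flank pairs x 6 classes, when contexts are
#'   available), `titv_ratio`, `ct_tc_ratio`, `cpg_fraction_of_ct`, `n`.
#' @export
summarize_spectrum <- function(changes) {
  cls <- factor(changes$collapsed_class, levels = .CLASSES)
  if (anyNA(cls) && nrow(changes))
    .stopf("unknown collapsed class: %s",
           paste(unique(changes$collapsed_class[is.na(cls)]), collapse = ", "))
  counts <- table(cls)
  n <- sum(counts)
  props <- if (n > 0) as.numeric(counts) / n else rep(NA_real_, length(.CLASSES))
  names(props) <- .CLASSES
  ti <- sum(counts[.TRANSITIONS])
  tv <- n - ti
  titv <- if (tv > 0) ti / tv else NA_real_
  ct_tc <- if (counts[["T>C"]] > 0) counts[["C>T"]] / counts[["T>C"]] else NA_real_

  cpg_frac <- NA_real_
  if (!is.null(changes$is_cpg)) {
    ct <- changes$collapsed_class == "C>T" & !is.na(changes$is_cpg)
    if (sum(ct) > 0) cpg_frac <- mean(changes$is_cpg[ct])
  }

  context_matrix <- NULL
  if (!is.null(changes$context)) {
    ctx <- factor(changes$context, levels = .SBS96)
    v <- table(ctx)
    up <- substr(.SBS96, 1, 1); down <- substr(.SBS96, nchar(.SBS96), nchar(.SBS96))
    cls96 <- sub("^.\\[(.*)\\].$", "\\1", .SBS96)
    flank <- paste0(up, ".", down)
    context_matrix <- matrix(0L, nrow = 16, ncol = 6,
                             dimnames = list(sort(unique(flank)), .CLASSES))
    for (i in seq_along(.SBS96))
      context_matrix[flank[i], cls96[i]] <- as.integer(v[[i]])
  }
  structure(list(counts = stats::setNames(as.integer(counts), .CLASSES),
                 proportions = props, context_matrix = context_matrix,
                 titv_ratio = titv, ct_tc_ratio = as.numeric(ct_tc),
                 cpg_fraction_of_ct = cpg_frac, n = as.integer(n)),
            class = "spectrum_summary")
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf("spectrum_summary: %d mutations; Ti/Tv = %s; C>T/T>C = %s; CpG fraction of C>T = %s\n",
              x$n,
              ifelse(is.na(x$titv_ratio), "undefined", sprintf("%.1f", x$titv_ratio)),
              ifelse(is.na(x$ct_tc_ratio), "undefined", sprintf("%.1f", x$ct_tc_ratio)),
              ifelse(is.na(x$cpg_fraction_of_ct), "undefined",
                     sprintf("%.0f%%", 100 * x$cpg_fraction_of_ct))))
  print(data.frame(class = names(x$counts), count = x$counts,
                   proportion = round(x$proportions, 3), row.names = NULL))
  invisible(x)
}
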