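## Follow-up panel genotyping (PlexSeq-style presence/absence calls) is used
## to confirm candidate DNM: a mutation transmitted to at least one offspring
## of the proband is germline; one absent from enough genotyped offspring is
## possibly somatic (post-zygotic, confined to part of the proband's body).

.PANEL_CALLS <- c("carrier", "non_carrier", "failed")
.VALIDATION_CLASSES <- c("germline", "possible_somatic", "not_validated",
                         "inconclusive", "assay_failed")

#' Classify one candidate DNM from panel genotypes
#'
#' Classes (mutually exclusive, every input maps to exactly one):
#' * `assay_failed` — the proband's assay failed;
#' * `not_validated` — the proband is a non-carrier, or a parent carries the
#'   allele (inherited, not de novo, even if offspring carry it too);
#' * `germline` — proband carrier, both parents non-carriers, and at least
#'   one offspring carrier;
#' * `possible_somatic` — proband carrier, parents non-carriers, at least
#'   `min_offspring_for_somatic` offspring successfully genotyped and none a
#'   carrier;
#' * `inconclusive` — anything else (e.g. a failed parent assay, or too few
#'   genotyped offspring to distinguish germline from somatic).
#'
#' @param proband,sire,dam Calls in `"carrier"`, `"non_carrier"`, `"failed"`.
#' @param offspring Character vector of offspring calls (possibly empty; up
#'   to nine are typically assayed).
#' @param min_offspring_for_somatic Minimum successfully genotyped,
#'   non-carrying offspring required to label a proband-only mutation as
#'   possibly somatic.
#' @return One of the five class labels.
#' @export
classify_validation <- function(proband, sire, dam, offspring = character(0),
                                min_offspring_for_somatic = 2L) {
  stopifnot(proband %in% .PANEL_CALLS, sire %in% .PANEL_CALLS,
            dam %in% .PANEL_CALLS, all(offspring %in% .PANEL_CALLS))
  if (proband == "failed") return("assay_failed")
  if (proband == "non_carrier") return("not_validated")
  if (sire == "carrier" || dam == "carrier") return("not_validated")
  genotyped <- offspring[offspring != "failed"]
  if (sire == "non_carrier" && dam == "non_carrier") {
    if (any(genotyped == "carrier")) return("germline")
    if (length(genotyped) >= min_offspring_for_somatic)
      return("possible_somatic")
  }
  "inconclusive"
}

#' Classify a whole panel-genotype table
#'
#' @param panel data.frame with columns `dnm_id`, `individual_id`, `role`
#'   (`proband`, `sire`, `dam`, `offspring`), `call`.
#' @param min_offspring_for_somatic See [classify_validation()].
#' @return data.frame with `dnm_id` and `class`; plus a `validation_rate`
#'   attribute: validated (germline + possible_somatic) over assayed
#'   (non-failed) DNM.
#' @export
classify_panel <- function(panel, min_offspring_for_somatic = 2L) {
  needed <- c("dnm_id", "individual_id", "role", "call")
  miss <- setdiff(needed, names(panel))
  if (length(miss)) .stopf("panel lacks column(s): %s", paste(miss, collapse = ", "))
  one <- function(df) {
    pick <- function(role) {
      v <- df$call[df$role == role]
      if (length(v) == 0) "failed" else v[1]
    }
    classify_validation(pick("proband"), pick("sire"), pick("dam"),
                        df$call[df$role == "offspring"],
                        min_offspring_for_somatic)
  }
  ids <- unique(panel$dnm_id)
  cls <- vapply(ids, function(id) one(panel[panel$dnm_id == id, , drop = FALSE]),
                character(1))
  out <- data.frame(dnm_id = ids, class = unname(cls), stringsAsFactors = FALSE)
  assayed <- sum(out$class != "assay_failed")
  validated <- sum(out$class %in% c("germline", "possible_somatic"))
  attr(out, "validation_rate") <- if (assayed > 0) validated / assayed else NA_real_
  out
}

#' Trace transmission of a DNM through the pedigree
#'
#' The proband is generation 1; descendants take the (shortest-path) pedigree
#' depth below it. Carrier counts are tallied per generation over genotyped
#' descendants; a mutation is "lost" at the first generation (from 2 onward)
#' whose genotyped descendants include no carrier, and "segregating" if
#' carriers persist through the deepest genotyped generation.
#'
#' @param ped A `dnm_pedigree`.
#' @param proband Founder carrier id.
#' @param genotyped Ids of individuals with a carrier/non-carrier observation.
#' @param carriers Subset of `genotyped` observed to carry the mutation
#'   (the proband itself need not be listed; it is assumed a carrier).
#' @return A `transmission_trace` list: `generation_counts` (named integer
#'   vector: carriers per generation), `genotyped_counts`, `lost_generation`
#'   (`NA` when segregating), `status` (`"lost"`/`"segregating"`).
#' @export
trace_transmission <- function(ped, proband, genotyped, carriers) {
  extra <- setdiff(carriers, genotyped)
  if (length(extra)) .stopf("carriers must be a subset of genotyped ids")
  gen <- descendant_generations(ped, proband)
  non_desc <- setdiff(carriers, names(gen))
  if (length(non_desc))
    .warnf("carrier(s) outside the proband's descendants: %s",
           paste(non_desc, collapse = ", "))
  genotyped <- union(genotyped, proband)
  carriers <- union(carriers, proband)
  in_lineage <- intersect(genotyped, names(gen))
  max_gen <- max(gen[in_lineage], 2L)
  gens <- seq_len(max_gen)
  g_count <- vapply(gens, function(g)
    sum(gen[in_lineage] == g), integer(1))
  c_count <- vapply(gens, function(g)
    sum(gen[intersect(carriers, in_lineage)] == g), integer(1))
  names(g_count) <- names(c_count) <- paste0("gen", gens)
  lost <- NA_integer_
  for (g in gens[-1]) if (c_count[g] == 0L) { lost <- g; break }
  structure(list(generation_counts = c_count, genotyped_counts = g_count,
                 lost_generation = lost,
                 status = if (is.na(lost)) "segregating" else "lost"),
            class = "transmission_trace")
}

#' Concordance of chip heterozygous calls with sequencing calls
#'
#' The proportion of array heterozygous genotypes that are also called
#' heterozygous in the whole-genome sequencing data at the same sites.
#' Sites with a missing sequencing call are excluded from the denominator
#' (their count is attached as an attribute).
#'
#' @param chip_calls,wgs_calls Equal-length genotype vectors coded
#'   `"hom_ref"`, `"het"`, `"hom_alt"` (`NA` = missing).
#' @return Concordance proportion in 0..1, with attributes `n_het_chip`,
#'   `n_excluded_missing`.
#' @export
het_concordance <- function(chip_calls, wgs_calls) {
  if (length(chip_calls) != length(wgs_calls))
    .stopf("call vectors must have equal length")
  idx <- which(!is.na(chip_calls) & chip_calls == "het")
  excl <- sum(is.na(wgs_calls[idx]))
  idx <- idx[!is.na(wgs_calls[idx])]
  if (!length(idx))
    .stopf("no overlapping chip-het site with a non-missing WGS call")
  out <- mean(wgs_calls[idx] == "het")
  attr(out, "n_het_chip") <- length(idx)
  attr(out, "n_excluded_missing") <- excl
  out
}

#' Fraction of genotype classes removed by filtering
#'
#' Compares genotype-class counts (hom-ref, het, hom-alt) before and after
#' the filter cascade; a filter that disproportionately removes heterozygous
#' calls would bias DNM detection.
#'
#' @param pre,post Named counts for classes `Hom_RR`, `Het_RA`, `Hom_AA`
#'   (post <= pre per class).
#' @return Named vector of removed fractions (1 - post/pre); `NA` where
#'   `pre` is zero.
#' @export
class_retention <- function(pre, post) {
  classes <- c("Hom_RR", "Het_RA", "Hom_AA")
  miss <- setdiff(classes, union(names(pre), character(0)))
  if (length(miss) || !all(classes %in% names(post)))
    .stopf("pre and post must be named counts for %s",
           paste(classes, collapse = ", "))
  pre <- pre[classes]; post <- post[classes]
  if (any(post > pre)) .stopf("post-filter count exceeds pre-filter count")
  out <- ifelse(pre > 0, 1 - post / pre, NA_real_)
  names(out) <- classes
  out
}
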