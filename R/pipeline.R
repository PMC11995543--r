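## Orchestration: compose simulate -> call -> rate -> spectrum -> validate ->
## annotate -> report over a directory of TSV outputs, with a JSON run
## manifest recording inputs, thresholds, per-stage counts and the seed.

#' Cohort summary in the style of a per-line results table
#'
#' @param n_dnm Total validated/candidate DNM.
#' @param n_trios Number of trios analysed.
#' @param rate_summary A `rate_summary` from [cohort_rate()], or `NULL`.
#' @param spectrum A `spectrum_summary` from [summarize_spectrum()], or
#'   `NULL`.
#' @return data.frame with rows: number of DNM, number of trios, average DNM
#'   per proband, mutation rate, minimum and maximum per-trio rate, Ti/Tv.
#' @export
cohort_summary_table <- function(n_dnm, n_trios, rate_summary = NULL,
                                 spectrum = NULL) {
  if (n_trios <= 0) .stopf("n_trios must be > 0")
  rows <- list(
    c("Number of DNM", as.character(n_dnm)),
    c("Number of trios", as.character(n_trios)),
    c("Average number of DNM per proband",
      sprintf("%.1f", n_dnm / n_trios)))
  if (!is.null(rate_summary)) {
    rows <- c(rows, list(
      c("Mutation rate", format_rate(rate_summary$cohort$rate)),
      c("Minimum mutation rate", format_rate(rate_summary$min_rate)),
      c("Maximum mutation rate", format_rate(rate_summary$max_rate))))
  }
  if (!is.null(spectrum)) {
    rows <- c(rows, list(
      c("Ti/Tv", ifelse(is.na(spectrum$titv_ratio), "undefined",
                        sprintf("%.1f", spectrum$titv_ratio)))))
  }
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(quantity = r[1], value = r[2], stringsAsFactors = FALSE)))
  out
}

.stage_log <- function(stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
}

#' Run the full DNM analysis pipeline
#'
#' Stages compose as in the command-line workflow: `simulate` (or load real
#' inputs), `call`, `rate`, `spectrum`, `validate`, `annotate`, `report`.
#' All outputs are TSV files under `out_dir`, plus `manifest.json` recording
#' input checksums, thresholds, per-stage counts and the seed; with a fixed
#' config the outputs are byte-identical across reruns.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [simulation_config()] (used when no VCF is given, and for
#'   the seed).
#' @param thresholds A [filter_thresholds()].
#' @param vcf,ped,fasta Optional real input paths; when `vcf` is given,
#'   `ped` is required and simulation is skipped.
#' @param annotation Optional annotation TSV path (simulate mode fabricates
#'   one).
#' @param stages Character vector of stages to run.
#' @param keep_ledger Keep the full rejection ledger TSV.
#' @return The manifest (list), invisibly.
#' @export
run_pipeline <- function(out_dir, config = simulation_config(),
                         thresholds = filter_thresholds(),
                         vcf = NULL, ped = NULL, fasta = NULL,
                         annotation = NULL,
                         stages = c("simulate", "call", "rate", "spectrum",
                                    "validate", "annotate", "report"),
                         keep_ledger = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("trionovo")),
                   seed = config$seed, thresholds = unclass(thresholds),
                   inputs = list(), counts = list())
  truth <- NULL; panel <- NULL

  if (!is.null(vcf)) {
    if (is.null(ped)) .stopf("missing input: pedigree (PED) file is required")
    if (!file.exists(vcf)) .stopf("missing input file: %s", vcf)
    if (!file.exists(ped)) .stopf("missing input file: %s", ped)
    cohort <- read_cohort(vcf, ped)
    manifest$inputs <- list(vcf = unname(tools::md5sum(vcf)),
                            ped = unname(tools::md5sum(ped)))
    autosome_length <- if (!is.null(fasta))
      autosome_length_from_fasta(fasta) else NA_real_
    .stage_log("load", sprintf("%d sites, %d samples, %d records skipped",
                               nrow(cohort$sites), length(cohort$samples),
                               cohort$n_skipped))
  } else if ("simulate" %in% stages) {
    truth <- simulate_truth(config)
    cohort <- render_observations(truth, config)
    panel <- simulate_panel(truth, config)
    autosome_length <- config$genome_length
    write_truth(truth, file.path(out_dir, "truth.tsv"))
    write_cohort(cohort, file.path(out_dir, "cohort.vcf"),
                 contig_lengths = stats::setNames(config$genome_length,
                                                  config$contig))
    write_ped(truth$pedigree, file.path(out_dir, "cohort.ped"))
    write_tsv(panel, file.path(out_dir, "panel.tsv"))
    if (is.null(annotation)) {
      ann <- simulate_annotations(truth$variants)
      write_tsv(ann, file.path(out_dir, "annotation.tsv"))
      annotation <- file.path(out_dir, "annotation.tsv")
    }
    if (config$genome_length <= 1e7)
      write_reference_fasta(truth, file.path(out_dir, "reference.fa"), config)
    manifest$counts$planted_germline <- sum(truth$events$type == "germline_dnm")
    manifest$counts$planted_mosaic <- sum(truth$events$type == "mosaic")
    .stage_log("simulate", sprintf(
      "%d trios, %d variant sites (%d planted germline DNM, %d mosaic)",
      config$n_trios, nrow(cohort$sites),
      manifest$counts$planted_germline, manifest$counts$planted_mosaic))
  } else .stopf("no input: give a VCF/PED pair or include the simulate stage")

  manifest$counts$sites <- nrow(cohort$sites)
  manifest$counts$samples <- length(cohort$samples)
  calls <- NULL; rates <- NULL; spec_sum <- NULL

  if ("call" %in% stages) {
    calls <- call_candidates(cohort, thresholds, ledger = keep_ledger)
    write_tsv(calls$candidates, file.path(out_dir, "candidates.tsv"))
    if (keep_ledger && !is.null(calls$ledger))
      write_tsv(calls$ledger, file.path(out_dir, "ledger.tsv"))
    manifest$counts$candidates <- nrow(calls$candidates)
    .stage_log("call", sprintf("%d candidate DNM (AC cap %d)",
                               nrow(calls$candidates), calls$ac_cap))
  }

  if ("rate" %in% stages && !is.null(calls)) {
    cs <- callable_stats(cohort, thresholds)
    counts <- dnm_counts(calls)
    pt <- do.call(rbind, lapply(seq_len(nrow(counts)), function(k) {
      p <- cs$proportion[match(counts$trio_id[k], cs$trio_id)]
      per_trio_rate(counts$n_dnm[k], autosome_length, p,
                    trio_id = counts$trio_id[k])
    }))
    rates <- cohort_rate(pt)
    write_tsv(rbind(pt, rates$cohort), file.path(out_dir, "rates.tsv"))
    manifest$counts$callable_proportion <- round(mean(cs$proportion), 4)
    .stage_log("rate", sprintf("cohort rate %s (callable proportion %.3f)",
                               format_rate(rates$cohort$rate),
                               mean(cs$proportion)))
  }

  if ("spectrum" %in% stages && !is.null(calls) && nrow(calls$candidates)) {
    cand <- calls$candidates
    fa <- fasta %||% file.path(out_dir, "reference.fa")
    if (file.exists(fa)) {
      ctx <- contexts_for_variants(cand[, c("chrom", "pos", "ref", "alt")], fa)
    } else {
      ctx <- cbind(cand[, c("chrom", "pos", "ref", "alt")],
                   collapse_change(cand$ref, cand$alt))
    }
    spec_sum <- summarize_spectrum(ctx)
    write_tsv(data.frame(class = names(spec_sum$counts),
                         count = spec_sum$counts,
                         proportion = spec_sum$proportions,
                         row.names = NULL),
              file.path(out_dir, "spectrum.tsv"))
    if (!is.null(spec_sum$context_matrix))
      utils::write.table(spec_sum$context_matrix,
                         file.path(out_dir, "context_matrix.tsv"),
                         sep = "\t", quote = FALSE, col.names = NA)
    .stage_log("spectrum", sprintf("Ti/Tv %s over %d DNM",
                                   ifelse(is.na(spec_sum$titv_ratio), "undefined",
                                          sprintf("%.2f", spec_sum$titv_ratio)),
                                   spec_sum$n))
  }

  if ("validate" %in% stages && !is.null(panel) && nrow(panel)) {
    val <- classify_panel(panel)
    write_tsv(val, file.path(out_dir, "validation.tsv"))
    manifest$counts$validated_germline <- sum(val$class == "germline")
    manifest$counts$possible_somatic <- sum(val$class == "possible_somatic")
    .stage_log("validate", sprintf("%d germline, %d possible somatic of %d assayed",
                                   sum(val$class == "germline"),
                                   sum(val$class == "possible_somatic"),
                                   sum(val$class != "assay_failed")))
  }

  if ("annotate" %in% stages && !is.null(calls) && !is.null(annotation) &&
      file.exists(annotation) && nrow(calls$candidates)) {
    ann <- read_tsv(annotation)
    joined <- join_annotations(calls$candidates, ann)
    write_tsv(joined, file.path(out_dir, "annotated.tsv"))
    cons_sum <- summarize_by_consequence(joined)
    write_tsv(cons_sum$by_consequence, file.path(out_dir, "consequences.tsv"))
    manifest$counts$high_impact <- nrow(cons_sum$high_impact)
    .stage_log("annotate", sprintf("%d/%d DNM annotated, %d high-impact",
                                   nrow(joined) - attr(joined, "n_unmatched"),
                                   nrow(joined), nrow(cons_sum$high_impact)))
  }

  if ("report" %in% stages && !is.null(calls)) {
    tbl <- cohort_summary_table(nrow(calls$candidates),
                                nrow(calls$trios), rates, spec_sum)
    write_tsv(tbl, file.path(out_dir, "report.tsv"))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
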