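## Synthetic trio-cohort generator. Emulates the observable features of a
## ~30X short-read trio cohort: germline DNM planted at a per-site per-gamete
## rate (Poisson, 2 x length x rate per offspring), Mendelian background
## variation from Hardy-Weinberg founders, binomial read sampling with mild
## reference bias at heterozygous sites, low-fraction mosaic variants, a
## C>T-enriched spectrum with CpG enrichment, and GATK-style GQ/INFO fields.
## Every draw flows from the seed, so a truth ledger plus rendered cohort is
## exactly reproducible.

#' Configuration for the synthetic trio-cohort generator
#'
#' Defaults mirror the study conditions the package is designed around:
#' 46 trios with partially shared sires (creating half-sib probands), mean
#' depth 30X, heterozygous alt-read fraction centred at 0.475 (reference
#' bias 0.025), a per-site per-gamete mutation rate of 6.3e-9, and a
#' substitution spectrum with Ti/Tv 3.2, C>T/T>C 4.4 and 35% of C>T at CpG
#' sites. The genome is a single synthetic contig; its default length (1 Mb)
#' and background SNP density are scaled down from a real 2.6 Gb genome so a
#' rendered cohort stays small — rate estimation is corrected by length and
#' callable fraction, so estimates are scale-free.
#'
#' @param n_trios Number of trios.
#' @param n_sires Number of distinct sires shared round-robin across trios
#'   (default about two trios per three sires); dams are unique per trio.
#' @param genome_length Length of the synthetic contig in bases (>= 1000).
#' @param contig Contig name.
#' @param mu Per-site per-gamete germline DNM rate; each offspring receives
#'   Poisson(2 x genome_length x mu) mutations.
#' @param background_snp_density Segregating background SNPs per base.
#' @param depth_mean Mean sequencing depth.
#' @param depth_floor Lower truncation of the Poisson depth draw.
#' @param fixed_depth If `TRUE`, every call has exactly `depth_mean` reads.
#' @param seq_error_rate Per-read probability that a read at a homozygous
#'   site reports the specific alternative allele in the AD field (residual
#'   post-QC error, far below the raw base-error rate).
#' @param reference_bias Shift b such that the expected alt-read fraction at
#'   a true heterozygote is 0.5 - b (reference mapping bias).
#' @param spectrum_weights Named probabilities over the six collapsed
#'   classes; default derived from Ti/Tv = 3.2 and C>T/T>C = 4.4 with equal
#'   transversion classes.
#' @param cpg_fraction_ct Probability that a planted C>T sits in a CpG
#'   context.
#' @param mosaic_rate Expected low-fraction mosaic variants per offspring.
#' @param mosaic_fraction Expected alt-read fraction of mosaic variants.
#' @param info_fail_rate Per-site probability of injecting one failing INFO
#'   annotation (for exercising the site filters).
#' @param ranksum_missing_rate Per-site probability that each rank-sum
#'   annotation is absent, as in real VCFs.
#' @param panel_offspring Offspring of each proband genotyped by the
#'   follow-up panel.
#' @param panel_fail_rate Per-DNM probability that the panel assay fails.
#' @param seed Integer seed; all randomness flows from it.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_trios = 46L,
                              n_sires = NULL,
                              genome_length = 1e6,
                              contig = "chrS1",
                              mu = 6.3e-9,
                              background_snp_density = 2e-3,
                              depth_mean = 30,
                              depth_floor = 1L,
                              fixed_depth = FALSE,
                              seq_error_rate = 5e-6,
                              reference_bias = 0.025,
                              spectrum_weights = NULL,
                              cpg_fraction_ct = 0.35,
                              mosaic_rate = 0.25,
                              mosaic_fraction = 0.10,
                              info_fail_rate = 0,
                              ranksum_missing_rate = 0.2,
                              panel_offspring = 5L,
                              panel_fail_rate = 0.108,
                              seed = 1L) {
  if (genome_length < 1000) .stopf("genome_length must be >= 1000")
  if (n_trios < 1) .stopf("n_trios must be >= 1")
  for (p in c(mu = mu, background_snp_density = background_snp_density,
              seq_error_rate = seq_error_rate, cpg_fraction_ct = cpg_fraction_ct,
              mosaic_fraction = mosaic_fraction, info_fail_rate = info_fail_rate,
              ranksum_missing_rate = ranksum_missing_rate,
              panel_fail_rate = panel_fail_rate))
    if (p < 0 || p > 1) .stopf("rates and probabilities must lie in [0, 1]")
  if (reference_bias < 0 || reference_bias >= 0.5)
    .stopf("reference_bias must lie in [0, 0.5)")
  if (depth_mean <= 0 || mosaic_rate < 0) .stopf("invalid depth or mosaic rate")
  if (is.null(spectrum_weights)) spectrum_weights <- default_spectrum_weights()
  if (!setequal(names(spectrum_weights), .CLASSES) ||
      any(spectrum_weights < 0) || sum(spectrum_weights) <= 0)
    .stopf("spectrum_weights must be non-negative and named by the six classes")
  spectrum_weights <- spectrum_weights[.CLASSES] / sum(spectrum_weights)
  if (is.null(n_sires)) n_sires <- max(1L, ceiling(n_trios * 2 / 3))
  structure(list(n_trios = as.integer(n_trios), n_sires = as.integer(n_sires),
                 genome_length = genome_length, contig = contig, mu = mu,
                 background_snp_density = background_snp_density,
                 depth_mean = depth_mean, depth_floor = as.integer(depth_floor),
                 fixed_depth = fixed_depth, seq_error_rate = seq_error_rate,
                 reference_bias = reference_bias,
                 spectrum_weights = spectrum_weights,
                 cpg_fraction_ct = cpg_fraction_ct,
                 mosaic_rate = mosaic_rate, mosaic_fraction = mosaic_fraction,
                 info_fail_rate = info_fail_rate,
                 ranksum_missing_rate = ranksum_missing_rate,
                 panel_offspring = as.integer(panel_offspring),
                 panel_fail_rate = panel_fail_rate,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default six-class substitution weights
#'
#' Derived from a transition/transversion ratio of 3.2 with C>T/T>C = 4.4
#' and the four transversion classes weighted equally.
#'
#' @return Named probability vector over the six collapsed classes.
#' @export
default_spectrum_weights <- function() {
  titv <- 3.2; ct_over_tc <- 4.4
  ti <- titv / (1 + titv)
  ct <- ti * ct_over_tc / (1 + ct_over_tc)
  tc <- ti / (1 + ct_over_tc)
  tv_each <- (1 - ti) / 4
  c("C>A" = tv_each, "C>G" = tv_each, "C>T" = ct,
    "T>A" = tv_each, "T>C" = tc, "T>G" = tv_each)
}

## Unique positions in 2..(L-1), pairwise separated by >= 3 bases so that
## trinucleotide windows never overlap; returned in random order.
.draw_positions <- function(n_needed, L) {
  if (n_needed == 0) return(integer(0))
  picked <- integer(0)
  for (try in 1:50) {
    if (length(picked) >= n_needed) break
    cand <- sample.int(L - 2L, min(L - 2L, n_needed - length(picked) + 10L)) + 1L
    all_p <- sort(unique(c(picked, cand)))
    keep <- logical(length(all_p)); last <- -10
    for (i in seq_along(all_p)) {
      if (all_p[i] - last >= 3) { keep[i] <- TRUE; last <- all_p[i] }
    }
    picked <- all_p[keep]
  }
  if (length(picked) < n_needed)
    .stopf("genome_length %d too short for %d separated variant sites", L, n_needed)
  sample(picked, n_needed)
}

## Draw substitution classes and trinucleotide contexts from the spectrum
## model; returns ref/alt on a random strand plus the collapsed labels.
.draw_changes <- function(n, config) {
  if (n == 0)
    return(data.frame(ref = character(0), alt = character(0),
                      collapsed_class = character(0), context = character(0),
                      trimer = character(0), is_cpg = logical(0)))
  cls <- sample(.CLASSES, n, replace = TRUE, prob = config$spectrum_weights)
  center <- substr(cls, 1, 1)
  alt_pyr <- substr(cls, 3, 3)
  up <- sample(.BASES, n, replace = TRUE)
  down <- sample(.BASES, n, replace = TRUE)
  ## CpG enrichment for C>T; other C>* classes keep the uniform flank
  is_ct <- cls == "C>T"
  cpg_draw <- stats::runif(n) < config$cpg_fraction_ct
  down[is_ct & cpg_draw] <- "G"
  down[is_ct & !cpg_draw] <- sample(setdiff(.BASES, "G"),
                                    sum(is_ct & !cpg_draw), replace = TRUE)
  flip <- stats::runif(n) < 0.5
  ref <- ifelse(flip, unname(.COMP[center]), center)
  alt <- ifelse(flip, unname(.COMP[alt_pyr]), alt_pyr)
  trimer_pyr <- paste0(up, center, down)
  trimer <- ifelse(flip, .revcomp(trimer_pyr), trimer_pyr)
  data.frame(ref = ref, alt = alt, collapsed_class = cls,
             context = sprintf("%s[%s]%s", up, cls, down),
             trimer = trimer,
             is_cpg = startsWith(cls, "C") & down == "G",
             stringsAsFactors = FALSE)
}

#' Simulate the ground truth of a trio cohort
#'
#' Builds the pedigree, plants germline DNM (Poisson with mean
#' 2 x genome_length x mu per offspring, het in the offspring and hom-ref in
#' both parents), segregates background SNPs by Mendelian transmission from
#' Hardy-Weinberg founder genotypes, and optionally plants low-fraction
#' mosaic variants. Fully reproducible from `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A `dnm_truth` list: `config`, `pedigree`, `samples`, `variants`
#'   (site table with origin and trinucleotide context), `G` (true germline
#'   genotype matrix, sites x samples), and `events` — the truth ledger of
#'   planted germline/mosaic events (`chrom`, `pos`, `ref`, `alt`,
#'   `trio_id`, `sample_id`, `type`, `parent_of_origin`,
#'   `true_alt_fraction`, `collapsed_class`, `context`, `is_cpg`).
#' @export
simulate_truth <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config"))
    .stopf("config must come from simulation_config()")
  set.seed(config$seed)
  L <- config$genome_length

  ## pedigree: shared sires, unique dams
  sires <- sprintf("S%03d", seq_len(config$n_sires))
  dams <- sprintf("D%03d", seq_len(config$n_trios))
  probands <- sprintf("P%03d", seq_len(config$n_trios))
  sire_of <- rep(sires, length.out = config$n_trios)
  ped <- as_pedigree(data.frame(
    fam = "F1",
    id = c(sires, dams, probands),
    sire = c(rep(NA, length(sires) + length(dams)), sire_of),
    dam = c(rep(NA, length(sires) + length(dams)), dams),
    sex = c(rep("1", length(sires)), rep("2", length(dams)),
            sample(c("1", "2"), config$n_trios, replace = TRUE)),
    phenotype = "0", stringsAsFactors = FALSE))
  samples <- c(sires, dams, probands)
  n_samples <- length(samples)

  n_dnm <- stats::rpois(config$n_trios, 2 * L * config$mu)
  n_mosaic <- stats::rpois(config$n_trios, config$mosaic_rate)
  n_bg <- stats::rpois(1, config$background_snp_density * L)
  total <- sum(n_dnm) + sum(n_mosaic) + n_bg
  pos_all <- .draw_positions(total, L)

  take <- function(k) {
    if (k == 0L) return(integer(0))
    out <- pos_all[seq_len(k)]
    pos_all <<- pos_all[-seq_len(k)]
    out
  }
  dnm_pos <- take(sum(n_dnm))
  mosaic_pos <- take(sum(n_mosaic))
  bg_pos <- take(n_bg)

  dnm_ch <- .draw_changes(sum(n_dnm), config)
  mosaic_ch <- .draw_changes(sum(n_mosaic), config)
  events <- rbind(
    if (sum(n_dnm)) data.frame(
      chrom = config$contig, pos = dnm_pos,
      ref = dnm_ch$ref, alt = dnm_ch$alt,
      trio_id = rep(probands, n_dnm), sample_id = rep(probands, n_dnm),
      type = "germline_dnm",
      parent_of_origin = sample(c("sire", "dam"), sum(n_dnm), replace = TRUE),
      true_alt_fraction = 0.5 - config$reference_bias,
      collapsed_class = dnm_ch$collapsed_class, context = dnm_ch$context,
      trimer = dnm_ch$trimer, is_cpg = dnm_ch$is_cpg,
      stringsAsFactors = FALSE),
    if (sum(n_mosaic)) data.frame(
      chrom = config$contig, pos = mosaic_pos,
      ref = mosaic_ch$ref, alt = mosaic_ch$alt,
      trio_id = rep(probands, n_mosaic), sample_id = rep(probands, n_mosaic),
      type = "mosaic", parent_of_origin = NA_character_,
      true_alt_fraction = config$mosaic_fraction,
      collapsed_class = mosaic_ch$collapsed_class, context = mosaic_ch$context,
      trimer = mosaic_ch$trimer, is_cpg = mosaic_ch$is_cpg,
      stringsAsFactors = FALSE))
  if (is.null(events))
    events <- data.frame(chrom = character(0), pos = integer(0),
                         ref = character(0), alt = character(0),
                         trio_id = character(0), sample_id = character(0),
                         type = character(0), parent_of_origin = character(0),
                         true_alt_fraction = numeric(0),
                         collapsed_class = character(0), context = character(0),
                         trimer = character(0), is_cpg = logical(0))

  ## background: Hardy-Weinberg founders, Mendelian transmission to probands
  bg_ch <- .draw_changes(n_bg, config)
  bg_freq <- stats::runif(n_bg, 0.05, 0.5)
  n_founders <- length(sires) + length(dams)
  G_bg <- matrix(0L, nrow = n_bg, ncol = n_samples,
                 dimnames = list(NULL, samples))
  if (n_bg > 0) {
    G_bg[, seq_len(n_founders)] <-
      stats::rbinom(n_bg * n_founders, 2, rep(bg_freq, n_founders))
    for (k in seq_len(config$n_trios)) {
      from_sire <- stats::rbinom(n_bg, 1, G_bg[, sire_of[k]] / 2)
      from_dam <- stats::rbinom(n_bg, 1, G_bg[, dams[k]] / 2)
      G_bg[, probands[k]] <- from_sire + from_dam
    }
  }

  variants <- rbind(
    data.frame(chrom = rep(config$contig, nrow(events)), pos = events$pos,
               ref = events$ref, alt = events$alt, origin = events$type,
               trimer = events$trimer, stringsAsFactors = FALSE),
    data.frame(chrom = rep(config$contig, n_bg), pos = bg_pos,
               ref = bg_ch$ref, alt = bg_ch$alt,
               origin = rep("background", n_bg), trimer = bg_ch$trimer,
               stringsAsFactors = FALSE))
  G <- rbind(
    matrix(0L, nrow = nrow(events), ncol = n_samples,
           dimnames = list(NULL, samples)),
    G_bg)
  ## germline DNM are het in their proband only
  is_g <- events$type == "germline_dnm"
  if (any(is_g))
    G[cbind(which(is_g), match(events$sample_id[is_g], samples))] <- 1L

  ord <- order(variants$pos)
  variants <- variants[ord, , drop = FALSE]; rownames(variants) <- NULL
  G <- G[ord, , drop = FALSE]
  structure(list(config = config, pedigree = ped, samples = samples,
                 variants = variants, G = G,
                 events = events[order(events$pos), , drop = FALSE]),
            class = "dnm_truth")
}

## Genotype call + GQ from read counts via a binomial genotype likelihood
## (fixed nominal error 1e-3, flat prior, GQ capped at 99).
.call_genotypes <- function(alt, dp) {
  e <- 1e-3
  ll0 <- stats::dbinom(alt, dp, e, log = TRUE)
  ll1 <- stats::dbinom(alt, dp, 0.5, log = TRUE)
  ll2 <- stats::dbinom(alt, dp, 1 - e, log = TRUE)
  mx <- pmax(ll0, ll1, ll2)
  mid <- ll0 + ll1 + ll2 - mx - pmin(ll0, ll1, ll2)
  gt <- max.col(cbind(ll0, ll1, ll2), ties.method = "first") - 1L
  gq <- pmin(99, round((10 / log(10)) * (mx - mid)))
  gt[dp == 0] <- NA_integer_
  list(gt = gt, gq = gq)
}

#' Render sequencing observations for a simulated truth
#'
#' Draws per-sample depths (Poisson with floor, or fixed), samples alt reads
#' binomially with an allele fraction of `seq_error_rate` at homozygous
#' reference calls, `0.5 - reference_bias` at heterozygous calls,
#' `1 - seq_error_rate` at homozygous alternative calls and
#' `mosaic_fraction` at mosaic sites of the affected proband, then assigns
#' GT/GQ from a binomial genotype-likelihood rule and draws site INFO
#' annotations from pass-region distributions (with optional fail
#' injection). Uses a seed stream derived from `config$seed`, so
#' truth + rendering is reproducible end to end.
#'
#' @param truth A `dnm_truth` from [simulate_truth()].
#' @param config Normally `truth$config`.
#' @return A `dnm_cohort` with the truth's pedigree attached.
#' @export
render_observations <- function(truth, config = truth$config) {
  set.seed(config$seed + 1000003L)
  v <- truth$variants
  n <- nrow(v); m <- length(truth$samples)
  if (config$fixed_depth) {
    dp <- matrix(as.integer(round(config$depth_mean)), n, m)
  } else {
    dp <- matrix(pmax(stats::rpois(n * m, config$depth_mean),
                      config$depth_floor), n, m)
  }
  f <- matrix(config$seq_error_rate, n, m)
  f[truth$G == 1L] <- 0.5 - config$reference_bias
  f[truth$G == 2L] <- 1 - config$seq_error_rate
  mos <- truth$events[truth$events$type == "mosaic", , drop = FALSE]
  if (nrow(mos)) {
    ri <- match(mos$pos, v$pos)
    ci <- match(mos$sample_id, truth$samples)
    f[cbind(ri, ci)] <- config$mosaic_fraction
  }
  alt <- matrix(stats::rbinom(n * m, as.vector(dp), as.vector(f)), n, m)
  called <- .call_genotypes(as.vector(alt), as.vector(dp))
  gt <- matrix(called$gt, n, m, dimnames = list(NULL, truth$samples))
  gq <- matrix(called$gq, n, m, dimnames = list(NULL, truth$samples))
  dimnames(dp) <- dimnames(alt) <- dimnames(gt)
  ad_ref <- dp - alt

  qd <- pmin(pmax(stats::rnorm(n, 25, 5), 4.5), 40)
  fs <- stats::runif(n, 0, 10)
  mq <- stats::rnorm(n, 60, 2)
  ## rank sums stay inside the pass region (> -2 / > -8); failures enter
  ## only through explicit injection below
  mqrs <- pmax(stats::rnorm(n, 0, 0.8), -1.9)
  rprs <- pmax(stats::rnorm(n, 0, 0.8), -1.9)
  mqrs[stats::runif(n) < config$ranksum_missing_rate] <- NA
  rprs[stats::runif(n) < config$ranksum_missing_rate] <- NA
  if (config$info_fail_rate > 0 && n > 0) {
    inject <- which(stats::runif(n) < config$info_fail_rate)
    which_field <- sample(5, length(inject), replace = TRUE)
    qd[inject[which_field == 1]] <- 2
    fs[inject[which_field == 2]] <- 70
    mq[inject[which_field == 3]] <- 35
    mqrs[inject[which_field == 4]] <- -3
    rprs[inject[which_field == 5]] <- -9
  }
  sites <- data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
                      qd = round(qd, 2), fs = round(fs, 2), mq = round(mq, 2),
                      mq_rank_sum = round(mqrs, 3),
                      read_pos_rank_sum = round(rprs, 3),
                      allele_count = as.integer(rowSums(gt, na.rm = TRUE)),
                      stringsAsFactors = FALSE)
  new_cohort(sites, gt, ad_ref, alt, dp, gq,
             pedigree = truth$pedigree, n_skipped = 0L)
}

#' Simulate a full cohort (truth plus rendered observations)
#'
#' @param config A [simulation_config()].
#' @return List with `truth` (see [simulate_truth()]) and `cohort` (see
#'   [render_observations()]).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  truth <- simulate_truth(config)
  list(truth = truth, cohort = render_observations(truth, config))
}

#' Simulate follow-up panel genotyping of planted events
#'
#' For each planted germline/mosaic event, emits PlexSeq-style
#' presence/absence calls for the proband, its parents and
#' `config$panel_offspring` offspring of the proband. Whole-assay failures
#' occur at `config$panel_fail_rate`; a germline mutation transmits to each
#' offspring with probability 1/2 (neutral expectation), a mosaic one does
#' not transmit.
#'
#' @param truth A `dnm_truth`.
#' @param config Normally `truth$config`.
#' @return Panel data.frame (`dnm_id`, `individual_id`, `role`, `call`) with
#'   the per-event truth attached as attribute `event_type`.
#' @export
simulate_panel <- function(truth, config = truth$config) {
  ev <- truth$events
  tr <- trios(truth$pedigree)
  rows <- lapply(seq_len(nrow(ev)), function(i) {
    id <- sprintf("%s_%d", ev$chrom[i], ev$pos[i])
    p <- ev$sample_id[i]
    k <- config$panel_offspring
    failed <- stats::runif(1) < config$panel_fail_rate
    if (failed) {
      calls <- rep("failed", 3 + k)
    } else {
      off <- if (ev$type[i] == "germline_dnm")
        ifelse(stats::runif(k) < 0.5, "carrier", "non_carrier")
      else rep("non_carrier", k)
      calls <- c("carrier", "non_carrier", "non_carrier", off)
    }
    data.frame(dnm_id = id,
               individual_id = c(p, tr$sire[tr$proband == p],
                                 tr$dam[tr$proband == p],
                                 sprintf("%s_o%d", p, seq_len(k))),
               role = c("proband", "sire", "dam", rep("offspring", k)),
               call = calls, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(dnm_id = character(0), individual_id = character(0),
               role = character(0), call = character(0))
  attr(out, "event_type") <- stats::setNames(ev$type,
                                             sprintf("%s_%d", ev$chrom, ev$pos))
  out
}

#' Fabricate an annotation table for simulated variants
#'
#' Consequences are drawn from a configurable distribution (defaults: mostly
#' intronic and intergenic, a small coding fraction); pCADD scores are drawn
#' per consequence class (higher for missense/stop/splice), and SIFT labels
#' are attached to missense variants. Draws from the ambient RNG stream.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param consequence_weights Named probability vector over VEP terms.
#' @return Annotation data.frame (`chrom`, `pos`, `ref`, `alt`, `pcadd`,
#'   `consequence`, `sift`, `gene`).
#' @export
simulate_annotations <- function(variants,
                                 consequence_weights = c(
                                   intron_variant = 0.465,
                                   intergenic_variant = 0.485,
                                   upstream_gene_variant = 0.010,
                                   downstream_gene_variant = 0.010,
                                   missense_variant = 0.020,
                                   synonymous_variant = 0.005,
                                   splice_donor_variant = 0.0025,
                                   stop_gained = 0.0025)) {
  n <- nrow(variants)
  cons <- sample(names(consequence_weights), n, replace = TRUE,
                 prob = consequence_weights)
  pcadd <- numeric(n)
  high <- cons %in% c("missense_variant", "splice_donor_variant", "stop_gained")
  coding <- cons == "synonymous_variant"
  pcadd[high] <- pmax(stats::rnorm(sum(high), 20.6, 5), 0)
  pcadd[coding] <- pmax(stats::rnorm(sum(coding), 8, 3), 0)
  pcadd[!high & !coding] <- stats::rexp(sum(!high & !coding), rate = 1 / 3)
  sift <- rep(NA_character_, n)
  mis <- cons == "missense_variant"
  sift[mis] <- ifelse(stats::runif(sum(mis)) < 0.625, "deleterious", "tolerated")
  genic <- cons != "intergenic_variant"
  gene <- rep(NA_character_, n)
  gene[genic] <- sprintf("GENE%04d", sample.int(5000, sum(genic), replace = TRUE))
  data.frame(chrom = variants$chrom, pos = variants$pos, ref = variants$ref,
             alt = variants$alt, pcadd = round(pcadd, 2), consequence = cons,
             sift = sift, gene = gene, stringsAsFactors = FALSE)
}

#' Materialise the synthetic reference genome as FASTA
#'
#' Generates the random contig sequence from a seed stream derived from
#' `config$seed` and embeds each variant's trinucleotide context at its
#' position, so context extraction from the FASTA agrees with the truth
#' ledger.
#'
#' @param truth A `dnm_truth`.
#' @param path Output FASTA path.
#' @param config Normally `truth$config`.
#' @return The path, invisibly.
#' @export
write_reference_fasta <- function(truth, path, config = truth$config) {
  set.seed(config$seed + 2000003L)
  L <- as.integer(config$genome_length)
  seq_chars <- sample(.BASES, L, replace = TRUE)
  v <- truth$variants
  for (i in seq_len(nrow(v))) {
    tri <- strsplit(v$trimer[i], "", fixed = TRUE)[[1]]
    seq_chars[(v$pos[i] - 1L):(v$pos[i] + 1L)] <- tri
  }
  dna <- Biostrings::DNAStringSet(paste(seq_chars, collapse = ""))
  names(dna) <- config$contig
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' Write the truth ledger as TSV
#'
#' @param truth A `dnm_truth`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_truth <- function(truth, path) {
  write_tsv(truth$events, path)
}
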