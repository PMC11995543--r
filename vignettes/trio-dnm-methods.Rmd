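---
title: "Methods: trio-based de novo mutation calling, rate estimation and spectrum analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trio-based de novo mutation calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trionovo)
```

## The problem

A de novo mutation (DNM) is a variant present in an offspring's germline
but absent from both parents. Direct DNM detection from parent–offspring
trios yields the per-generation mutation rate — a fundamental quantity for
dating evolutionary events and for understanding how new variation enters
breeding populations — and a catalogue of fresh variants whose fitness
effects can then be studied. The signal is tiny (a handful of true events
per genome) against an enormous background of inherited variation and
sequencing artefacts, so the analysis is dominated by filtering, and every
filter choice trades sensitivity against false positives. `trionovo`
implements the full analysis as composable, tested functions, and pairs it
with a synthetic cohort generator so that each stage can be validated
against a known truth.

## Candidate calling model

A candidate DNM at a biallelic SNV site requires the Mendelian-violation
genotype configuration: proband heterozygous, both parents homozygous
reference. On top of that, `call_candidates()` applies three stages, each
returning machine-readable reason codes:

1. **Site quality** (`site_quality_pass()`). The site is excluded when
   `QD <= 4.0`, `FS >= 60.0`, `MQ <= 40`, `MQRankSum <= -2` or
   `ReadPosRankSum <= -8.0`, or when the minimum genotype quality over the
   three trio members is below 20 or any member's depth falls outside
   [10, 100]. Where quality descriptions of such cascades are ambiguous
   about strictness, we follow the executable exclusion-expression form
   (fail on equality for QD/MQ/rank sums, inclusive GQ/DP windows), because
   a command is unambiguous where prose is not. Rank-sum annotations are
   genuinely absent at sites lacking heterozygous reference-supporting
   reads; absence is represented as `NA` and never fails a filter —
   zero-filling would silently convert "unknown" into "pass/fail" at the
   threshold boundary.
2. **Trio genotype test** (`trio_genotype_test()`). The proband must carry
   the alternative allele on strictly more than 20% of reads. A true
   constitutional heterozygote has allele balance near 0.5; calls far below
   that are usually post-zygotic (mosaic) mutations confined to part of the
   body, or artefacts. Parents must have **zero** alternative-supporting
   reads (AD field): a single parental read is more plausibly an inherited
   allele or parental mosaicism than noise, and parental mosaicism means
   the variant is not de novo in the proband.
3. **Cohort uniqueness** (`population_screen()`). A genuine DNM is
   essentially private: the screen rejects sites whose cohort allele count
   reaches `max(4, ceiling(0.1% x n_samples))` or where any sample outside
   the proband's exemption set carries the allele (het/hom-alt call or
   at least one alt read). The exemption set contains the proband's sibs
   sharing at least one parent and the proband's own offspring: a parental
   germline-mosaic mutation can recur in a sib, and a true DNM transmits to
   offspring. We exempt full sibs together with half sibs — a full sib
   shares both parental germlines, so the mosaic-recurrence argument
   applies with at least equal force; the distinction only matters in
   pedigrees that contain full sibs at all, and the choice is logged by the
   reason codes either way. The trio's parents are deliberately *not*
   exempt: a parental alt read already fails stage 2, and the screen
   reports it independently (`population_carrier`), which makes the ledger
   self-explanatory.

The MIN/MAX GQ/DP semantics apply over the three trio members, not the
whole cohort: candidate validity is a trio property, and a cohort-wide
minimum over a hundred samples would discard nearly every site. The site
INFO fields are taken as given in the joint-called cohort VCF.

Every evaluated (site, proband) pair appears in the rejection ledger with
its reason codes; a pair is a candidate iff the reason set is empty. The
output order (chromosome, position, proband) is deterministic.

## Mutation-rate estimation

The per-site per-gamete rate for one trio is

$$\mu = \frac{n_\mathrm{DNM}}{2\,L\,p},$$

with `L` the autosome length (always read from the FASTA index, never
hard-coded) and `p` the callable proportion. The factor 2 converts the
diploid offspring genome into gametes: each offspring receives two gametes
in which mutation could have occurred; omitting it would double the
estimate. The callable proportion is a SNP-based proxy: the fraction of all
cohort SNP sites that pass the same filter cascade, computed per trio from
that trio's GQ/DP values together with the site-level INFO filters
(`callable_stats()`). This assumes filter pass rates at segregating SNPs
are representative of the genome at large — the standard assumption for
this correction. Cohort estimates pool numerators and denominators,
`sum(n) / sum(2 L p)`, which weights trios by their callable genome rather
than averaging ratios.

## Mutational spectrum

Base changes are collapsed to the six pyrimidine-centred classes (SBS
convention): a purine reference is reverse-complemented together with its
alternative and both flanking bases, so `G>A` in context `AGT` is reported
as `A[C>T]T`. Transitions are the collapsed classes C>T and T>C;
Ti/Tv is their count over the remaining four classes. A C-reference change
with downstream G is a CpG-site mutation — methylated CpG cytosines
spontaneously deaminate to thymine, which is why the C>T class is enriched
and why `summarize_spectrum()` reports the CpG fraction of C>T separately.
Ratios with zero denominators are reported as `NA` ("undefined"), never as
infinities or errors, so downstream tabulation stays total. Context
classification uses the ±1 window only; wider windows add nothing to the
six-class/96-context summaries.

## Validation and transmission

Follow-up panel genotyping yields presence/absence calls for the proband,
its parents, and up to nine of its offspring. `classify_validation()` maps
every configuration to exactly one class: transmission to at least one
offspring proves a germline mutation; a proband-only call with at least two
successfully genotyped, non-carrying offspring is *possibly somatic* (with
k genotyped offspring a germline mutation escapes detection with
probability 0.5^k, which is why a minimum of two is required before
claiming somatic status); a carrier parent means the variant was inherited
(not de novo) even when offspring carry it; a failed proband assay is
`assay_failed`; everything else — failed parents, too few offspring — is
`inconclusive` rather than silently forced into a class.
`trace_transmission()` numbers the proband as generation 1 and reports
carrier counts per pedigree generation; a mutation is "lost" at the first
generation from 2 onward whose genotyped descendants include no carrier —
so a proband without genotyped carrier descendants is lost at generation 2
— and "segregating" otherwise.

## Statistical tests

The three tests used for cohort comparisons are all two-sided:
`two_proportion_z_test()` is the pooled-variance z without continuity
correction (its square equals the uncorrected chi-square statistic);
`welch_t_test()` and `one_sample_t_test()` delegate to `stats::t.test`
behind validated interfaces. Two-sidedness and the pooled, uncorrected z
are the conventional defaults for such comparisons; the test suite
verifies all three against direct formula evaluation and checks their
type-I error at the 5% level by simulation. Degenerate inputs (zero pooled
standard error, zero variance, n < 2) yield an undefined result or a clear
error rather than a misleading p-value.

## The synthetic cohort generator

`simulate_truth()` + `render_observations()` emulate the observable
features of a high-coverage short-read trio cohort:

| parameter | default | rationale |
|---|---|---|
| `n_trios` | 46 | cohort size of the motivating study design |
| `n_sires` | ~2/3 of trios | shared sires create half-sib probands, exercising the exemption logic |
| `mu` | 6.3e-9 /site/gamete | headline germline SNV rate in pigs; each offspring gets Poisson(2·L·mu) mutations |
| `depth_mean` | 30 | ~30X design depth; Poisson-distributed with floor 1, or fixed |
| `reference_bias` | 0.025 | het alt-read fraction centred at 0.475, as observed for validated DNM (reference mapping bias) |
| `spectrum_weights` | from Ti/Tv 3.2, C>T/T>C 4.4 | transversion classes equal; `cpg_fraction_ct` = 0.35 |
| `seq_error_rate` | 5e-6 | per-read probability of an alt-supporting read at a hom-ref site *in the AD field*: raw base error (~1e-3) is spread over three alternative bases and mostly removed by base-quality filtering before AD counting, leaving a small residual |
| `genome_length` | 1 Mb | scaled down from a ~2.6 Gb genome: rate estimation divides by 2·L·p, so estimates are scale-free, and a rendered cohort stays small enough to test quickly |
| `background_snp_density` | 2e-3 /bp | scaled down with the genome (real cohorts run near 0.01/bp); background SNPs segregate from Hardy–Weinberg founders (allele frequency U(0.05, 0.5)) by Mendelian transmission |
| `mosaic_rate`, `mosaic_fraction` | 0.25 /offspring, 0.10 | a small admixture of post-zygotic variants at low allele fraction, matching the few-percent possible-somatic share among validated calls |

Reads are binomial given depth and the true allele fraction; genotypes and
GQ come from a binomial genotype likelihood with a fixed nominal error of
1e-3, flat prior, GQ capped at 99 — enough to exercise the GQ thresholds
without re-implementing a production caller. Site INFO fields are drawn
from pass-region distributions (QD ~ N(25,5) clipped to [4.5, 40], FS ~
U(0,10), MQ ~ N(60,2), rank sums ~ N(0,0.8) truncated above −1.9); filter
failures enter only through the explicit `info_fail_rate` injection, so
"zero noise in, perfect recovery out" holds exactly. Rank-sum annotations
go missing at a configurable rate, as in real VCFs. Variant positions are
kept at least 3 bp apart so trinucleotide windows never overlap, and
`write_reference_fasta()` embeds each variant's context into the generated
contig, making FASTA-based context extraction agree with the truth ledger.

All randomness flows from `config$seed`: `simulate_truth()` seeds the
stream directly, `render_observations()` and `write_reference_fasta()` use
fixed offsets of it, so a truth/cohort/reference triple is reproducible
from a single integer and the pipeline's outputs are byte-identical across
reruns.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: alignment and mapping artefacts beyond a uniform
allele-fraction shift, indels and multi-nucleotide variants, depth
correlation along the genome, batch effects between samples, linkage
disequilibrium among background SNPs, recombination, and selection. The
generator validates the *logic* of the pipeline; thresholds for real
cohorts still need the usual manual review of candidate alignments.

## Problem sizes used in the tests

The test suite and acceptance script run scaled studies chosen to give
tight statistical bounds at interactive runtimes: the rate-recovery checks
use 38 trios on a 50 Mb contig over 200 replicates (Monte-Carlo standard
error ~1.5% of the rate), estimator calibration uses 60 replicates of 20
trios on 10 Mb, sensitivity checks use 46 trios on 2 Mb with ~180 planted
events, and oracle-equivalence checks use ≤10 kb cohorts where a
brute-force re-evaluation of every rule is feasible. Statistical
assertions use 3–4 standard-error bounds derived from the binomial or
multinomial sampling model of the quantity under test.

## Known limitations

* The callable-proportion proxy inherits any ascertainment bias of the
  cohort SNP set; per-trio proportions require the cohort VCF, not a
  per-trio subset.
* `classify_panel()` treats any het/hom-alt panel call as "carrier"; assay
  allele-fraction information, if available, is not modelled.
* The population screen's "one alt read anywhere" rule is strict: in very
  large cohorts with appreciable residual error it will cost sensitivity,
  which is why the pipeline reports reason codes rather than silently
  dropping sites.
* Paternal-age effects and parent-of-origin phasing are out of scope; the
  truth ledger records a simulated parent-of-origin but the caller does
  not infer one.
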