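Package: trionovo
Title: Trio-Based De Novo Mutation Calling, Rate Estimation and Spectrum
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate single-nucleotide de novo mutations (DNM) in
    parent-offspring trios from a joint-called multi-sample VCF and a pedigree,
    applying a quality filter cascade (genotype quality, depth, site INFO
    annotations, allele balance, parental read support, cohort uniqueness with
    half-sib and offspring exemptions). Estimates per-site per-gamete germline
    mutation rates corrected by the callable fraction of the genome,
    characterises the mutational spectrum (six-class base changes,
    transition/transversion ratio, trinucleotide context, CpG deamination),
    classifies follow-up panel genotyping into germline and possible-somatic
    calls, traces transmission of mutations through multi-generation pedigrees,
    and joins external deleteriousness annotations. A seeded synthetic
    trio-cohort generator with a truth ledger makes every stage testable
    without access to restricted breeding-programme data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
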