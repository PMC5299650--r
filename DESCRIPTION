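Package: rmocomp
Title: Individualized Differential Methylation from Within-Sample
    Relative Methylation Orderings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects differentially methylated CpG sites in individual
    tumour samples by exploiting the within-sample relative ordering of
    beta values at pairs of CpG sites.  Orderings that are conserved in
    at least a threshold fraction of a normal reference cohort form a
    stable background; for one tumour profile, each CpG site is tested
    with Fisher's exact test for an excess of reversed orderings on the
    side supporting hyper- versus hypomethylation (the RankComp scheme).
    Also provides population-level differential methylation, reversal
    frequency testing of stable pairs across cohorts, cross-dataset
    concordance scoring under a cumulative binomial model, cohort
    summaries (precision against paired adjacent normals, recurrence
    frequencies, promoter-gene methylation status, per-sample pathway
    over-representation), and a synthetic beta-value cohort simulator
    with ground truth for benchmarking.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    fgsea
Config/testthat/edition: 3
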