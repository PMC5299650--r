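# rmocomp

Individualized differential-methylation calling from within-sample
relative methylation orderings.

## The problem

Cohort-level tests find CpG sites that are differentially methylated
(DM) between a set of tumours and a set of normals, but cancers are
heterogeneous: they cannot say *which patient* carries an aberration at
a given site. Absolute beta values also vary across healthy individuals,
laboratories and array platforms, so thresholding one tumour profile
against a normal average is fragile. What is conserved, to a remarkable
degree, is the *ordering* of beta values at pairs of CpG sites within a
single sample: if site A is less methylated than site B in essentially
every normal tissue sample, that relative methylation ordering (RMO) is
a property of the tissue. In tumours these stable orderings are widely
reversed, and the pattern of reversals betrays which sites moved.

`rmocomp` is for epigenomics analysts who have promoter-scale beta-value
matrices (e.g. the ~26k-site intersection of the Illumina 27K and 450K
arrays) and want per-patient hyper-/hypomethylation calls, plus the
cohort machinery around them: population-level DM detection,
reversal-pair testing, cross-dataset concordance scoring, recurrence
frequencies, promoter-gene status, pathway over-representation, and a
ground-truthed simulator for benchmarking.

## The statistic at its core

Fit a background on normal profiles: pair (i, j) is **stable** with
direction βᵢ < βⱼ (or >) if that strict ordering holds in at least θ
(default 0.99) of the pairwise-complete normal samples. For one tumour
profile, classify each stable pair as consistent or reversed. For a site
C with *a* stable pairs where C is the lower member (a₁ of them
reversed — evidence C moved **up**) and *b* pairs where C is the higher
member (b₁ reversed — evidence C moved **down**), test

    [ a1  a - a1 ]
    [ b1  b - b1 ]

with Fisher's exact two-sided test; under the null that C is unchanged,
reversals implicating it are its partners' noise and the two proportions
agree. BH-adjust within the sample, keep FDR < 0.01, and label the call
hyper if a₁/a > b₁/b, hypo otherwise. Concordance of two
direction-labelled lists is s/k over their k shared items with
significance from the upper binomial tail P(X ≥ s), X ~ Binomial(k, Pe),
Pe = 0.5.

## Worked example

```r
library(rmocomp)

cfg  <- sim_config(seed = 1)            # 500 sites, 80 normals, 30 tumours,
                                        # 10% aberrant sites, delta 0.3
norm <- simulate_normal_cohort(cfg)
bg   <- rmo_background(norm, theta = 0.99)
bg
#> Stable relative methylation-ordering background
#>   sites: 500   normal samples: 80   theta: 0.99
#>   stable pairs: 100782 of 124750 (80.8%)

tum <- simulate_tumor_cohort(cfg, norm)
pop <- ttest_dm(tum$beta, norm, fdr_threshold = 0.05)   # 52 sites
calls <- predict(bg, tum$beta, fdr_threshold = 0.01,
                 restrict_to = pop$site_id)
head(calls, 5)
#>   sample_id site_id direction             p           fdr
#> 1      T001 cg00478      hypo 8.210851e-124 3.941208e-122
#> 2      T001 cg00173     hyper 1.793088e-106 3.749631e-105
#> 3      T001 cg00119      hypo 2.343519e-106 3.749631e-105
#> 4      T001 cg00275      hypo 4.054340e-106 4.865208e-105
#> 5      T001 cg00123      hypo 7.493091e-104 7.193368e-103

recovery_metrics(calls, tum$truth)$pooled
#> $tp: 970   $n_calls: 1049   $n_truth: 1339
#> $precision: 0.925   $recall: 0.724
```

80.8% of all site pairs are stably ordered across the 80 normals.
Restricting per-sample calls to the 52 population-level DM sites (the
standard evaluation protocol — it anchors calls to cancer-associated
sites and narrows the BH universe), the caller recovers 970 of the 1,339
injected aberrations with direction-matched precision 92.5%. Recurrence
profiling then follows directly:

```r
freq <- aberration_frequency(calls, n_samples = 30, min_frequency = 0.9)
nrow(freq$recurrent)     # 21 sites aberrant in >90% of tumours
```

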