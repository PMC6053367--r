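# spliceage

Alternative splicing changes across adult life: the inclusion level of an
exon — its PSI, *percent spliced in*, a value in [0, 1] — can drift up or
down with donor age. `spliceage` is an R package plus analysis workflow
for detecting such age-associated splicing events in population RNA-seq
cohorts and exploiting them downstream: transcriptomic age clocks,
relative-age prediction for longitudinal samples, nomination of upstream
splicing-factor drivers, and quantification of splicing's independent
contribution to disease. It is aimed at computational biologists working
with SUPPA-style PSI matrices (tab-delimited, `-1` marking events whose
gene is not expressed in a sample) and matched phenotype tables.

## The model

For event *i* and donor *j*, usable samples are fitted by least squares to

    PSI_ij = a_i + b1_i * AGE_j + b2_i * GENDER_j + sum_k b_(k+2),i * CF_j^k + e_ij

with 20 hidden confounding factors `CF` (principal-component surrogates of
PEER factors) estimated from the PSI matrix and filtered of any factor
significantly correlated with age. Events need >= 50 usable samples to be
tested. Significance requires both BH FDR <= 0.05 across tested events
and a permutation check: fewer than 5% of 1000 age-shuffled refits may
reach the observed significance. The same scan runs on gene expression,
transcript expression and within-gene transcript ratios; cross-tissue
sharing is summarised by Jaccard indices; age clocks are LASSO models on
the top 30 MDS components of a profile under 100 rounds of randomised
10-fold cross-validation (accuracy = Spearman rho); drivers are splicing
factors whose IUPAC motifs are enriched (rank-sum, FDR <= 0.1) in one of
seven regions flanking trend-classified cassette exons *and* whose own
expression is age-associated; and the disease contribution is a
chi-square likelihood-ratio test between nested logistic models with and
without PSI components of the significant events.

Cohorts of this kind are access-controlled, so the package includes a
ground-truth synthetic generator (`sim_config()`, `simulate_*()`)
emulating bounded PSI with logit-linear age trends, batch-like hidden
factors, sentinel missingness, planted motif enrichment and disease
labels — every stage of the pipeline is tested against it.

## Worked example

The numbered scripts under `analysis/` run the whole study on the default
synthetic world (150 donors aged 20–70, 500 events, 10% truly
age-associated) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_scan_age_association.R
...
Rscript analysis/07_disease_llr.R
```

`02_scan_age_association.R` prints:

```
tested 500 of 500 events (>= 50 usable samples each)
hidden factors retained after age-correlation exclusion: 19 of 20
significant (q <= 0.05 and permutation check): 48 (24 up, 24 down with age)
against ground truth: recall 0.92, false discoveries 2 of 48 calls
```

48 events clear the dual criterion; against the generator's ground truth
that is 46 of the 50 planted events recovered with 2 false calls —
consistent with the 5% FDR target. `05_age_prediction.R` then builds the
clocks and the relative-age model:

```
splicing clock Spearman rho: 0.896
gene-expression clock Spearman rho: 0.825
old/young (age-extreme quartiles) classification accuracy: 1.00
robust age-associated events (>= 8/10 detection runs): 48
pairs with the older member ranked older: 9 of 10 (Wilcoxon over 100 rounds)
```

The splicing profile predicts age better than gene expression in this
world (signal was planted in splicing), 48 events survive ten repetitions
of the stochastic permutation check, and in ten simulated longitudinal
pairs taken 15 years apart the model ranks the older sample older in 9 of
10. `07_disease_llr.R` closes the chain:

```
LLR = 35.03 on 20 df, chi-square p = 0.0199
splicing adds significant disease information beyond age, gender and expression
```

A library-level entry point, `run_pipeline(pipeline_config(...), out_dir)`,
runs all stages in one call and writes a reproducibility manifest;
outputs are byte-identical under a fixed seed.

## Acceptance script

`scripts/acceptance.R` re-runs the complete pipeline from scratch against
the installed package under a given seed and writes a results JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Repository layout

    R/                  package code (generator, scans, clocks, drivers, LLR, IO)
    analysis/           numbered narrative drivers writing results/
    tests/testthat/     unit, property and acceptance suites
    scripts/            acceptance entry point
    vignettes/          methods vignette: models, defaults, design choices
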