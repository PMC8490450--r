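# hccsubtypes

Multi-omic molecular subtyping of hepatocellular carcinoma (HCC), as a
tested R package plus a numbered analysis workflow.

A minority of tumors diagnosed histologically as HCC carry the
transcriptional program of another liver lineage: **CCA-Like** tumors
resemble cholangiocarcinoma (CCA), and **Blast-Like** tumors resemble the
fetal hepatoblast progenitor. Both subclasses have distinct mutational
signatures and copy-number landscapes and a worse prognosis than classical
HCC. This package is for computational biologists who want to run, audit or
extend that subtyping analysis: every statistical step is an exported,
unit-tested function, and a synthetic multi-omic cohort generator plants the
exact structure the analysis assumes so the whole pipeline can be validated
against ground truth without any data download.

## The core procedure

Given a combined CCA/HCC log2 expression matrix, the classifier

1. filters to highly and variably expressed genes (expression floor, then
   top *n* by median absolute deviation),
2. median-centers each gene,
3. computes every sample's Spearman correlation ρ to the cohort CCA
   centroid (per-gene median of the CCA samples),
4. labels a tumor **CCA-Like** when ρ ≥ mean(ρ_CCA) − sd(ρ_CCA), the CCA
   class's own self-correlation band, and
5. labels remaining tumors **Blast-Like** when their correlation to a fetal
   hepatoblast reference centroid reaches the upper tertile of all non-CCA
   tumors; the rest stay **HCC**.

Around this sit the companion analyses: 96-trinucleotide-context motif
counting with pyrimidine strand collapse and de novo mutational-signature
extraction (multiplicative-update NMF, Frobenius loss) matched to a
reference catalog by cosine similarity; class-specific copy-number
comparison (class-mean tracks, per-gene Welch tests, segment-wise Fisher
exact tests under Benjamini–Hochberg control); a ClaNC-style 150-gene
nearest-centroid classifier for cross-cohort prediction; and five-year-
censored Kaplan–Meier / log-rank / Cox proportional-hazards survival
comparison (Efron ties, HCC referent).

## Worked example

```r
library(hccsubtypes)

co <- simulate_cohort(sim_config(seed = 42L, n_normal = 10L))
truth <- co$truth$true_class
asg <- assign_subtypes(co$expr, names(truth)[truth == "CCA"], co$centroids,
                       config = list(min_expr = 1, min_expr_fraction = 0.7,
                                     top_n_variable = 1000L),
                       normal_ids = names(truth)[truth == "Normal"])
table(truth = truth[asg$sample_id], predicted = asg$label)
```

On this seed the pipeline prints a clean diagonal — every planted label
recovered:

```
            predicted
truth        Blast-Like CCA CCA-Like HCC Normal
  Blast-Like         40   0        0   0      0
  CCA                 0  40        0   0      0
  CCA-Like            0   0       40   0      0
  HCC                 0   0        0  40      0
  Normal              0   0        0   0     10
```

with classification threshold 0.3793 (the CCA band's mean − 1 SD) and
hepatoblast tertile cutoff 0.1004. Downstream, the same cohort yields the
planted class pattern: BAP1 copy-number loss in 80% of CCA, 42.5% of
CCA-Like and 12.5% of HCC samples; the de novo signatures match their
planted generators at cosine ≥ 0.999, with mismatch-repair-like exposure
dominating CCA/CCA-Like; TP53 p.R249S carriers sit significantly closer to
the aflatoxin-like catalog signature (t = 14.5, p ≈ 9e−15); and the
five-year-censored Cox model gives Blast-Like a hazard ratio of ≈3.4–4.4
versus HCC (planted: 3.72).

The full workflow is the numbered scripts:

```sh
Rscript analysis/01_simulate_cohort.R        # writes results/cohort/
Rscript analysis/02_classify_subtypes.R      # subtype assignments
Rscript analysis/03_expression_scores.R      # module scores, DE, enrichment
Rscript analysis/04_mutational_signatures.R  # motifs, NMF, catalog matching
Rscript analysis/05_copy_number.R            # CN tracks, segment tests
Rscript analysis/06_classifier_validation.R  # ClaNC train + transfer
Rscript analysis/07_survival.R               # KM, log-rank, Cox
```

Each script narrates what it found and writes its tables under `results/`.

## Layout

```
R/                 package code: io, simulation, classification, scores,
                   signatures, copy number, classifier, survival
analysis/          numbered workflow drivers (thin wrappers over R/)
scripts/           acceptance.R
tests/testthat/    unit, property and acceptance tests with brute-force oracles
vignettes/         methods vignette: models, assumptions, numerical choices
```
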