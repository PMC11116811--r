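# ffpecms

Consensus molecular subtype (CMS) classification of colorectal-cancer
expression profiles derived from degraded, formalin-fixed paraffin-embedded
(FFPE) RNA — for bioinformaticians and translational researchers who need
CMS1–4 calls on archival clinical material where classifiers built on
fresh-frozen (FF) data break down.

## What it does

FFPE RNA is fragmented, and the loss is not uniform: immune-pathway
transcripts (the CMS1 markers) degrade far more than epithelial or stromal
ones. `ffpecms` implements a pipeline built around two defenses:

1. **Transcript integrity scoring and gene selection.** For per-base read
   coverage c₁…c_k sampled along a transcript, with pᵢ = cᵢ/Σcⱼ and entropy
   H = −Σ pᵢ ln pᵢ, the transcript integrity number is

       TIN = 100 · e^H / k  ∈ [0, 100],

   the effective percentage of the transcript with uniform coverage.
   Candidate signature genes are kept only if their median TIN across a
   degraded reference cohort is **strictly greater than 20**.

2. **Binary gene-pair features on cohort-internal z-scores.** Expression is
   log2(x+1)-transformed, z-normalized per gene within each cohort, and
   encoded as indicators 1[z_a > z_b] for every ordered gene pair a < b
   (m(m−1)/2 features for m genes; ties encode 0). The encoding is
   bit-identical under any per-gene increasing affine transform, which is
   what lets one model serve RNA-seq TPM, microarray, and degraded
   libraries.

A 500-tree random forest (mtry = ⌊√P⌋) on these features returns, per
sample, a CMS1–4 call plus the exact fraction of trees voting each class.
Evaluation utilities provide accuracy against a benchmark labeling, 4×4
contingency tables, one-vs-rest sensitivity/specificity, and one-sided
exact binomial concordance tests (null p₀ = 0.25 by default). A synthetic
paired FF/FFPE cohort simulator with planted subtypes, module-specific
degradation, matched TIN tables, and library dropout makes the whole
pipeline testable offline.

## Worked example

```r
library(ffpecms)

cohort <- simulate_cohort(sim_config(n_samples = 120, seed = 11))
train_ids <- cohort$true_labels$sample_id[1:60]
test_ids  <- cohort$true_labels$sample_id[61:120]
cols <- function(x, ids) x[, c(names(x)[1], ids)]

# degradation-aware gene selection on the training half's TIN table
fs <- select_feature_genes(candidate_genes(cohort), cols(cohort$tin, train_ids))
#> <feature_gene_set> 128 of 200 candidates with median TIN > 20

# train on fresh-frozen pair features, classify the degraded FFPE half
feats <- pair_features(cols(cohort$ff_expr, train_ids), fs)
model <- cms_train(feats, cohort$true_labels[1:60, ], seed = 11)
glance(model)
#>   n_train n_genes n_pairs n_trees  mtry oob_accuracy
#> 1      60     128    8128     500    90        0.917

calls <- predict(model, pair_features(cols(cohort$ffpe_expr, test_ids), fs))
head(calls, 3)
#>   sample_id cms   p_CMS1 p_CMS2 p_CMS3 p_CMS4
#> 1 S0061     CMS2   0.118  0.756  0.086  0.04
#> 2 S0062     CMS2   0.274  0.286  0.284  0.156
#> 3 S0063     CMS2   0.118  0.658  0.108  0.116

cms_evaluate(calls, cohort$true_labels)
#> accuracy: 81.7% (49/60 concordant; null p0 = 0.25, exact binomial P = 4.93e-20)
#>          benchmark
#> predicted CMS1 CMS2 CMS3 CMS4
#>      CMS1    0    0    0    0
#>      CMS2    2   25    8    1
#>      CMS3    0    0    3    0
#>      CMS4    0    0    0   21
```

The probability vector is the model's confidence: S0061 is a clear CMS2
(76% of trees), S0062 is a mixed-looking sample called CMS2 on a narrow
margin. On this small degraded test half, 49 of 60 calls match the planted
truth (81.7%), far beyond the 25% chance level (exact binomial P ≈ 5e-20);
misclassifications concentrate in the degraded immune (CMS1) and the
metabolic (CMS3) subtypes, mirroring what degradation does to real
archival cohorts.

The same stages are available from the shell via
`Rscript inst/cli/ffpecms.R <simulate|tin|select-genes|train|classify|evaluate>`,
reading and writing plain TSV artifacts with JSON run manifests.

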