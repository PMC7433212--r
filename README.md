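# pancanSig

Pan-cancer identification of putative loss- and gain-of-function pathway
genes from copy number plus expression, with pathway scoring and
survival evaluation.

## The problem

Large pan-cancer programs provide, for each cancer type, a gene-level
thresholded copy-number matrix (GISTIC calls in {−2, −1, 0, +1, +2}), a
tumor/non-tumor expression matrix, and clinical follow-up.  A recurring
analysis pattern asks: *which genes of a pathway are both recurrently
copy-number altered and concordantly differentially expressed across many
cancer types, and does their joint expression carry prognostic
information?*  pancanSig implements that pattern as a tested, reusable
pipeline for computational oncologists: the alteration taxonomy and
recurrence filter, differential expression, the LoF/GoF intersection
call, pathway scoring, and the survival, ordination and enrichment
statistics — plus a synthetic multi-cancer cohort generator with planted
ground truth, so every stage is verifiable without any data download.

## The model

* **Recurrence filter.** Gene *g* is recurrently deleted iff
  `frac_del(g, c) ≥ 0.20` in at least `⌈K/3⌉` of the K cancer types
  (7 of 21), where `frac_del` counts shallow (−1) and deep (−2) calls
  over evaluable tumors; amplification mirrors this for +1/+2.
* **LoF/GoF call.** LoF = recurrently deleted ∩ recurrently
  downregulated (Wilcoxon rank-sum tumor vs non-tumor, BH `q ≤ 0.05`,
  in ≥ ⌈K/3⌉ cancers); GoF = amplified ∩ upregulated.  Genes qualifying
  for both are excluded from both and reported as conflicts.
* **Pathway score.** For sample *j* and gene set *S*,
  `score_j = mean_{g∈S} x_gj` on log2 expression, or the signed sum
  `Σ_g sign_g · x_gj` for composite pathways (the packaged
  mTOR/PI3K/AKT score is `AKT + mTOR + GSK3 + S6K + S6 − PTEN`).
* **Survival.** Kaplan–Meier product-limit curves; Mantel–Haenszel
  log-rank; Cox proportional hazards maximized by Newton–Raphson with
  Efron tie handling, Wald `HR = exp(β)` with 95% CI
  `exp(β ± 1.96·SE)`; time-dependent ROC/AUC at a fixed horizon using
  cumulative cases and dynamic controls with Kaplan–Meier censoring
  weights; Spearman correlation of mid-ranks.
* **Ordination.** Principal coordinates (classical MDS, Gower
  double-centering) on Euclidean distances over the signature genes, and
  one-factor PERMANOVA with permutation p
  `(1 + #{F* ≥ F}) / (1 + n_perm)`.
* **Enrichment.** Upper-tail hypergeometric over-representation of DEG
  lists against GMT libraries, BH-corrected within each library.

The packaged gene lists are the 24-gene AMPK loss-of-function set, the
18-gene PPAR set, and the 6-term signed mTOR composite.

## Worked example

```r
library(pancanSig)

spec <- cohortSpec(n_cancers = 6, tumors_per_cancer = 30,
                   normals_per_cancer = 8, n_genes = 100,
                   planted_lof = sprintf("G%04d", 1:5),
                   planted_gof = sprintf("G%04d", 6:8),
                   n_cancers_affected = 4, seed = 20)
cohort <- generateCohort(spec)

fr  <- alterationFractions(cnv(cohort))
del <- recurrentGenes(fr, "deletion")
amp <- recurrentGenes(fr, "amplification")
de  <- deTestPerCancer(expr(cohort))
rde <- recurrentDeGenes(de)
(call <- callPutativeLofGof(del, amp,
                            rde[rde$direction == "down", ],
                            rde[rde$direction == "up", ]))
#> GeneSetCall
#>   putative LoF (5): G0001, G0002, G0003, G0004, G0005
#>   putative GoF (3): G0006, G0007, G0008
```

All five planted loss-of-function genes and all three gain-of-function
genes are recovered, with no false calls.  Scoring patients on the
derived LoF set and fitting the survival models:

```r
score <- meanExpressionScore(expr(cohort),
                             scoreSpec("derived_LoF", lofGenes(call)))
clin  <- clinical(cohort)
coxFit(clin$time, clin$event,
       matrix(score[clin$sample], ncol = 1,
              dimnames = list(NULL, "score")))
#> Cox proportional-hazards fit (Efron ties): n = 180, events = 124
#>    term   coef    hr     se ciLower ciUpper    waldP
#> 1 score 0.5057 1.658 0.1947   1.132   2.429 0.009407

strata <- stratifyByQuantile(score, 4)
eq  <- extremeQuartiles(strata)
sub <- clin[clin$sample %in% c(eq$low, eq$high), ]
logrankTest(sub$time, sub$event,
            ifelse(sub$sample %in% eq$high, "Q4", "Q1"))
#> Log-rank test: chisq = 9.4531, df = 1, p = 0.002108
#>   group observed expected
#> 1    Q1       28    39.68
#> 2    Q4       36    24.32
```

The cohort was generated with a positive log-hazard coefficient on the
planted score (`beta = log 2`), so high-scoring patients die faster: the
Cox hazard ratio per score unit is above 1 and the fourth quartile shows
more deaths than expected (36 observed vs 24.3).  The estimate (1.66) is
attenuated relative to `exp(beta)` because the univariate model omits
the simulated stage effect.

A YAML-configured end-to-end run (all stages, TSV/JSON artifacts, hash
manifest) is available as `runFullPipeline(config, outDir)`, or from the
shell via `inst/scripts/run_pipeline.R`.

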