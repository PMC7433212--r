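---
title: "Pan-cancer pathway signatures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pan-cancer pathway signatures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pancanSig)
```

# The analysis in one paragraph

pancanSig implements a pan-cancer screen for pathway genes whose somatic
copy-number changes are accompanied by concordant expression changes.  A
gene is a *putative loss-of-function* (LoF) candidate when it is
recurrently deleted — altered in at least 20% of tumors within a cancer
type, in at least one third of the cancer types studied — **and**
recurrently downregulated in tumor versus non-tumor comparisons across the
same minimum number of cancer types; *gain-of-function* (GoF) candidates
mirror this with amplification and upregulation.  The derived gene set is
then summarized per patient as a pathway score (the arithmetic mean of
log2 expression over the set, or a signed sum for composite pathways),
and the score's clinical relevance is evaluated with quartile and
joint-median stratification, Kaplan–Meier curves, log-rank tests, Cox
proportional-hazards regression, time-dependent ROC analysis at a fixed
horizon, principal-coordinates ordination with PERMANOVA, and
hypergeometric over-representation analysis of stratum-specific
differentially expressed genes.

# The recurrence filter

For each gene and cancer type we compute the fraction of evaluable tumors
carrying a deletion (GISTIC thresholded value −1 or −2) or an
amplification (+1 or +2).  Shallow (±1, heterozygous) and deep (±2,
homozygous) events are tallied separately but are **combined** for the
recurrence rule: the published filter text does not separate them and its
per-cancer stacked summaries display both classes together, so the
combined fraction is the default, with per-class fractions always
reported and a `combineShallowDeep = FALSE` switch for the deep-only
variant.  Both comparisons in the rule — the 20% sample fraction and the
minimum cancer-type count — are inclusive (`>=`), as "at least" demands;
with 21 cancer types the default minimum is `ceiling(21 / 3) = 7`.  NA
calls are removed from both numerator and denominator, making every
fraction a fraction of evaluable samples.

# Differential expression

The design compares tumor with non-tumor samples within each cancer type.
The test is the two-sided Wilcoxon rank-sum test on log2 expression
(configurable to Welch's *t*): rank-based inference is robust to the
unknown upstream normalization of public expression matrices, which is
the realistic situation for GISTIC-era cohorts.  `stats::wilcox.test`
supplies the machinery (exact enumeration for small untied groups, the
mid-rank normal approximation with continuity correction otherwise).
Significance is Benjamini–Hochberg `q <= 0.05` across genes *within* each
cancer, with no fold-change floor; the effect size reported is the
difference of group means on the log2 scale.  Cancers with fewer than
three tumors or three non-tumors are skipped with a warning rather than
failing the run — sparse non-tumor arms are a fact of real cohorts (one
of the studied sarcoma datasets had only two).  The same two-group
machinery drives the Q4-versus-Q1 contrast used for enrichment input.

# Pathway scores and stratification

Mean-expression scores require, by default, every gene of the list to be
present (`minCoverage = 1`, relaxable to e.g. 0.8 for ragged matrices);
signed composite scores never relax coverage because a signed sum with a
missing term silently changes meaning.  Scores are computed on tumor
samples only, except when feeding ordination where non-tumor samples are
deliberately included.  The shipped lists are the 24-gene AMPK LoF set,
the 18-gene PPAR set, and the six-term signed mTOR/PI3K/AKT composite.
The mTOR list names pathway members at the protein level; the packaged
fixture maps each to a single canonical gene symbol (AKT1, MTOR, GSK3B,
RPS6KB1, RPS6, PTEN with a −1 sign) and the mapping is documented as an
interpretation, since paralogs (AKT2/3, GSK3A, RPS6KB2) exist.

Quartile stratification uses the linear-interpolation quantile definition
(`stats::quantile`, type 7); a sample lying exactly on a cutoff goes to
the **lower** bin, a deterministic tie rule chosen once and exposed in
the returned cutoffs.  Joint stratification dichotomizes two scores at
their medians with "high" meaning strictly above the median; the four
quadrant labels are `low-low`, `low-high`, `high-low`, `high-high`.

Genes qualifying for both the LoF and the GoF call are excluded from both
sets and listed separately as conflicts, with a warning.  This turns the
observed mutual exclusivity of the two sets into an enforced invariant
rather than an assumption that could fail silently.

# Survival machinery

Kaplan–Meier, log-rank, Cox regression, time-dependent ROC and Spearman
correlation are implemented in the package itself (the `survival`
package, `cmdscale`, `cor.test` and `vegan::adonis2` appear only as
independent oracles in the test suite).  Choices that were genuinely
open:

* **Ties in Cox regression** use the Efron approximation — more accurate
  than Breslow at the heavy tie loads produced by day-granularity
  follow-up, at no extra asymptotic cost.  Newton–Raphson with step
  halving maximizes the partial likelihood; convergence is declared on a
  relative log-likelihood change below `1e-9` within 25 iterations.
  Non-convergence and monotone-likelihood fits (|coef| > 15, the
  separation signature) are flagged with warnings, never returned
  silently.  Zero-variance and collinear covariates are rejected up
  front.
* **Inference** is Wald: `p` from the normal approximation and 95%
  confidence intervals `exp(coef ± 1.96·SE)`, matching the reporting
  style the pipeline's outputs imitate.
* **Time-dependent ROC** uses the cumulative-case/dynamic-control
  definition with Kaplan–Meier inverse-probability-of-censoring weights:
  cases (events by the horizon) weighted by `1/G(T−)`, controls (followed
  beyond the horizon) by `1/G(horizon)`.  This estimator reduces exactly
  to the Mann–Whitney AUC when no censoring precedes the horizon, which
  is the property the tests pin to machine precision.  AUC may fall in
  [0, 1]; a marker oriented protectively is reported with an orientation
  flag, never silently flipped.
* **Spearman correlation** is the Pearson correlation of mid-ranks, with
  an exact permutation p for n ≤ 9 and the t-approximation above that.

# Ordination and PERMANOVA

Distances are Euclidean on the signature genes, without standardization
by default (z-scoring is a switch) — the upstream publication names no
metric, so the simplest choice is the default and is stated rather than
guessed at run time.  PCoA performs Gower double-centering of −d²/2 and
an eigendecomposition; negative eigenvalues are reported and their axes
dropped, with no Cailliez/Lingoes correction applied silently.
PERMANOVA partitions distance-based sums of squares (total = Σd²/n over
pairs, within-group analogously) into a pseudo-F; the permutation p is
`(1 + #{F* ≥ F}) / (1 + nPerm)` under label shuffling with a mandatory
seed, and an `exhaustive = TRUE` mode enumerates all distinct label
arrangements for small groups, where the permutation p becomes exact.

# Enrichment

Web enrichment services are version-dependent and unusable offline, so
over-representation analysis is a transparent upper-tail hypergeometric
test over user-supplied GMT libraries: `p = P(X ≥ k)` for overlap k, with
BH correction across the terms of one library (not across libraries).
The universe defaults to the genes of the expression matrix, not the
library.  Cross-cancer transcription-factor target logic intersects each
TF's per-cancer target sets and then unions the per-TF common targets
with each gene counted once.

# The synthetic cohort generator

The generator is first-class, tested code, and its defaults are the
study conditions used throughout the acceptance checks: 21 cancer types,
40 tumors and 10 non-tumors each, 300 genes, ten planted LoF genes
deleted with probability 0.5 in 10 of the 21 cancers with a −2 log2
expression shift, a mirrored five-gene GoF set, residual noise SD 0.7,
and a 2% background alteration rate.  Values the source design leaves
open were fixed once at field-realistic levels: 30% of alteration calls
deep, 30% censoring, baseline hazard 0.1 per time unit, four stage
levels with hazard multipliers 1/1.2/1.5/2.

Survival is exponential proportional hazards: the log hazard is
`beta·(score − mean score) + log(stage multiplier)`, with score the mean
expression of the planted LoF genes over tumors.  Centering makes
`baseline_hazard` interpretable as the event rate of an average-score,
reference-stage patient.  Censoring is an independent uniform time on
`[0, c]`, with `c` solved by root-finding from the closed form
`P(C < T) = mean((1 − exp(−λᵢc))/(λᵢc))` so the requested censoring
fraction is hit in expectation — the closed form is the reason an
exponential baseline was chosen.  Expression is simulated directly on
the log2 scale with additive shifts (the upstream normalization being
unstated, the generator is explicit about this assumption).  Three
derived RNG sub-streams (copy number, expression, clinical) keep the
draw blocks independent, so enlarging the gene panel does not reshuffle
survival times.

What the generator does **not** emulate: segment-level correlation of
copy-number calls along chromosomes (noise calls are independent per
gene and sample), count-level RNA-seq properties, batch effects, and
non-proportional hazards.  Passing tests therefore demonstrate that the
pipeline's logic and statistics behave correctly under its stated
assumptions — not that those assumptions hold in any particular real
cohort.

# Problem sizes in the checks

The repeated-simulation checks use: 20 cohorts at the default design for
planted-signature recovery; 200 replicates of n = 1000 patients for Cox
hazard-ratio recovery (mean estimated HR within [1.8, 2.2] of a true 2.0
and 90–98% empirical CI coverage); 2000 null replicates of n = 100 for
log-rank size; 500 null replicates (199 permutations each) for PERMANOVA
calibration; and n = 2000 for the null time-dependent AUC.  These sizes
give Monte-Carlo standard errors comfortably below the tolerances being
asserted while keeping a full run in minutes on a single core.

# Known limitations

* The recurrence filter ignores GISTIC's own significance model
  (q-values) and the focal/arm-level distinction; it is a counting rule.
* The Wilcoxon DE test has no paired or covariate-adjusted mode.
* Cox fitting covers fixed covariates only — no time-varying effects,
  stratified baselines, frailty, or competing risks.
* PERMANOVA is single-factor with unrestricted permutations.
* The reference group for quadrant-wise Cox comparisons is a required
  analysis choice, not a package default: results depend on it, and no
  convention is imposed.
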