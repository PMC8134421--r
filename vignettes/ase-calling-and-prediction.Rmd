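---
title: "Calling and predicting allele-specific expression: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and predicting allele-specific expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asepred)
```

This vignette documents the statistical models behind `asepred`, the
parameters that matter, the choices made where the design was genuinely
open, and what the synthetic-data tests do and do not demonstrate about
real cohorts.

## The beta-binomial model for allelic counts

At a heterozygous single-nucleotide variant, a diploid individual's RNA
reads split between the two alleles. With $n_i$ total and $k_i$
alternative-allele reads for individual $i$, a binomial model
$k_i \sim \mathrm{Bin}(n_i, \pi)$ is too narrow: biological and technical
variation between individuals overdisperses the counts. We therefore let
the per-individual success probability itself be beta-distributed, giving
the beta-binomial

$$\Pr(k \mid n, \pi, \rho) = \binom{n}{k}
  \frac{B(k + \alpha,\; n - k + \beta)}{B(\alpha, \beta)},
  \qquad \alpha = \pi\frac{1-\rho}{\rho},\;
         \beta = (1-\pi)\frac{1-\rho}{\rho},$$

parameterized directly by the mean alternative fraction $\pi \in (0,1)$
and the overdispersion $\rho \in (0,1)$, so that
$\mathrm{E}[k/n] = \pi$ and
$\mathrm{Var}[k] = n\pi(1-\pi)\,(1 + (n-1)\rho)$. This parameterization
was chosen because balanced expression is then the single constraint
$\pi = 0.5$, and $\rho \to 0$ recovers the binomial. All likelihood
arithmetic goes through log-gamma functions, so depths in the thousands
are numerically safe.

### The likelihood-ratio test

Per locus, all individuals' counts are aggregated into one likelihood.
Two fits are compared:

* **null**: $\pi$ fixed at $0.5$, $\rho$ free — balanced expression with
  arbitrary inter-individual variability;
* **alternative**: $\pi$ and $\rho$ both free.

The statistic $\Lambda = \max\{0,\, 2(\hat\ell_1 - \hat\ell_0)\}$ is
referred to $\chi^2_1$ (one constrained parameter). Keeping $\rho$ free in
*both* models is deliberate: it prevents overdispersion alone from
masquerading as allelic imbalance. The max-with-zero clip absorbs the tiny
negative differences a bounded numerical optimizer can produce when the
null is effectively true.

Numerical details that matter:

* Parameters are bounded to $[10^{-6}, 1-10^{-6}]$.
* The 1-parameter null fit uses Brent search (`optimize`), which cannot
  fail to converge.
* The 2-parameter fit uses bounded quasi-Newton (L-BFGS-B) from a
  moment-based start (pooled $k/n$ for $\pi$; the chi-square inflation
  estimator mapped through $1 + (\bar n - 1)\rho$ for $\rho$), plus two
  *fixed* fallback starts and, if the optimizer still reports failure, a
  derivative-free Nelder–Mead polish on the logit scale. All starts are
  deterministic: fitting never consumes the global random-number stream,
  which keeps whole-pipeline outputs checksum-reproducible. Random
  restarts were considered and rejected for exactly that reason.
* A locus whose fits do not converge gets `p_value = NA` and is excluded
  from FDR adjustment rather than silently contributing a wrong value.

Cohort-level calling (`call_ase`) tests only loci observed in at least 5
individuals (configurable), adjusts p-values once per cohort with
Benjamini–Hochberg, and flags ASE at FDR < 0.05. Overdispersion is fitted
per locus; a cohort-shared $\rho$ was considered and not implemented,
because it requires a joint optimization over all loci and conflates
between-locus heterogeneity with within-locus dispersion — the per-locus
fit is the more conservative default and keeps loci independent.
Reference/alternative orientation does not affect the test: the likelihood
is symmetric under $(k, \pi) \to (n-k, 1-\pi)$.

## The synthetic cohort generator

The generator exists so that every downstream stage has a test surface
with known ground truth; it emulates the structure of a cohort of
heterozygous exonic loci, not any particular dataset. Defaults, and why:

| parameter | default | rationale |
|---|---|---|
| individuals per locus | uniform 20–60 | heterozygous sites are seen in a minority of a cohort; spans the ≥5 filter comfortably |
| read depth | 1 + NB(mean 39, size 5) | right-skewed exome-coverage-like RNA depths, minimum 1 read |
| ASE fraction | 0.15 | of loci tested in real cohorts, roughly one in eight reaches ASE significance; 0.15 gives both classes weight in small simulations |
| null $\pi$ | 0.5 | balanced expression |
| ASE $\pi$ | uniform (0.6, 0.95), mirrored to (0.05, 0.4) with probability ½ | effect sizes bounded away from 0.5; mirroring keeps ASE direction symmetric so calling cannot exploit a directional artifact |
| $\rho$ | 0.05 | mild but non-negligible overdispersion; at depth 40 it roughly triples the binomial variance |

Reproducibility uses a counter-based seed fan-out: each locus draws from
its own substream derived from (global seed, locus index), so any subset
of loci is reproducible regardless of iteration order.

The feature generator plants signal by shifting class-conditional
distributions: numeric feature $j$ is $N(0,1)$ for non-ASE rows and
$N(e_j, 1)$ for ASE rows; categorical features tilt their level
probabilities by $e_j$. Missing entries are inserted uniformly at a
configurable rate. The planted effect vector is retained on the object so
recovery tests can check it.

**What passing these tests shows — and does not.** The synthetic features
are conditionally independent given the label, have Gaussian tails and
planted monotone effects. Real annotation features are collinear
(conservation scores), heavy-tailed (distance features), block-missing
(transcript-level annotations), and their association with ASE is weaker
and partly mediated by detectability. Green tests therefore demonstrate
that the machinery is correct — calibrated null, controlled FDR, signal
recovered when present, chance-level AUROC when absent — not that any
particular real-data AUROC is attainable.

## Feature curation, imputation and encoding

The candidate table has 109 columns: the CADD v1.4 annotation set (107)
plus the gene-level loss-of-function intolerance `pLI_score` and the
population allele frequency `gnomAD_AF`. Three packaged exclusion lists
remove 39: 12 non-functional identifiers (chromosome, position, gene ids
and similar), 16 columns with over 40% missing values (motif, microRNA
and splice-distance annotations), and 11 columns correlated with ASE
*detectability* rather than ASE biology (expression level and local
variant-frequency windows, including `gnomAD_AF` — removing these keeps
the model from merely learning where ASE is easy to measure). That leaves
70 model features. `gnomAD_AF` appears both as an added feature and on
the detectability list; it is treated as excluded.

Imputation defaults are configurable per column; when none is supplied
the package falls back to the training column's median (numeric) or most
frequent level (categorical). The original empirical CADD release-note
values can be supplied through the spec table, but are not redistributed
here. Categorical features are encoded as ordinal integer codes in
alphabetical order (0..K−1): boosted trees split on thresholds, so
ordinal codes lose nothing that one-hot columns would add, and the
dictionary is persisted with the matrix so apply-time encoding is
identical to training. A level unseen at training maps to the reserved
code K with a warning.

## The boosted classifier and nested cross-validation

The predictor is gradient-boosted decision trees (via xgboost with exact
greedy splits), 100 boosting stages per model — "100 iterations" read as
100 trees, the natural unit for a boosting configuration. The training
scheme is nested: 10 stratified outer folds each yield one model trained
on the other nine folds; within each outer-training portion an inner
6-fold cross-validation selects hyperparameters by mean AUROC. The
default grid is the single point (learning rate 0.1, depth 3) — the
conventional library defaults — so inner selection is a no-op unless a
real grid is supplied; the structure is there because selection inside
the outer loop is what keeps the outer estimate unbiased. 10% of rows are
held out before any training as the independent test set, stratified by
label.

Prediction averages the 10 fold models' probabilities (per-fold output is
also exposed, since per-fold ROC curves are how spread is reported).
Feature importance is the impurity-decrease (gain) importance of each
fold model, normalized to sum to one, summarized as mean and quartiles
across folds. No resampling is applied for class imbalance: at roughly
1:7, boosted trees handle the skew, and rebalancing trades the
specificity that makes a 0.5 threshold useful.

Evaluation reports AUROC per fold model (mean ± sd) via the rank
(Mann–Whitney) formulation with ties counted half — exactly the
probability that a random positive outranks a random negative — plus
PPV, NPV, sensitivity and specificity at the threshold, with the
$p \ge t$ convention for positive calls and explicit undefined flags for
zero denominators. Display rounding is half-up to two decimals; stored
values are full precision.

## The rank-resampling bias test

To ask whether a model's *correct* ASE predictions are biased towards
particular gene functions, the predicted ASE-SNVs' genes are profiled by
gene-set over-representation (hypergeometric upper tail within a
background universe; terms ranked by p-value, ties broken by larger
overlap then term id) and the profile is compared with profiles of
equally sized random draws from the full ASE-SNV set (without
replacement, default 10 draws, top 10 terms). If the observed ranks sit
inside the resampled rank distributions, the predictions are
functionally indistinguishable from random ASE-SNVs — no bias. The
over-representation test is local and file-based (GMT input) rather than
a web service, so the diagnostic is reproducible offline; any consistent
ranking function serves the comparison. A term missing from a resample
profile receives rank T+1 and is flagged rather than dropped, keeping
rank distributions comparable across resamples.

Under a model-free null (the "predictions" are themselves a random draw),
the observed rank sits inside the 10-resample range for 9 of the top 10
terms on average — the self-consistency property the suite checks as an
across-seed mean of at least 8, since the per-seed count fluctuates by
±1–2 by construction.

## Problem sizes used by the test suite

The suite and the acceptance script run at sizes chosen to make the
statistical assertions meaningful at desk scale: 2000 null loci of 30
individuals for test calibration (type-I error asserted within
[0.03, 0.07] at nominal 0.05, Kolmogorov–Smirnov distance from
uniformity < 0.05); 100 replicates of 50 individuals at depth 50 for
parameter recovery within ±0.05; 5000 rows × 20 features × 10 seeds for
planted-importance recovery (the three informative features must occupy
the top three ranks in at least 9 of 10 seeds); a 500-locus cohort for
the end-to-end run; and a 200-locus smoke pipeline.

## Known limitations

* Calls are per-SNV and cohort-level: no per-individual calls, no
  haplotype- or gene-level aggregation, no allelic direction, autosomes
  only.
* The $\chi^2_1$ reference is asymptotic; at very few individuals or very
  low depth the test is conservative near the $\rho$ boundary.
* Ordinal encoding of categoricals is tailored to tree models; a linear
  model consuming the encoded matrix would see spurious order.
* The bias test ranks by raw hypergeometric p-value; services that rank
  by combined scores will order near-tied terms differently, which is
  immaterial to the resampling comparison but means absolute ranks are
  not comparable across ranking functions.
* Synthetic cohorts do not model mapping bias, genotyping error, phasing
  or linkage between loci.
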