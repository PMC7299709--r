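---
title: "Progenitorness scoring: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Progenitorness scoring: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(progenitorness)
```

## The score and the biology behind it

The atavistic view of cancer holds that tumours re-activate an ancient,
pre-multicellular expression program built for unconstrained proliferation.
This package quantifies that re-activation per sample. The signature is the
set of *progenitor genes*: genes flagged essential whose phyletic age —
the evolutionary era in which the gene family arose, on the six-category
ordered scale *cellular organisms < Eukaryota < Fungi/Metazoa group <
Metazoa < Chordata < Mammalia* — falls in one of the two eras predating
multicellular life. `curate_progenitor_genes()` applies exactly this
filter to an OGEE-style gene-age/essentiality table.

The *progenitorness score* of a sample is a single-sample gene-set
enrichment statistic of that signature in the sample's expression profile.
Within one sample, genes are ordered by decreasing expression and the score
integrates, over every position $i$ in the ranking, the gap between the
weighted in-set cumulative distribution and the unweighted out-of-set one:

$$
ES \;=\; \sum_{i=1}^{N}\bigl[P_{\mathrm{in}}(i)-P_{\mathrm{out}}(i)\bigr],
\qquad
P_{\mathrm{in}}(i)=\frac{\sum_{g \in S,\; \mathrm{pos}(g)\le i} |v_g|^{\alpha}}
                        {\sum_{g \in S} |v_g|^{\alpha}},
\qquad
P_{\mathrm{out}}(i)=\frac{\#\{g \notin S,\ \mathrm{pos}(g)\le i\}}{N-|S|},
$$

where $v_g$ is the gene's (rank-normalized) value. A positive $ES$ means
the signature concentrates at the top of the profile. This is the
integrated-difference form of the running-sum statistic — the sum over all
positions, not the supremum — which is the conventional single-sample
variant of gene-set enrichment.

## Parameters and defaults

* **`alpha` (default 0.25)** — the weight exponent on in-set genes.
  `alpha = 0` gives every signature gene equal weight; larger values
  emphasise the most highly expressed ones. 0.25 is the conventional
  single-sample default and is deliberately mild: with per-sample rank
  normalization the weights span only $[1, N^{0.25}]$.
* **`sample_norm = "rank"` (default)** — each sample's values are replaced
  by ascending ranks (average ties) before scoring. This makes the score
  invariant under any strictly increasing per-sample transform, which is
  what lets one statistic serve FPKM, microarray intensities, single-cell
  counts and protein abundances without choosing a normalization per
  platform. `"none"` scores raw values and forfeits that invariance.
* **`batch_norm` (default on)** — NES $= ES / (\max ES - \min ES)$ over
  the scored batch. NES is convenient for within-dataset displays (its
  range is exactly one), but it is batch-dependent by construction:
  cross-dataset comparisons should use raw ES, or renormalize within each
  dataset. The paired pre/post-treatment analysis in this package uses raw
  ES for precisely this reason.
* **`min_overlap` (default 0.8)** — the minimum fraction of the signature
  that must be present among the matrix rows. Scoring a profile that lacks
  a large part of the set silently measures a different signature, so the
  default refuses below 80% and lists the missing symbols.

## Input handling rules

Expression matrices are genes × samples with gene symbols as row keys.
Symbols are matched case-sensitively after whitespace trimming; no alias or
identifier mapping is attempted. Duplicated symbols are collapsed by the
elementwise per-sample maximum (`collapse_duplicates()`): "keep the max"
admits a whole-row and a per-cell reading, and the per-cell maximum
dominates both for rank-based scoring while staying deterministic; the
whole-row alternative (`"max-mean-row"`, keep the row with the largest
mean) is available behind a flag. Missing values are ignored by the
max-collapse (a cell missing in every duplicate stays missing) and are
placed at the bottom of the sample's ranking at scoring time, with a
warning — a rank statistic needs a total order, and "absent" is treated as
"not detected". A gene-age table may carry several records per symbol;
conflicts are resolved inclusively (essential if any record says so,
ancient if any record says so) with a warning, on the logic that a
curation-positive record in an aggregated database is stronger evidence
than its absence elsewhere.

## Statistical procedures

The evaluation stages use the field-standard procedures: two-sided
Wilcoxon rank-sum (exact for ≤ 20 untied observations, otherwise normal
approximation with tie and continuity corrections), Wilcoxon signed-rank
for paired designs (zero differences dropped with a warning; all-zero is an
error), ROC/AUROC by threshold sweep and trapezoid integration (provably
equal to the Mann–Whitney $U/(n_1 n_2)$ probability with half-credit
ties — the test suite asserts the identity to $10^{-12}$), Cox
proportional-hazards regression by partial likelihood with the Efron tie
correction and Wald confidence intervals, Kaplan–Meier curves with the
two-group log-rank test after a median split, and Spearman correlation
(t-approximation) with Benjamini–Hochberg adjustment across drugs.

Choices worth flagging:

* **Median-split ties** go to the low-score group, for determinism.
* **BH rather than an empirical-null fdr tool** for the drug screen:
  empirical-null fitting is unstable at the screen sizes used here, while
  BH is distribution-free and preserves the FDR < 0.05 flagging semantics.
* **Hazard-ratio scale**: the score enters Cox regression on its natural
  scale. Because NES lives on a unit-ish range, the HR "per +1.0 score" can
  be astronomically large without being remarkable; `cox_fit()` therefore
  also reports HR per +0.1 and per +1 SD.
* **Dummy coding** of categorical covariates is against the first level by
  sorted label; incomplete cases are dropped and the drop is logged.
* **Cox error handling**: fewer than two events, a constant score, or
  failure to converge within the iteration bound are errors, not silent
  output. The fitted coefficient is verified in the tests against a
  grid-search maximization of the hand-written partial likelihood on an
  untied four-subject design.

## What the synthetic cohorts emulate — and what they do not

The generators in `sim_*()` reproduce the *statistical structure* each
analysis assumes, not the biology of any real cohort:

* `sim_expression()` — lognormal(0, `noise_sd`) background with a
  `delta` log-scale up-shift of signature genes in the tumour arm.
  Defaults: 5000 genes, 77-gene signature, 50 samples per arm,
  `delta = 2`, `noise_sd = 1` — a clean, strong two-arm contrast.
* `sim_graded()` — per-grade shifts, strictly increasing by construction
  (defaults 0, 1, 2 across three grades of 50).
* `sim_survival()` — exponential event times with rate
  $h_0 e^{\beta \cdot \mathrm{score}}$ and independent exponential
  censoring whose rate is solved numerically to hit the target censoring
  fraction in expectation (default 30%, a typical cohort attrition).
* `sim_paired_treatment()` — the same subjects re-profiled with the
  signature pulled down by `treatment_delta × dose`, background redrawn.
* `sim_drug_response()` — drug AUC (higher = more resistant) linear in the
  score for a configured fraction of drugs, pure noise for the rest, with
  the ground truth returned for power/FDR accounting.
* `sim_dropout()` — independent zeroing of nonzero entries, the simplest
  dropout model, to probe rank-score robustness at 50% loss.

Every generator is a pure function of its configuration and seed (the
tests assert bit-identical replays), and none of them attempts platform
effects, batch structure, FFPE degradation, realistic library-size
variation, or correlated gene modules. Consequently, a passing synthetic
suite shows that *the pipeline detects the structure it is designed to
detect at realistic effect sizes and sample sizes* — it does not show that
real tumours carry that structure; that question needs real accessions,
which this package deliberately does not download.

## Problem sizes and numerical notes

The packaged evaluation uses cohorts small enough to run on a laptop while
keeping each test decisive: 100–150 samples for diagnosis and grading, 30
pairs for treatment, 100 drugs × 100 cell lines for the screen, and 2000
samples for survival, where Cox parameter recovery is assessed across
replicates (the single-cohort sampling SD of $\hat\beta$ at that size is
about 0.04, so recovery is asserted on the replicate mean). Enrichment
scores are validated exhaustively against a literal two-ECDF brute-force
oracle for all membership vectors at $N \le 8$; ties in the descending
ordering are broken by stable input order so every code path is
deterministic. The log-rank statistic is checked against hand-evaluated
observed/expected sums on a four-subject design ($\chi^2 = 49/17$).

## Known limitations

* The packaged 77-gene signature is a **synthetic stand-in** assembled
  from human genes in phyletically ancient essential complexes (proteasome,
  chaperonin, replicative helicase, ribosome, spliceosome); analyses of
  real data should curate the signature from a current OGEE export.
* NES is batch-relative; never pool NES across separately scored batches.
* The score is blind to signature *direction* within the set (all
  progenitor genes are treated as "up"); a signature with mixed-direction
  members would need a signed extension.
* Exact Wilcoxon enumeration is only used in the untied small-sample
  regime; deep-tail p-values under the normal approximation carry the
  usual relative error of that approximation.
* No proportional-hazards diagnostics, time-varying covariates, or
  multi-group log-rank tests are provided — the evaluation designs here do
  not need them.
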