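---
title: "Methods: subgroup-dissecting prognostic signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subgroup-dissecting prognostic signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(recurisk)
```

## The problem

Early-stage tumors treated by surgery alone recur in a minority of patients,
and the patients who recur are not one homogeneous group: distinct expression
programs (for example loss of epithelial/proliferative identity with an
immune-depleted microenvironment, versus a TGF-β-driven hybrid
epithelial–mesenchymal state) can each carry an elevated recurrence hazard.
A single risk score blurs these programs together. `recurisk` learns **two**
nearest-centroid gene signatures from bulk expression plus
recurrence-free-survival (RFS) follow-up, and calls each tumor `low_risk`,
`high_risk_1`, or `high_risk_2`.

Inputs are a genes × samples matrix of log2-scale normalized abundances
(upstream quantification and normalization are out of scope; the package
applies none) and a clinical table with time to recurrence in months and a
0/1 event flag.

## The training procedure

1. **Cohort filters.** Recurrences earlier than 2 months are excluded
   (residual disease); recurrences after 60 months fall outside the
   recurrence-group window and are recoded as censored at 60; optionally,
   treated non-recurrence samples are removed. The recode-at-60 choice (rather
   than dropping the sample) keeps the sample's event-free follow-up
   information; each action is logged per row.
2. **Standardization.** Per-gene z-scores; the training means and standard
   deviations are frozen and travel with the model so that validation samples
   are always scored on the training scale. Zero-variance genes map to 0 and
   are flagged rather than dropped, so gene lists keep their length.
3. **Partition of recurrence tumors.** The recurrence samples are split into
   `n_branches` (default 2) candidate subgroups. The matrix is restricted to
   the `n_variance_genes` (default 500) most variable genes, z-scored, and
   projected onto its first `n_branches` principal components computed on
   *all* cohort samples; the recurrence samples are then clustered on these
   coordinates with k-medoids (`cluster::pam`). The projection is the design
   choice that was genuinely open: clustering samples directly on
   (1 − Pearson) distances is noise-dominated when per-gene effects are
   around one standard deviation spread over a few dozen genes — the expected
   between-carrier correlation is smaller than the correlation noise floor —
   whereas the principal components pool evidence across the whole program.
   The axes are computed without reference to outcome, so the partition stays
   unsupervised. Branch numbering is canonical: when epithelial markers
   (EPCAM, CDH1, EGFR, MET by default) are present, branch 1 is the branch
   with the lower mean marker z-score (the epithelial-loss phenotype);
   otherwise branches are ordered by size.
4. **Cox prescreen.** Each gene is fitted by univariate Cox proportional
   hazards regression; genes with Wald p below `prescreen_alpha`
   (default 0.01, raw — no multiple-testing correction, because the stability
   stage is the guard against false positives) form the screened set. By
   default the stability stage still ranks **all** genes
   (`universe = "all"`): restricting the candidate universe to the screened
   set makes the top-`top_k` rank threshold vacuous whenever the screen
   returns fewer than `top_k` genes, which at panel scale silently selects
   every screened gene. `universe = "prescreen"` is available for
   transcriptome-scale matrices, where the two modes effectively coincide.
5. **Stability selection per branch.** The branch's working cohort is its
   recurrence samples plus all non-recurrence samples. For `cv_rounds`
   (default 200; the scaled-down experiments in this package use 20) rounds
   of `cv_folds` (default 10) fold cross-validation — folds stratified on
   event status so every training fit keeps events — a univariate Cox model
   is fitted per candidate gene on the training folds and genes are ranked by
   ascending p-value (ties by ascending |beta|, then gene id). A gene scores
   a hit when it ranks within `top_k` (default 150); genes with hit frequency
   at least `freq_threshold` (default 0.80) become the branch's signature.
   Hits are counted per fold-fit (`count_unit = "fold_fit"`,
   `cv_rounds * cv_folds` fits); `"per_round"` aggregates each round's fold
   ranks by their median first. The trainer requires each training fit to
   carry at least 2 events on average (`n_events * (folds − 1) / folds ≥ 2`);
   with fewer events it advises reducing `cv_folds`. When fewer than 10 genes
   reach the threshold the signature falls back to the top 10 by frequency,
   with a warning — weak or null cohorts then still produce a working (and
   appropriately uninformative) model.
6. **Centroids and cutoffs.** For each branch, `centroid_high` is the mean
   z-profile of the branch's recurrence samples over its signature genes and
   `centroid_low` the mean over all non-recurrence samples. A sample's score
   is Pearson correlation with the high centroid minus Pearson correlation
   with the low centroid (the standard similarity scale for expression
   centroid classifiers; printed cutoffs near zero are consistent with a
   difference-of-correlations scale). The decision cutoff maximizes the
   two-group log-rank chi-square of the induced training split over the
   midpoints of adjacent sorted scores, requiring each arm to hold at least
   `min_group_frac` (default 10%) of samples; ties go to the more balanced
   split.
7. **Combination.** A sample is high-risk when either score exceeds its
   cutoff (OR rule); among high-risk samples the subgroup is the signature
   with the larger cutoff-centred margin, ties to subgroup 1. The continuous
   combined score is the larger margin; it feeds the concordance AUC.

## Survival statistics

All estimators are implemented from first principles and cross-checked in
the test suite against independent brute-force oracles (and against the
`survival` package, which is never used as the implementation):

* **Product-limit curves** with Greenwood variance; simultaneous handling of
  tied events. Pointwise confidence intervals use the complementary log-log
  transform, which keeps the interval inside [0, 1] and matches the common
  survival-package default.
* **Two-group log-rank test**: hypergeometric variance summed over event
  times, chi-square with 1 df.
* **Univariate Cox regression**: safeguarded Newton maximization of the
  partial likelihood with the Efron tie correction (the default of the
  package family practitioners use). Steps are trust-region bounded at 2 and
  halved until the likelihood is non-decreasing; convergence is `|U| < 1e-9`;
  a monotone likelihood (perfect separation) is detected when |beta| escapes
  15, the coefficient capped, and `converged` cleared. Reported p-values are
  Wald, the per-coefficient p conventionally reported. Constant covariates
  and event-free cohorts are rejected with typed errors.
* **Concordance AUC** via the rank-sum identity; tied scores count one half.
  The AUC label is the recorded event flag: samples censored early are *not*
  excluded or reweighted, a documented caveat — with heavy early censoring
  the AUC target is a noisy surrogate for 36-month discrimination.
* **Wilcoxon rank-sum comparisons** (characterization read-outs) call
  `stats::wilcox.test`, exact when both groups have at most 10 tie-free
  values, otherwise the normal approximation with continuity and tie
  correction.

## The synthetic cohort generator

Real training data of this kind (archival FFPE RNAseq with multi-year
follow-up) is access-restricted, so the package ships a generator whose
defaults emulate the cohort shape the method was designed for: 220 samples;
two high-risk classes of 20% each; 2000 genes with 40 signature genes per
program shifted by 1.0 within-gene SD (program 1 down — including the
epithelial markers — program 2 up); 13 immune marker genes (optionally
depleted in class 1); exponential failure times at 0.004 events/month
baseline with 4.0-fold hazards in the high-risk classes; administrative
censoring at 41 ± 12 months (uniform jitter), capped at 60. Per-gene baseline
means are drawn from N(6, 1.5) on the log2 scale for realism; z-scores and
group deltas are unaffected. Everything is reproducible from one seed via a
documented sub-seed counter (`derive_seeds()`), and per-sample/per-gene truth
tables are emitted for test harnesses.

What the generator deliberately does **not** emulate: count-level noise,
library-size and batch effects, and within-program gene–gene correlation
beyond the shared block shift. Passing tests therefore demonstrate that the
pipeline recovers *planted block-shift structure with constant hazards*; they
do not certify performance on real RNAseq.

## Known limitations

* **Selection power at few events.** A branch's working cohort carries only
  the branch's recurrence events (~10 at the default cohort size after a
  50/50 split). At that event count, univariate Cox p-values cannot reliably
  separate 1-SD single-gene effects from the best of ~2000 background genes,
  so stability-selected signatures contain a substantial admixture of
  background genes, and a rank threshold of 150 on a 2000-gene universe
  retains background genes whose cohort-level rank is stable across folds.
  Both effects shrink as the universe grows (rank-150 churn increases) and as
  events accumulate; they are properties of this selection
  mechanism at desk scale, not implementation artifacts, and the end-to-end
  recovery experiments report them honestly.
* Cutoffs are tuned on training data only; with noisy signatures the
  training log-rank optimum overestimates the separation achievable on
  held-out samples.
* The bundled immune marker panel is partial (13 markers) and labelled as
  such; the full 43-marker/14-cell-type panel and the FOLFOX resistance
  signatures must be supplied as gene-set files.
* No multivariate or covariate-adjusted Cox modelling, competing risks, or
  proportionality diagnostics.

## Problem sizes used by the test suite

Unit tests run on reduced cohorts (60–200 samples, 40–400 genes, strong
planted effects) so each file completes in seconds. The acceptance
experiments use the generator defaults (220 × 2000) with 20 rounds of
cross-validation, 2000 null replicates for log-rank calibration, and 20
seeded repeats for null-safety of the end-to-end pipeline — the sizes at
which the statistical properties they check are meaningful.
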