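---
title: "Differential-correlation marker discovery: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential-correlation marker discovery: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcmarker)
```

## The problem and the model

In a two-class study (controls vs cases) over a panel of $m$ molecules, the
conventional marker is a *mean shift*: a molecule whose average level
differs between classes. `dcmarker` targets the complementary signal, a
*correlation shift*: a molecule pair $(i, j)$ whose within-class
correlation differs between classes. The ranking statistic is

$$s_{ij} = |r_1 - r_2|,$$

the absolute difference of the per-class Spearman rank correlations. Rank
correlations are used because qPCR expression values are heavy-tailed on
the linear scale and only defined up to monotone calibration; every
statistic in the ranking is invariant to strictly increasing per-molecule
transforms. All $m(m-1)/2$ pairs are ranked by $s_{ij}$ (ties broken
lexicographically by molecule IDs so re-runs are identical) and pairs with
$s_{ij}$ strictly above a threshold — default 0.8 — become marker
candidates.

### Significance of a correlation difference

Each pair receives a p-value for $H_0\!:\rho_1 = \rho_2$. The test is run
not on the Spearman correlations but on the van der Waerden
(normal-scores) correlations

$$r_n = \frac{\sum_i \Phi^{-1}\{R_i/(n+1)\}\,\Phi^{-1}\{Q_i/(n+1)\}}
             {\sum_i [\Phi^{-1}\{i/(n+1)\}]^2},$$

a Pearson-type rank statistic that behaves like the correlation of an
underlying Gaussian and is therefore well suited to a likelihood-based
test. The two statistics track each other closely: across simulated pairs
at $n = 30$ the mean signed difference $r_n - r_s$ is on the order of
$10^{-3}$ (the per-pair sampling difference is larger, around 0.03 in
absolute value — the two statistics weigh ranks differently — but it is
noise, not bias, and cancels in the mean).

The likelihood-ratio construction: for a bivariate normal sample with
correlation $\rho$, profiling out means and variances leaves (up to
constants)

$$\ell(\rho; r, n) = -n\log(1-\rho r) + \tfrac{n}{2}\log(1-\rho^2),$$

maximized at $\rho = r$. The alternative maximizes each class at its own
$r_n$; the null maximizes the pooled profile likelihood over a common
$\rho$ by a bounded one-dimensional search on $(-1+10^{-9},\,1-10^{-9})$
with convergence tolerance $10^{-10}$ (deterministic; equal inputs return
$p = 1$ exactly without a search). The statistic $-2\log\Lambda$ is
referred to $\chi^2_1$, two-sided by construction.

**Small-sample correction.** The $\chi^2$ reference is asymptotic, and at
cohort sizes of 20–30 per class the raw statistic is anti-conservative.
The implementation therefore uses per-class effective sample sizes
$n_k - 2$ inside the profile likelihood, in the same spirit as the $n - 3$
variance correction of the Fisher z transformation. This choice was
calibrated by a null Monte-Carlo at the default study size (30/23, common
$\rho = 0.3$, 10,000 replicates): the rejection rate at $\alpha = 0.05$ is
0.050–0.055 with the correction, versus ≈ 0.060 without it. A classical
Fisher z two-sample test (`p_method = "fisher"`) is provided as an
independent alternative; the two agree to within an order of magnitude on
p-values throughout the relevant range. P-values are reported as a
reference for significance; selection is by the score threshold, and no
multiple-testing correction is applied across pairs.

### Evaluating marker pairs

A correlation change need not move any marginal mean, so single-molecule
classifiers can be blind to it. The evaluation model is logistic regression
with an interaction term,

$$\log\frac{p}{1-p} = \beta_0 + \beta_1 X_1 + \beta_2 X_2 + \beta_{12} X_1 X_2,$$

whose product term lets the class-dependent coupling of $X_1$ and $X_2$
drive the fitted probabilities. Several pairs are evaluated jointly by
entering one main effect per *distinct* molecule and one product term per
pair (a molecule shared by two pairs contributes a single main effect and
appears in both products). Performance is the ROC AUC of the fitted
probabilities, computed as the Mann–Whitney concordance with ties counted
one half.

Two caveats are deliberate properties of the design, not oversights:

* **AUC is in-sample.** The whole cohort is used for both fitting and ROC,
  so AUCs carry optimism, which grows with model size (an exhaustive search
  over combinations maximizes over that optimism too). In-sample evaluation
  is retained as the package's default because the method is a *screening*
  tool whose outputs are candidates for independent validation; the
  comparison against the equally in-sample t-test baseline is like-for-like.
* **Separation.** With 53 samples and flexible interaction models, perfect
  separation occurs. It is detected (non-convergence or fitted probabilities
  at the 0/1 boundary), flagged on the result, and fitted probabilities are
  clamped to $[\varepsilon, 1-\varepsilon]$, $\varepsilon = 10^{-12}$ —
  harmless for AUC, which depends only on the score ordering.

The exhaustive two-pair search evaluates all $\binom{k}{2}$ combinations of
the $k$ marker pairs; equal AUCs are ordered by the sum of the constituent
pairs' original ranks, then lexicographically, so results are reproducible.

## qPCR preprocessing

The filtering cascade reflects how plasma qPCR panels fail, with the
boundary semantics chosen by a literal reading of the underlying rules:

| rule | semantics | default |
|---|---|---|
| detection | Cp strictly below the cutoff, *or* at least `nc_margin` cycles below the negative control | cutoff 37, margin 3 |
| efficiency | reactions with per-cycle amplification strictly below the floor are removed (the floor itself is kept) | 1.6 |
| normalization | $-\mathrm{dCp} = \overline{\mathrm{Cp}}_{<37} - \mathrm{Cp}$, per sample | cutoff 37 |
| detection rate | molecule kept if detected in strictly over `rate` of samples in *either* class | 0.8 |
| low expression | molecules whose median $-\mathrm{dCp}$ falls strictly below the given quantile of those medians are removed | 0.20 |

Two decisions deserve justification. First, the normalization averaging set
contains only reactions with Cp strictly under the cutoff: a reaction
rescued by the negative-control clause is itself normalized but does not
contribute to the sample mean, so the mean of $-\mathrm{dCp}$ over the
averaging set is exactly zero — an identity the tests assert. Second, "low
expression" is not a standard term; this package reads it as the bottom
quantile of per-molecule median normalized expression, with the quantile
exposed as a parameter (0 disables the filter) because other readings
(per-value cutoffs, mean-based references) are defensible. Undetected
entries stay missing — nothing is imputed, since imputation would inject
exactly the kind of cross-molecule structure the method is trying to
detect; all downstream correlations are pairwise-complete with per-pair
sample sizes recorded.

Samples with no reaction under the Cp cutoff cannot be normalized and are
dropped with a message. Each filter's removal count is logged in the QC
report, because a panel's arithmetic (how 745 assays become 85) is only
auditable through such counts.

## The synthetic-data generator

There is no public cohort to test against, so the generator *is* the study
design used by the test suite: 30 controls and 23 cases over an 85-molecule
panel, three planted differentially correlated pairs at Spearman
$(\rho_1, \rho_2) = (0.8, -0.2)$, two planted mean-shift molecules (1.0 and
1.5 within-class SD), independent background, and normal marginals with a
2-cycle SD on the $-\mathrm{dCp}$ scale (a realistic spread for a plasma
panel; the location is immaterial because normalization centres each
sample). Sampling is by Gaussian copula: a target Spearman matrix is
converted entrywise to the Pearson scale via $r = 2\sin(\pi\rho_s/6)$ —
exact for bivariate normals — and sampled with normal marginals, so planted
pairs hit their population Spearman targets. If the assembled target matrix
is not positive definite, eigenvalues are clipped at a floor ($10^{-8}$)
and the matrix rescaled to unit diagonal with a warning; if that repair
would move any requested correlation by more than 0.05 the generator
refuses and names the worst-offending pair. Raw panels are derived as
$\mathrm{Cp} = 28 - \mathrm{expression}$ with negative controls at 40
cycles and efficiency 1.9, and QC artifacts are planted by rewriting chosen
reactions (Cp 39 with control 40; efficiency 1.45) so that preprocessing
removes exactly the planted records.

What the generator does *not* emulate: plate and batch effects, hub-like
background correlation (an option exists via `background_rho`, but the
default background is independent), heteroscedastic detection (dropout
correlated with expression level), and non-normal marginals. Passing tests
therefore demonstrate that the *machinery* is correct and that the method's
operating characteristics hold under a clean null — not that real plasma
panels satisfy those conditions.

## Operating characteristics at the study scale

Monte-Carlo results the test suite recomputes (all at 30/23 samples):

* **Recovery.** A planted $(0.8, -0.2)$ pair lands in the top 100 of the
  3570 ranked pairs (top ~3 %) in ≈ 95 % of replicates, and in the top 20
  in ≈ 81 %. The top-100 cutoff is the package's pilot-calibrated
  definition of "recovered": with 53 samples the sampling SD of a
  correlation difference is ≈ 0.2–0.3, so a handful of the 3567 background
  pairs routinely overtake a planted pair, and demanding top-20 placement
  would mostly measure that noise. The same noise means the strict
  score > 0.8 rule recovers a planted pair only ~78 % of the time —
  screening by rank is more stable than screening by absolute score.
* **Interaction vs main effects.** On correlation-only signal the
  interaction model's in-sample AUC beats the main-effects-only model in
  ≈ 98 % of replicates, and the best two-pair interaction model beats the
  best four-molecule main-effects model in ~100 % — the method detects
  what the t-test cannot. Conversely the per-molecule t-test rejects at
  ≈ its nominal α on such data, confirming the signal is invisible
  marginally.
* **Calibration.** The equality LRT holds its nominal size (above); the
  permutation null of the single-pair interaction AUC sits near 0.57 rather
  than 0.5 — in-sample optimism of a 4-parameter model at $n = 53$ —
  which is why marker AUCs should be read comparatively, not absolutely.

Problem sizes in the routine test suite are scaled (10–20 molecule panels,
50–100 replicates; 10,000 replicates for the LRT null) as the package's
chosen compromise between Monte-Carlo resolution and a test suite that runs
in about a minute.

## Known limitations

* In-sample AUC overstates out-of-sample discrimination; use the provided
  machinery for screening and validate externally.
* The LRT assumes the normal-scores correlation behaves like a bivariate
  normal correlation; heavy ties (e.g. many identical Cp values) weaken
  that approximation.
* With ~50 samples, score-based selection at a fixed threshold is noisy;
  the threshold 0.8 is a design point inherited from the analysis this
  package operationalizes, not an estimated quantity.
* The generator's clean background makes recovery rates optimistic relative
  to panels with pervasive co-expression.
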