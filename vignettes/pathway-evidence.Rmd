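---
title: "Scoring basal-ganglia action-control pathways with Bayes-factor products"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring basal-ganglia action-control pathways with Bayes-factor products}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathwaybf)
```

## The analysis in one page

The package takes long-format percent-BOLD observations — one value per
participant, fMRI contrast and region of interest (ROI) — over 16
lateralised regions: pre-SMA, IFG, striatum (STR), globus pallidus externa
(GPe) and interna (GPi), substantia nigra (SN), subthalamic nucleus (STN)
and thalamus (THAL), left and right. Four stages follow.

**Compound averaging.** Each contrast is assigned to one behavioural
condition — response execution, proactive (preparatory) inhibition, or
reactive inhibition — and each participant × ROI cell is the arithmetic
mean of its condition set. The premise is that individual contrasts differ
mainly in their baselines, which are not of interest, while the condition
signal is common to all of them; averaging suppresses the former and
stabilises the latter. The pooled `inhibition_all` condition is the mean
over the *union* of proactive and reactive observations, weighting every
contrast equally. (The alternative, a mean of the two sub-means, is
available via `inhibition_all = "mean_of_means"`; with near-equal subset
sizes the two differ negligibly, and equal weight per contrast is the more
defensible default because the subset sizes are an artefact of how many
contrasts could be constructed, not of evidential weight.)

**Activation tests.** Each ROI's 30 compound values are tested against
zero. The Bayes factor is the Jeffreys–Zellner–Siow (JZS) default for a
one-sample *t*-test: the noncentral-*t* likelihood of the observed
statistic, marginalised over a zero-centred Cauchy prior on the
standardised effect size $\delta$,

$$
\mathrm{BF}_{10}
  = \frac{\int f(t;\,\nu,\,\delta\sqrt{N})\,
          \mathrm{Cauchy}(\delta;\,0,\,r)\,d\delta}
         {f(t;\,\nu,\,0)} .
$$

An ROI is *active* when $p < 0.05$ or $\mathrm{BF}_{10} > 3$ — a
disjunction of the conventional frequentist and Bayesian thresholds, used
as stated rather than replaced by any combined statistic. At $N = 30$
with the default prior, $\mathrm{BF}_{10} > 3$ implies $p < 0.05$, so the
joint false-active level is exactly 0.05. The tests are exploratory and
uncorrected by default; `holm_adjust()` (Holm–Bonferroni step-down) is
available as an opt-in column.

**Moderator/mediator screen.** For every ordered pair of active ROIs the
target is regressed on the covariate and the intercept is tested:
$t = \hat\beta_0 / \mathrm{SE}(\hat\beta_0)$ with $\nu = N - 2$, and a JZS
Bayes factor from that statistic with $n_\mathrm{eff} = N$. A covariate
*mediates* the target if the adjusted evidence collapses
($\mathrm{BF}_{10} < 1/3$ *and* $p > 0.05$), *moderates* it if the
evidence is reduced but not eliminated
($1/3 \le \mathrm{BF}_{10} < 3$, below the original), and leaves it
*unchanged* otherwise. These two published rules do not partition the
outcome space — the Bayesian and frequentist thresholds can disagree
(e.g. $\mathrm{BF}_{10} < 1/3$ with $p \le 0.05$) — so the remaining cells
are flagged `inconsistent` rather than silently binned. Only simple
one-covariate regressions are run; this is a correlational screen, not
causal mediation analysis (no product-of-paths tests, no bootstrap CIs).

**Pathway evidence.** A pathway model is a membership map over the twelve
lateralised subcortical ROIs. Its evidence score is

$$
\prod_{k \in \mathrm{members}} \mathrm{BF}_{10}^{(k)}
\times
\prod_{k \notin \mathrm{members}} \frac{1}{\mathrm{BF}_{10}^{(k)}},
$$

activation evidence where the model predicts activity and null evidence
where it predicts none. For right-hand responses the defaults are: direct
= left {STR, GPi, SN, THAL}; indirect = all six right subcortical
structures; hyperdirect = right {GPi, STN, SN, THAL}; mirrored for
left-hand responses. Only the hyperdirect membership is fully dictated by
the anatomical account; the direct and indirect maps were fixed by
requiring that the published per-ROI Bayes factors shipped with the
package (`published_roi_bf()`) reproduce the published evidence products,
which they do within the 2-decimal rounding of the inputs (≤ 5%
relative). That derivation also settles two otherwise open choices: the
mismatched execution cells use the right-hemisphere inhibitory models
(left-hemisphere variants do not reproduce the published control values),
and a member ROI whose Bayes factor favours the null (right GPi under
inhibition, BF 0.24) is multiplied in unchanged. The grid always crosses
every condition with every pathway, so behaviourally mismatched cells are
computed as overfitting controls; the proactive and reactive rows reuse
the same membership maps. Predicted *direction* of activity
(up/down-regulation) is deliberately not encoded: the constituent tests
are two-sided, and a signed variant would be a different statistic.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| prior scale `r` | $\sqrt{1/2} \approx 0.707$ | effect-size SD | the conventional "medium" default; confirmed by calibration against the published (t, BF) pairs, which it reproduces within 0.3% (scales 1, $\sqrt2$, $\sqrt{12}$ miss by 15–70%) |
| activation thresholds | $p<0.05$ *or* BF > 3 | — | as published; disjunction kept verbatim |
| mediation thresholds | BF < 1/3 and $p>0.05$ | — | as published |
| `n_eff` for (t, df) input | df + 1 | — | one-sample convention; confirmed by the same calibration |
| `inhibition_all` | union mean | — | equal weight per contrast (see above) |

## The synthetic generator

`generate_dataset()` draws, for participant $i$, ROI $k$, condition $c$, a
latent mean $m_{ikc} = \mu_{kc} + b$, $b \sim N(0, \tau^2)$, independently
per condition; each of the condition's contrasts then yields
$m_{ikc} + N(0, \sigma^2)$. Coupling directives overwrite a target ROI's
latent mean with $\alpha + \beta\, m_{\mathrm{cov}} + N(0,
\sigma_\varepsilon^2)$ — coupling lives at the latent participant level,
not in contrast noise, so the mediation screen has a clean ground truth.
Defaults: 30 participants; 131 contrasts split 44/44/43 across conditions
(the emulated study reports only the total, so near-equal thirds are
used); effect 0.3 %BOLD in active ROIs; $\tau = 0.2$, $\sigma = 0.3$
%BOLD; for the mediation presets, covariate mean 0.5 %BOLD, slope 1,
intercept 0, residual SD 0.05. These are plausible ROI-level magnitudes;
recovery behaviour depends only on their ratios. All draws come from R's
Mersenne-Twister stream in a fixed order, so datasets are reproducible
bit-for-bit from `(params, seed)`.

What the generator does *not* emulate: hemodynamics and time-series
structure, voxel-level spatial correlation within and between masks,
shared participant traits across conditions (latents are drawn per
condition), heavy-tailed or skewed BOLD noise, and any behavioural
(reaction-time / stop-signal race) layer. Passing recovery tests
therefore show that the *statistical chain* recovers its own generative
structure, not that real fMRI data satisfy these assumptions.

## Numerical choices

* The prior integral is evaluated in log space: the log-integrand is
  shifted by its maximum (probed around $\delta = t/\sqrt N$, where the
  noncentral-*t* factor peaks) before `stats::integrate()` on
  $(-\infty, \infty)$ with relative tolerance $10^{-10}$. This keeps
  Bayes factors finite and accurate out to $|t| = 15$ (BF $\sim 10^{10}$),
  with absolute log-BF error well below $10^{-3}$.
* R's noncentral-*t* density carries a documented accuracy plateau around
  $10^{-12}$; its precision warnings are suppressed as they concern
  digits far below the quadrature tolerance.
* Evidence products are sums of signed $\log_{10}$ Bayes factors,
  exponentiated once at the end; a per-ROI contribution ledger is kept so
  every product is auditable.
* The test suite cross-checks the quadrature against an independent
  Monte-Carlo oracle (the mean noncentral-*t* likelihood over $10^7$
  Cauchy draws, evaluated from a dense spline tabulation of the
  log-density) to 0.5% on a grid $t \in \{0,1,2,3,5,8\}$,
  $\nu \in \{5, 29, 100\}$.
* Degenerate inputs fail loudly with typed conditions: zero-variance
  samples, zero-variance covariates, unassigned contrasts, missing
  compound cells (named by participant, ROI and condition), non-positive
  Bayes factors, cyclic coupling graphs. An exactly collinear
  target/covariate pair with zero intercept is the perfect-mediation
  limit and returns $t = 0$ rather than 0/0.
* Simulation-based tests use 12–50 seeded replicates at the default
  problem size (30 participants × 16 ROIs × 131 contrasts), which keeps
  the full suite within a few minutes while leaving the binomial
  pass-bands comfortably wide.

## Known limitations

* **The product rule rewards asymmetry under the null.** A truly inactive
  ROI yields $\mathrm{BF}_{01} \approx 5$ at $N = 30$ (the minimum JZS
  $\mathrm{BF}_{10}$ is ≈ 0.19), so a model with 4 members and 8
  non-members scores $E[\log_{10}]$ ≈ +2 on pure noise — genuine evidence
  that the 8 predicted-silent regions are silent, but easily misread as
  support for the pathway's *active* claim. Comparisons should be made
  across pathways within a condition, not against an absolute bar.
* **"Mediated" is a strict label at this sample size.** Under exact
  mediation the adjusted intercept *t* is (nearly) central
  $t_{28}$, and $\mathrm{BF}_{10} < 1/3$ requires $|t| \lesssim 1.05$ —
  probability ≈ 0.70. Regression dilution from within-participant
  contrast noise (reliability $\lambda \approx 0.95$ at the default
  noise) biases the intercept slightly upward and lowers the single-run
  mediated rate to ≈ 0.6; the *mediated-or-moderated* rate is ≈ 0.95.
  Mediation labels from single datasets of this size are accordingly
  unstable around their thresholds.
* **False actives enter the screen.** With 16 ROIs at a joint 0.05
  activation level, half of all null datasets admit at least one spurious
  ROI into the mediation matrix; its relations are noise.
* The pipeline consumes ROI-level tables only; mask construction, GLM
  fitting and whole-brain inference are upstream and out of scope.
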