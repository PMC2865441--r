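---
title: "Estimating physician treatment thresholds from ordinal recommendations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating physician treatment thresholds from ordinal recommendations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treatthresh)
```

## The estimation problem

A physician's treatment threshold is the disease risk at which they are
equally likely to recommend treatment or observation. Eliciting it
directly requires the physician to quantify risk, which clinicians do
poorly. `treatthresh` instead derives the threshold from ordinary
clinical behaviour: recommendations made on a set of cases whose risks
are computable from an external risk model. The motivating setting is
ocular hypertension, where 5-year glaucoma risk can be calculated from
age, intraocular pressure (IOP, mmHg), cup-disc ratio (CDR), pattern
standard deviation (PSD, dB), central corneal thickness (CCT, µm) and
diabetes status — but the estimator only sees a risk number per case, so
any condition with a risk calculator fits.

## The per-physician model

Recommendations arrive on a 7-point scale and are collapsed to
No < Unsure < Yes: the two firm negative levels become No, the three
hedged middle levels become Unsure, the two firm positive levels become
Yes. This keeps an explicit uncertainty category while guaranteeing
usable counts per level.

The collapsed response $t$ is modelled by a proportional-odds
(cumulative-logit) regression on case risk $r$:

$$\operatorname{logit} P(t \ge j \mid r) = \alpha_j + \beta r,
\qquad j \in \{\text{Unsure}, \text{Yes}\},$$

with $\alpha_U \ge \alpha_Y$ and a single slope $\beta$ (how sharply the
physician's recommendations switch with risk). Because there is nothing
below No and nothing above Yes,

$$P(\text{No} \mid r) = 1 - P(t \ge \text{Unsure} \mid r), \qquad
  P(\text{Yes} \mid r) = P(t \ge \text{Yes} \mid r).$$

Setting the two equal, $\sigma(-(\alpha_U + \beta r)) =
\sigma(\alpha_Y + \beta r)$ gives the unique balance point

$$r^{*} = -\frac{\alpha_U + \alpha_Y}{2\beta}.$$

The test suite verifies this closed form against a bisection root of
$P(\text{Yes}\mid r) - P(\text{No}\mid r)$ to $10^{-9}$, and verifies the
balance identity at every converged fit.

### Sign conventions

The canonical form above models $P(t \ge j)$. Most off-the-shelf
cumulative-link fitters (e.g. `MASS::polr`) model $P(t \le j) =
\sigma(\zeta_j - \beta x)$, so $\alpha_U = -\zeta_1$, $\alpha_Y =
-\zeta_2$ and the slopes coincide. A sign slip here silently inverts
every threshold, so the conversion is pinned by a dedicated test against
`polr`.

### Likelihood maximization

The likelihood is maximized in-package rather than through a wrapper, so
the parameterization is never ambiguous. The cutpoint ordering is
enforced by optimizing over $(\alpha_U, \gamma, \beta)$ with $\alpha_Y =
\alpha_U - e^{\gamma}$: BFGS with analytic gradients, followed by Newton
polishing to a gradient norm of $10^{-8}$ (relative to $1 + |\ell|$ as a
floor for large samples), with up to three jittered restarts. Standard
errors come from the inverse observed information evaluated in the
natural parameterization. The intercept-only log-likelihood has the
closed form $\sum_j n_j \log(n_j/n)$.

Degenerate inputs are routed, not forced through the optimizer:

* **No Yes responses** (never-treat): threshold assigned as
  $(\max_i r_i + 1)/2$ — between the highest risk presented (too low to
  trigger treatment) and certainty.
* **No No responses** (always-treat): the assignment rule above only
  covers never-treaters; we adopt the symmetric mirror
  $\min_i r_i / 2$ and tag it `always_treat`, since threshold
  distributions do show a left tail of near-universal treaters.
* **Only Unsure**: no balance point is identifiable; the threshold is
  reported `undefined` rather than imputed.
* **Only No and Yes**: binary logistic regression; the threshold is the
  $P = 0.5$ point $-\alpha/\beta$, the same balance definition in the
  two-category limit.
* **Complete separation** (all sub-Yes risks strictly below all Yes
  risks, or $|\hat\beta| > 10^4$ per unit risk): every point in the
  empirical gap maximizes the likelihood, so the symmetric
  representative — the gap midpoint — is returned with an explicit
  `separation_midpoint` tag. Fits with $\beta \le 0$ are returned with a
  warning, not an error: they signal recommendations that decrease with
  risk and deserve inspection, not silent failure.

Risk enters the regression as a proportion by default, but the estimator
is unit-agnostic: the likelihood is invariant under affine maps of risk,
so fitting percent-scaled risks returns exactly $100\times$ the
proportion-scale threshold (property-tested to $10^{-6}$).

### Diagnostics

Each regression-based fit reports the Nagelkerke pseudo-$R^2$,
$$R^2 = \frac{1 - \exp\{(2/n)(\ell_0 - \ell_1)\}}
             {1 - \exp\{(2/n)\,\ell_0\}},$$
and the concordance index: over all case pairs with different collapsed
categories, the fraction where the higher category carries the strictly
higher risk, ties counting one half (equal to the ROC area for binary
responses). Both are checked against brute-force oracles — an
independent grid-plus-polish maximization of the same likelihood on
6-observation fixtures, and exhaustive pair enumeration.

## Synthetic cohorts and physicians

The package ships generators for both sides of the survey it emulates.

**Cases.** Each risk factor is drawn independently from its marginal:
truncated normals for the continuous factors (truncation by rejection
resampling, never clipping — clipping would pile probability mass on the
eligibility bounds; an attempt cap of 10,000 turns unsatisfiable bounds
into an explicit error naming the factor), Bernoulli diabetes,
categorical gender (carried but unused by the risk model). Correlations
among factors are deliberately not modelled. The shipped
`population.yaml` values are *illustrative*, not the source trial's
statistics, and every bound is optional because eligibility rules vary.

**Risk model.** A configurable weighted sum through either a logistic
link or a survival form $1 - S_0^{\exp(lp)}$; which form a given
published calculator uses varies, so both are supported and the choice
is configuration. The shipped coefficients are tuned only so the derived
risk distribution is right-skewed with mean near 0.14, matching the
shape a real ocular-hypertension cohort exhibits; the cohort is
summarized by a moment-matched log-normal
($\sigma^2 = \log(1 + v/m^2)$, $\mu = \log m - \sigma^2/2$), whose round
trip is exact to $10^{-12}$ relative error.

**Physicians.** Latent thresholds are i.i.d. Beta(2.56, 9.14) by
default — a right-skewed population with mean ≈ 0.22 and mode in the
0.10–0.20 range — and responses are drawn from a 7-category
proportional-odds model with cumulative logits $\beta(r - r^*) + s_j$.
The offsets $s_2 > \dots > s_7$ (default $(3, 1.5, 0.5, -0.5, -1.5,
-3)$) are symmetric about zero with $s_3 = -s_6$, which makes the
collapsed-scale balance point equal $r^*$ *exactly* — the generative
identity that makes recovery testable. Real respondents were never
simulated this way, of course: the generator assumes symmetric hedging
around the threshold, no fatigue, no ordering effects, and a per-case
response that depends on risk alone. Passing recovery tests therefore
demonstrates correctness of the estimator under the model, not
robustness to human response quirks.

## Population analysis

Physicians who treat on an IOP cutoff alone are screened out before
estimation (they are not using overall risk). Per-physician thresholds
are pooled by a maximum-likelihood beta fit (moment-matched starting
values; standard errors from the observed information; checked against
a dense grid-search oracle to $10^{-4}$). Assigned never/always-treat
thresholds are included by default, mirroring the inclusion of assigned
values in the population distribution; values at 0 or 1 are nudged
inward by $10^{-6}$, and regression balance points falling outside
$[0, 1]$ (a physician whose threshold sits beyond the presented risks)
are clamped before the fit. The population summary reports the mean
threshold, a histogram of bin width 0.05 — fine enough to resolve a
10–20% modal band — the modal bin, and a method tally.

## Problem sizes and reproducibility

All simulation is seeded; the pipeline derives per-stage substreams from
one global seed so stages can be rerun independently, and a rerun with
an identical configuration is byte-identical (manifest-verified). The
test suite's chosen problem sizes: 50-case cohorts for pipeline checks
(matching the survey design the package emulates), 2,000 observations
for single-fit parameter recovery, 100 replicates of 500 cases for the
threshold-recovery study (mean absolute error ≤ 0.02 at discrimination
40), 50,000 draws for beta-shape recovery, and a 200-physician ×
200-case end-to-end study. The end-to-end study uses a wide-coverage
population configuration (risks spanning most of the unit interval)
rather than the illustrative cohort config, because shape recovery
requires case risks to cover the threshold support — with risks
concentrated near 0.14, upper-tail thresholds would be estimated only by
the assignment rule.

## Known limitations

* Factors are drawn independently; real risk-factor correlations (e.g.
  IOP with CCT) are absent, so the simulated risk distribution is
  narrower than a fully realistic cohort's.
* The estimator conditions on the risk model being correct; risk-model
  misspecification translates directly into threshold bias.
* The proportional-odds assumption (one slope across both cutpoints) is
  not tested per physician; strong violations would surface as poor
  pseudo-$R^2$ rather than as an explicit flag.
* Thresholds for never/always-treat physicians are assignments, not
  estimates; population fits including many of them inherit that
  convention.
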