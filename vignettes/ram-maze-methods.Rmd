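---
title: "Methods: radial-arm-maze analysis of bee spatial working memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radial-arm-maze analysis of bee spatial working memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramforage)
```

## The assay and the question

An open-field radial-arm maze (RAM) for bees presents eight artificial
flowers equally spaced on a circle in a vertical plane. Each flower holds a
single sucrose reward that is not refilled within a bout, so a forager
maximises intake by visiting all eight flowers while avoiding the ones it
has already drained. A *revisit* to a drained flower is a spatial
working-memory error. The package implements the complete analysis for such
assays: per-bout performance statistics, Monte Carlo null models that ask
whether observed performance could arise without memory, diagnostics for
stereotyped movement, a synthetic dose–response experiment generator, and
an information-theoretic inference stage for treatment effects.

## Geometry and performance statistics

Flower 1 sits at the top of the circle and ids increase clockwise; all file
formats use 1-based ids. The labelling origin is a convention only — the
stereotypy diagnostics depend on relative geometry, and the suite checks
that rotating the labels together with their positions leaves the
vertical-bias correlation unchanged.

Four statistics summarise a bout:

* **total revisits** — visits to flowers already visited in the bout;
* **correct choices before the first revisit** — the length of the initial
  duplicate-free run;
* **correct choices in the first eight visits** — novel flowers among the
  first eight choices; *missing*, not zero, for bouts shorter than eight
  visits (downstream models drop such records and report the count);
* **time per visit** — bout duration divided by the number of visits,
  modelled on the log scale.

On the last point the source material is internally inconsistent (duration
per *visit* in one place, per *revisit* in another); division by total
visits is adopted because the per-revisit quantity is undefined in an
error-free bout. `time_per_visit(..., per_revisit = TRUE)` exposes the
alternative.

For the survival analysis of *when* the first error occurs, the event time
is the choice index of the first revisit (so `time = correct before first
revisit + 1`, and the earliest possible event time is 2). A bout with no
revisit is right-censored at choice 8, regardless of whether the bee went
on to complete the maze — the censoring convention is applied uniformly
because a bee that found all eight flowers without error has simply not
yet made an error by its eighth informative choice.

## Null models

Two Monte Carlo null models generate reference distributions for the three
count statistics.

**Chance (C).** Every choice, including the first, is uniform over all
eight flowers. Self-transitions are allowed — the literal reading of "every
flower equally likely"; `chance_policy(exclude_current = TRUE)` gives the
uniform-over-the-other-seven variant since reasonable protocols differ.
The default has closed-form expectations that the suite and the acceptance
script verify against simulation:

* expected total revisits: the coupon-collector mean minus the eight
  successes, $8 H_8 - 8 \approx 13.743$;
* expected correct in the first eight: the occupancy mean
  $8\,(1 - (7/8)^8) \approx 5.251$;
* expected correct before the first revisit:
  $\sum_{k=1}^{8} \prod_{j=0}^{k-1} \frac{8-j}{8} \approx 3.245$.

**Chance plus stereotypy (C+S).** Real bees favour adjacent flowers and
upward flight, which inflates maze performance without any memory. The
stereotyped policy draws each move from an empirical 8×8 transition matrix
pooled over observed bouts (`estimate_transition_matrix()`), crucially
*ignoring* whether the target was already visited. The first choice is
drawn from the pooled empirical first-choice distribution (uniform is the
fallback); self-transitions are neither added nor filtered — the matrix
reflects whatever the supplied data contain. Unobserved rows fall back to
uniform with a warning when no pseudocount is supplied.

Observed means are compared to null means with a two-sided Student-t
interval on $n-1$ degrees of freedom (a percentile bootstrap is available
via `type = "bootstrap"`); the interval type on the observed mean is a
declared choice, as is the convention that the total-revisits comparison
uses only bouts that covered all eight flowers while the other two metrics
use all bouts.

The simulation core is compiled (a small C++ loop driven by R's RNG), so a
million-iteration null costs seconds and results are bit-reproducible for
a fixed seed. A hard cap of 10,000 visits per bout guarantees termination
for pathological matrices such as absorbing cycles that never reach some
flower; cap-hit bouts are flagged incomplete with a warning.

## Stereotypy diagnostics

`contiguity_preference()` reports the proportion of transitions landing on
an angularly adjacent flower against its chance expectation (2/8 with
self-transitions, 2/7 without). `vertical_bias()` pairs each of the 16
directed neighbour transitions with its travel angle from vertical
(0° = straight up) and rank-correlates frequency with angle; a strongly
negative Spearman rho indicates a preference for flying upwards between
adjacent flowers. Directed pairs with frequencies normalised by all
transitions are the default; an undirected 8-pair variant (angles folded
into [0°, 90°]) and row-conditional frequencies are flags, because the
exact construction behind published values of this statistic is not
specified. Angles are snapped to 10⁻⁹ degrees before ranking so that
geometrically equal chords tie exactly. Spearman's rho is computed as the
Pearson correlation of mid-ranks and errors on constant input.

## The synthetic experiment generator

No raw behavioural data accompany the motivating study, so the generator
produces complete experiments with the same design and the statistical
structure the analysis assumes: 7 colonies; 61 bees in four acute-dose
groups (0 / 0.091 / 0.377 / 2.5 ng per bee; n = 16/14/16/15); thorax
widths from a truncated normal (mean 5.45 mm, sd 0.35, bounds 4.4–6.2 mm,
bracketing the published 4.51–6.07 mm range); ten training bouts and one
post-exposure test bout per bee.

Behaviour is driven by a *memory policy*: with probability $m$ the bee
draws its next flower from the base distribution renormalised over
unvisited flowers (perfect avoidance), otherwise from the unmodified base
distribution. The mixture is deliberately simple machinery — it reduces to
chance at $m = 0$ and never revisits at $m = 1$, bracketing real
behaviour. Under a uniform base its expected revisit count has the closed
form $\sum_{k=1}^{7} (1/p_k - 1)$ with $p_k = m + (1-m)(8-k)/8$, which is
what the calibration below uses.

Training follows a saturating trajectory
$m(\text{bout}) = m_{\max}\,(1 - e^{-\text{bout}/\tau})$ with
$m_{\max} = 0.85$, $\tau = 3$, reaching asymptote by bout ten, consistent
with pilot evidence that most bees plateau within ten bouts. Colony
heterogeneity enters solely as a normal random intercept (sd 0.3) on the
logit-memory scale, matching the single random-intercept structure the
statistical models assume.

Exposure degrades the asymptotic memory strength on the logit scale:

$$\mathrm{logit}(m_{\text{test}}) = \mathrm{logit}(m_{\text{train}})
  - \gamma\,\log(1 + d)\,\bigl(1 + \delta\,(s - \bar{s})\bigr),$$

with dose $d$ in ng, thorax width $s$ in mm and $\bar{s} = 5.45$ mm. The
log1p transform gives diminishing returns between the two upper doses (no
dose–response shape is published); a zero dose returns the training value
exactly. The defaults $\gamma = 1.4$, $\delta = 0.5$ were set once, from
the closed-form expectation above, so that a mean-sized high-dose bee
makes roughly three to four times the control group's expected revisits
and the largest bees five to six times — the reported qualitative pattern
("up to five times more revisits", with larger bees hit harder). Per-visit
times are log-normal, $\log t \sim N(\mu_0 + \beta_s (s - \bar{s}),
\sigma)$ with $\mu_0 = \log 25$ s, $\beta_s = -0.335$ (the published
size slope for log time per visit) and $\sigma = 0.3$; bout duration is
the visit count times the per-visit draw. An optional per-visit quit
hazard (default 0) produces incomplete bouts so the completeness filter
has something to act on.

What the generator does *not* emulate — and therefore what passing tests
cannot certify about real data: scent-mark or other non-memory cues,
within-bout movement stereotypy (the base policy is uniform, so synthetic
bees show no contiguity or vertical bias), inter-bout memory carry-over,
motivational drift, and any pharmacokinetics behind the dose effect. The
generator validates the *pipeline*, not the biology.

## The inference stage

For each response the all-subsets candidate set contains exactly five
hierarchical models: basic (constant), size, treatment, treatment + size,
treatment * size, each with the family's random-effect structure:

| response | family | random effects |
|---|---|---|
| total revisits | negative binomial (NB2), log link | colony intercept |
| correct in first eight | binomial, logit link, per-choice | bee in colony |
| log time per visit | Gaussian | colony intercept |
| choice at first revisit | Cox proportional hazards | colony frailty |

Mixed models are fitted by maximum likelihood (never REML, so AICs are
comparable across fixed-effect structures) with Laplace approximation via
`glmmTMB`. The AIC parameter count is: fixed coefficients, plus one per
random-effect variance, plus one NB dispersion or Gaussian residual
variance; for Cox, the number of regression coefficients. Because the
source material never defines its parameter count, absolute AICs are not
comparable to published tables — only the selection *procedure* is.

The Cox models use Efron tie handling throughout (event times are eight
small integers, so ties dominate). How colony should enter a Cox model is
genuinely ambiguous when the design says only that every model "contained
colony as a random effect"; the default is a gamma shared frailty, with
stratification or omission as flags. Since all five candidates share the
same colony handling, the choice cancels in AIC differences. The frailty's
penalised degrees of freedom are excluded from the Cox AIC count for the
same reason.

Selection uses Akaike weights $w_i = e^{-\Delta_i/2}/\sum_j e^{-\Delta_j/2}$.
When two or more models fall within two AIC units of the best (strictly
$\Delta < 2$), coefficients are model-averaged over that best set with
weights renormalised inside it. The default is *conditional* averaging
(each coefficient averaged only over the models that contain it); *full*
averaging, which shrinks by treating absent coefficients as zero, is a
flag, and outputs label which was used. The unconditional standard error
is $\sum_i \hat{w}_i \sqrt{\mathrm{se}_i^2 + (b_i - \bar{b})^2}$, and
intervals are Wald with the normal 0.975 quantile. Non-converged fits are
excluded from selection with a warning rather than imputed; a separated
binomial fit (all successes or all failures) is flagged and its intercept
reported at a ±15 logit clamp.

The size-split re-analysis partitions bees at 5.46 mm thorax width
(≤ vs >), refits the treatment and basic negative-binomial models within
each stratum, and reports ΔAIC(basic − treatment) with treatment
coefficients and Wald intervals. Kaplan–Meier curves of the choice at
first revisit use the product-limit estimator with Greenwood standard
errors, grouped by treatment.

## Numerical conventions and degenerate inputs

* Probability vectors must sum to 1 within 10⁻¹²; transition-matrix rows
  are validated on construction and on CSV read.
* The bout cap is 10,000 visits; cap hits warn and flag incompleteness.
* Empty transition rows fall back to uniform with a warning (pseudocount
  0); a configurable pseudocount smooths all cells.
* Constant vectors make a rank correlation undefined: `spearman_rho()`
  errors, `vertical_bias()` returns `NA` with a warning.
* A bout shorter than eight visits yields missing first-eight statistics,
  never an exception.
* Ties at the ΔAIC = 2 boundary are excluded from the best set (strict
  inequality).

## Problem sizes used by the test and validation suites

The packaged checks run chance-policy nulls at 10⁵–10⁶ iterations
(comparing to the closed forms within three Monte Carlo standard errors),
matrix re-estimation at 10⁵ bouts (L∞ tolerance 0.02), memory-strength
monotonicity at 10⁴ bouts per grid point, and parameter recovery over 50
replicate synthetic experiments at quadrupled group sizes for the planted
dose effect (with a 50-replicate null run at the design's own sizes to
bound spurious selection below 40%). These sizes were chosen to make the
Monte Carlo error small relative to each tolerance.

## Known limitations

* The synthetic bees' base movement is uniform, so the stereotypy
  diagnostics only show strong signals on constructed fixtures, not on
  default synthetic data.
* AIC selection over five models is not a hypothesis test; the null-data
  bound (best model contains treatment in under 40% of replicates) is a
  sanity cap on pathological behaviour, not a size guarantee.
* The Cox frailty AIC convention makes frailty-variance support invisible
  to selection; all candidates share it, so within-set comparisons are
  unaffected.
* Model averaging of hazard ratios exponentiates averaged coefficients;
  intervals are Wald on the log scale.
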