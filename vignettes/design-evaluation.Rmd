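---
title: "Evaluating designs for conveyor-greenhouse experiments"
author: "smartdesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating designs for conveyor-greenhouse experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smartdesign)
```

## The problem

Conveyor-equipped phenotyping greenhouses (Smarthouses) carry plants in
carts arranged in lanes (numbered south to north) and positions within lanes
(west to east). Microclimate is not uniform: air conditioners along the
western side induce a west-to-east trend in growth, and equipment adjoining
the northern end shades the northernmost lanes, depressing growth there.
Experimenters can respond in two ways: relocate plants during the experiment
so that every plant samples many microclimates, or keep plants fixed and
remove spatial effects by blocking and modelling. This package provides the
machinery to compare the two strategies, and to rank candidate designs, on
simulated uniformity trials — experiments with no treatments whose variation
reveals what a design would have to overcome.

## The simulation model

A zone of the house is a 3-lane by 24-position grid of 72 carts. The
expected response of the cart at lane $l$, position $p$ is

$$\mu(l, p) = \mu_z + \beta\,(p - \bar p) + \lambda_l,$$

multiplied by a shade penalty $s \in (0, 1]$ when lane $l$ is shaded. Because
position scores are centered, $\mu_z$ is the prediction at the centre of a
lane. Noise is Gaussian with per-zone standard deviation $\sigma_z$,
optionally with stationary AR1 correlation $\rho$ along positions, and
optionally with iid block effects of variance $\sigma^2_b$ when a blocking
arrangement is supplied (a device for parameter-recovery checks). Gaussian
noise is an assumption, not an observation: single-plant area measurements
are plausibly right-skewed, but the mixed-model framework downstream assumes
normal residuals, so the generator matches it.

Default calibration (units: thousand pixels of day-51 projected shoot area):

* `zone_mean = 71.62` and `zone_sd = 20.2` — a bench-grown wheat zone with a
  plant-to-plant CV of 28%, the middle of the 20–30% band typical for this
  trait at this age;
* `pos_slope = 0.5` per position step — a mild west–east trend that keeps
  the whole-grid CV inside the 20–30% band;
* `lane_effects = 0` — lanes within a 3-lane zone are treated as
  homogeneous, which is what uniformity analyses of such zones show;
* `shade_penalty = 0.75` on shaded lanes, `ar1_rho = 0` — local spatial
  correlation is generated only when asked for, since fitted
  autocorrelation in this setting tends to be weak and unstable.

For scenarios that need a *strong* trend we use `pos_slope = 1.67`. That
value is back-computed from the observation that pooling positions into
error typically moves the residual sd of a fixed-position zone from about 19
to about 22 (a pooled/separated variance ratio near 137%): solving
$\beta^2 \mathrm{Var}(p) = 22.2^2 - 19.0^2$ with 24 positions gives
$\beta \approx 1.67$.

What the generator does **not** emulate: curved (spline-shaped) trends,
greenhouse-phase carry-over, multivariate responses, watering/weighing
events, and heterogeneous within-zone variance during fitting (it can
generate heterogeneous zones, but fits assume a single residual variance).
Passing tests therefore demonstrate that the machinery is correct under a
linear-trend Gaussian world, not that any particular greenhouse obeys that
world.

## Relocation tactics

Four policies move (or do not move) the 72 plants of a zone between the 14
imaging time points:

* **bench** and **same_lane** — fixed positions;
* **half_lane** — the western half of each lane advances to the eastern half
  of the same lane, the eastern half to the western half of the next lane,
  cycling through the 16 half-lane slots of lanes 4–11;
* **next_lane** — whole lanes advance one lane through lanes 12–24, position
  unchanged, lane 24 wrapping to lane 12.

Two conventions had to be fixed where the movement rules leave room:
half-lane groups wrap as intact groups of 12 at the lane-11-east boundary,
and the within-half mapping is order-preserving ($p \mapsto p + 12$ within a
lane, $p \mapsto p - 12$ into the next), which is the physically natural
way to push a belt of carts forward. Moves are uniformly spaced (the real
Monday/Wednesday/Friday calendar is not modelled).

Growth along a schedule is multiplicative on the log scale: over each of the
13 intervals between imagings, log-area increases by a rate times the
occupied cell's relative microclimate multiplier. Accruing growth over
*intervals* (not time points) makes the equal-exposure argument exact: over
14 time points every next-lane plant occupies each of the 13 cycle lanes for
exactly one interval, so a pure lane trend produces identical final values
for all plants regardless of starting lane. Half-lane plants, by contrast,
keep their east–west order, so a position trend is diluted but never
equalized — the mechanism behind the observation that position-swapping
reduces a trend at the cost of inflated plant-to-plant variance.

## Designs and their restricted randomizations

The design menu for $v$ equally replicated lines on 72 carts: CRD, CRD with
a linear position-trend term (CRD+Adj), trend-free design (TFD), RCBD with
replicates of 3 lanes by 12 positions, RCBD with within-block trend
adjustment, trend-free complete-block design with equal slopes, resolved
row-column design, and resolved incomplete block designs with blocks of
3×1, 1×4 and 3×6. All but the CRD are resolved: each replicate tile holds a
complete set of lines.

Optimized designs come from a seeded interchange algorithm: a random scan
proposing swaps within replicates, accepting the first strictly improving
swap, with a fixed budget of 20&nbsp;000 proposals (4&nbsp;000 when
regenerating inside Monte-Carlo loops, where the 72-cell instances converge
long before the budget). Objectives:

* incomplete blocks — sum of squared pairwise concurrence counts, with a
  prohibitive penalty on within-block repeats (started from a cyclic
  repeat-free layout so the constraint holds throughout);
* row-column — sum of squared treatment-by-lane and
  treatment-by-column-index counts;
* trend-free — $Q = \sum_t \left(\sum_{\text{cells of } t} x\right)^2$ over
  centered position scores $x$ (centered per block when blocks exist), with
  early stop at $Q = 0$. $Q = 0$ is *trend-free*; otherwise the best found
  design is *nearly trend-free*.

On exhaustively enumerable instances the optimizer attains the brute-force
optimum (see the test suite); this concurrence-based construction is cheap
and standard, and stands in for specialist design-generation software whose
outputs only matter here through these same structural properties.

Randomization respects each design's construction: CRD and RCBD are fully
re-randomized within their structure; optimized designs get exactly the
allowed moves — whole-layout position reversal with probability 1/2, a
random lane permutation, and permutation of congruent block contents within
replicates — all of which provably preserve $Q$ (reversal negates every
centered score; the permutations shuffle identical score sets). Trend-free
designs can instead be *regenerated* (a fresh optimizer run), which widens
the randomization distribution beyond label swaps. Position reversal is
applied across the whole layout, not per replicate, matching how a reversal
is physically realized on a conveyor.

## Models, REML and degrees of freedom

Null (no-treatment) fits use exact balanced ANOVA method-of-moments
estimators truncated at zero. On the balanced rectangular arrangements this
package constructs, these coincide with nonnegativity-constrained REML — a
fact the tests verify against lme4 — while being exact, fast, and free of
optimizer tolerance. The no-blocking error variance is the plain sample
variance of the 72 observations. REML log-likelihoods are evaluated at the
estimates with a dense-matrix evaluator (numerically identical to lme4's
REML criterion), and variance components are tested with the
boundary-adjusted likelihood-ratio test: the statistic is truncated at zero
and the $\chi^2_1$ tail probability halved, the 50:50 mixture appropriate
when the component sits on the boundary of its parameter space.

Treatment fits with random block terms go through `lme4::lmer` (REML, with
variance components constrained nonnegative by construction), so treatment
predictions combine intra- and inter-block information. Fits without random
terms are ordinary least squares. The inputs to the efficiency criterion are
the variances of all pairwise treatment-prediction differences, which with
treatment-contrast coding depend only on the treatment coefficient
covariance block.

Error degrees of freedom are containment-style: $d = N -
\mathrm{rank}([X\,|\,Z])$, which reproduces the classical ANOVA counts for
orthogonal designs (RCBD with $v = 36$, $r = 2$: $d = 35$). Kenward–Roger
adjusted degrees of freedom are **not** implemented; for designs with much
information recovery (row-column, small incomplete blocks) containment df
are conservative, so the reported efficiencies of those designs are, if
anything, understated. This is a known, deliberate approximation.

## The efficiency criterion

The modified A-optimality criterion is
$AP = F_{1,d,1-\alpha}\,\overline{\sigma^2_{\mathrm{diff}}}$ with $\alpha =
0.05$: the mean pairwise-difference variance, penalized by the F quantile so
that designs that spend df on blocks pay for it. Efficiency relative to a
completely randomized design is $RE_{PDA} = 100 \times AP_{CRD} / AP_{PDA}$.
$AP_{CRD}$ is closed-form ($\overline{\sigma^2_{\mathrm{diff}}} = 2s^2/r$,
$d = N - v$); for an RCBD the exact value uses the randomization expectation
of the error mean square, which equals the pooled within-block mean square
of the null blocked analysis. All other entries are Monte-Carlo: randomize,
overlay, fit, average $\overline{\sigma^2_{\mathrm{diff}}}$ and $d$ over the
sample. Variance components are re-estimated in every Monte-Carlo fit (each
randomization is analysed as its own experiment). Non-converged fits are
dropped with a logged count, aborting beyond 1%; per-iteration seeds are
spawned from one root seed so results are reproducible and order-independent.

Full-scale sampling is 5000 randomizations (1000 with regeneration for
trend-free designs); at that size the Monte-Carlo AP for the RCBD agrees
with the exact value to well within 1%, which is the framework's own
internal consistency check. The analysis scripts default to a few hundred
samples, which leaves Monte-Carlo standard errors of one to two percentage
points of RE — adequate for ranking; the problem sizes in the test suite
(5000 ANOVA fits for the consistency check, 500 simulation replicates for
parameter recovery, 150–300 mixed-model fits per menu entry) were chosen as
the smallest that leave the checked margins comfortably larger than the
Monte-Carlo noise.

## Numerical and degenerate-case choices

* Variance components are truncated at zero (never negative); a zero error
  variance makes relative precision infinite, which is flagged with a
  warning rather than silently returned.
* A group mean of zero makes a CV undefined: flagged `NA`, never dropped.
* Optimizer tie-break: the first strictly improving swap (tolerance
  $10^{-12}$) in a seeded random scan; equal-objective swaps are rejected so
  the trajectory is deterministic given the seed.
* Inestimable models (unequal per-block slopes with one block, saturated
  single-replicate designs) raise explicit errors rather than returning NA
  effects.
* With `v = N, r = 1`, the trend criterion is the constant
  $\sum_i x_i^2$; the optimizer returns it unchanged, as no swap can act.

## Worked example

```{r example, eval = FALSE}
lay <- grid_layout(3, 24)
uni <- simulate_uniformity(make_field(lay, field_params(pos_slope = 1.67)),
                           seed = 2026)
res <- compare_designs(uni, design_menu(36, lay), n_samples = 300,
                       seed = 2026)
res[order(-res$re_percent), c("design", "re_percent", "mc_se")]
```

On a strongly trended zone this ranks the trend-aware strategies (TFD,
TFCBDEqLin, CRD+Adj) and the small-block designs (RIBD1x4, RIBD3x6,
RIBD3x1) above the plain CRD, with the row-column design held back by its
containment df — the qualitative pattern the framework is designed to
expose. Numbers for a specific seed are printed by
`analysis/04_compare_designs.R`.

## Known limitations

* Spline trends, fitted AR1 residuals, heterogeneous-variance fitting and
  covariate adjustment are out of scope; the generator's AR1 and
  heterogeneous-zone options exist to stress the framework, not to be
  estimated.
* Containment df understate the efficiency of designs with strong
  information recovery (see above).
* The uniformity data are synthetic; conclusions about any real greenhouse
  require recalibrating `field_params()` to that house's uniformity data.
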