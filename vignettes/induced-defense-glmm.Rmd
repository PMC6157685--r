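---
title: "Means-parameterized Bayesian GLMMs for induced-defense field experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Means-parameterized Bayesian GLMMs for induced-defense field experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery of **mejaglmm**: the data
model, the five response models and their error structures, the MCMC
protocol and diagnostics, the posterior-contrast significance procedure,
the synthetic-data generator, and the design choices made where more than
one reasonable option existed.

## 1. The experiment the data model encodes

A methyl jasmonate (MeJA) induction experiment on clonal bilberry: ten
blocks, four transects per block (two sprayed with MeJA at the focal ramet,
two water controls, randomized within block), five marked ramets per
transect at distance classes 0–4 from the focal ramet. Each ramet is
censused three times per growing season (about days 0, 30 and 72 of the
treatment year) for three years. Recorded per census: height (cm), stem
diameter at ground (mm), and counts of annual shoots, leaves, insect-grazed
leaves, ungulate-browsed shoots, flowers and berries. Berry counting only
began at the second census of year 1, so `n_berries` is defined as missing
at (year 1, census 1). Ramets die over the years; their later rows keep
`alive = FALSE` with missing measurements, which keeps the panel structure
explicit while models simply drop unusable rows (and count them). Mortality
is absorbing: validation rejects any ramet recorded alive after a death.

The table is long format (one row per ramet per census), the natural shape
for repeated-measures modelling. Calendar dates are not stored; censuses in
later years are mapped onto the same three within-season slots, since exact
dates beyond year 1 are design metadata rather than model inputs.

## 2. Response models

Every model is *means-parameterized*: each treatment-group × year cell has
its own intercept (and, where applicable, within-season slope) on the link
scale, instead of deviations from a reference level. With groups `control`,
`meja_d0` … `meja_d4` and three years this declares 18 intercepts and 18
slopes. The payoff is that treatment effects are plain posterior
differences between cells, with no implicit baseline algebra.

The linear predictor for observation $j$ of ramet $i$ is
$$\eta_j = \alpha_{g(j),y(j)} + \beta_{g(j),y(j)}\,t_j + u_i + \varepsilon_j,$$
with $u_i \sim N(0, \sigma_u^2)$ shared across all of a ramet's
observations (the repeated-measures term) and $\varepsilon_j \sim
N(0,\sigma_\varepsilon^2)$ an observation-level random effect (OLRE)
present only in the binomial/Poisson models, where it absorbs
overdispersion relative to the family variance.

| response | family/link | OLRE | zero-inflation | slope |
|---|---|---|---|---|
| `dry_mass` | Gaussian/identity | – | – | yes |
| `grazed_ratio` | binomial/logit | yes | – | yes |
| `browsed_shoots` | Poisson/log | yes | yes | yes |
| `flowers`, `berries` | Poisson/log | yes | – | no |

Notes on the individual responses:

* **Dry mass** is the nondestructive allometric estimate
  $\log_2 DM = 1.41700 \log_2 DS + 0.97104 \log_2 H + 0.44153 \log_2(AS+1)
  - 7.52070$, applied to raw measured values (mm, cm, counts — the
  calibration study used these units directly). The Gaussian model fits the
  log2-scale value, which is the scale on which the estimator is linear and
  near-normal; effects are therefore log2-fold changes. The absolute
  dry-mass unit of the calibration is not restated here, so outputs are
  labelled "dry-mass units".
* **Grazed ratio** is modelled as Binomial(successes = grazed leaves,
  trials = leaves) with a logit link — the only construction consistent
  with a binomial family for a ratio. Rows with zero leaves carry no
  information and are excluded (and counted).
* **Browsed shoots** mixes a latent per-observation Bernoulli state with
  shared probability $\psi$ ("browsing pressure present") with a Poisson
  count: $p(y) = (1-\psi)\,1\{y=0\} + \psi\,\text{Pois}(y; e^\eta)$.
  $\psi$ is shared across groups; nothing in the design identifies a
  per-group $\psi$ separately from the group rate parameters at this
  sample size.
* **Flowers/berries** are yearly outcomes taken from the last census of
  each year, so seasonal slopes do not exist for them; contrast tables
  and reports show NA in slope cells.

Season time $t$ is coded `0, 0.5, 1` across the three censuses (the
"slot" coding). The censuses are close to equally informative and the slot
coding makes slopes directly comparable across years; a day-proportional
coding (`0, 30/72, 1`, matching the year-1 census days) is available via
`model_spec(..., time_coding = "days")` for sensitivity checks. Neither
coding is asserted as uniquely correct.

The control group is the distance-0 ramet of control transects only:
every comparison is "MeJA group versus the control at distance 0".
Untreated neighbours on control transects stay in the data model but are
excluded from fitting by default
(`include_control_neighbors = TRUE` pools them into the control).

A block random intercept is available (`block_effect = TRUE`) but off by
default: with mortality-driven unbalanced panels the block term tends to
prevent convergence, and the final models rely on the individual random
effect, overdispersion and zero-inflation structure instead.

## 3. Priors

Defaults (see `prior_spec()`):

* intercepts and slopes: Normal(0, precision 0.001), i.e. sd ≈ 31.6 on the
  link scale. The protocol is often quoted as "standard deviation 0.001",
  which in the JAGS `dnorm(mean, precision)` convention denotes the
  *precision*; a literal sd of 0.001 would pin every coefficient to zero
  and contradict the stated intent of uninformative priors. Both readings
  are implemented; the precision reading is the default and the one used
  everywhere in this package's own runs.
* ramet random-effect sd: Uniform(0, 100).
* residual/observation scales: sd ~ Uniform(0, 100) with precision
  $\sigma^{-2}$ by default; the alternative reading (variance uniform,
  precision its reciprocal) is available via
  `prior_spec(scale_reading = "inverse_uniform")`.
* zero-inflation probability: Uniform(0, 1).

`log_prior()` evaluates exactly these densities (returning `-Inf` outside
support), so the prior actually sampled and the prior the code documents
are the same object.

## 4. MCMC protocol and diagnostics

The full protocol (`mcmc_settings("paper")`) runs four chains of 200,000
iterations, discards the first 100,000 (covering sampler adaptation), and
keeps every 20th retained iteration: exactly
$4 \times 100{,}000 / 20 = 20{,}000$ posterior draws per parameter. The
discard count is enforced as a count of *iterations*, independent of the
backend's internal warm-up bookkeeping, so the retained-draw arithmetic is
exact by construction.

Sampling is delegated to JAGS through `rjags`; the package owns the model
construction, priors, monitored-parameter set, seeding and bookkeeping.
Runs are deterministic given the seed: each chain gets a Mersenne–Twister
state derived from it, and initial values are drawn from seed-derived
streams. Initial values use scaled-down distributions (coefficients
N(0, 1), scales U(0.5, 3), ψ U(0.3, 0.9)) rather than the near-flat priors
themselves: a coefficient initialized at sd ≈ 31.6 overflows `exp()` in
the log-link models before the sampler can recover. If initialization
still fails, new values are drawn and the fit retried a few times. For the
zero-inflated model the latent states are initialized all-on, which is
feasible for every observed count.

Monitored parameters are the declared ones: `alpha`, `beta`, `sigma_u`,
`sigma_resid`/`sigma_eps`, `psi` (per-ramet intercepts optionally via
`monitor_ranef = TRUE`); latent per-observation quantities are sampled but
not retained.

Two diagnostics implement the acceptance protocol:

* **Gelman–Rubin** (`gelman_rubin()`): the classic potential scale
  reduction factor $\hat R = \sqrt{\widehat{var}^+/W}$ from between- and
  within-chain variances, accepted at $\hat R < 1.1$
  (`check_convergence()`). Degenerate stuck chains (zero within-chain
  variance, distinct means) report `Inf`. The implementation is
  cross-checked in the test suite against an independent transcription of
  the formula and against `coda::gelman.diag`.
* **Posterior-shape screening** (`posterior_density_report()`): an
  automated stand-in for visual density checks. A kernel density estimate
  of each parameter's pooled draws is scanned for local maxima; peaks
  below 10% of the highest peak are ignored, and two peaks separated only
  by a shallow dip (valley above 90% of the lower peak) count as one mode
  with a shoulder. Parameters with more than one remaining mode are
  flagged. Both thresholds are relative, so the decision is invariant to
  affine rescaling of the draws. The flag is advisory — it marks
  posteriors for inspection and sets the model's manifest status to
  `flagged`, it does not abort a pipeline run.

Desk-scale defaults (`mcmc_settings("test")`: 4 chains × 7,000 iterations,
2,000 discarded, thin 5 → 4,000 draws) are used throughout the examples
and tests; they are the same protocol run shorter, chosen so a full
five-model analysis of the default synthetic dataset completes in minutes
on one core while still passing the R̂ < 1.1 rule for the Gaussian model.

## 5. Posterior contrasts and significance tiers

For each MeJA group, year and component (intercept; slope where the model
has one), the control cell's draws are subtracted from the group cell's
draws *draw by draw* within the joint posterior — parameters are jointly
sampled, so the paired difference is the posterior of the difference, with
all posterior correlation honoured. Cross-pairing independent runs would
discard that correlation and is deliberately not offered.

The report gives the posterior mean difference (positive = higher in the
MeJA group), the fractions of difference draws below and above zero, and a
star tier from $p_{tail} = \min(P(d<0), P(d>0))$: the smallest of
0.001/0.01/0.05/0.1 exceeding $2p_{tail}$ gives \*\*\*, \*\*, \*, (\*),
else `ns`. Whether the historical star convention was one- or two-sided is
ambiguous; doubling the minimum tail matches conventional two-sided star
semantics, and because both raw fractions are always reported, a one-sided
reading can be recovered from any table. Exact zero draws (possible only
in degenerate inputs) are split evenly between the tails. No multiplicity
correction is applied across the many contrasts — each tier is a
per-comparison posterior statement, and readers should weigh the number of
comparisons when scanning a table.

Under a null simulation this procedure behaves like a two-sided test at
its nominal levels: the test suite verifies a tier-\* (or beyond) rate
statistically compatible with 5% over 50 replicate fits, using a
replicate-clustered standard error because the 30 contrasts within one fit
share draws.

## 6. The synthetic-data generator

`simulate_dataset()` draws data *forward from the same generative model
the analysis assumes*: per-ramet intercepts, OLRE deviates and latent
zero-inflation states exactly as in §2, binomial grazing given a
negative-binomial leaf count (mean 20, size 4 — trials vary realistically,
occasionally hitting zero), Poisson browsing/flowers/berries, Gaussian
log2 dry mass. Yearly mortality (hazard 0.1 by default) thins later years,
reproducing the increasingly unbalanced panels of the real design.

Sizes are generated by back-solving the allometric estimator: height is
drawn uniform on 10–25 cm (the height range of marked ramets), shoot count
1 + Poisson(3), and stem diameter solved to hit the simulated log2 dry
mass; solutions outside 0.2–25 mm trigger a resample. Values are rounded
to field precision (0.1 cm, 0.001 mm), which perturbs the stored response
by well under 0.01 log2 units.

The default truth (`scenario_paper_like()`) injects the multiannual
induction pattern this design exists to detect, with link-scale effects at
the treated ramet of realistic published magnitude: insect grazing
suppressed most strongly in year 2 (intercept effect −2.67), ungulate
browsing in year 3 (−1.97), flowers and berries *increased* in year 3
(+1.71, +1.87), smaller effects elsewhere, and neighbour effects decaying
geometrically with distance class (factor 0.5 per class — a plain
monotone stand-in for plant–plant signal attenuation, not a mechanistic
volatile-transport model). `null_scenario()` sets every group equal to the
control, making all true contrasts exactly zero.

What the generator deliberately does **not** emulate: spatial
autocorrelation beyond the block/transect hierarchy, weather-driven year
effects beyond the injected year-specific cells, measurement error in
counts, and within-season survival. Passing recovery tests therefore shows
the estimation machinery is sound under the model's own assumptions — not
that real bilberry data satisfy those assumptions.

## 7. Validation summary (computed by the test suite)

The test suite, not this text, is the source of every empirical claim: the
allometric constants and slopes to printed precision; exact retained-draw
bookkeeping (20,000 for the full protocol, verified arithmetically and on
a 100-iteration dry run); bit-identical reruns under a fixed seed; the
known-variance conjugate toy matched within three Monte-Carlo standard
errors; R̂ < 1.1 for the Gaussian dry-mass fit on the default dataset;
likelihood normalization (including the zero-inflated pmf to 1e-8);
null-scenario tier calibration (50 replicates, 4 blocks, Gaussian
response); and ~95% credible-interval coverage (12 replicates at the
default size) plus sign-pattern recovery of the injected scenario for the
four count-type responses. Problem sizes were chosen so the whole suite
runs in minutes on a single core; they are stated in the tests themselves.

## 8. Known limitations

* A single shared ψ across groups and years; a treatment-dependent
  zero-inflation process is not identifiable here and not offered.
* The OLRE absorbs overdispersion but does not distinguish its sources
  (aggregated herbivore visits vs. measurement issues).
* Contrasts are reported per comparison without multiplicity adjustment.
* The multimodality screen is a heuristic; it catches separated modes and
  obvious shoulders, not every pathological posterior shape.
* The sampler backend is single-threaded JAGS; paper-scale runs of the
  overdispersed Poisson models take hours, which is inherent to the
  protocol, not to this implementation.
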