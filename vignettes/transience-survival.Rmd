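---
title: "Estimating spatially structured survival from ringing data with transience"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating spatially structured survival from ringing data with transience}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transmark)
```

## The problem

Public ringing schemes accumulate large numbers of capture records without
a designed spatial protocol: licensed ringers mist-net where and when they
can. Two features of such data dominate any survival analysis. First,
effort is wildly uneven, so locations must be screened by realized capture
effort before they can support a capture-mark-recapture (CMR) model.
Second, mist-netting at reed-bed edges catches many birds that are merely
passing through. These *transients* have effectively zero probability of
being re-encountered, and ignoring them biases apparent survival downward.

`transmark` implements a complete pipeline for this situation: record
validation, effort filtering and spatial pooling, encounter-history
construction, a directional test for transience, a hierarchical
three-state CMR model fitted by MCMC, and derived site- and group-level
survival summaries. A synthetic-data generator with exactly the model's
statistical structure makes every stage testable without access to any
scheme's raw data.

## Data preparation rules

* **Effort.** The effort of a location (an exact coordinate pair) is the
  number of distinct calendar dates with at least one capture there over
  the study window. Only locations with at least `min_effort_days`
  (default 24) are retained. Because a species-filtered record file cannot
  show days on which a station operated but caught nothing of the focal
  species, this is a lower bound on true ringing effort; the threshold
  should be read as "at least this many productive days".
* **Pooling.** Every record within `pooling_radius` (default 0.17 decimal
  degrees) of a retained location is assigned to the nearest one; records
  outside all radii are dropped with a logged count. The default distance
  is Chebyshev -- max(|dlat|, |dlon|) -- because a radius quoted in
  minutes "South and East" describes a box; Euclidean is available via
  `distance_metric`. Ties go to the smaller distance, then the lower site
  id. Locations that are mutually within the radius and belong to the
  same vegetation unit are merged into one site through an explicit merge
  map (vegetation-unit membership comes from GIS sources we deliberately
  do not re-implement, so the merge is configuration, not inference).
* **Occasions.** An occasion is one August-July year (configurable
  boundary month). All captures of a bird within an occasion collapse to
  a single detection. Birds first captured at the final occasion carry no
  information after conditioning on first capture and are excluded with a
  logged count. Non-adult records are dropped at read time: age
  classification in the source scheme is not modelled here, so this is a
  stated policy, not an inference.
* **Migratory split.** Sites strictly south of `migratory_latitude`
  (default -26) are classed migratory; a site exactly on the threshold is
  sedentary. The underlying biology is a gradual transition, so the strict
  inequality is only a documented tie-break.

## The three-state model

Each bird is in one of three latent states after its first capture:
**Initial** (just marked), **Resident**, or **Dead** (which absorbs
permanent emigration -- survival is *apparent* survival). Over the
interval following release, an Initial bird becomes a Resident with
probability `phi * psi` and otherwise leaves the risk set; Residents
survive each interval with probability `phi`:

|            | Initial | Resident  | Dead          |
|------------|---------|-----------|---------------|
| Initial    | 0       | phi * psi | 1 - phi * psi |
| Resident   | 0       | phi       | 1 - phi       |
| Dead       | 0       | 0         | 1             |

Only Residents can be detected, with recapture probability `p`. The
residence probability `psi` is constant over time but site-specific;
transients are the complement `1 - psi` of newly marked survivors.

Survival and recapture are modelled hierarchically on the logit scale:

* `logit(phi[s, t]) = mu + eta[s] + eps[t]`, with `eta[s] ~ N(0,
  sigma_space^2)` site effects and `eps[t] ~ N(0, sigma_time^2)` year
  effects (one per interval `t -> t+1`: 11 intervals for 12 occasions,
  the minimal identifiable choice);
* `logit(p[s, t]) = beta + gamma[s, t]`, with a single site-by-occasion
  random effect `gamma ~ N(0, sigma_gamma^2)` for recapture occasions
  `2..T` (sparse ringing data cannot support separate spatial and
  temporal recapture effects). Recapture at a bird's first occasion is
  not defined: the model conditions on first capture.

Priors are noninformative: U(-5, 5) for `mu` and `beta`, U(0, 1) for each
`psi[s]`, U(0, 5) for the three standard deviations.

### Marginalized likelihood

Rather than sampling the latent states, `transmark` computes the exact
marginal probability of each encounter history by a forward recursion
over the three states (a hidden-Markov filter), implemented in C++ with
per-step normalization so long histories cannot underflow. Marginalizing
makes the likelihood a deterministic function of the parameters, which
(a) decouples the model from the sampler and (b) lets the test suite
check the recursion against brute-force enumeration of all latent state
sequences -- agreement to a relative 1e-10 is part of the acceptance
suite. Identical histories within a site are collapsed to unique patterns
with counts, which is the sufficient structure of the likelihood and the
main computational win on sparse data. Boundary parameter values that
make an observed history impossible yield `-Inf`, never an exception.

With `psi = 1` the model reduces exactly to Cormack-Jolly-Seber; the
suite verifies that likelihood differences agree with the independent
product-multinomial m-array factorization to 1e-8.

## Transience test (3.SR)

For each occasion, birds detected there are cross-classified newly versus
previously marked against re-encountered later versus never. Per
informative table (no zero margin) the Pearson chi-square statistic is
computed without continuity correction and signed positive when newly
marked birds are re-encountered *less* than expected; the components are
combined with equal weights, `Z = sum(z_i)/sqrt(M)`, and referred
one-sided to a standard normal. Equal weighting is a documented choice:
it keeps the null distribution exactly standard normal and the
calibration testable by simulation, at the price of not being guaranteed
numerically identical to other software's weighting. Tables with a zero
margin are skipped rather than continuity-corrected for the same reason.
By default all sites are pooled for the test, matching how the model's
transience structure is motivated; a per-site test is available via
`subset_histories()`.

The calibration/power simulations use a single site, 12 occasions, 500
individuals, survival 0.67, and recapture 0.3. Recapture 0.3 rather than
the sparse 0.12 regime is deliberate: the chi-square reference
distribution needs adequate expected cell counts, and at recapture 0.12 a
500-bird study yields nearly empty previously-marked rows (the regime in
which the test is used in practice pairs sparse recapture with
several-thousand-bird samples). At these settings the one-sided test
holds its 5% level and detects a residence probability of 0.5 with power
above 0.9.

## Sampler

`run_mcmc()` is an adaptive random-walk Metropolis-within-Gibbs sampler
over all scalar parameters, written in C++. Standard deviations are
proposed on the log scale and `psi` on the logit scale (with the
corresponding Jacobians); `mu`, `beta` and the random effects are updated
on their natural scales. Proposal scales adapt toward an acceptance rate
of 0.44 in windows of 50 sweeps **during burn-in only**, so the retained
draws come from a fixed, detailed-balance-preserving kernel. Chains are
initialized from the priors: with uniform hyperpriors this guarantees
support and gives genuinely overdispersed starting points for the
Brooks-Gelman-Rubin diagnostic (`rhat()`, classic PSRF). Updating a
site-local parameter re-evaluates only that site's likelihood; the three
SDs touch only their prior terms.

Defaults are 3 chains of 20,000 iterations, burn-in 10,000, thinning 10
-- a scaled-down protocol suitable for simulation studies at the package's
default problem sizes; a full analysis of a 12-year multi-site dataset
would use the `iterations = 1e5, burn_in = 5e4, thinning = 20` protocol
via `run_config()`. Non-finite likelihood at initialization triggers a
bounded number of re-draws, then fails loudly.

Summaries are posterior means with central 95% equal-tailed credible
intervals. Survival-type quantities are transformed per draw
(`invlogit` before averaging), never by transforming the summary of the
logit -- the Jensen gap between the two is real and tested. SDs are
reported on the logit scale, as is conventional for these models.

## Derived quantities

* `site_mean_survival()`: per draw, the mean over intervals of
  `invlogit(mu + eta[s] + eps[t])` -- a period-average on the probability
  scale, matching how multi-year site survival is usually reported.
* `group_mean_survival()`: per draw, the *unweighted* mean over member
  sites (rainfall regimes, migratory versus sedentary, and so on).
  Unweighted is a choice: capture-weighted means would let one
  well-sampled site dominate a group.
* `seasonality_score()`: APCV + MAT + MAFD, binned below 50 / 50 to 80 /
  80 and above (half-open intervals, configurable breakpoints). A missing
  covariate makes the score undefined; the site is reported as such, not
  dropped silently. When a table carries reported bin labels,
  `score_sites()` flags disagreements between the labels and the stated
  rule instead of guessing which is authoritative: in the motivating
  climate table three units are labelled low although their printed
  covariates sum into the intermediate bin, and the package surfaces
  exactly that.
* `latitude_association()`: per draw, the Pearson correlation between
  logit site survival and latitude. This is exploratory plumbing (no
  formal trend model); draws with zero cross-site variance are excluded
  with a count.

## Synthetic data

`simulation_scenario()` defaults describe the regime the package is
designed for: 16 sites spanning 21-34 degrees south, 12 annual occasions,
435 new adults per site (about 7,000 birds), true mean survival 0.67,
spatial SD 0.70, temporal SD 1.08, mean recapture 0.12, recapture SD
1.21, and residence probabilities spanning 0.25-0.86 across sites. First
captures are assigned uniformly over occasions 1 to T-1 because public
schemes have no designed entry schedule. `simulate_records()` expands
each detection into 1-3 dated records, mostly at the site center (so the
center accumulates effort) with a configurable fraction jittered within
90% of the pooling radius, and appends decoy locations with 23 distinct
capture dates -- one below the default effort threshold -- far outside
all radii. Preprocessing the generated records reproduces the generating
encounter histories exactly, which is itself an acceptance test.

What the generator does *not* emulate: unequal per-site sample sizes,
age misclassification, within-season robust-design structure, gradual
(rather than permanent) emigration, and ring loss. Passing recovery
tests therefore demonstrates correctness of the implementation under the
model's own assumptions, not robustness to their violation in real
ringing data.

## Problem sizes and numerical choices

The test suite exercises, among others: the likelihood oracle on 1,000
random parameter draws (histories up to 6 post-release occasions);
probability conservation over all detection patterns; a reduced-model
check where the sampler posterior must match a 201 x 201 trapezoid-grid
posterior within 0.01; ten recovery replicates at 8 sites x 10 occasions
x 150 birds per site requiring 95% CRI coverage of the generating `mu`,
`sigma_space` and `beta` in at least 8 of 10 and PSRF < 1.1 for all
top-level parameters; 500 null and 500 alternative 3.SR simulations; and
a prior-recovery run with zero individuals (60,000 iterations, cheap
because the likelihood is empty) whose SD posteriors must be
indistinguishable from U(0, 5) by a Kolmogorov-Smirnov test.

Tie-breaks and degenerate cases are all explicit: equidistant records go
to the lower site id; a site exactly on the migratory threshold is
sedentary; `sigma = 0` has prior density `-Inf` (the uniform-on-SD prior
is absolutely continuous); a transience table with any zero margin is
uninformative; zero within-chain variance makes the PSRF `NA` with a
warning rather than `Inf`.

## Limitations

* Effort is species-filtered (see above); with access to full scheme
  effort logs the filter should use those instead.
* The recapture model shares one random effect across sites and
  occasions; strongly site-structured detection would need a richer (and
  data-hungrier) model.
* `psi` is time-constant per site; a pulse of transients in one year
  would be absorbed partly by `eps`.
* The sampler is single-scalar Metropolis-within-Gibbs: robust and
  testable, but for much larger models a joint or gradient-based sampler
  would mix faster.
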