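# transmark

Hierarchical multistate capture-mark-recapture (CMR) models for
estimating apparent survival of ringed birds from public ringing-scheme
data, with explicit handling of **transience** — birds captured once
while passing through, which otherwise bias survival downward.

## Who this is for

Analysts of ringing/banding data collected without a designed spatial
protocol: many locations, uneven effort, sparse recaptures, and a need
for site-level and regional survival estimates. The package covers the
whole path from raw capture records to posterior survival summaries, and
ships a synthetic-data generator with exactly the model's statistical
structure so every stage is testable.

## The model

Each bird, after first capture, occupies one of three latent states —
Initial, Resident, Dead — with transition matrix

|          | Initial | Resident | Dead      |
|----------|---------|----------|-----------|
| Initial  | 0       | φψ       | 1 − φψ    |
| Resident | 0       | φ        | 1 − φ     |
| Dead     | 0       | 0        | 1         |

where φ is apparent survival and ψ the (site-specific, time-constant)
residence probability; 1 − ψ of newly marked survivors are transients.
Only Residents are detectable, with recapture probability p. Survival
and recapture are hierarchical on the logit scale:

    logit(φ[s,t]) = μ + η[s] + ε[t],   η[s] ~ N(0, σ²_space),  ε[t] ~ N(0, σ²_time)
    logit(p[s,t]) = β + γ[s,t],        γ[s,t] ~ N(0, σ²_γ)

with priors U(−5, 5) on μ and β, U(0, 1) on each ψ[s], U(0, 5) on the
SDs. The likelihood marginalizes the latent states exactly (a forward
recursion, in C++) and the posterior is sampled by an adaptive
Metropolis-within-Gibbs sampler; convergence is monitored with the
Brooks-Gelman-Rubin diagnostic. The directional z-test for transience
(3.SR) motivates the three-state structure from the data themselves.

## Worked example

Simulate a 4-site, 10-occasion study with known truths (overall survival
0.67, spatial SD 0.7, mean recapture 0.12, residence 0.4–0.9 by site),
test for transience, and fit the model:

```r
library(transmark)

scenario  <- simulation_scenario(seed = 1, S = 4, T_occ = 10,
                                 n_per_site = 200,
                                 psi = c(0.4, 0.6, 0.7, 0.9))
histories <- simulate_histories(scenario)
histories
#> Encounter histories: 800 individuals x 10 occasions, 4 site(s)
#>   recaptured at least once: 138

test_3sr(transience_tables(histories))
#> Directional z-test for transience (3.SR)
#>   informative tables: 8
#>   Z = 2.536, one-sided p = 0.005613

fit <- run_mcmc(histories, run_config(seed = 2))
site_survival_summary(fit)
#>   site_id mean lower upper
#> 1       1 0.70  0.48  0.93
#> 2       2 0.75  0.64  0.87
#> 3       3 0.74  0.53  0.97
#> 4       4 0.94  0.84  1.00

group_mean_survival(fit, c(1, 2))     # e.g. a rainfall-regime group
#>   mean lower upper    n
#> 1 0.73  0.59  0.87 3000
```

The transience test rejects the no-transients null (Z = 2.54, one-sided
p = 0.006), as it should for data generated with ψ < 1. Site survival
summaries are posterior means of the per-draw period-average survival
invlogit(μ + η[s] + ε[t]) with central 95% credible intervals; group
means average member sites per draw, unweighted. True per-site means lie
inside these intervals here; with only 4 sites the spatial SD is wide,
which is the expected behaviour, not a defect.

Real data enter through `read_records()` (CSV: `ring_id, date, lat,
lon, age`), `compute_effort()` / `filter_high_effort()` /
`pool_captures()` for the 24-day effort rule and 0.17-degree pooling,
and `build_histories()` for Aug–Jul occasions; `preprocess_records()`
chains them.

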