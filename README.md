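# mediabo

Bayesian-optimization-based iterative experimental design for cell
culture media development.

## The problem

Media optimization — picking concentrations of carbon sources, blend
ratios of basal media, doses of cytokines, the *identity* of a co-feed —
is a search over a mixed continuous/discrete/categorical design space
where every point costs a noisy wet-lab experiment. Classical DoE
schemes (factorials, central composite, Box–Behnken) discretize the
space, scale badly with categorical factors, and cannot plan inside
constrained regions such as blend ratios that must sum to one.

`mediabo` closes the loop instead: fit a Gaussian-process surrogate to
the experiments executed so far, propose the next batch with an
acquisition function that trades exploration against exploitation,
ingest the results, repeat until the model predicts new observations
well or the budget runs out. The package is aimed at groups running
plate-scale campaigns (protein titers in yeast cultivations, PBMC
viability in media blends) and at methodologists who want a testable,
fully simulated version of that workflow.

## The model

Targets are modeled as `y_i = f(x_i) + eps_i`, `f ~ GP(0, k)` on
standardized targets, `eps_i ~ N(0, sigma_i^2)` with the noise variance
**fixed** at the pooled variance of control-condition replicates. The
kernel over an encoded point `z = (x, h)` (continuous block `x` scaled
to the unit box, categorical block `h`) is

```
k_cont(x, x') = Matern_nu( sqrt(sum_j (x_j - x'_j)^2 / theta_j^2) ),  nu in {3/2, 5/2}
k_cat(h, h')  = (sigma / c) * #{i : h_i = h'_i}
k(z, z')      = alpha * (k_cat * k_cont) + (1 - alpha) * (k_cat + k_cont)
```

with length scales `theta`, categorical scale `sigma` and trade-off
`alpha` (initialized at 0.5) learned by multi-start marginal-likelihood
maximization. Acquisition: upper confidence bound `mu + kappa*sd` with
quasi-Newton or constrained refinement for continuous spaces; EXP3
bandit over categories plus Thompson sampling early, and a 10,000-point
brute-force screen later, for mixed spaces; constant-liar batching for
parallel experiments. Transfer learning warm-starts a campaign on an
extended factor space from the previous GP instead of a new space-filling
design. A one-hot-encoding baseline kernel, synthetic landscapes with
certified optima, and a DoE run-count calculator support benchmarking.

## Worked example

A four-factor carbon-source campaign: declare the space, plan a
12-experiment initial design, ingest simulated lab results, inspect the
fitted surrogate, and ask for the next batch of six.

```r
library(mediabo)

space <- design_space(
  design_factor("Glycerol", "continuous", 0, 10, units = "%", phase = "Outgrowth"),
  design_factor("Methanol", "continuous", 0, 10, units = "%", phase = "Production"),
  design_factor("CoFeedType", "categorical",
                categories = c("Ethanol", "Sorbitol", "Rhamnose", "Lactose"),
                phase = "Production"),
  design_factor("CoFeedConc", "continuous", 0, 50, units = "g/L",
                phase = "Production", linked_to = "CoFeedType"))

campaign <- campaign_new(space, acq_config(batch_size = 6, restarts = 4),
                         noise_variance = 0.25)
campaign <- campaign_init(campaign, n = 12, seed = 1)
campaign$ledger
#> # A tibble: 12 x 5
#>   experiment_id Glycerol Methanol CoFeedType CoFeedConc
#>   <chr>            <dbl>    <dbl> <chr>           <dbl>
#> 1 exp_0001          8.16    9.26  Sorbitol        11.3
#> 2 exp_0002          9.51    8.18  Ethanol         40.2
#> 3 exp_0003          3.99    5.46  Rhamnose         2.21
#> 4 exp_0004          8.99    0.853 Sorbitol        22.8
#> # i 8 more rows
```

After running the 12 cultivations, results come back as a tibble of
`experiment_id` + `target` (or replicate columns `rep_1, rep_2, ...`,
averaged on ingest):

```r
campaign <- ingest(campaign, results)   # refits the GP
campaign
#> <bo_campaign> iteration 0, 12 ledger rows (12 executed)
#> <bo_gp> 12 experiments, kernel = mixed (nu = 2.5)
#>   log marginal likelihood: -15.57409
#>   training RMSE: 0.3075224
#>   best target so far: 9.27 (exp_0008)

tidy(campaign$model)
#> # A tibble: 7 x 2
#>   term             estimate
#> 1 theta_Glycerol    756.
#> 2 theta_Methanol    884.
#> 3 theta_CoFeedConc    0.448
#> 4 sigma_cat           1.03
#> 5 alpha               1
#> 6 nu                  2.5
#> 7 noise_variance      0.25
```

The training RMSE (0.31) sits near the injected noise sd (0.5), and the
short `CoFeedConc` length scale with `alpha = 1` says the model already
attributes most structure to the co-feed concentration interacting with
the co-feed type. The next batch concentrates near the emerging optimum
while still probing alternative co-feeds:

```r
campaign <- campaign_suggest(campaign, seed = 2)
dplyr::filter(campaign$ledger, role == "planned")
#> # A tibble: 6 x 8
#>   experiment_id iteration role    Glycerol Methanol CoFeedType CoFeedConc target
#> 1 exp_0013              1 planned    1.77      1.82 Rhamnose        25.2      NA
#> 2 exp_0014              1 planned    7.38      1.83 Sorbitol        48.2      NA
#> 3 exp_0015              1 planned    1.15      1.18 Sorbitol         1.03     NA
#> 4 exp_0016              1 planned    0.655     7.83 Lactose         17.6      NA
#> 5 exp_0017              1 planned    1.58      5.62 Lactose         24.2      NA
#> 6 exp_0018              1 planned    2.47      3.61 Sorbitol        35.7      NA
```

`autoplot(campaign)` shows target distributions per iteration;
`autoplot(campaign$model)` shows predicted-vs-observed with uncertainty.
A command-line wrapper (`inst/cli/mediabo.R`) exposes the same loop as
`init` / `suggest` / `ingest` / `status` / `simulate` / `doe-size`
subcommands over YAML configs, CSV ledgers and JSON state files.

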