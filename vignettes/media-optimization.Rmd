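---
title: "Closed-loop Bayesian optimization of culture media: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop Bayesian optimization of culture media: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mediabo)
```

## The problem

Developing a cell-culture medium means searching a large, mixed design
space: continuous concentrations (carbon sources, surfactants, cytokine
doses), discrete settings with a fixed menu (pH), categorical identity
choices (which carbon co-feed to use), and sometimes hard composition
constraints (blend ratios of basal media must sum to one). Each candidate
medium costs a wet-lab experiment with substantial biological noise, so
exhaustive or factorial designs are rarely affordable.

`mediabo` implements the iterative alternative: a Gaussian-process (GP)
surrogate is fit to all experiments executed so far, an acquisition
function proposes the next batch by trading off exploration of uncertain
regions against exploitation of promising ones, the batch is executed,
and the loop repeats until the model predicts new observations well or
the budget is exhausted.

## The surrogate model

Targets $y_i$ are modeled as $y_i = f(x_i) + \epsilon_i$ with
$f \sim \mathcal{GP}(0, k)$ on standardized targets and
$\epsilon_i \sim \mathcal{N}(0, \sigma_i^2)$. The noise variance is
**fixed**, never optimized: it is estimated as the variance of pooled
control-condition replicates across all iterations including the current
one (population convention, denominator $n$), so replicate scatter in
the controls directly calibrates how much the model is allowed to
disbelieve any single observation.

Over the continuous/discrete inputs $x$ (each min–max scaled to
$[0,1]$) the covariance is a Matérn kernel with per-dimension length
scales $\theta$,
$$k_{cont}(x, x') = \frac{2^{1-\nu}}{\Gamma(\nu)}
\left(\sqrt{2\nu}\, d\right)^{\nu} K_\nu\!\left(\sqrt{2\nu}\, d\right),
\qquad d = \sqrt{\textstyle\sum_j (x_j - x'_j)^2 / \theta_j^2},$$
implemented through the $\nu = 3/2$ and $\nu = 5/2$ closed forms (the
Bessel form above is kept as a numerical cross-check, `matern_bessel()`).
Categorical inputs $h$ use the overlap kernel
$$k_{cat}(h, h') = \frac{\sigma}{c} \sum_{i=1}^{c} \mathbf{1}(h_i = h'_i),$$
the count of matching categories scaled by $\sigma$ and the number of
categorical variables $c$. The two are combined with a learned trade-off
weight $\alpha \in [0,1]$:
$$k(z, z') = \alpha\, (k_{cat} \cdot k_{cont}) +
(1-\alpha)\,(k_{cat} + k_{cont}).$$

Hyperparameters ($\theta$, $\sigma$, $\alpha$) are obtained by
maximizing the log marginal likelihood with multi-start L-BFGS-B;
$\alpha$ is initialized at $0.5$ (equal weight to the additive and
multiplicative combinations) and the length scales at $1$ on the scaled
axes. Training RMSE is logged after every fit. A one-hot-encoding
baseline (`kernel = "ohe"`: Matérn over the continuous coordinates
concatenated with indicator coordinates) is included for comparison; on
category-structured synthetic responses the mixed kernel's held-out
error is at or below the baseline's (the test suite measures this over
20 seeds).

### Defaults and tunables

| parameter | default | meaning |
|---|---|---|
| `nu` | 2.5 with categorical factors, 1.5 otherwise | Matérn smoothness; the overlap kernel composes cleanly with at least twice-differentiable kernels, while the noisier all-continuous blending problem favors the rougher 1.5 |
| `theta` bounds | $[10^{-3}, 10^3]$ (scaled axes) | length-scale search range |
| `alpha` | init 0.5, bounds $[0,1]$ | product-vs-sum kernel weight |
| `restarts` | 10 | optimizer multistarts; closed-loop simulations use 4 (an exposed config field) since refits there happen dozens of times per sweep |
| `noise_variance` | 0, or pooled control variance | fixed Gaussian noise on the raw target scale |
| `kappa` | 2 | UCB exploration weight |
| `screen_size` | 10000 | brute-force acquisition candidate screen |
| `thompson_screen` | 512 | Thompson-sampling candidate screen (see below) |
| `batch_size` | 6 | experiments per iteration |

## Design spaces and initial designs

Spaces are declared factor-by-factor (`design_factor()`, `design_space()`)
and serialize to YAML/JSON. Discrete factors (e.g. pH levels) are modeled
as continuous on $[\min, \max]$ and snapped to the nearest declared level
at suggestion time. A continuous factor may be declared `linked_to` a
categorical one (a co-feed concentration linked to the co-feed type);
the link is reporting metadata only — the kernel operates on the joint
encoding with no special coupling term. A campaign whose history contains
conditions without a co-feed is encoded as concentration zero with an
arbitrary declared type, which the overlap kernel treats consistently.

Iteration 0 uses a Latin hypercube over the continuous factors (each of
the $n$ axis bins holds exactly one point, placed uniformly within its
bin) with independent uniform draws over categories, from a separate RNG
stream so adding categories never perturbs the continuous coordinates.
Spaces with an equality constraint are sampled uniformly instead:
a single sum-to-one constraint over nonnegative ratios is drawn exactly
uniformly via symmetric Dirichlet variables (rescaled, with rejection
against upper bounds); general single-constraint systems fall back to
rejection sampling on the constraint's affine slice.

## Acquisition and batching

All acquisition logic maximizes; minimization targets are negated at the
campaign boundary.

* **Continuous unconstrained spaces** — upper confidence bound
  ($\mu + \kappa\sigma$) maximized by multistart bounded quasi-Newton
  ascent on the encoded unit box.
* **Constrained spaces** — a feasible candidate screen followed by local
  refinement restricted to the constraint's affine slice (one constrained
  coordinate is eliminated; bounds are enforced by penalty). Suggestions
  always satisfy the constraint to within $10^{-6}$.
* **Mixed spaces** — early iterations (through `bandit_until`, default 3)
  pick the category of each batch slot by an EXP3 multi-armed bandit and
  the continuous coordinates by Thompson sampling; later iterations
  switch to a brute-force screen (`screen_size` candidates, LHS over
  continuous axes, uniform over categories) scored by UCB.
* **Batches** — Thompson sampling yields a batch directly (independent
  posterior sample paths). UCB/brute-force acquisition uses the constant
  liar: after each suggestion a pseudo-observation equal to the mean of
  the current training targets is inserted (without re-optimizing
  hyperparameters), deflating the acquisition there so the next batch
  member lands elsewhere.

Bandit rewards are the best target achieved by the chosen category in the
latest batch, min–max scaled over campaign history to $[0,1]$; the EXP3
rate is $\sqrt{2\ln K/(K t)}$ and every arm retains nonzero selection
probability. These reward/rate choices are stated defaults of this
package, not published ground truth.

**Numerical choices.** Thompson sampling needs a joint posterior draw —
a dense covariance and Cholesky factorization over the candidate screen —
so its screen has its own default (512 candidates); a $10^4$-point joint
draw would cost $O(10^{12})$ flops for no practical gain at these
dimensions. Gram matrices get a $10^{-8}$ diagonal jitter before
factorization so replicated conditions (repeated controls) stay
numerically positive definite. Ties in candidate screens break to the
lowest index; every stochastic step takes an explicit seed, and campaign
state reloads reproduce predictions bit-identically (doubles are
serialized as 17-significant-digit strings because decimal JSON numbers
lose the final ulp).

## Convergence

A campaign is judged converged when the model already predicts the latest
batch: an observation agrees when it is within
$2\,(\text{posterior sd} + \sqrt{\text{noise variance}})$ of the
posterior mean, and the batch converges when at least 80% of its points
agree. Both the width and the fraction are configurable — this criterion
is a stated default of the package.

## Transfer learning

When new design factors are added mid-program (`extend_space()`), the
existing experiments are embedded into the extended space with the new
factors fixed at the conditions under which history was generated —
typically the benchmark settings (`embed_history()`) — and the surrogate
refit on the embedded data becomes the prior for the new campaign
(`warm_start_campaign()`). Iteration 0 of the new campaign comes straight
from the acquisition function; no new space-filling design is planned.
New continuous dimensions start at unit length scale on the scaled axis
(smooth but maximally uncertain) before refitting. Because all embedded
rows share the fill values, the added dimensions contribute zero distance
and the embedded model's predictions at historical points equal the
original model's before re-optimization (a property the test suite
checks to $10^{-6}$).

## Synthetic landscapes and what the tests show

The benchmark module generates ground-truth landscapes with certified
optima so the full closed loop is testable without wet-lab data:

* `make_mixed_landscape()` — continuous factors plus one categorical;
  each category has its own radial bump (distinct best location and
  amplitude, one globally best category) over a shared smooth trend.
  The default shape (3 continuous factors, 19 categories) mirrors a
  carbon-source optimization; closed-loop comparisons use a reduced
  2-continuous/4-category instance with budget 36 so 20-seed sweeps run
  in minutes. Optima are certified on a 50-per-axis grid per category
  plus local ascent, so the certificate is resolution-limited only up to
  the polish step.
* `make_simplex_landscape()` — a blend response on the probability
  simplex whose interior optimum strictly exceeds every vertex: the
  structure of a basal-media blending problem where the best mixture
  beats each single medium.
* `make_continuous_landscape()` — an unconstrained multi-bump response
  emulating supplement-dose optimization.
* `make_transfer_scenario()` — paired landscapes sharing structure, the
  extended one adding a mild nuisance dimension, built with wider bumps
  (width 0.3) and 3 categories so that reaching 95% of the optimum is
  attainable within a 30-experiment budget — the regime in which
  warm-vs-cold comparisons are informative.

For the surrogate-recovery check, truths are drawn from the mixed kernel
itself with length scales 0.7 on the scaled axes: at $n = 60$ training
points in a 2-continuous/4-category space the sampling spacing is about
0.25 per category, so a recoverable truth must be smooth relative to
that spacing; rougher truths would measure sample sparsity rather than
the fitting machinery.

These landscapes emulate the *structure* of media-response surfaces —
smoothness, category-dependent optima, simplex constraints, noise — not
the biological magnitudes (viabilities, titers). Closed-loop tests
passing here show the machinery allocates experiments efficiently on
such structures; they do not certify performance on any particular
biological system, where noise may be heteroscedastic, responses
non-stationary, and replicates structured.

## Limitations

* Inequality constraints, nonlinear constraints and conditional
  (hierarchical) factor spaces are out of scope.
* One equality constraint per space is supported for sampling and
  refinement.
* No sparse or GPU-accelerated GP back end: fits are exact Cholesky,
  comfortable to a few hundred experiments.
* The bandit operates on a single categorical variable (as in the
  carbon co-feed case); multiple categorical factors fall back to the
  brute-force screen.
* Batch diversity under the constant liar relies on the lie deflating
  the acquisition; with a very large `kappa` the same region can still
  be re-suggested.

## Reproducing the numbers

The acceptance script recomputes the package's desk-scale quantities from
scratch (campaign ledger accounting, configuration defaults, transfer
budget arithmetic, kernel exactness, designed-kernel vs one-hot error,
closed-loop efficiency, warm-start evaluation counts):

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
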