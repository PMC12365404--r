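---
title: "Estimating donor and recipient straying of hatchery salmon: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating donor and recipient straying of hatchery salmon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Adult Pacific salmon mostly home to their natal river to spawn, but a
fraction disperse ("stray") into non-natal rivers. `cwtstray` estimates,
from coded-wire-tag (CWT) release and recovery records, two complementary
rates for each hatchery programme and return year:

* the **donor rate** — of a programme's recovered fish, the proportion that
  strayed elsewhere: strays / (home + strays), over recoveries at all
  locations;
* the **recipient rate** — of the fish recovered at a hatchery, the
  proportion that originated elsewhere: strays / (local + strays), with
  strays from *any* programme, not only the focal ones.

It then models those rates jointly with a Bayesian zero/one-inflated beta
(ZOIB) hierarchical regression against river-level habitat covariates.

## From tag reads to rates

**Scale and classification.** Homing is judged at the river (sub-basin)
scale. A recovery is *home* if it occurred in the river of release — even
at a different hatchery on the same river; *ambiguous* if it occurred in a
river the group experienced during incubation or rearing but was not
released in; otherwise *stray*. Recoveries in the ocean or in the mainstem
en route, fishery recoveries, and fish from release groups flagged
experimental are *excluded*: those fish had no opportunity to express a
volitional choice of spawning river. Ambiguous recoveries enter neither
the numerator nor the denominator of either rate. Site names are
canonicalized case-insensitively, and anything beyond that must be
resolved by an explicit alias table in the river map — an unmapped site is
an error, never silently a stray.

**Expansion.** Each tag read stands for more fish than itself, for two
reasons: only a fraction of each sample was examined for tags, and only a
fraction of the release group was tagged. The two-step expansion factor is

$$ e = \frac{1}{\text{sampling fraction}} \times
       \frac{\text{tagged} + \text{untagged}}{\text{tagged}}, $$

and all counts in the rate tables are sums of these real-valued expansions
(rounding happens only in final reports, half-to-even). Because both rates
are ratios of expanded counts within one hatchery-year, they are invariant
to any uniform rescaling of the expansion factors — a property the test
suite exercises directly. No correction is attempted for natural or
fishery mortality.

**Missingness.** A hatchery-year with no home-or-stray recoveries yields a
*missing* rate, not a zero: an absence of recoveries is not an observation
of no straying, and conflating the two would contaminate the model's
zero-inflation component, which represents genuine all-home years. A
hypothetical year in which *every* recovery is a stray would give a rate of
exactly 1, outside the model's support; such years are flagged with a
warning and set missing rather than silently retained.

## The zero/one-inflated beta model

Each observed rate $Y_j \in [0, 1)$ (response $k \in$ {donor, recipient},
population $g$) follows the piecewise density

$$ f(y) = \begin{cases}
  p_j & y = 0 \\
  (1 - p_j)\,q_j & y = 1 \\
  (1 - p_j)(1 - q_j)\,\mathrm{Beta}(y;\ \mu_j\phi,\ (1-\mu_j)\phi) & y \in (0,1),
\end{cases} $$

with links

$$ \mathrm{logit}\,\mu_j = \beta_{0,k} + \beta_{1,k} x_j + b_{0,k,g} +
   b_{1,k,g} x_j\ (+\ \epsilon_{k,j}), \qquad
   \log \phi_k = \text{const}, \qquad
   \mathrm{logit}\,p_j = \gamma_{0,k} + \gamma_{1,k} x_j + u_{0,k,g} + u_{1,k,g} x_j. $$

The beta component is parameterized by its mean $\mu$ and dispersion
$\phi = \alpha_1 + \alpha_2$, so the conditional variance is
$\mu(1-\mu)/(1+\phi)$ — an identity the tests verify against large Monte
Carlo samples. One-inflation is disabled by default ($q_j \equiv 0$):
observed rates of exactly one do not occur in these data, and the
component is only kept behind a flag for generality.

Design choices that were genuinely open:

* **Dispersion.** $\phi$ is constant across populations within a response
  (an intercept-only log link). A population-varying $\phi$ is available
  behind `phi_by_population = TRUE` for model-comparison exercises, but it
  converges poorly and is not the default.
* **Observation residual $\epsilon_{k,j}$.** The mean-model link admits an
  observation-level normal residual, but jointly with $\phi$ it is weakly
  identified — both absorb extra-beta variation. It is implemented behind
  `include_eps` and off by default; enabling it without a tight prior on
  its scale invites slow mixing.
* **Random effects.** Intercepts and slopes are mutually independent,
  each $\sim N(0, \sigma^2)$ with its own scale; no correlation matrix is
  estimated, since nothing in the fitted summaries constrains one. Random
  slopes are restricted to covariates that vary annually within a
  population (flow, temperatures, escapement); static river properties
  (area, isolation, distance) cannot support population-level slope
  variation and enter as fixed effects only.
* **Joint fitting.** Donor and recipient responses are stacked with
  response-indexed coefficients; they share the data layout but no
  parameters, and no cross-response correlation is modelled.
* **Priors.** Normal(0, 5) on all logit/log-scale fixed effects and
  half-normal(2) on every scale: vague on the probability scale while
  keeping the sampler away from degenerate regions. These constants live
  in one place in the source and are deliberately easy to change.
* **Standardization.** All covariates are centred and scaled (divisor
  $n - 1$) jointly over the included hatchery-year rows — a single
  centring, not within-hatchery — and the centres/scales are stored so
  that effects can be reported and prediction grids built on original
  units. The temperature contrast is `local - confluence` (positive =
  natal reach warmer than the junction en route).

## Estimation, diagnostics, comparison

The likelihood factorizes over the zero indicator (Bernoulli, logit link)
and the strictly positive rates (beta), so the model is expressed directly
in the BUGS language and sampled with JAGS. Defaults follow the study
design: six chains of 4,000 iterations with the first half discarded
(adaptation happens inside the warm-up). The seed fully determines the
draws, and identical seeds give bit-identical output.

Convergence is assessed with the split-chain Gelman–Rubin statistic
(each chain halved, so within-chain drift is detected as well as
between-chain disagreement), with the conventional < 1.01 threshold;
the fitting pipeline refuses to rank models by LOO if any fit fails it.
Model comparison uses PSIS-LOO — leave-one-out predictive density
approximated by Pareto-smoothed importance sampling, implemented in the
package and validated in the tests against exact leave-one-out refitting —
with paired standard errors on elpd differences and the usual Pareto-$k$
reliability diagnostic. Pointwise log-likelihoods are recomputed in R from
the posterior draws by the same density code the tests verify against an
independent brute-force evaluator.

Posterior-predictive effect curves are built by pushing a covariate grid
through the draws: for an *unsampled* population the random effects are
drawn afresh from their scale hyperparameters at every draw (so the band
carries full between-population uncertainty and is strictly wider), while
a named population uses its own posterior random effects.

## What the synthetic data do and do not emulate

`simulate_rates()` generates data in the exact generative direction of the
model: covariates, population effects, zero indicators, then beta draws.
Its defaults *are* the study conditions — 19 populations by 23 years by
two responses — with covariate marginals echoing the packaged river table
(lognormal for the positively skewed quantities, normal for temperatures)
and true fixed effects anchored at the published posterior medians
(escapement −0.40/−0.43 on the mean sub-model, and so on). Values the
study does not print were fixed once at realistic magnitudes: mean-model
intercepts of −3.2/−3.5 (baseline conditional stray rates of 3–4%),
zero-model intercepts of −0.4 (about 40% structural-zero years, matching
the observed preponderance of zeros), dispersion $\phi = 8$, random
intercept scales 0.8 (mean model) and 1.0 (zero model), random slope
scales 0.3. The generator draws covariates independently across
populations: it does not emulate spatial correlation among neighbouring
rivers, serial correlation in annual covariates, or the donor-recipient
coupling created by real strays arriving somewhere. Passing tests
therefore demonstrate that the estimation machinery recovers the
generative process at the study's dimensions — not that the model is
correctly specified for any particular real watershed.

`simulate_recovery_files()` closes the loop at the file level: it emits
release and recovery records that, pushed through classification,
expansion and rate estimation, reproduce target rates exactly (integer
fish counts are matched by largest-remainder rounding, so targets are hit
exactly whenever `rate × n` is integral), and remain unchanged under
uniform sampling-fraction changes, tagging-fraction changes, and injected
ambiguous or experimental recoveries.

## Numerical notes

* Positive beta draws are clamped to $[10^{-12}, 1 - 10^{-12}]$ so a
  floating-point 0 or 1 cannot leak into the likelihood.
* When pointwise log-likelihoods are evaluated over raw posterior draws,
  pre-convergence excursions can push $\mu$ numerically to a boundary
  where the beta shapes degenerate; $\mu$ is clamped to
  $[10^{-12}, 1-10^{-12}]$ there (and only there — the user-facing density
  functions are strict).
* The generalized Pareto tail fit uses the profile-likelihood
  quadrature estimator with a weak prior pulling the shape toward 0.5;
  smoothed tail weights are truncated at the largest raw weight.
* Quadrature in the density tests uses `integrate()` at a relative
  tolerance of 1e-10 against an acceptance tolerance of 1e-8.

## Problem sizes used by the test suite

The default model settings (6 × 4,000 iterations) are for analyses. The
package's own validation uses smaller, fixed problem sizes chosen to keep
the full suite fast while leaving the checks statistically meaningful:
unit tests fit 2 chains of 400–1,500 iterations on 6–8 populations;
the study-scale recovery checks run 19 × 23 × 2 with 2 chains
(1,000–1,400 iterations), ten seeded replicates for coverage, and a
30-observation toy for exact-LOO agreement. With interval coverage
nominally 0.95, requiring at least 9 of 10 replicate intervals to cover
has about a 9% chance of a false alarm under perfect calibration; the
suite accepts that risk deliberately rather than weaken the check.

## Known limitations

* River assignment is only as good as the supplied river map; the package
  refuses to guess (unmapped sites are errors), which means real RMIS
  extracts need a curated alias table before use.
* The recipient rate is attributed to the hatchery site of recovery by
  default (`scope = "hatchery"`), which distinguishes two programmes on
  one river; a river-level scope is available but cannot make that
  distinction.
* PSIS-LOO is an approximation; observations with Pareto $k > 0.7$ are
  flagged, and the honest fallback is exact refitting.
* The escapement covariate can be supplied externally or derived from the
  package's own CWT expansions; the two need not agree if tagging rates
  vary strongly among programmes.
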