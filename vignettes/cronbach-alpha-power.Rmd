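---
title: "Power for parallel-item scale scores: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power for parallel-item scale scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cronpower)
```

## The measurement model

`cronpower` computes power and sample size for comparisons of
**scale scores** — per-subject sums of `k` questionnaire items — under a
parallel-items measurement-error model. Item `j` of subject `i` scores

$$Y_{ij} = \mu_i + e_{ij},$$

where $\mu_i$ is the subject's latent *true score* with population mean
$\mu$ and variance $\sigma_\mu^2$, and $e_{ij}$ is a mean-zero
measurement error with variance $\sigma_e^2$, independent of $\mu_i$ and
independent across items within a subject. This is a two-level mixed
model: item scores nested in subjects. It implies a compound-symmetry
item covariance matrix $\sigma_e^2 I + \sigma_\mu^2 1 1^T$ — the items
are exchangeable replicates of a single unidimensional construct
(essential $\tau$-equivalence) — with common inter-item correlation

$$\rho = \frac{\sigma_\mu^2}{\sigma_\mu^2 + \sigma_e^2}.$$

Under this structure Cronbach alpha of the `k` items is

$$C_\alpha = \frac{k\rho}{1 + \rho(k-1)},$$

and it coincides with the reliability of the scale score
$S_i = \sum_j Y_{ij}$ (squared correlation of $S_i/k$ with $\mu_i$) and
with the test-retest correlation of $S$ across two administrations that
share $\mu_i$. At $k = 1$ all four quantities — $\rho$, $C_\alpha$,
reliability, test-retest correlation — are one number, which is why a
single-item instrument's alpha can still be *estimated*, via test-retest.

### The fixed true-score-variance assumption

The pivotal modelling commitment is that $\sigma_\mu^2$ is a property of
the population, not of the instrument: improving the items changes
$\sigma_e^2$ only. Then $\sigma_e^2 = (1/\rho - 1)\sigma_\mu^2$ and the
total variance $\sigma^2 = \sigma_\mu^2/\rho$ both *decrease* in $\rho$,
and so does $Var(S) = k^2\sigma_\mu^2/C_\alpha$ — the opposite of the
familiar fixed-total-variance picture in cluster-correlated data, where
correlation inflates the variance of a sum. This is what makes every
power function below increase with $C_\alpha$. For the paired designs
the assumption is actually immaterial (true scores cancel in pre-post
differences); for the cross-sectional two-sample comparison it is
essential.

## The four power functions

All tests are two-tailed at level $\alpha$ with normal critical value
$z_c = \Phi^{-1}(1-\alpha/2)$, effect sizes standardized as
$\Delta = \delta/\sigma_\mu$:

* **Significance of alpha** (`power_alpha_test`): the test-retest
  correlation of $N$ subjects equals $C_\alpha$, so its significance is
  tested through the Fisher z-transformation, with the usual
  $C_\alpha/(2(N-1))$ small-sample mean correction inside the
  non-centrality term. Needs $N \ge 4$.
* **Pre-post** (`power_prepost`): paired comparison in one group of $N$,
  $\varphi = \Phi\{|\Delta|\sqrt{N/(2(1/C_\alpha - 1))} - z_c\}$.
* **Between-group within-group** (`power_between_within`): difference of
  pre-post changes between two groups of $N$ each; same form with
  denominator $4(1/C_\alpha - 1)$ (two independent changes are
  differenced).
* **Two-sample** (`power_two_sample`): cross-sectional group comparison,
  $\varphi = \Phi\{|\Delta|\sqrt{C_\alpha N/2} - z_c\}$.

Each also exists parameterized by $(\rho, k)$ (`power_rho`); the two
parameterizations agree identically after conversion, so power depends
on the instrument only through $C_\alpha$ — a 5-item and a 10-item
instrument with equal alpha buy exactly the same power.

Closed-form inverses give the required sample size
(`samplesize_*`: $N = 2(1/C_\alpha-1)z_{\alpha,\varphi}^2/\Delta^2$ and
its factor-4 and $2z_{\alpha,\varphi}^2/(C_\alpha\Delta^2)$ analogues,
with $z_{\alpha,\varphi} = z_c + \Phi^{-1}(\varphi)$) and the required
item count (`items_required`) when $\rho$ and $N$ are fixed. The
two-sample item count has denominator
$N - 2z_{\alpha,\varphi}^2/\Delta^2$: if $N$ is not above the error-free
requirement no number of items is enough, and the function raises an
infeasible-design error rather than returning a negative count.

## Tunable parameters

| parameter | meaning | units | default |
|---|---|---|---|
| `k` | items per instrument | count | 5 |
| `rho` / `c_alpha` | inter-item correlation / Cronbach alpha | – | required |
| `sigma_mu2` | true-score variance | squared score units | 1 |
| `mu` | true-score mean | score units | 0 |
| `delta` | standardized effect $\delta/\sigma_\mu$ | – | 0 |
| `n` | subjects (total for pre-post/alpha, per group otherwise) | count | required |
| `sig.level` | two-tailed level | probability | 0.05 |
| `nreps` | Monte Carlo replicates | count | 1000 |

`sigma_mu2 = 1` and `mu = 0` are pure conventions — every power quantity
depends only on standardized inputs — and are configurable for users who
want score-unit output from the simulator.

## Numerical and design choices

* **One-tail convention.** The closed forms count only the rejection
  tail on the side of the effect; at $\Delta = 0$ they return
  $\alpha/2$, not $\alpha$. The neglected tail is astronomically small
  for any design worth running, and keeping it out makes the
  power/sample-size pair an exact algebraic inverse.
  `exact_two_sided = TRUE` adds the opposite tail for users who want the
  exact size at the null.
* **Normal, not t.** The closed forms use normal quantiles (variances
  treated as known); the Monte Carlo engine deliberately uses the
  t-tests a practitioner would actually run, so their agreement also
  bounds the normal-vs-t discrepancy (negligible at $N \ge 30$).
* **Rounding.** Sample-size and item-count functions return the
  continuous solution *and* its ceiling; the ceiling is the conservative
  integer choice, and the continuous value is what satisfies the
  inversion identity `power(samplesize(phi)) = phi` to 1e-10.
* **Domain edges.** $\rho = 0$ is accepted by the pure conversions
  ($C_\alpha = 0$) but rejected wherever $1/\rho$ appears (variances,
  paired powers); $C_\alpha = 1$ is rejected by the paired designs
  (degenerate zero-variance differences) but allowed in the two-sample
  formula, where it reproduces the classical error-free normal power.
  Negative *sample* alphas are passed through unclamped — the estimator
  is defined for any covariance matrix even though the population model
  forbids $\rho < 0$.
* **Interaction item count.** Inverting the between-within power
  function for `k` gives numerator factor 4, consistent with its
  sample-size formula; a factor-2 variant of the same expression also
  circulates. `items_required` returns the self-consistent factor-4
  solution (it reproduces the target power on substitution) and surfaces
  the factor-2 value as `k_printed` rather than silently discarding
  either.
* **Degenerate Monte Carlo cells.** With error-free items and no shift,
  difference vectors are constant and the t statistic is 0/0; `run_test`
  returns p = 1 (and p = 0 for a constant non-zero difference) so
  simulation loops stay total. Pooled-variance two-sample tests are the
  default — the model guarantees equal arm variances — with Welch behind
  a flag.

## What the simulator emulates — and what it does not

`simulate_design` draws $\mu_i \sim N(\mu, \sigma_\mu^2)$ once per
subject and independent $e_{ij} \sim N(0, \sigma_e^2)$ per item *and per
administration*; repeated administrations share the subject's true score
exactly. Independence of errors across administrations is the only
reading consistent with the test-retest covariance
$k^2\rho\sigma^2$ — identical errors would force correlation 1.
Intervention shifts are fixed location offsets applied to every item of
the shifted administration or group; between-within groups get
independent true-score draws (distinct subjects).

Replicate seeds are spawned once from a root seed, so a full run is
deterministic and any single replicate can be regenerated in isolation.

The generator is faithful to the model, which means passing tests show
*internal* consistency, not realism. Real questionnaire data are
typically ordinal or binary (Likert), have unequal item variances and
loadings, multidimensional structure, floor/ceiling effects, and
drop-out; none of these are emulated, and for strongly non-normal items
the closed forms hold only through the central limit theorem. The
compound-symmetry assumption itself is strong, and no diagnostic for
departures from it is provided — `cronbach_alpha` will happily summarize
a covariance matrix the model does not describe.

## Validation problem sizes

The test suite validates each closed form against the Monte Carlo
engine on the four benchmark grids (test-retest correlation for alpha
0.1–0.9; the three comparison designs for alpha 0.5–0.9 at two
$(N, \Delta)$ blocks each, $k \in \{5, 10\}$) at 1000 replicates per
cell, bounding $|$empirical $-$ theoretical$|$ by 4 binomial standard
errors; test size at the null is checked at $10^4$ replicates within 3
standard errors of 0.05; simulator moments are checked at $N = 10^5$.
These sizes give Monte Carlo standard errors of about 0.015, 0.002 and
0.003 respectively — small enough that a formula error of a point or
two would be caught, while a full run of the suite stays comfortably
interactive.

```{r example}
# the headline comparison: same trial, better instrument
sapply(seq(0.5, 0.9, 0.1), function(a) power_prepost(0.4, a, 30))
```

## Known limitations

Equal group sizes only; no one-sided tests as a first-class option; no
confidence intervals for sample alpha; no binary/ordinal item models or
GEE-style marginal extensions; no covariate adjustment or
cluster-randomized variants. These are deliberate scope boundaries, not
oversights.
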