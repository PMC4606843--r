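# cronpower

Power analysis and sample-size determination for studies whose outcome is
the **scale score** (per-subject sum) of parallel questionnaire items,
parameterized by the instrument's **Cronbach alpha**.

Clinical trials routinely measure outcomes with multi-item instruments.
Measurement error in the items propagates into the scale score and erodes
statistical power, and at the design stage the one summary of an
instrument's quality that is almost always available is its Cronbach alpha
(coefficient alpha), `C_a`. `cronpower` is for biostatisticians and trial
designers who want power and sample size written directly in terms of
`C_a`.

## The model

Item `j` of subject `i` scores

    Y_ij = mu_i + e_ij,   Var(mu_i) = sigma_mu^2,   Var(e_ij) = sigma_e^2,

with errors independent across items given the subject (a two-level mixed
model; the item covariance matrix is compound symmetric, i.e. the items
are essentially tau-equivalent "parallel" replicates of one construct).
Holding the *true-score* variance fixed, the inter-item correlation
`rho = sigma_mu^2 / (sigma_mu^2 + sigma_e^2)` determines everything:

    C_a = k * rho / (1 + rho * (k - 1))          (k items)
    sigma_e^2 = (1/rho - 1) * sigma_mu^2
    Var(S) = k^2 * sigma_mu^2 / C_a              (S = scale score)

and `C_a` equals both the reliability of `S` and the test-retest
correlation of `S`. For a standardized effect `Delta = delta / sigma_mu`
and two-tailed level `alpha`, the power of the three scale-score
comparisons is

    pre-post (paired, total N):    Phi( |Delta| * sqrt(N / (2 (1/C_a - 1))) - z_{1-alpha/2} )
    interaction (per-group N):     Phi( |Delta| * sqrt(N / (4 (1/C_a - 1))) - z_{1-alpha/2} )
    two-sample (per-group N):      Phi( |Delta| * sqrt(C_a * N / 2)         - z_{1-alpha/2} )

all increasing in `C_a` and independent of `k` given `C_a`. The
significance of `C_a` itself is tested as that of the test-retest
correlation via the Fisher z-transformation. Closed-form inverses give
the required `N` (and, for instrument development, the required number of
items `k`). A parallel-item simulator and Monte Carlo engine reproduce
every power value empirically.

## Worked example

```r
library(cronpower)

# an instrument with 5 items and Cronbach alpha 0.5, pre-post trial,
# 30 subjects, standardized effect 0.4
d <- cron_design("prepost", n = 30, delta = 0.4, k = 5, c_alpha = 0.5)
summary(d)
#> Design: pre-post (paired) comparison
#>   N = 30 (total), two-tailed alpha level = 0.05
#>   standardized effect size Delta = 0.4
#>   instrument: k = 5, rho = 0.1667, Cronbach alpha = 0.5
#>   theoretical power = 0.3406

# power is modest; how many subjects for 80%?
samplesize_prepost(0.4, 0.5, power = 0.80)
#> Required sample size (prepost design): N = 98.11 (total), round up to 99
#>   Delta = 0.4, Cronbach alpha = 0.5, sig.level = 0.05, power = 0.8

# or keep N = 30 and improve the instrument instead
power_prepost(0.4, 0.9, 30)
#> [1] 0.9964018

# check the closed form by simulation
empirical_power(d, nreps = 1000, seed = 1)
#> Empirical power: 0.3490 (MC SE 0.0151, 1000 replicates, seed 1)
#> Theoretical power: 0.3406
```

Raising alpha from 0.5 to 0.9 lifts the power of the same 30-subject
trial from 0.34 to 0.996 — more consistent items buy power that would
otherwise cost 69 extra subjects.

A command-line interface wraps the same functions
(`exec/cronpower convert|power|samplesize|items|simulate|validate`); see
`?cronpower_cli`.

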