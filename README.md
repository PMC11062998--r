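# latdif

Differential item functioning (DIF) analysis for binary item response data
when **neither the comparison groups nor an anchor set is known**. The
intended users are psychometricians and biostatisticians screening survey
questionnaires, patient-reported-outcome instruments, or educational tests
for items that behave differently across unobserved respondent groups —
the canonical example being test speededness, where an unknown subset of
respondents effectively fails end-of-test items.

## Model and estimator

Respondents belong to one of `K + 1` latent classes; given class `k` and a
unidimensional ability `θ`, responses follow a mixture two-parameter
logistic model

```
logit P(Y_ij = 1 | θ_i, ξ_i = k) = a_j θ_i + d_j + δ_jk ,
```

where `δ_jk` is the class-`k` DIF effect on item `j` (a log-odds ratio at
equal ability). The reference class pins the ability scale
(`θ | ξ=0 ~ N(0,1)`, `δ_j0 = 0`); focal classes have free normal ability
distributions `N(μ_k, σ²_k)` and mixing proportions `ν_k`. Parameters are
estimated by L1-regularised marginal maximum likelihood,

```
min over Δ :  −log L(Δ) + λ Σ_jk |δ_jk| ,
```

solved by a generalized EM algorithm whose M-step takes line-searched
proximal-gradient steps (soft-thresholding gives exact zeros). The tuning
parameter λ and the number of classes are chosen by BIC computed on
constrained maximum-likelihood refits of each candidate support; items with
nonzero refitted offsets are the flagged DIF items, and respondents are
classified by the posterior mode (MAP).

## Worked example

Simulate a severe-speededness dataset — 2000 respondents, 20 items, a 25%
latent "speeded" class that effectively fails items 16–20 (offsets drawn
from U(−4.5, −3)) — and run the full selection pipeline:

```r
library(latdif)

sc <- scenario_config(
  N = 2000, J = 20, class_proportions = c(0.75, 0.25),
  class_means = c(0, 0), class_variances = c(1, 1),
  dif_items_per_class = list(16:20), dif_ranges = list(c(-4.5, -3)),
  seed = 11, name = "speeded_synthetic")
sim <- generate_dataset(sc, 13)

sel <- select_lambda(sim$responses, K = 1,
                     controls = em_controls(Q = 21, n_starts = 2, seed = 5))
sel
#> <latdif_selection> K = 1: best lambda = 14.43 (BIC = 44518.6), 5 DIF item(s)
#> # A tibble: 10 × 4
#>    lambda    bic n_nonzero converged
#>     <dbl>  <dbl>     <int> <lgl>
#>  1 24.1   44691.         0 TRUE
#>  2 14.4   44519.         5 TRUE
#>  3  8.65  44532.         7 TRUE
#>  4  5.19  44532.         7 TRUE
#>  5  3.11  44553.        10 TRUE
#>  ...
```

The BIC path shows the no-DIF model (first row) losing clearly to the
5-item support, and denser supports penalised away. The flagged items are
exactly the injected block:

```r
which(sel$dif_items)
#> [1] 16 17 18 19 20

dplyr::filter(tidy(sel$final_fit), parameter == "delta", estimate != 0)
#> # A tibble: 5 × 4
#>   parameter  item class estimate
#>   <chr>     <int> <int>    <dbl>
#> 1 delta        16     1    -4.00
#> 2 delta        17     1   -16.5
#> 3 delta        18     1    -5.17
#> 4 delta        19     1    -2.61
#> 5 delta        20     1    -3.11
```

Negative offsets mean the items are much harder for the second latent
class at equal ability — the speededness signature (item 17's offset is
essentially at the "never correct" boundary). Respondent-level posteriors
and MAP classes come back as a tibble:

```r
classify_respondents(sel$final_fit, sim$responses, Q = 21)
#> # A tibble: 2,000 × 4
#>   respondent p_class0 p_class1 map_class
#>        <int>    <dbl>    <dbl>     <int>
#> 1          1    0.431   0.569          1
#> 2          2    0.908   0.0920         0
#> 3          3    0.716   0.284          0
#> ...
```

Against the simulation truth this MAP rule misclassifies 16.9% of
respondents (the naive rule that assigns everyone to the majority class
errs 25%). `autoplot(sel)` draws the BIC path, `autoplot(sel$final_fit)`
the estimated offsets per item, and `tidy()`/`glance()` give broom-style
summaries of every result object.

A command-line front end with `fit`, `select`, `select-k`, `classify` and
`simulate` subcommands is installed under `exec/latdif.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("exec/latdif.R", package = "latdif"))')" \
  select --responses responses.csv --K 1 --grid auto --out sel.json
```

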