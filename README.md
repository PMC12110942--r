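# sccr — parametric copula-based regression for semi-competing risks data

In semi-competing risks data a subject can experience a non-terminal event
(disease progression, a virological switch) and a terminal event (death):
the terminal event can censor the non-terminal one, but not the other way
around.  Ignoring that asymmetry — fitting each margin as if all censoring
were independent — biases the non-terminal model, because censoring by the
terminal event is informative whenever the two event times are dependent.

`sccr` is for biostatisticians analysing such data (or studying estimators
for it).  It fits the fully parametric joint model

> S(t₁, t₂ | z) = C<sub>θ(z)</sub>( S₁(t₁ | z), S₂(t₂ | z) )

where C is a **Clayton, Frank, Gumbel or Gaussian survival copula**, the
margins S₁, S₂ are **exponential, Weibull or Gompertz** with covariates on
the rate through λ = exp(β₀ + βᵀz) (so exp(β_k) is a hazard ratio), and the
dependence parameter θ is itself covariate-dependent through a
family-specific link (Clayton θ = e^η, Frank θ = η, Gumbel θ = e^η + 1,
Gaussian θ = tanh η, with η = b₀ + bᵀz).  Each subject contributes one of
four likelihood factors according to its censoring pattern (δ₁, δ₂):
the bivariate density c·f₁·f₂, an h-function ∂C/∂u times a marginal
density when only one event is observed, or the joint survival C(u, v)
when both are censored.

Estimation is **two-stage** (grid-search initialisation; margins by
censored ML ignoring dependence; then copula coefficients with margins
plugged in) optionally followed by the **two-step** joint maximisation of
the full likelihood from the two-stage start — the default, which removes
the dependent-censoring bias.  Optimisation is bound-constrained and
derivative-free (Powell's BOBYQA via `minqa`; L-BFGS-B available), with
Wald inference from the numerical Hessian, hazard-ratio tables and AIC.
A simulation engine generates data by conditional copula inversion and
summarises estimator performance by per-parameter MSE and coverage
probability.

## A worked example

```r
library(sccr)

design <- sccr_design(copula = "clayton", n = 3000)  # reference study design
dat    <- rsemicompeting(design, seed = 1)
fit    <- sccr(SemiComp(time1, status1, time2, status2) ~ Z1 + Z2, dat,
               copula = "clayton")
fit
#> Copula-based semi-competing risks regression
#>   copula: clayton  margins: exponential / exponential
#>   procedure: two_step  optimizer: bobyqa  n = 3000
#>   logLik: 1795  AIC: -3572  converged: TRUE
#>
#> Coefficients:
#>     NT.(Intercept)              NT.Z1              NT.Z2      T.(Intercept)
#>             1.3915             0.5536             0.1131             1.0073
#>               T.Z1               T.Z2 Copula.(Intercept)          Copula.Z1
#>             0.2284             0.2001             1.4668            -0.2691
#>          Copula.Z2
#>            -1.4856

hazard_ratio_table(fit)
#>        margin covariate   hr lower upper
#> 1 nonterminal        Z1 1.74  1.49  1.99
#> 2 nonterminal        Z2 1.12  1.01  1.23
#> 3    terminal        Z1 1.26  1.06  1.45
#> 4    terminal        Z2 1.22  1.10  1.34
```

The coefficients recover the design truths (β_NT = (1.360, 0.577, 0.100),
β_T = (0.980, 0.300, 0.150), b = (1.260, −0.037, −1.200)) to within
sampling error.  The `NT.`/`T.` blocks are the non-terminal and terminal
margin coefficients; `Copula.Z2 ≈ −1.49` says the dependence between the
two events is much weaker in the Z2 = 1 subgroup (θ drops from
e^1.47 ≈ 4.3 to e^−0.02 ≈ 1.0, i.e. Kendall's τ from ≈ 0.68 to ≈ 0.33).
Hazard ratios above 1 mean faster event occurrence; their default
confidence intervals use the delta method on the HR scale.

Compare copula/margin families on a fixed dataset with `AIC(fit)`, and
read real CSV data with `read_semicomp()` (columns
`time1, status1, time2, status2`, then covariates).  A thin command-line
wrapper with `fit` / `simulate` / `calibrate-censoring` / `make-fixture`
subcommands is installed at `inst/cli/sccr.R`.

## Simulation studies

```r
study <- sccr_sim_study(sccr_design(copula = "clayton"), reps = 150, seed = 42)
study   # per-parameter MSE and 95%-CI coverage, two-stage vs two-step
```

Under the reference design the two-step estimator achieves ≈ 94–96%
coverage for every parameter, while two-stage coverage for the
non-terminal intercept collapses to ≈ 0% — the dependent-censoring bias
this methodology exists to fix.

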