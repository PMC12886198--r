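# cscpcox: change-point deep partially linear Cox models for current status data

`cscpcox` fits a Cox-type cumulative hazard model with a covariate
threshold (change point) to **current status data** — case-I
interval-censored survival data, where each subject contributes only one
examination time `U` and the indicator `Δ = 1{T ≤ U}`; the failure time
`T` itself is never observed. Such data arise in tumor screening,
cross-sectional disease surveys, and any study where status is checked
once per subject.

The model for the conditional cumulative hazard is

```
Λ(t | X, Z, E) = Λ0(t) · exp{ β'X + g(Z) + (γ'X + h(Z)) · 1{E > ζ} }
```

* `X` (dimension p): treatment covariates with linear effects `β`, and an
  additional effect `γ` that switches on when the change-point covariate
  `E` exceeds the threshold `ζ`;
* `Z` (dimension r): covariates whose baseline effect `g(Z)` and jump
  effect `h(Z)` are nonparametric, represented by one two-headed ReLU
  feed-forward network trained on the model likelihood;
* `Λ0`: the baseline cumulative hazard, a monotone I-spline expansion
  with nonnegative coefficients.

Estimation is sieve maximum likelihood by iterative profiling
(block ascent): network training (Adam, full batch), a box-constrained
spline-coefficient update, a quasi-Newton update of `θ = (β', γ')'`, and
a grid search for `ζ` (gap 0.01, smallest argmax on ties). Standard
errors for `θ` come from a plug-in semiparametric-efficient information
matrix: the score weight `Q = h_η·[Δ e^{-h_η}/(1-e^{-h_η}) - (1-Δ)]` is
projected onto functions of `U` and additive functions of `Z` by weighted
least squares, and the information is the second moment of the weighted
residuals. Whether a change point exists at all is tested by a
score-based supremum statistic `SUP_k = sup U'Σ⁻U` over candidate
thresholds and indicator directions `1{Z_j < z_j}`, calibrated by
permuting `E`.

A synthetic-data module generates datasets from the supported simulation
designs (three nonparametric effect cases: linear, additive, and
non-additive), and a replication harness computes Bias / SSE / ESE /
coverage for `θ`, relative errors for `(g, h)`, and
Bias / 95% interval length / SSE for `ζ`.

## Worked example

```r
library(cscpcox)

cfg <- cscp_sim_config(n = 1000, case = 1, seed = 1)   # beta0 = -1, gamma0 = 2, zeta0 = 2
dat <- cscp_simulate(cfg)

ctl <- cscp_control(net = net_config(depth = 2, width = 16, epochs = 50),
                    seed = 1, max_outer = 10)
fit <- cscp_fit(dat, model = "deep-cp", control = ctl)
fit
#> Current status change-point Cox fit (deep-cp)
#>   n = 1000, log-likelihood = -0.504087, NOT converged after 10 outer iteration(s)
#>   beta:  -0.8822
#>   gamma: 2.0042
#>   change point zeta = 2.0000

cscp_wald(fit, dat)
#> Wald inference (plug-in efficient information, 95% CI)
#>   beta1     -0.8822  SE  0.1660  p  1.1e-07  [ -1.2075,  -0.5569]
#>   gamma1     2.0042  SE  0.1929  p  2.8e-25  [  1.6260,   2.3823]

cscp_suptest(dat, null_model = "linear-null", B = 199, seed = 2,
             control = cscp_control(max_outer = 10))
#> SUP_5 permutation test for a change point (linear-null restricted fit)
#>   observed SUP = 91.0715, B = 199 permutations, p = 0.005
#>   argmax: zeta = 2.0215, direction 1{Z5 < 1.1104}
```

The fit recovers the generating values `β0 = -1`, `γ0 = 2`, `ζ0 = 2`
within one standard error; the Wald intervals cover them; and the
permutation test rejects the no-change-point null at its resolution
(p = 1/200 with B = 199 draws). The "NOT converged" flag only means the
θ-iterates were still moving by more than `tol = 1e-3` when the outer
iteration budget was reached — the trajectory (in `fit$theta_path`) shows
them oscillating in the third decimal.

Real datasets are fitted from a flat CSV via `read_cscp()` (column roles
are configurable), or from the shell via the bundled CLI
(`inst/scripts/cscpcox`): `simulate`, `fit`, `test`, `replicate`
subcommands writing JSON.

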