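# gmews — generalized-model early warning signals

`gmews` anticipates critical transitions — sudden, hard-to-reverse regime
shifts in ecological and other complex systems — from short segments of
time-series data, for ecologists, fisheries scientists and anyone
monitoring a system suspected of approaching a tipping point.

Statistical early-warning indicators (rolling variance, lag-1
autocorrelation) use the time series alone; fully parameterized simulation
models need knowledge that is rarely available. `gmews` implements the
intermediate route: a **generalized model** fixes only the *structure* of
the system — its state variables and the gain/loss processes in each
balance equation, e.g.

    dA/dt = B(A) − D(A; t)        (a population with births and deaths)

— while leaving the functional forms `B`, `D` unspecified. The Jacobian of
such a model at the (quasi-)steady state contains a handful of unknown
partial derivatives with clear ecological meaning. `gmews` estimates them
directly from observations:

* **one-sided finite differences** for an observed process against its
  free variable: `B′ ≈ (B_k − B_{k−1}) / (A_k − A_{k−1})`, trailing so an
  estimate exists at the most recent observation;
* **balance inference** for the single unobserved process in a balance:
  `D_k = B_k − (A_k − A_{k−1}) / (t_k − t_{k−1})`;
* **structural assumptions** turning magnitudes into derivatives: if `D`
  is linear in `A` (with a possibly drifting coefficient), `∂D/∂A = D/A`;
  for a power law with exponent `p`, `p·D/A`.

The eigenvalues λ of the assembled Jacobian are tracked through time and a
**warning** is raised when the stability margin — `−max Re λ` for
continuous-time systems, `1 − max |λ|` for annual maps — shows a clear
downward trend (Kendall τ ≤ −0.6 over the record) *and* has dropped below
half its initial value. A dominant complex-conjugate pair flags an
oncoming Hopf bifurcation (onset of oscillations); a real dominant
eigenvalue flags a fold-like crossing.

Three fully specified stochastic simulators with known ground truth are
included for testing the method end to end: an Allee-effect population
under slowly rising mortality (fold), an annually observed harvested
fishery with a hidden juvenile stage (fold of the annual map, with
deliberate structural mismatch), and a tri-trophic food chain under rising
top-predator mortality (Hopf).

## Worked example

```r
library(gmews)

sim <- simulate_allee(allee_config(seed = 11))   # 15 annual observations
fit <- gm_ews(allee_model(), sim$observations)
fit
#> Generalized-model early-warning fit
#>   14 Jacobian estimates (continuous time), 1 eigenvalue branch(es)
#>   WARNING raised at t = 6 (real_crossing): margin 1.174 -> 0.664, trend -0.733

round(sim$true_bifurcation$time, 2)  # 13.42 — the fold of the frozen system
round(sim$collapse_time, 2)          # 27.22 — extinction, well after the fold
```

From fifteen noisy annual observations of population size and birth rate,
the estimated eigenvalue (initially −1.17/yr, i.e. a stability margin of
1.17/yr) climbs steadily towards zero; the warning fires in year 6, more
than seven years before the fold bifurcation of the underlying simulation
(year 13.4) and two decades before the actual extinction (year 27) — the
gap between bifurcation and collapse is the bifurcation delay, the window
in which management action can still avert the transition. `plot(fit)`
shows the margin series and the tracked eigenvalue branches;
`summary(fit)` adds skipped-index and negative-rate diagnostics.

The same surface drives the other scenarios, e.g. the food chain:

```r
sim <- simulate_food_chain(food_chain_config(seed = 1))
fit <- gm_ews(food_chain_model(), sim$observations, smoothing = 5, floor = 0.03)
fit$report$transition_type   # "hopf_pair": a complex pair approaches the axis
```

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/gmews.R", package="gmews"))')" \
    demo --system fishery --seed 1 --out out/
```

with subcommands `simulate`, `estimate`, `detect`, `baseline` and `demo`
(exit codes: 0 ok, 2 validation, 3 identifiability, 4 numerical).

## Package layout

* `R/` — model description (`gm_model`, `gm_process`,
  `validate_identifiability`), estimators (`estimate_jacobian_series` and
  friends), signal logic (`track_eigenvalues`, `exclude_spurious`,
  `warning_report`, `classify_transition`, `rolling_baseline`),
  simulators (`simulate_allee`, `simulate_fishery`,
  `simulate_food_chain`, `true_bifurcation_point`) and the `gm_ews` fit.
* `inst/extdata/` — the three generalized-model description files (YAML).
* `vignettes/generalized-model-ews.Rmd` — the methods vignette: model,
  assumptions, tunable parameters, numerical choices and limitations.
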