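---
title: "Early warning signals from generalized models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Early warning signals from generalized models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmews)
```

## The model and its assumptions

A system at risk of a critical transition is described on two timescales:
a *fast* subsystem — the state variables, assumed to fluctuate around a
steady state — and a *slow* external forcing (a rising mortality, a
harvest ramp) that drags that steady state towards a bifurcation. The
warning problem is to detect the approach from data before the crossing.

A generalized model fixes only the structure of the fast subsystem. For
each state variable $x_i$ (a population size or biomass) it lists signed
processes,
$$\dot x_i = \sum_{\text{gains}} G(\cdot) - \sum_{\text{losses}} L(\cdot),$$
or, for an annually indexed stock,
$x_{t+1} = x_t + \text{gains} - \text{losses}$, without committing to
functional forms. The Jacobian of this model at the steady state contains
the partial derivatives of each process with respect to each state it
depends on — quantities with direct ecological interpretations (a birth
slope, a per-capita predation rate). Stability is read off the
eigenvalues: all real parts negative (continuous time), all moduli below
one (maps). The **stability margin** is the distance of the dominant
eigenvalue from that boundary, $-\max\operatorname{Re}\lambda$ or
$1-\max|\lambda|$; it unifies the two cases, so the warning logic has a
single code path.

Three estimators recover the unknown entries from observed states and
process rates:

1. *one-sided differences*: for a process magnitude known along the
   trajectory and depending freely on one variable, the trailing chord
   $(f_k - f_{k-1})/(x_k - x_{k-1})$. Trailing (never centered) stencils
   lose accuracy but keep the estimate available at the most recent
   observation — essential when the transition is imminent.
2. *balance inference*: the single unobserved process in a variable's
   budget is solved from the discretized balance,
   $D_k = B_k - (x_k - x_{k-1})/(t_k - t_{k-1})$ (one-step-exact, without
   the time division, for maps).
3. *assumption-based derivatives*: a process assumed linear in its
   argument contributes magnitude/state; a power law with exponent $p$
   contributes $p \cdot$ magnitude/state. The linear coefficient may
   itself drift with time — that is precisely how the slow forcing enters.

A process can combine 2 and 3 with 1: for a process
$M = C(x_f)\prod_v x_v^{p_v}$ with power-law assumptions on all
dependencies but one, the reduced coefficient $C = M / \prod x_v^{p_v}$
is differenced against the free variable $x_f$.

**Identifiability** requires (a) at most one balance-inferred process per
variable, with every other process in that balance observed or of known
form; (b) assumptions on all but one dependency of every estimated
process; and (c) known-form processes referencing only declared constants
(and, for scaled forms such as "predation loss = top-predator intake /
conversion efficiency", a resolvable base process). A process flagged as
*drifting* — the one carrying the external forcing — must carry
assumptions on **all** its dependencies: differencing its magnitude
against a state cannot separate the state dependence from the temporal
drift, so a free dependency there is unidentifiable even though the same
construction is fine for autonomous processes.

## The warning rule and its tunable parameters

Eigenvalues of consecutive Jacobian estimates are aligned into branches by
exact minimum-distance assignment (enumerated; dimensions here are at
most three, and ties resolve to the lexicographically smallest assignment,
which keeps conjugate pairs together). A warning is raised at the first
time point where both

* the Kendall rank correlation of the margin series against time, over a
  trailing assessment window (default: everything observed so far), is at
  most $-\tau_{\text{crit}}$, **and**
* the current margin is at most $\rho$ times the first estimated margin.

Defaults: $\tau_{\text{crit}} = 0.6$, $\rho = 0.5$,
$\iota_{\min} = 10^{-3}$ (the imaginary-part tolerance separating real
eigenvalues from complex pairs). Rank correlation is the standard trend
measure for early-warning indicators (invariant under monotone rescaling
of the margin); the margin-drop condition keeps a clean but shallow trend
from firing. Both are exposed as arguments of `gm_ews()` /
`warning_report()`; "a clear trend toward the boundary" has no canonical
quantitative definition, so these are explicit, documented conventions
rather than estimated quantities. The scan over expanding prefixes is
causal: truncating the record after the warning time cannot change it.
The transition type reported with a warning is likewise assessed from the
record available at the warning time: a dominant complex-conjugate pair
(|Im| > $\iota_{\min}$) indicates a Hopf bifurcation and oncoming
oscillations, a dominant real branch a fold-like crossing.

In higher dimensions, noisy estimation can produce a jittery, dynamically
meaningless real eigenvalue (in the food chain it reflects the producer's
fast response to fluctuations above it). `exclude_spurious()` removes a
real branch whose temporal variance of the real part is at least five
times the median branch variance; three-dimensional trajectories are
first re-threaded per time point into their natural spectral streams (one
conjugate pair plus one real eigenvalue, or three reals assigned by
continuity), because a jittery real eigenvalue leapfrogs sorted branches.

Statistical baselines for comparison are computed by
`rolling_baseline()`: trailing-window sample variance or lag-1
autocorrelation (Pearson correlation of the window against itself shifted
by one step), with optional within-window linear detrending. The mirror
warning rule for a rising indicator (`baseline_warning_time()`) uses the
same $\tau_{\text{crit}}$ and a doubling over the *running median* of
earlier values, and only starts once eight windowed values exist — a
single window's variance estimate carries too few degrees of freedom to
anchor either the reference level or an early trend.

## The simulators: what they emulate, and what they do not

Each scenario is a fully specified stochastic model integrated by
fixed-step Euler–Maruyama (step 1/64 yr for the continuous systems) with
additive noise, a linear ramp on the forcing parameter, a reflecting
floor at zero, and noise suppressed for any variable after it is absorbed
at zero, so extinct populations stay extinct. One independent normal
stream per noise channel is derived from the master seed, so adding an
observation channel never perturbs the process noise; identical seeds
give bit-identical output. Observation times are snapped to the
integration grid. Ground truth — the bifurcation point of the frozen fast
subsystem — is located by Newton continuation of the equilibrium branch
with bisection to $10^{-6}$ relative accuracy
(`true_bifurcation_point()`), distinguishing smooth crossings from branch
folds.

**Allee population.** $\dot A = B(A) - c(t)A + \sigma\xi$ with
$B(A) = b\,A^2/(A+h)\,(1-A/K)$: per-capita births rise with $A$ at low
density (the Allee effect), mortality is exactly linear with a drifting
coefficient, so the estimation assumptions hold exactly and the fold sits
at the maximum of the per-capita birth rate. Defaults: $h=0.2$, $K=1$,
$\sigma=0.01$, ramp $0.005$/yr, fifteen annual observations. The birth
scale is $b=20$: the method presumes the fast subsystem relaxes quickly
between observations, so the initial stability margin (about 1.4/yr,
relaxation time well under a year) is kept far above both the annual
sampling rate and the ramp. With slow dynamics ($b$ of order one) the
trajectory lags the equilibrium branch so strongly near the fold
(bifurcation delay) that no margin-based rule can respond before the
crossing. The ramp start $c_0 = 8.337$ places the fold at
$t \approx 13.4$ of the 15-year record.

**Fishery.** A three-state annual stock model: adult piscivores $A$,
juveniles $J$ hidden from the observer, planktivores $F$ with within-year
dynamics $\dot F = f_{\text{in}} + r_F F (1 - F/K_F) - aFA$ integrated in
twelve substeps. At the year boundary juveniles mature with survival
$h_J/(h_J + F + c_{JA}A)$ — predation by planktivores plus cannibalism;
without the direct density dependence $c_{JA}$ the high-piscivore fixed
point is provably unstable — adults suffer natural mortality and the
ramped harvest, and reproduce a new cohort. The generalized model sees
only end-of-year $P$, $F$ and the catch, with two state variables: the
hidden stage and the intra-annual dynamics are a deliberate structural
mismatch, testing the method where its model is wrong in ways the analyst
cannot know. The planktivore growth parameters ($r_F$, $K_F$), natural
mortality, reproduction rate and refuge influx are treated as known — the
kind of information obtainable from life-history studies — because the
planktivore balance contains two unobserved processes and only one can be
inferred from the budget.

**Food chain.** Producer $X$ (logistic), grazer $Y$ (mass-action
grazing), top predator $Z$ with a sigmoid (type III) per-capita intake
$a_2 Y^2/(h_Y^2+Y^2)$ and ramped linear mortality $m_Z(t)$. Rising $m_Z$
releases the grazer; once its biomass passes the inflection of the
sigmoid response the $Y$–$Z$ interaction loses its stabilizing grip and
the coexistence equilibrium crosses a genuine Hopf bifurcation
(conjugate pair $\pm0.8i$ at $m_Z^\ast \approx 0.596$), with an extended
unstable-spiral region beyond, so oscillations grow visibly and, with
noise, collapse the chain. This structure was chosen deliberately: in
plain prey-dependent chains with saturating links, raising top mortality
stabilizes the oscillatory modes or runs into a fold first, and a
ratio-dependent top link would produce the right bifurcation but violate
the linear-in-$Z$ estimation assumption. Here every assumption of the
generalized model (grazing linear in $Y$, top intake linear in $Z$,
linear mortalities, free producer production) is exact, so noise-free
estimates converge to the analytic Jacobian at first order in the
sampling interval. The oscillation-onset time recorded in the output is
the first departure of the producer from its trailing ten-year linear fit
by more than a quarter of its pre-ramp level — deliberately conservative,
so noise-driven quasi-cycles near the Hopf point do not count as onset.

What the simulators do **not** emulate: observation/measurement error
(exposed as an option, default zero — the recorded birth rate is the
exact yearly rate at the sampled state), demographic (multiplicative)
noise, irregular sampling, missing data, and spatial structure. Passing
the packaged tests therefore demonstrates the estimators and warning
logic under additive environmental noise with clean channels, not
robustness to poor-quality field data: the method differentiates time
series, and its noise sensitivity is a real limitation discussed below.

## Numerical choices

* **Spacing floor and stencil widening.** A chord needs
  $|\Delta x| \ge \text{floor}\cdot\max(|x|,1)$; otherwise the stencil
  widens to the nearest earlier admissible index. The package default
  floor ($10^{-9}$) only guards against exact plateaus. For channels that
  drift slowly relative to their noise (the food-chain grazer moves only
  ~$10^{-3}$ per year; the fishery planktivore similarly before the
  shift) the chord baseline must exceed the noise amplitude, so the
  packaged pipelines use floors of 0.03 (food chain) and 0.02 (fishery).
  Indices whose stencils stay degenerate are skipped and logged, never
  fabricated.
* **Smoothing.** Trailing moving average over 5 observations for the two
  noisy, densely observed scenarios; the sparse 15-point population
  record is used raw. Window 1 is the identity; times never change.
* **Negative inferred rates.** Noise can push a balance-inferred rate
  slightly negative, which is biologically impossible; the raw value is
  kept (and flagged) for differencing, but clipped to zero for
  assumption-based derivatives so the sign of the eigenvalue estimate is
  not flipped by a small negative magnitude.
* **Deterministic ordering.** Eigenvalues sort by descending real part
  (descending modulus for maps), ties by descending imaginary part, so
  outputs are reproducible; branch matching breaks cost ties
  lexicographically.
* **Problem sizes.** The oracle-accuracy checks use 64 noise-free
  observations over eight years (and 128 for the convergence ratio); the
  ensemble checks use 100 seeded replicates per scenario, enough to
  resolve detection rates to a few percent while keeping the whole test
  suite in minutes.

## Known limitations

* The one-sided chord of an observed channel against a noisy state
  amplifies state noise by the channel's curvature: the eigenvalue-
  estimate noise is roughly $|B''|\,\mathrm{sd}(\Delta A)/2$ plus the
  balance term, and the two add coherently. Under the sparse Allee
  conditions (fifteen raw annual points, $\sigma = 0.01$) this noise is
  two to three times the per-step margin decline for *any* birth scale,
  so the joint trend-plus-level rule fires before the fold in only about
  half of noisy realizations — the trend is usually visible, but the
  conjunction at the default thresholds is strict. Denser records,
  smoother channels, or integrated (count-type) rate observations would
  all help; so would model-based filtering, which is out of scope here.
* Near a fold the trajectory lags the equilibrium branch (bifurcation
  delay), so margins estimated from data are systematically fatter than
  the frozen-system margin; warnings are correspondingly conservative.
  The flip side, as the collapse-time records show, is that the window
  for intervention extends well past the bifurcation itself.
* The spurious-branch exclusion and the baseline warning rule are
  explicit reproducible conventions standing in for what is, in
  practice, expert inspection; their thresholds (variance ratio 5,
  doubling over the running median, eight-value burn-in) are exposed and
  documented rather than derived.
* Parameter drift is assumed linear-in-time and slow; the fast subsystem
  is assumed stationary between observations. Strongly non-stationary
  forcing or fast-comparable ramps violate the premise of the method.
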