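---
title: "Modelling Cand1-mediated substrate receptor exchange: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Cand1-mediated substrate receptor exchange}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cand1cycle)
```

## The model

SCF ubiquitin ligases are modular: interchangeable substrate receptors
(F-box proteins, docked via the Skp1 adapter; here `SR1`, `SR2`, ...)
assemble on a common Cul1 scaffold.  The receptor-scaffold interaction is
extraordinarily tight (sub-picomolar), which poses a problem: how does a
cell re-deploy its limited Cul1 pool when the substrate spectrum changes?
The answer is the exchange factor Cand1, which binds Cul1 and destabilises
the bound receptor by six orders of magnitude (and vice versa), opening a
fast exchange route through a short-lived ternary Cul1.Cand1.SR complex.

The core model is mass-action kinetics over the four binding equilibria

* `Cul1 + SR <-> Cul1.SR` (constants `Ksr`, `ksr`),
* `Cul1 + Cand1 <-> Cul1.Cand1` (`Kca`, `kca`),
* `Cul1.SR + Cand1 <-> Cul1.Cand1.SR` (`Kca'`, `kca'`),
* `Cul1.Cand1 + SR <-> Cul1.Cand1.SR` (`Ksr'`, `ksr'`),

replicated per receptor species.  These form a closed thermodynamic cycle,
so the free-energy of the ternary complex must not depend on the assembly
order: detailed balance demands `Kca * Ksr' = Kca' * Ksr`.  Three
dimensionless factors summarise the cycle: the relative binding preference
`eta = Kca/Ksr = Kca'/Ksr'` (`eta < 1` means Cand1 out-competes receptors
for Cul1), and the rate ratios `alpha = kca/ksr` and `beta = kca'/ksr'`.

`kinetic_params()` enforces all of this at construction time.  Because the
published table rounds `Kca` to 1.73e-5 nM (leaving a ~4e-4 relative
residual in the cycle), the default constructor *derives* `Kca` from the
other three constants instead; with the rounded value the algebraic
equilibrium would not be an exact fixed point of the dynamics.
`check_detailed_balance()` exposes the residual for any parameter set.

```{r}
default_params()
```

## Dynamics: conservation-law elimination

Only complexes (and, when degradation is active, free substrate) are
integrated.  Free Cul1, Cand1 and free receptors are recovered
algebraically from the conserved totals at every right-hand-side
evaluation, so conservation holds *by construction* rather than up to
integration error, and the two-receptor base system is exactly the
five-state reduced system in the complexes `Cul1.SR1`, `Cul1.SR2`,
`Cul1.Cand1`, `Cul1.Cand1.SR1`, `Cul1.Cand1.SR2`.  Free substrate must be
dynamic because degradation removes substrate from its conservation law.

The implied association rate constants (`k/K`) span about six orders of
magnitude against dissociation rates down to 1e-6 1/s, so the system is
stiff; `simulate_network()` uses `deSolve::lsoda` with `rtol = 1e-8`,
`atol = 1e-12` nM as the default contract.  Trajectories are returned on a
log-spaced grid dense enough for interpolation-based read-outs.

## Equilibria and the exchange rate

The substrate-free binding network obeys detailed balance, so its steady
state is a thermodynamic equilibrium.  `solve_equilibrium()` exploits
this: given free Cul1 and free Cand1, every other concentration is closed
form, leaving two nested scalar root-finds.  Both are solved in log space
because free concentrations can sit 10+ orders of magnitude below the
totals (free Cul1 is ~2e-5 nM at the default working point); a naive
linear bracket would lose all relative precision.  The bracket endpoints
are written so that the enclosing sign change is exact at the boundary
(the residual is expressed as `bound - (total - free)`), which avoids
catastrophic cancellation when nearly all of a pool is free.  An
ODE-relaxation route serves as an independent cross-check
(`cross_check = TRUE` enforces agreement to 1e-6 relative).

The receptor exchange timescale is quantified by linearising the reduced
dynamics at the equilibrium (`network_jacobian()`, central differences
with relative step 1e-7 -- adequate for a polynomial right-hand side at
these magnitudes) and taking the eigenvalue with the largest real part.
Because the free species are eliminated, the reduced Jacobian carries no
structural zero modes, so no eigenvalue filtering is needed.  The
exchange rate is `|Re(rho_l)|` and `tau_s = 1/|Re(rho_l)|` is the
relaxation time towards a new steady state, e.g. after adding a receptor
bolus (`sr_addition_transient()` checks the two agree within a factor of
two).

Closed-form approximations are provided alongside the numerics:
`occupancy_low_cand1()`/`slope_f()` (linear decline of SCF occupancy with
total Cand1; the slope lies in (0,1)), `occupancy_high_cand1()` (1/Cand1
power law) and `exchange_rate_limits()`.  The suite documents their
quality against the numeric oracle: the power law carries a slowly
vanishing correction (~17% at 10x Cul1, ~9% at 100x), and the low-Cand1
eigenvalue formula sits ~25% below the numeric leading eigenvalue across
its regime while capturing the correct limits.  They are used for insight
and regime bracketing, never in place of the solver.

## Substrate binding topologies and the neddylation proxy

Degradation is lumped into a single first-order step
`Cul1.SR.S -> Cul1.SR` (`kdeg`), standing in for neddylation, ubiquitin
transfer and proteasomal digestion.  Degradation never proceeds from
Cand1-bound complexes (Cand1 and the activating Nedd8 modification are
mutually exclusive on Cul1).

Three binding topologies cover the experiments:

1. **Sequential, ligase-only** (`substrate_params(..., binding_mode =
   "sequential")`, the default): substrate binds the assembled ligase
   `Cul1.SR` only.  No ternary-substrate species exists; this is the
   minimal scheme used for the dose-response, remodelling and hierarchy
   experiments.
2. **Sequential with ternary binding** (`ternary_binding = TRUE`):
   substrate additionally binds the ternary `Cul1.Cand1.SR` complex, and
   Cand1 exchanges reversibly on the loaded ligase
   (`Cul1.SR.S + Cand1 <-> Cul1.Cand1.SR.S` with the ternary constants
   `kca'`, `Kca'`).  We keep this exchange reversible deliberately: all
   substrate-binding constants are context-independent, so reversibility
   makes every added square of the reaction graph exactly
   detailed-balanced -- the added substrate layer introduces no hidden
   free-energy source.
3. **Random order** (`binding_mode = "random"`): substrate also binds the
   free receptor, and the loaded module `SR.S` docks onto Cul1
   (reversibly, spontaneous route) and onto `Cul1.Cand1`.  The latter
   docking is one-way: the exchange pathway (`ksr'` route) cannot eject a
   substrate-loaded receptor module from the ternary complex.  This is
   the package's reading of "substrate binding shuts down receptor
   exchange": substrate engagement triggers neddylation, an ATP-driven
   modification, so suppressing the Cand1-mediated ejection of loaded
   modules is exactly where the cycle is allowed to break detailed
   balance.  With a fully reversible random topology one can show that
   the Cul1 partition over receptor species is invariant to
   context-independent substrate binding -- substrate could then never
   recruit extra Cul1 into its ligase, contradicting the redistribution
   that the exchange factor demonstrably enables.  The one-way rule
   confines the irreversibility to the loaded ternary complex and leaves
   every substrate-free reaction, and all spontaneous routes, reversible.

## Experiment pipelines

* `run_degradation()` pre-equilibrates analytically (no arbitrary burn-in
  integration), injects substrate at t = 0, and reads `t_half` off the
  total-substrate curve by a bracketed natural-spline root at the first
  half-crossing.  The suite checks `t_half` moves by <0.1% under a
  tolerance refinement from 1e-8 to 1e-10.
* `cand1_dose_response()` classifies the half-life curve over a Cand1
  grid and refines an interior optimum by golden-section search between
  the grid neighbours of the argmin (default resolution a few nM).
* `redistribution_analysis()` decomposes the growth of the engaged pool
  (`[Cul1.SR1] + [Cul1.SR1.S1]`) into depletion curves of the reservoir
  complexes; Cul1 conservation makes the decomposition close identically
  (the free-Cul1 remainder is ~1e-5 nM at the default working point).
* `hierarchy_experiment()` runs the three-receptor, two-substrate
  competition.  The receptor-affinity variant scales `Ksr`, `ksr`,
  `Ksr'`, `ksr'` of one receptor jointly (x5), which preserves detailed
  balance automatically; the abundance variant defaults to receptor
  totals of 90/30 nM (the reference splits 660 nM as 60/60/540) -- the
  source material states no numbers for this case, so the split is a
  package choice, kept configurable.
* `compare_architectures()` contrasts the natural design (Cand1 present,
  tight binding) with a hypothetical exchange-factor-free design in which
  `ksr` and `kca` are multiplied by a factor `gamma` (so `Ksr`, `Kca`
  scale while `eta` and detailed balance are preserved).  `match_gamma()`
  root-finds `gamma` so both designs start from the same pre-stimulus
  `[Cul1.SR1]`; a closed-form competitive-binding argument fixes the
  expected value near 1.7e7 for the 30/630 receptor split and the suite
  verifies the solver against it.
* `simulate_fret_exchange()` reproduces the receptor-exchange FRET assay
  used to pin down `kca'`, the only rate not measured directly: Cul1 is
  pre-equilibrated with an equimolar competitor receptor *and with
  Cand1*, then the labelled receptor is added and `[Cul1.SR1](t)` is
  fitted by a single exponential after a 5 s discard window
  (`fit_single_exponential()`, Levenberg-Marquardt).  Pre-incubating
  Cand1 matters: co-injecting Cand1 with the labelled receptor makes the
  trace multi-exponential (Cand1 loading of the scaffold and receptor
  exchange then overlap in time) and the fitted rate drops by a third.
  With Cand1 pre-equilibrated, the fitted rate essentially coincides with
  the leading Jacobian eigenvalue of the post-addition mixture, which is
  what the one-parameter calibration (`estimate_kca_prime()`, log-space
  root find over `kca'` in [1e-4, 10] 1/s) targets.  The labelled
  receptor dose is not stated in the source assay; the default of 70 nM
  mirrors the other amounts, and the suite bounds its influence on the
  fitted rate to <15% over 35-140 nM.

## Synthetic data

The generator (`noise_model()`, `generate_noisy_trace()`) emulates
observable traces as a deterministic trajectory sampled at a fixed
interval plus i.i.d. additive Gaussian noise, with negative readings
clipped at zero and the clipped fraction reported.  That is the
statistical structure the estimators assume -- it deliberately does *not*
emulate drift, photobleaching or correlated detector noise, so a passing
recovery study certifies the estimation machinery, not robustness to real
fluorescence artefacts.  `parameter_recovery_suite()` closes the loop
(simulate, perturb, re-estimate) with per-replicate seeds derived from a
single suite seed, reporting bias and RMSE; at 2% amplitude noise the
calibration recovers `kca'` with relative bias under 5%.

## Numerical choices, sizes and limitations

* Units: nM and seconds internally; substrate `kon` accepted in 1/M/s
  (x1e-9 conversion); half-lives reported in minutes.
* Default problem sizes: 5-10 dynamic states; degradation runs use ~400
  log-spaced output points over up to 1e5 s (architecture runs 4e6 s);
  trade-off scans use ~40 grid points per eta.  Every simulation
  completes in well under a minute on one core.
* Tie-breaking: none needed -- total substrate is strictly decreasing
  wherever `t_half` is read, and the dose-response argmin is refined
  locally.
* Degenerate inputs: zero Cand1, zero receptor pools and zero added
  substrate are all handled as exact limits (the inner root-find is
  skipped, not approximated).
* The model lumps neddylation/deneddylation, E2 recruitment and
  ubiquitin-chain dynamics into `kdeg`; there is no stochastic engine, no
  explicit CSN, and no claim about absolute in-vivo rates beyond the
  measured constants it was built on.
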