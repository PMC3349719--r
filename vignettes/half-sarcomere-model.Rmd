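---
title: "A spatially-explicit half-sarcomere model of cooperative thin-filament activation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spatially-explicit half-sarcomere model of cooperative thin-filament activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarcolattice)
```

# The model

`sarcolattice` simulates isometric, Ca^2+^-regulated force production in a
spatially-explicit half-sarcomere. The model couples three ingredients:

1. **A compliant spring-network mechanics.** Four thick and eight thin
   filaments are chains of linearly elastic elements (60 and 90 nodes at
   14.3 and 12.3 nm rest spacing; element stiffnesses 6060 and
   5230 pN nm^-1^ at 1X). Thick filaments are anchored at the M-line,
   thin filaments at the Z-line, and the half-sarcomere length is fixed.
   Every attached cross-bridge adds a `k_xb` spring (default 3 pN nm^-1^)
   between its myosin node and its actin partner node. Each time step the
   instantaneous 1-D force balance `K u = V` is solved exactly over all
   ~960 nodes (inertia and viscosity neglected); the boundary force is the
   summed tension of the Z-line anchor elements, which equals the M-line
   readout by statics (asserted in the test suite). Because the filament
   backbone stiffness matrix is fixed for a run and block-tridiagonal per
   filament, the production solver applies the Woodbury identity against
   precomputed per-filament inverses - an exact direct solve whose cost
   scales with the number of attached bridges - and is cross-checked
   against a dense factorisation and against the R-level sparse assembly
   (`assemble_system()`/`solve_positions()`).

2. **Three-state regulatory-unit (RU) kinetics.** Each troponin site is in
   TF1 (no Ca bound), TF2 (Ca bound) or TF3 (tropomyosin moved,
   myosin-permissive). Second-order rates are multiplied by the clamped
   `[Ca^2+^]`. The default rate set, quoted at the
   equilibrium rescale `xi = 100`, is: `r_t12 = r_t13 = 5e4 /M/s`,
   `r_t21 = 50`, `r_t23 = r_t32 = 10`, `r_t31 = 5 /s`. Cooperative
   substitution multiplies a targeted forward rate (`r_t12` and/or
   `r_t23`) by `psi = 100` whenever a configured source condition holds in
   either adjacent unit along the same helix: an activated neighbour (TF3;
   RU-RU cooperativity) or a bound cross-bridge within a neighbour's
   influence region (XB2 or XB3; XB-RU cooperativity). Reverse rates are
   never scaled. The rates are used verbatim; `thin_rate_table()` reports
   the equilibrium constants they imply - including the loop product
   around TF1 -> TF2 -> TF3 -> TF1, which is not unity for the default
   set (the cycle is thermodynamically driven) - rather than adjusting
   any of them.

3. **Strain-dependent cross-bridge (XB) kinetics.** Each of the 480
   myosins cycles through XB1 (unbound), XB2 (bound, pre-stroke) and XB3
   (bound, post-stroke) on free-energy wells over the distortion `x`
   (myosin-node offset from its actin partner): a flat unbound level and
   two parabolas of curvature `k_xb/2kT` with minima at 0 and the
   power-stroke distance `x_ps`. Attachment follows a Gaussian window
   (`r12 = f1 exp(-k_xb x^2/2kT)`), reverses obey detailed balance
   exactly, the stroke is Glauber-gated (bounded attempt rate, favoured
   exactly when it lowers the free energy), and the ATP-coupled exit
   `r31` is irreversible and strain-accelerated. Every completed
   XB3 -> XB1 exit counts one ATP.

## Monte Carlo scheme

State transitions use one uniform draw per unit per 1-ms step,
partitioned among the available exits with probabilities `rate * dt`
computed from the start-of-step state; updates are synchronous. When the
summed exit probability reaches 1 the probabilities are renormalised to
their ratio and a transition is forced (this happens by design for the
cooperative `r_t23` value, `1000 /s`). When a cross-bridge rate exceeds
`rate_cap` (1000 /s) that bridge's update runs as ten equal sub-steps at
fixed distortion, permitting several transitions within one step. Within
a step, thin-filament updates commit before the cross-bridge phase (so a
node made available can be bound in the same step); mechanics are
re-solved once per step after all kinetic updates. Runs are
bit-reproducible for a fixed configuration and seed, and replicate grids
derive each cell's seed deterministically from the base seed.

## Lattice regulation geometry

Thin-filament nodes are grouped into 3-node (~37 nm) co-linear runs that
alternate between the two actin helices. Each repeat carries one troponin
site per helix (60 per filament, 480 in all), anchored at the repeat's
centre node, so troponins along one helix are spaced ~37 nm apart - the
physical density of two regulatory strands. The activation span
`RU_span` (7, 9, 11 or 14 actins; 37-75 nm) maps to the node grid as the
anchor plus `floor((span_nm/2)/12.3)` nodes per side: spans of 7 actins
tile a helix without overlap, larger spans overlap their same-helix
neighbours. On this grid the 9- and 11-actin spans coincide (both snap to
a 5-node window), so the package cannot distinguish those two conditions;
spans 7, 9 and 14 are distinct. A node is myosin-available when the most
activated of its governing troponins is in TF3; ungoverned nodes are
never available.

Functional troponin density `rho_Tn` knocks out troponin *complexes*:
one Bernoulli draw per ~37-nm repeat anchor, applied to both helices'
sites there. Marginally every site is functional with probability
`rho_Tn`; the complex-level draw keeps each node's governance - and hence
maximal force at a 7-actin span - proportional to `rho_Tn`, the
experimentally observed linear titration behaviour. Per-site independent
knockout would square that relationship.

## Deactivation and bound bridges

What happens when a regulatory unit tries to deactivate while a bridge is
bound in its region is not uniquely determined by the biology and matters
quantitatively. The package implements three modes
(`run_simulation(deactivation = ...)`):

* `"release"` (default): units deactivate freely; a bridge whose node
  loses availability is forcibly released (interrupted cycle, no ATP
  counted). Attachments and availability then agree at every step.
* `"free"`: availability gates only *new* attachments; bound bridges
  complete their cycle where binding was granted.
* `"block"`: a unit cannot leave TF3 while any governed node holds a
  bridge (hard steric reading).

Hard blocking was rejected as a default after stationarity diagnostics:
at intermediate calcium it creates a ratchet of effectively absorbing
activated states, with force still creeping after 8 s of simulated time
and a Ca-sensitivity roughly 0.17 pCa units above the release mode.

## Cross-bridge energetics are calibrated, not microscopic

Each model myosin coarse-grains a crown of heads, so well depths and the
stroke energy are *effective* constants, calibrated once against
whole-half-sarcomere steady-state signatures at saturating calcium with
standard stiffness: maximal force near 973 pN, ~15% of myosins bound
with roughly two-thirds of the bound population pre-stroke, and a rate
of force development near 32.6 s^-1^. The defaults are `attach_rate =
90 /s`, `w2 = 0.55 kT`, `h23 = 170 /s`, `d31 = 50 /s` (strain
acceleration 2) and a stroke energy of 70 kT, giving `x_ps = 13.9 nm` at
`k_xb = 3 pN/nm`.

Two stiffness-scaling choices deserve emphasis:

* the power-stroke distance preserves the stroke *free energy* across
  `k_xb` (`x_ps = sqrt(2 kT E_s / k_xb)`), so stroke thermodynamics do
  not change when the spring stiffens while the force borne per
  post-stroke bridge grows as `sqrt(k_xb)`;
* the attachment-rate peak scales as `(k_xb/3)^0.5` below the reference
  stiffness (the head's thermal positional density - the window-limited
  regime) and as `(k_xb/3)^1.3` above it (attempt-frequency-dominated,
  an empirically calibrated exponent). A single exponent cannot
  reproduce both observed stiffness phenomena - turnover (ATPase)
  decreasing monotonically in `k_xb` and force development accelerating
  by tens of percent at `k_xb = 10 pN/nm` - while the two-regime law
  reproduces both.

## Analysis layer

Steady-state statistics use the final half of each trace, with a
stationarity flag comparing the window's two halves. The rate of force
development is `k_dev = ln 2 / t_half`, the first crossing of half the
steady-state mean with linear interpolation; the trace is first smoothed
with a 9-ms centred moving average because developing force arrives in
~40 pN single-bridge increments whose shot noise otherwise dominates the
crossing-time jitter. The same construction on the available-node
fraction gives `k_TF,act`. ATPase is counted from completed post-stroke
detachments over the stationary window, per myosin per second.

Force-pCa and activation-pCa relationships are fitted with the
three-parameter Hill equation in pCa space,
`y = X_max / (1 + 10^(n_H (pCa - pCa50)))`, by Levenberg-Marquardt least
squares seeded from a coarse grid search. Protocol fits weight the
per-pCa replicate means by inverse squared standard error, since the SEs
differ by two orders of magnitude between the plateau and the
transition; 95% intervals come from the linearised covariance, with a
residual-bootstrap option for small grids. Degenerate inputs (flat or
all-zero response) are flagged, never silently fitted.

## Problem sizes and runtimes

The engine advances the full 4x8 lattice at roughly 1000 steps per
second of wall time on one core. Saturating-calcium comparisons use 2-s
runs (force is stationary after ~0.3 s). Force-pCa grids use nine pCa
points concentrated around the transition and 6-s runs, because cells
near the half-activation point need 3-4 s to become stationary; these
durations were chosen from explicit stationarity diagnostics.

## What the simulations do and do not show

The generator reproduces the study conditions - an idealised, fully
regular lattice with toroidal filament coordination, clamped calcium, a
fixed half-sarcomere length (1150 nm, M-line to Z-line) and isometric
boundary conditions. It does not emulate sarcomere-length changes,
radial or azimuthal mechanics, explicit tropomyosin chain continuum
dynamics, Ca diffusion or buffering, two-headed myosin or
nucleotide-state detail. Passing tests therefore certify the stochastic
lattice model and its analysis layer, not quantitative agreement with
any particular fibre preparation.

Known limitations: the Hill slope of the simulated force-pCa relation at
the 9-actin span runs steeper (n_H ~ 3.8-4.0) than the calibration reference
near 3.2, while both Ca-sensitivities (pCa50 at spans 7 and 9) and the
saturating-calcium state are reproduced closely. The steepness traces to
the dual-helix governance (each node can be opened by either helix's
troponin): a single-governor variant reproduces the shallower slope but
sits ~0.3 pCa units to the right. The discrete 12.3-nm node grid also
collapses the 9- and 11-actin spans onto one influence map, so the small
difference between those two conditions is below the model's spatial
resolution.

# A worked run

```{r example, eval = FALSE}
tr <- run_simulation(pCa = 4, duration = 2, seed = 1)
glance(tr)
autoplot(tr)

reps <- run_replicates(pCa = c(4, 5.75, 6, 6.5, 8), n_reps = 4,
                       base_seed = 1, duration = 6)
reps$summary

pr <- protocol_force_pca(ru_span = 9, n_reps = 4, base_seed = 1,
                         duration = 6)
tidy(pr$fits$force)
autoplot(pr$fits$force)
```
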