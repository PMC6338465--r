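---
title: "Discriminating helicase translocation mechanisms from force-dependent kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating helicase translocation mechanisms from force-dependent kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helicycle)
```

## The model

A processive helicase is described by a minimal ATPase cycle — reversible
ATP binding (`k+b`, `k-b`), irreversible hydrolysis (`k_h`) and
irreversible product release (`k_r`) — plus one translocation step of
`delta` base pairs per cycle. Products are assumed absent in solution
([ADP] = [Pi] = 0), so rebinding of products is not modelled. How the step
enters the cycle defines the candidate mechanisms:

* **Power stroke (PS)**: one chemical transition itself carries the step.
  Its forward rate acquires the force coupling; if the transition is
  irreversible there is no reverse path, so only the forward Bell factor
  applies.
* **Brownian ratchet (BR)**: a fast reversible pre/post-translocation
  fluctuation (`k+tr`, `k-tr`; equilibrium constant
  `K_eq = k-tr / k+tr`) is inserted immediately before a chemical step
  that can only proceed from the post-translocation state, rectifying the
  fluctuations.

Crossing each of the two mechanisms with the three possible placements
(binding, hydrolysis, release) gives exactly six schemes
(`enumerate_schemes()`). All six are unicyclic Markov chains, so at fixed
force and [ATP] the stationary flux is available both from the null space
of the generator and from the closed-form unicyclic flux; the two routes
are verified against each other in the test suite, and all six schemes
are *exactly* Michaelis–Menten in ATP because ATP enters linearly through
a single transition.

### Force coupling in the two assays

In the **opposing-force** geometry the load acts directly on the
translocation step, treated as a single barrier crossing: the forward
rate is multiplied by `exp(-F x‡ / kBT)` and the backward rate by
`exp(+F (delta - x‡) / kBT)`, so the equilibrium constant shifts as
`K_eq exp(F delta / kBT) = K_eq exp(F/F0)` with `F0 = kBT/delta`
independent of the transition-state position `x‡`. By default `x‡` is
pinned at the full step (`x‡ = delta`), the assumption under which the
saturating-ATP force-velocity curve reduces to the logistic law
`v(F) = v0 / (1 + exp((F - F_half)/F0))`; `x‡` can be freed in fitting.
Distances in base pairs are converted to nanometres at 0.34 nm/bp (B-DNA
rise) with `kBT = 4.11 pN nm` (25 °C); both are configurable because
these conversions are conventions, not measurements.

In the **hairpin-under-tension** geometry no force acts on the enzyme;
tension destabilizes the fork ahead of it. Since DNA breathing is fast
compared to stepping, the transiently open fork is treated as a substrate
of translocation: the forward translocation rate is multiplied by
`P_open(F)`, the probability that at least `n_step` base pairs ahead are
open, and force enters the cycle nowhere else.

### The fork-opening probability

`p_open()` uses a deliberately minimal, sequence-averaged zipper: opening
each base pair costs `dg_bp`, reduced by a helicase destabilization
energy `dG_dest` (applied uniformly per open bp) and by the stretching
free energy of the two released nucleotides at tension `F`, computed in
closed form from the freely-jointed chain. With the per-bp free energy
`dg(F)`, `P_open = sum_{j=n}^{m} e^{-j dg} / sum_{j=0}^{m} e^{-j dg}` with
a window of `m_window` = 20 bp. The prior literature contains several
dialects for each of these four choices (sequence-resolved energies,
first-bp-only destabilization, worm-like-chain ssDNA); all four choices
here are the simplest members of their families and all are parameters of
`fork_params()`/`polymer_params()`, so other dialects can be swapped in.

### Tether mechanics

dsDNA uses the high-force extensible Marko–Siggia interpolation
`x = L (1 - (1/2) sqrt(kBT/(F L_p)) + F/S)` with `L_p` = 40 nm and
`S` = 1000 pN; its inverse is the exact algebraic rearrangement, so
contour conversion is a numerical identity (checked to 1e-6 relative over
0.5–60 pN). Samples below 0.5 pN are masked rather than extrapolated —
the interpolation is unreliable there and real instruments cannot hold a
tether taut at such forces anyway. ssDNA uses an FJC with Kuhn length
1.5 nm and 0.59 nm/nt, standard literature values.

## The synthetic study

No raw traces are deposited with the study this package models, so the
simulator is a first-class module, not a fixture: it defines the study
conditions everything else is tested against.

**Enzyme contexts.** The generating scheme is the Brownian ratchet
rectified by ATP binding. Two contexts share all chemistry
(`k+b` = 2e7 /M/s, `k-b` = 500 /s, `k_h = k_r` = 300 /s so
`k_c_eff` = 150 /s, `k+tr` = 2e5 /s, `delta` = 3.3 bp) and differ only in
the ratchet equilibrium and destabilization energy: in-complex
`K_eq = 0.05`, isolated `K_eq = 10` (the 200-fold shift toward the
post-translocation state attributed to the partner subunits) with
`dG_dest = 0.6 kBT`. These values were fixed once, from the study-scale
phenomenology they must reproduce: ~480 bp/s at 2 mM ATP and zero force,
half-velocity near 25 pN of opposing load, an isolated enzyme that
barely unwinds at low force (`P_open` of a 2.5-kBT/bp fork is ~1e-3 at
zero force for a 3-bp step) yet plateaus near the in-complex rate once
tension opens the fork (~12–14 pN). `k+tr` is large enough that
translocation is not rate-limiting below ~25 pN, yet small enough that
exact stochastic simulation of every futile ratchet excursion stays
cheap.

**Tether fixtures.** Opposing assay: a 4500-bp dsDNA track whose contour
shortens by `delta` bp per step, starting at 3 pN so a single trace
develops force over most of the 0–60 pN range. Hairpin assay: 3400 bp of
dsDNA handles plus a 2000-bp hairpin releasing 2 nt of ssDNA per unwound
bp, starting at 14.5 pN so the force relaxes through the fork-opening
transition as unwinding proceeds. Combined trap stiffness 0.4 pN/nm
(passive mode, fixed separation); white Gaussian extension noise of
2 nm at 2500 Hz, propagated to the force channel through the trap
stiffness. The simulation is exact: enzyme positions are the only
extension changes, the equilibrium force at every reachable position is
precomputed by a monotone Newton solve of the force balance, and
propensities are refreshed at each position change.

**What the generator does not emulate** — bead Brownian dynamics and
trap anharmonicity, drift, multi-tether artefacts, sequence-resolved fork
energies, and the enzyme's off-pathway states. Closure of the pipeline on
these traces therefore demonstrates correctness of the estimator chain
under idealized noise, not robustness to instrument pathology.

## The trace pipeline and its estimator properties

The processing chain follows the standard passive-mode recipe: smooth
extension and force to 250 Hz with a centered truncated moving average;
convert to contour (bp); estimate velocity as the OLS slope in
non-overlapping 100-ms windows paired with the window-mean force; apply a
running median filter of one tenth of the window count per trace
(shrinking at the edges); pool windows across the trace ensemble of each
condition and bin at 3 pN (opposing) or 2 pN (hairpin) over 0–60 pN,
dropping bins with fewer than 5 points. Windows are non-overlapping so
that per-bin standard errors are computed from effectively independent
points; overlap is configurable but would invalidate the naive s.e.m.

One estimator property deserves flagging. When fewer than ~2 steps fall
in a window, the per-window velocity distribution is right-skewed
(stepping shot noise), and a running *median* then systematically
underestimates the *mean* velocity — a few percent at typical conditions,
up to tens of percent in the slowest bins. With the median filter
disabled the pipeline closes on the generating velocity surface
essentially everywhere; with it enabled a small minority of slow bins sit
beyond three standard errors in a seed-dependent way. The default remains
the standard recipe (the filter exists to suppress outliers in real
data, where symmetric measurement noise dominates and the bias is
negligible); quantitative closure work on clean synthetic data should
pass `median_frac = 0` to `process_traces()`.

## Fitting, selection, and identifiability

`fit_cycle()` minimizes the unweighted SSE between binned velocities and
the model surface evaluated at bin-center forces (weighted 1/sem² is
available behind a flag), with rates on log10 scale in [1e-2, 1e8],
`delta` in [0.5, 10] bp, `dG_dest` in [0, 5] kBT, multi-start local
optimization (Latin-hypercube placement plus one data-scaled heuristic
start, `nlminb` descent), deterministic under a fixed seed. By default
hydrolysis and release are tied (`k_h = k_r`, one composite catalytic
parameter) to limit the parameter count; the two-rate variant is a flag.
`mode = "separate"` fits each geometry its own rate set — the strategy
appropriate when partner subunits may modulate the microscopic rates —
and `select_scheme()` ranks all six schemes by the sum of minimized SSE,
always reporting the full ranking. Parameter uncertainties use a residual
bootstrap (default 200 resamples) rather than curvature-based errors,
since the binned residuals are heteroscedastic and the objective is not a
likelihood.

Three identifiability facts, established numerically by the package's own
probes and worth knowing before interpreting any fit:

1. **Placement degeneracy.** Schemes differing only in where the step
   sits overlap exactly on single-geometry `v(F, [ATP])` surfaces:
   another placement can reproduce the generating surface by parameter
   compensation (for instance, a stroke at hydrolysis mimics a stroke at
   release as `k-b → 0`). Under separate-rates fitting the overlap
   persists with both assays, so binding-vs-hydrolysis rectification for
   a ratchet truth is decided by noise between two near-tied fits.
2. **Mechanism nesting.** Every ratchet scheme nests its power-stroke
   counterpart (`K_eq → 0` turns the reversible ratchet step into a
   stroke), so discrimination is one-directional: no power-stroke scheme
   can reproduce a genuine ratchet surface (the force-shifted `K_M`
   crossover with a near-constant `v_max` at moderate force), while
   ratchet schemes always fit power-stroke data.
3. **Hairpin-side degeneracies.** In the hairpin geometry force enters
   only through `P_open`, so `delta` appears purely as an amplitude and
   trades against `k_c_eff`; and when `K_eq >> P_open` across the
   sampled forces, `K_eq` enters only in products with other rates — its
   profiled SSE is flat over orders of magnitude. Step size and ratchet
   equilibrium should be read from the opposing-force context, where the
   Bell force scale `kBT/delta` and the `K_M(F)` crossover pin them.

## Numerical choices

* Steady states: null-space solve (QR, residual-checked) as the reference
  path; closed-form unicyclic flux for fitting; both error on
  non-finite input and return exactly zero velocity at [ATP] = 0.
* `v_max` by decade-doubling of ATP until the relative change per decade
  is below 1e-6; `K_M` by monotone bracketing to 1e-8 relative.
* Force balance: damped Newton with analytic tether compliance,
  1e-9 pN residual tolerance, error (with the offending position) on
  non-convergence.
* Constant-force oracle runs measure velocity from the stationary
  increment after a 20% burn-in: runs start in a fixed cycle state, and
  the first cycle otherwise contributes an O(delta/duration) bias.
* Reproducibility: every stochastic entry point takes a seed; per-trace
  seeds derive deterministically from a master seed; identical seeds give
  bit-identical event lists.

## Problem sizes used by the tests and the acceptance script

The stochastic-oracle grid uses all 6 schemes x 2 geometries x 5x5
(force, ATP) cells with 200 runs per cell, each long enough to expect
roughly eight complete cycles (0.15–3 s). The closure study uses 10
traces per condition at 5 ATP concentrations per geometry (4-s opposing
traces, 1.5-s hairpin traces); the recovery study repeats it over 5
master seeds with 6-start fits. These sizes put all simulation-based
checks within a few minutes on one CPU while keeping every per-bin
standard error honest.

## Known limitations

* Single-cycle models only: no off-pathway pauses, no auxiliary
  ATP-binding sites (their effect is absorbed into effective binding
  rates), no inter-subunit coupling in the two-motor assay.
* The hairpin fits inherit the `P_open` dialect choices; absolute values
  of `dG_dest` shift if a different zipper convention is assumed.
* Selection is by raw SSE, as is conventional for this analysis; AIC is
  reported informationally because the ratchet schemes carry two more
  parameters than the strokes and SSE alone cannot penalize the nesting
  of point 2 above.
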