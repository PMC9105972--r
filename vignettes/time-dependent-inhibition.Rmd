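---
title: "Modelling time-dependent enzyme inhibition: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling time-dependent enzyme inhibition: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdikin)
```

# The problem

Classical steady-state inhibition analysis rests on three assumptions: free
ligand ($[S], [I] \gg e_0$), steady state, and rapid equilibration of every
binding step. Slow-binding and slow-dissociating inhibitors violate the
third. When the enzyme--inhibitor complex relaxes on the same timescale as
the measurement, the "initial velocity" an experimenter records is not the
steady-state rate, and the familiar double-reciprocal machinery silently
returns wrong constants and even a wrong mechanism.

The failure mode this package is built around is the *pre-incubation
artifact*. To sidestep slow onset, enzyme and inhibitor are routinely
pre-incubated to equilibrium before the reaction is started with substrate.
But if the inhibitor dissociates slowly (long residence time
$\tau = 1/k_{\mathrm{off}}$), the substrate-driven displacement of the
EI equilibrium is itself slow: the enzyme appears to *activate* over tens
to hundreds of seconds. Velocities read early in the trace then follow

$$v_{\mathrm{meas}} = \frac{V_{\max}}{1 + I/K_i}\cdot\frac{S}{S + K_m},$$

the pure-noncompetitive form, rather than the true competitive law

$$v_{\mathrm{ss}} = \frac{V_{\max}\,S}{S + K_m\,(1 + I/K_i)}.$$

For intermediate $k_{\mathrm{off}}$ the measured velocities fall between
the two laws and a spurious "mixed-type" mechanism is diagnosed with an
apparent uncompetitive constant $K_{iu}$ that shrinks as the residence time
grows. The package's case study is acetylcholinesterase inhibited by
galantamine, where this artifact is quantified and then resolved by global
fitting of full progress curves.

# Models

## Mass-action core

Mechanisms are explicit reaction networks (`mechanism()`, `build_scheme()`)
integrated by exact mass action; no steady-state or rapid-equilibrium
shortcut enters the simulations. Four schemes are built in:

* `competitive_mm` / `mixed_mm` — generic Michaelis--Menten schemes with a
  one-step inhibitor (and, for the mixed variant, an ESI complex);
* `slyke_cullen_product` — the two-step irreversible hydrolysis
  $E+S \xrightarrow{k_1} EA+P$, $EA \xrightarrow{k_2} E+A$ appropriate for
  acetylcholinesterase ($k_1 \equiv k_{cat}/K_m$, $k_2 \equiv k_{cat}$,
  $K_m = k_2/k_1$), with competitive product binding
  $E+P \rightleftharpoons EP$ ($k_3/k_4$). In the Ellman assay the
  detected chromophore (thiocholine-TNB) *is* the inhibitory product, so
  product inhibition must be carried in the model;
* `slyke_cullen_product_inhibitor` — the same plus a one-step competitive
  inhibitor $E+I \rightleftharpoons EI$ ($k_5/k_6$, i.e.
  $k_{\mathrm{on}}/k_{\mathrm{off}}$; $K_i = k_6/k_5$).

Units are molar and seconds throughout; converters (absorbance via
$A = \varepsilon\, l\, [P]$, $\varepsilon = 13{,}600$ M$^{-1}$cm$^{-1}$)
are explicit and never inferred.

## Protocols

`run_protocol()` executes multi-phase experiments — pre-incubation, order
of addition, sequential substrate additions into the same cuvette — with
state continuity across phases apart from the stated additions. A long
E--I pre-incubation whose only active chemistry is one reversible
bimolecular step is resolved analytically (`equilibrium_bound()`, the
depletion-aware quadratic) whenever the relaxation time
$1/(k_{\mathrm{on}} c + k_{\mathrm{off}})$ is below one twentieth of the
phase duration; integrating $10^6$ s of an equilibrated flat system adds
nothing but solver cost. The criterion is conservative and the numerical
path remains available (`shortcut = FALSE`); the two agree to well inside
the integration tolerance (tested).

# Tunable parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `rtol` | 1e-8 | — | rate constants span $10^{-4}$–$10^8$; the schemes are stiff and an implicit solver (lsoda with analytic Jacobian) with a tight relative tolerance keeps trajectories integrator-independent to $<10^{-4}$ |
| `atol` | 1e-12 M, scaled | M | a fixed 1e-12 M floor is far too loose for 100 pM enzyme species, so the assay generator scales it to $10^{-6} e_0$; sub-nanomolar species then retain $\ge 4$ significant digits |
| `dead_time_s` | 10 | s | typical mixing-to-detection lag without stopped flow; the quantity that hides (or reveals) slow relaxations |
| `window_s` | 10 | s | the span of trace used for an "initial" velocity |
| velocity `mode` | `"chord"` | — | see below |
| classification thresholds | 10, 1.25 | — | labels only; a $K_{iu}/K_{ic}$ ratio ≥ 10 reads competitive, ≤ 1.25 noncompetitive, between is mixed. They never enter numeric fits |
| `init_bounds_frac` | 0.2 | — | when nominal concentrations are co-fitted they stay within ±20% of nominal, reflecting pipetting accuracy |

## The initial-velocity definition

Two operational definitions are provided. `mode = "window"` is an OLS slope
on $[t_{\mathrm{dead}}, t_{\mathrm{dead}}+w]$ — an instantaneous-rate
estimate that ignores everything before the dead time. `mode = "chord"`
(the default) is the straight line from the reaction start, whose signal the
blank fixes at zero, to the first reading after the dead time:
$v = \mathrm{signal}(t_1)/t_1$ with $t_1 = \max(t_{\mathrm{dead}}, w)$.
The chord is what the dashed "slope of the first seconds" lines on an assay
trace depict, and it is the definition under which the dissociation-rate
scan reproduces the documented transition of the apparent mechanism: with
the chord, the apparent $K_{iu}/K_{ic}$ ratio at
$k_{\mathrm{off}} = 3\times10^{-2}$ s$^{-1}$ lands at the expected ~20 and
the mixed-type band spans $3\times10^{-4}$–$3\times10^{-2}$ s$^{-1}$,
whereas the window slope — which integrates a partially re-activated
enzyme — displaces the whole band about threefold toward faster
$k_{\mathrm{off}}$. Both modes are kept because the difference between them
is itself an instance of the package's central point: what you call an initial
velocity decides the mechanism you will report.

# The synthetic-data generator

`generate_curves()` is first-class, tested code, and its defaults *are* the
study conditions:

* the dissociation-rate scan (`preincubation_design()`): $K_m \approx 10$ µM
  (ES on/off $10^8$ M$^{-1}$s$^{-1}$ / 1 s$^{-1}$, $k_{cat}=1000$
  s$^{-1}$), $K_i = 1$ µM held fixed while
  $k_{\mathrm{off}} \in [10^{-5}, 10^3]$ s$^{-1}$ varies
  ($k_{\mathrm{on}} = k_{\mathrm{off}}/10^{-6}$), $e_0 = 100$ pM, substrate
  1–200 µM (nine levels; the scan figure uses the eight-level 2–200 µM
  grid), inhibitor 0–50 µM (eight levels), $10^6$ s pre-incubation, 10 s
  dead time, substrate-initiated;
* the Ellman-assay layouts (`gal_design()`): 200 pM (enzyme-initiated) or
  50 pM (substrate-initiated, 20 min pre-incubation) enzyme, ATCh
  10–200 µM, galantamine 5–400 nM, 60 s monitored; the five-addition
  product series (5 × 35 µM ATCh, one continuous trace); and the
  global-fit series (50 µM ATCh, GAL 0–180 nM, up to 33 min).

Choices the protocols leave open were fixed once: the sequential-addition
phases last 500 s each (long enough for each 35 µM load to be consumed
even under ~140 µM product inhibition); sampling is 0.5 s for the 60 s
assays and 1 s for the long fitting series, ordinary spectrophotometer
rates that also keep the test suite and the acceptance script fast.
Enzyme-initiated mixing is instantaneous (all species present, zero
complexes at $t=0$); the ~0.2% cuvette dilution from 2 µL additions is
ignored as far below any other error source.

Noise is off by default — the synthetic study is noiseless, and noise
exists for robustness tests. When on, it is Gaussian with an additive
absorbance component and a relative (CV) component; per-curve seeds derive
from a stable hash of (s0, i0, replicate), so datasets are reproducible and
independent of generation order.

What the generator does *not* emulate: mixing transients, instrument
drift and baseline offsets, DTNB reaction kinetics (detection is treated
as stoichiometric and instantaneous), pipetting error in the nominal
concentrations, and temperature effects. Passing tests therefore
demonstrate correctness of the analysis machinery under the model's own
assumptions, not robustness to everything a real cuvette can do.

# Global fitting

`fit_progress()` minimizes the unweighted sum of squared residuals on the
detected-signal scale over all curves simultaneously, by trust-region
Levenberg--Marquardt (minpack.lm) with every free parameter in $\log_{10}$
space — rate constants span ten decades and log-scale optimization both
enforces positivity and equalizes step sizes. Convergence demands a
relative loss change below $10^{-10}$ and a step norm below $10^{-8}$.
Because the loss is a uniform rescaling under unit conversion, fitting in
absorbance or concentration units gives identical estimates (tested to
$10^{-6}$).

The case-study workflow is two-stage, mirroring how the catalytic
machinery must be pinned down before the inhibitor is probed:

1. **`fit_stage1()`** frees $k_1, k_2, k_4$ on the five-addition product
   series, fitted as *one* continuous multi-phase trajectory — the shared
   cuvette state (accumulating product) is the point of the design. $k_3$
   is fixed at the diffusion limit $2\times10^8$ M$^{-1}$s$^{-1}$: near
   binding equilibrium only the ratio $K_{i,P} = k_4/k_3$ is identified,
   and the fitted $K_{i,P}$ is insensitive to the choice of $k_3$ (tested
   against $10^9$).
2. **`fit_stage2()`** constrains $k_1..k_4$ to their stage-1 values and
   frees $k_5, k_6$ on the enzyme-initiated inhibited series. The
   pre-steady-state onset of inhibition — visible because the reactions are
   started *without* pre-incubation — is what separates $k_5$ from $k_6$;
   $K_i = k_6/k_5$ and $\tau = 1/k_6$ are derived, never fitted
   independently. Per-curve substrate and a shared enzyme concentration can
   be co-fitted (`fit_s0`, `fit_e0`, ±20%); sharing $e_0$ across curves is
   assumed since all curves come from one enzyme stock.

Standard errors come from the linearized Jacobian at the optimum —
adequate near a deep noiseless optimum, misleading in flat directions —
so `profile_uncertainty()` re-optimizes the remaining parameters along a
grid of one parameter and returns the residual-norm profile. A Jacobian
condition number above $10^8$ flags structural unidentifiability (an
uninhibited dataset flags $k_5, k_6$ immediately); parameters at bounds are
warned about, and a non-converged fit marks its estimates provisional.

# Numerical choices and degenerate inputs

* Stiff integration: lsoda with an analytic mass-action Jacobian;
  tolerance-halving changes no reported concentration by more than
  $10^{-4}$ relative (tested).
* Negative concentrations: values in $[-10\,\mathrm{atol}, 0)$ are clamped
  to zero; anything more negative is an error, not a warning — it means
  the tolerances failed.
* Conservation: every built-in scheme carries conserved moieties (total
  enzyme, substrate-derived material); drift along full protocols stays
  below $10^{-6}$ relative (tested).
* Replot degeneracies: a replot slope that is non-positive or below
  $10^{-3}$ of intercept$/I_{\max}$ reports the component as *absent*
  ($K = \infty$), exported as an empty field plus a boolean flag, never a
  numeric sentinel. Velocity records with $v \le 0$ are excluded from
  reciprocal fits with a warning. Fewer than three inhibitor levels, or
  fewer than two substrate levels per inhibitor level, is an error.
* Dissociation-fraction arithmetic: $1 - e^{-k_{\mathrm{off}}t}$ gives
  95.0% at $3.0\tau$ and 96.98% at $3.5\tau$; the package reports the
  analytic value. (Statements that ~95% dissociation takes $3.5\tau$
  round the same curve differently.)

# Problem sizes

The shipped defaults — 64–72 conditions per scan point, 2.5 ks / 2501
samples for the product series, six curves × 1981 samples for the
inhibited series — run the full test suite in well under a minute and the
acceptance script in seconds on one CPU. These sizes were chosen as
realistic assay dimensions; nothing in the machinery depends on them.

# Known limitations

* One-step inhibitor binding only; the two-step induced-fit isomerization
  mechanism some slow binders follow is out of scope, as are tight-binding
  (Morrison) corrections — the free-ligand approximation is assumed by the
  *analysis* layers (the simulator itself is exact).
* No thermodynamic-cycle consistency checks for user-built mechanisms, no
  spatial/temperature models.
* Linearized standard errors; use the profile for anything that matters.
* The apparent-mechanism classification is a label with configurable
  thresholds, not an inference.
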