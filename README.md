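# tdikin — time-dependent enzyme inhibition kinetics

`tdikin` is an R package for enzymologists and medicinal chemists who work
with **slow-binding / slow-dissociating inhibitors** — compounds whose
enzyme–inhibitor complex equilibrates on the same timescale as the assay.
For such inhibitors the standard initial-velocity analysis quietly breaks:
after an enzyme–inhibitor pre-incubation, a long residence time
(τ = 1/k_off) makes a purely competitive inhibitor *look* mixed-type or
noncompetitive, and without pre-incubation its potency is grossly
underestimated. The package both reproduces these artifacts quantitatively
and implements the analysis that avoids them: global fitting of full
reaction progress curves by ODE integration, which recovers the true K_i
together with the microscopic rate constants k_on and k_off.

## The models

Mechanisms are mass-action reaction networks integrated with a stiff
solver. The two laws at the heart of the pre-incubation artifact are the
true competitive steady-state rate

    v_ss = Vmax · S / (S + Km · (1 + I/Ki))

and the rate actually measured when a pre-incubated EI complex fails to
dissociate during the measurement,

    v_meas = Vmax / (1 + I/Ki) · S / (S + Km)

— formally the pure-noncompetitive law. Measured velocities interpolate
between the two as k_off varies, which is what the Dixon / Cornish–Bowden
replot machinery then misreads as a mechanism change.

The case study is acetylcholinesterase (Ellman assay, where the detected
thiocholine-TNB chromophore is itself a competitive product inhibitor)
inhibited by galantamine, modelled with the van Slyke–Cullen scheme:

    E + S  →  EA + P        k1  (= kcat/Km)
    EA     →  E + A         k2  (= kcat)
    E + P  ⇌  EP            k3 / k4   (product inhibition, Ki,P = k4/k3)
    E + I  ⇌  EI            k5 / k6   (inhibitor, Ki = k6/k5, τ = 1/k6)

## Worked example

Scan the dissociation rate and watch a competitive inhibitor's *apparent*
mechanism change with its residence time (K_i is 1 µM throughout):

```r
library(tdikin)
koff_scan(c(1e-4, 3e-3, 3e-2, 1e2))
#>   k_off K_ic_app K_iu_app    ratio classification
#> 1 1e-04 1.04e-06 1.10e-06     1.06 noncompetitive
#> 2 3e-03 1.11e-06 3.92e-06     3.52          mixed
#> 3 3e-02 1.09e-06 2.43e-05    22.40    competitive
#> 4 1e+02 1.04e-06 1.32e-02 12700.00    competitive
```

The apparent competitive constant stays near the true 1 µM, but a spurious
uncompetitive component (finite `K_iu_app`) materializes as k_off drops:
at k_off = 3×10⁻² s⁻¹ the replots report K_iu ≈ 20 K_ic, and for very slow
dissociation the inhibition looks purely noncompetitive — all from
simulated data generated with an unchanging competitive mechanism.

The two-stage progress-curve fit recovers the galantamine constants from
full time courses (here a noiseless self-consistency round trip starting
from 3-fold-perturbed guesses):

```r
truth <- tcache_rates()   # published TcAChE/galantamine parameter set
c1 <- generate_curves(gal_design("product_series"),
                      build_scheme("slyke_cullen_product"),
                      truth[c("k1", "k2", "k3", "k4")])
s1 <- fit_stage1(c1, start = c(k1 = truth[["k1"]] * 3,
                               k2 = truth[["k2"]] / 3,
                               k4 = truth[["k4"]] * 3))
c2 <- generate_curves(gal_design("gal_fit_series"),
                      build_scheme("slyke_cullen_product_inhibitor"), truth)
s2 <- fit_stage2(c2, s1, start = c(k5 = truth[["k5"]] * 3,
                                   k6 = truth[["k6"]] / 3))
s2
#> Global progress-curve fit (6 curves, 11886 points)
#> Converged in 7 iterations; RSS = 4.811e-31
#>     estimate        se
#> k5 1.900e+06 1.421e-07
#> k6 1.606e-02 1.489e-15
#> Derived:
#>   Km       7.949e-06
#>   kcat     2965
#>   kcat_Km  3.73e+08
#>   Ki_P     2.154e-05
#>   Ki       8.45e-09
#>   tau      62.29
```

Stage 1 pins the catalytic machinery on a five-addition product-inhibition
series (k_cat = 2965 s⁻¹, k_cat/K_m = 3.73×10⁸ M⁻¹s⁻¹, product
K_i = 21.54 µM); stage 2 constrains those values and extracts the
inhibitor rates from the pre-steady-state onset of inhibition:
k_on = 1.9×10⁶ M⁻¹s⁻¹ and K_i = k6/k5 = 8.45 nM — a ~100-fold higher
potency than initial-velocity analysis of the same system suggests
(`run_steady_state()` shows the enzyme-initiated emulation misreporting
K_i above 100 nM).

`plot(s2)` overlays data and fitted curves; `profile_uncertainty()` gives
profile-based uncertainty for any free parameter.

## Command line

A thin wrapper over the pipeline functions is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/tdikin.R", package="tdikin"))')" \
    scan-koff --out runs/scan --seed 1
```

Commands: `simulate`, `scan-koff`, `steady-state`, `globalfit`; each takes
`--config FILE` (YAML), `--out DIR`, `--seed N` and writes its tables plus
a reproducibility manifest.
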