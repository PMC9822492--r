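---
title: "Modelling nanoparticle passage through the stratum corneum as diffusion in an equivalent capillary"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling nanoparticle passage through the stratum corneum as diffusion in an equivalent capillary}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corneocap)
```

## The model chain

The stratum corneum — the outermost, rate-limiting layer of the epidermis —
is classically idealised as bricks and mortar: rectangular keratinocytes of
footprint $a \times b$ and height $h_k$, embedded in lipid channels of
width $d$. Transdermal transport of nanoparticles proceeds through the
lipid channels. `corneocap` implements this picture as a chain of three
models:

1. **Geometric reduction.** A skin patch of size $L_1 \times L_2$ holds a
   real-valued number of keratinocytes per direction,
   $n = (L + d)/(a + d)$, under which the patch edge is reconstructed
   exactly: $a\,n + (n-1)\,d = L$. The fraction of the surface occupied by
   lipid, $\varepsilon = (S - S_n)/S$, and the keratinocyte specific
   surface, $a_p = 2(ab + b h_k + a h_k)/(a b h_k)$, reduce the channel
   network to a single capillary of hydraulic radius
   $$r_h = \frac{\varepsilon}{a_p\,(1 - \varepsilon)},$$
   the standard hydraulic-radius reduction of a granular (Kozeny–Carman)
   bed. For the reference patch ($L = 2$ cm, $a = b = 20\ \mu m$,
   $d = 50$ nm, $h_k = 10\ \mu m$) this gives $r_h = 12.5$ nm, a capillary
   diameter of 25 nm.

2. **Stochastic transport.** Nanoparticles of diameter $d_p$ move in the
   capillary under a thermal force of per-axis scale
   $\sigma_F = \sqrt{6\pi k_B \eta T d_p/\Delta t}$ balanced by Stokes drag
   $\gamma = 3\pi\eta d_p$. The top face and the cylindrical wall reflect
   specularly; the bottom face absorbs. The output is the passage curve:
   the cumulative fraction $N_{pt}/N_{p0}$ of released particles absorbed
   at the outlet versus time.

3. **Effective-diffusion summary.** A mass balance built on Fick's first
   law, closed with an empirical shape exponent $n$, gives the Hill-form
   saturation model
   $$\frac{N_{pt}}{N_{p0}} = \frac{D_{\mathrm{eff}}\,t^{\,n}}{h^2 +
   D_{\mathrm{eff}}\,t^{\,n}},$$
   which is fitted to each passage curve to extract the effective
   diffusion coefficient $D_\mathrm{eff}$ and exponent $n$.

## Parameters that matter

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `L1`, `L2` | patch size, m | 0.02 | reference donor area (2 cm square) |
| `a`, `b`, `h_k` | keratinocyte size, m | 2e-5, 2e-5, 1e-5 | typical corneocyte footprint and layer thickness |
| `d1`, `d2` | lipid channel width, m | 5e-8 | typical inter-corneocyte gap |
| capillary `length` | diffusion distance, m | 1e-6 | resistance of one keratinocyte layer |
| `d_p` | particle diameter, m | — | study grid 1–15 nm |
| `rho_p` | particle density, kg/m³ | 2200 | mineral (silica-like) carriers |
| `eta` | fluid viscosity, Pa·s | — | study grid 10–50 mPa·s |
| `temperature` | K | 298 | ambient; comparison tables pin 293 (see below) |
| `n_particles` | released particles | 5000 | count beyond which curves stop changing |
| `t_end` | horizon, s | 500 | reference end time |
| `release_offset` | release depth, m | 3e-8 | particle centres start 30 nm below the top |
| `h` (fitting) | Hill diffusion length, m | 1e-6 | fixed; a free `h` is degenerate with `D_eff` |

Two deliberately distinct lengths appear: the keratinocyte height
`h_k = 1e-5` m enters only the geometric reduction (it is what makes
$r_h$ come out at 12.5 nm), while the capillary/diffusion length
`1e-6` m enters only transport and fitting. They are independent fields
and are never shared.

Two temperature conventions are supported. The package default is 298 K;
the bundled comparison tables are numerically consistent with 293 K, so
`build_comparison()` pins 293 K by default. The Boltzmann constant is
`1.381e-23` J/K throughout.

The Stokes–Einstein comparison deliberately uses the *diameter* form
$D = k_B T/(6\pi\eta d_p)$ (`stokes_einstein_printed()`), half the
standard radius-form value, because the reference comparison tables were
computed with that convention. The physical free diffusion coefficient of
the dynamics is `free_diffusion_coefficient()`, $k_B T/(3\pi\eta d_p)$.

## Numerical choices

**Integrator.** The momentum relaxation time
$\tau = \rho_p d_p^2/(18\eta)$ is at most $3\times10^{-12}$ s on the study
grid — at least six orders of magnitude below any feasible time step — so
the default scheme is overdamped: per-axis Gaussian increments of standard
deviation $\sqrt{2 D \Delta t}$ with $D = k_B T/\gamma$. This is exactly
equal in law to the thermal-force/drag balance because
$(\sigma_F \Delta t/\gamma)^2 = 2 D \Delta t$ holds identically
(fluctuation–dissipation). A semi-implicit Langevin scheme that integrates
the velocity explicitly is retained for cross-validation; the test suite
verifies the two schemes agree in passage law.

**Time step.** `auto_timestep()` picks the largest $\Delta t$ whose
per-axis RMS displacement stays below one fifth of the accessible radius
and one third of the release offset, and at least $100\tau$. The first
bound keeps wall collisions resolved; the second keeps the initial
condition meaningful; the third keeps the overdamped limit valid.

**Walls and absorption.** Finite particle size enters only through the
accessible radius $r_\mathrm{acc} = r_h - d_p/2$ (centre-excluded shell);
no hydrodynamic wall retardation is modelled. Absorption is tested on the
straight pre-reflection segment — if the proposed axial move crosses the
outlet plane the particle is absorbed before any reflection is applied —
and by default the *centre* crossing `length` counts as absorbed
(`absorb_at_contact = TRUE` moves the plane to `length - d_p/2`).
Reflection is specular, applied repeatedly. Near-tangential chords can
bounce arbitrarily often (each grazing bounce consumes a vanishing chord),
so after 512 bounces the float-scale grazing remainder is terminated on
the wall; a gross excess there is a hard error. Because neither wall
interaction alters the axial coordinate's law, axial motion is exactly
one-dimensional diffusion on a reflecting–absorbing interval; the package
therefore ships the closed-form eigenfunction series
`first_passage_fraction()` (truncated when the term envelope falls below
1e-12) as an exact oracle, and the tests hold simulated curves to its
99.7% binomial band at every recorded time.

**Fitting.** `fit_hill()` runs bounded Levenberg–Marquardt on the fraction
scale, unweighted, with $D_\mathrm{eff} \in (0, \infty)$ and
$n \in (0, 5]$, initialised by the exact logit–log linearisation
$\log(F/(1-F)) = \log(D_\mathrm{eff}/h^2) + n \log t$ over interior points
(points at exactly 0 or 1 are kept in the nonlinear fit, excluded only
from the initialiser). Absolute time in seconds is used; fitting on
normalised time $t/t_c$ would rescale $D_\mathrm{eff}$ by the known factor
$t_c^{\,n}$ and nothing else. Non-convergence flags the result rather than
raising. $R^2$ is $1 - SS_\mathrm{res}/SS_\mathrm{tot}$ on the fraction
scale.

**Reproducibility.** One seeded generator; particles are simulated in a
fixed order, each consuming its draws sequentially, so every curve, sweep
and output file is bit-identical given the seed.

## What the synthetic generator does and does not emulate

`generate_hill_curve()` produces exact Hill curves with optional additive
Gaussian noise, clipped to $[0,1]$ and monotonised by running maximum — a
controlled stand-in for the sampling noise of a finite-particle passage
record. It validates the fitting machinery (round-trip recovery to 1e-4
relative without noise; median errors well under 20% at 2% noise). It does
not emulate the binomial, time-correlated noise of a real cumulative
count, nor any physics: passing fit tests demonstrates estimator
correctness, not model adequacy for skin data. Model adequacy is probed
separately by fitting the analytic first-passage curve, where the Hill
form achieves $R^2 > 0.95$ — adequate but not exact, matching its role as
a summary model.

## Problem sizes

The default sweep uses 1000 particles per cell with a per-cell horizon of
20 analytic mean first-passage times, which resolves every fitted
$D_\mathrm{eff}$ on the study grid to a few percent; the packaged
`default_sweep.yaml` config restores the full 5000-particle, 500 s
reference conditions for higher-fidelity runs. Oracle comparisons in the
tests use 1500–2000 particles, where the 99.7% binomial band is about
±3 percentage points at mid-passage.

## Design choices made where the design was open

* **Specific surface with all six faces.** The reduction admits a variant
  with half the specific surface (which doubles $r_h$ to 25 nm). The
  full-surface form follows from $a_p = S_p/V_p$ with
  $S_p = 2(ab + bh_k + ah_k)$ and is the only choice consistent with the
  12.5 nm reference radius, so it is the default; the halved variant is
  available via `printed_form = TRUE` for comparison.
* **The thermal random number is a standard normal,** independent per
  Cartesian component per step. Any bounded alternative would fail the
  realised-diffusivity checks in the simulator tests.
* **Real-valued brick counts.** Rounding $n$ to an integer breaks the
  exact edge reconstruction; the integer-tiling picture survives only as
  the brute-force oracle in the tests.
* **Centre-crossing absorption.** The contact convention (surface touches
  the outlet) is physically defensible too; it is exposed as a flag rather
  than a default because the centre convention keeps the analytic oracle
  exact at every particle size.

## Known limitations

* Fitted $D_\mathrm{eff}$ values from the ideal Brownian simulator are
  systematically larger than the bundled finite-element reference fits —
  an ideal reflecting-wall random walk passes particles faster than that
  solver's collision handling did. Sweep validation therefore asserts the
  *ordering* of $D_\mathrm{eff}$ across the grid (decreasing in $d_p$ and
  $\eta$), not its absolute values; the quantitative surface of the
  simulator is its agreement with the exact first-passage law.
* No inter-particle interactions, flow, electrostatics, hindered-diffusion
  wall corrections, or multi-layer stacking of the stratum corneum (the
  resistance of one keratinocyte layer is modelled; horizontal lipid
  layers are taken as negligible).
* The Hill exponent $n$ is a shape parameter, not a mechanistic quantity.

## A compact end-to-end run

```{r example, eval = FALSE}
library(corneocap)

cap <- reference_capillary()
tidy(cap)

cfg <- simulation_config(cap, particle_spec(5e-9), fluid_medium(0.01),
                         n_particles = 2000, t_end = 1, seed = 1)
curve <- run_simulation(cfg)
autoplot(curve)

fit <- fit_hill(curve, h = 1e-6)
glance(fit)
autoplot(fit)

build_comparison(reference_fit_table(), temperature = 293)
```
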