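---
title: "The linearized OHC amplifier: model, parameters, and numerical choices"
author: "ohcamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The linearized OHC amplifier: model, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ohcamp)
```

## The model and its assumptions

The outer hair cell (OHC) is modeled as three coupled linear subsystems:

1. **A two-state motor population.** The lateral wall carries `N`
   identical motile elements; each contributes length `a > 0` to the
   cell and moves charge `q < 0` across the membrane when it switches
   from the short to the long state. The open fraction `P` relaxes
   toward a Boltzmann equilibrium set by the membrane potential and the
   axial force. The package works **only** with the first-order
   expansion of that equilibrium about the operating point `P0`, which
   introduces the activity `gamma = 4 P0 (1 - P0)`; `gamma = 1` at
   `P0 = 0.5`, where the motors are most sensitive. Large-signal
   (saturating) behavior is deliberately out of scope: every solver in
   the package is exactly linear in the drive, and a test asserts that.

2. **A mechanical load.** The cell (axial stiffness `ko`) works against
   an external spring `Ke` (the basilar membrane), a viscous drag `eta`,
   and a mass. The mass is never given directly; the system is
   parameterized by its resonance frequency `fr` through
   `m = (ko + Ke)/omega_r^2`, because that is how the physiological
   scenarios are specified. Series and parallel attachment of the cell
   to the load differ only through the drive factor `alpha_c` (1 vs
   `1 - Kbar_e`); the distinction is negligible when `ua << 1`, and a
   property test verifies that the difference shrinks linearly with
   `ua`.

3. **The membrane circuit.** A structural capacitance `C0` and steady
   conductance `sigma`, driven by the hair-bundle (apical) conductance.
   Bundle deflection follows load displacement, so the relative
   resistance change closes the loop as `r = g p` with
   `g = a N (1 - Kbar_e) gx`. Amplification requires `g < 0` (cell
   shortening must increase transducer current); the reference scenario
   stores `gx` negative for that reason, and `guinea_pig_4khz(amplifying
   = FALSE)` flips it.

All solvers consume dimensionless groups (`derive_groups()`); see the
README table for their definitions. Two groups beyond the obvious ones
are required to close the algebra: `chi = beta N q^2/(4 C0)`, the
strain-induced polarization stiffness, and `a1 = beta q i0 g/(4 omega_r
C0)`, the bundle-current anti-damping gain. Dimensionless input mode
(`dimensionless_groups()`, or a YAML `dimensionless:` block) therefore
asks for both.

## Tunable parameters and defaults

| parameter | unit | default | why |
|-----------|------|---------|-----|
| `kBT` | J | 4.142e-21 | 300 K; the value under which the reference coefficients (`ua = 0.14`, `chi = 0.989`) reproduce exactly. Configurable. |
| `ua` | — | `beta a^2 N ko / 4` | The `/4` form is adopted: it is the form consistent with the linearization factor `gamma/4` and it reproduces the quoted 0.14 on the reference cell. |
| `omega_bar_eta` (figure mode) | — | 10 | The canonical `(ko+Ke)/eta/omega_r` gives 18.4 on the reference cell, but the published sweeps quote 10 — which is what `Ke/eta/omega_r` gives (9.95). Figure mode pins the quoted value; `derive_groups()` keeps the canonical definition and accepts an override. |
| `omega_bar_m` (figure mode) | — | 0.01326 | Derived from `sigma/(omega_r C0)` of the reference cell. The figure-discussion text also mentions 0.1, which contradicts the 0.013 printed beside it; 0.013 is the value consistent with the cell's electrical parameters and with the quoted approximation-error magnitudes, so the derived value is the default and `figure_mode_groups(omega_bar_m = )` allows the alternative. |
| `i0` mode | A | resting-potential | `i0 = (V0 - eK)/Rm` is how the quoted 0.3/0.4 nA arise; divider mode `(eep - eK)/(R0 + Rm)` is also provided. |
| grid | — | 400 log points | 100+ points per decade, enough for peak bracketing and refinement. High-frequency sweeps use 0.3–3, low-frequency 1e-3–1e-1. |

## The approximations

Above the middle frequency, expanding `1/(sigma + i w C0)` to first
order in `sigma/(w C0)` yields the anti-damping factor
`Ah = a1 - chi * omega_bar_m` and stiffness factor
`Bh(wb) = -ua Kbar_e + chi + a1 omega_bar_m / wb^2`. Two bookkeeping
decisions:

* The conductance term of `Ah` uses the **total** motile charge `N q`
  (i.e. `Ah_term2 = chi * omega_bar_m`). This is what an honest
  re-derivation of the expansion gives, and it reproduces the quoted
  0.013 on the reference cell.
* The `wb`-dependent third term of `Bh` is retained in coefficient
  reports (it is 0.0015 at `wb = 1` on the reference cell) but excluded
  from the scalar `Bh` used by the effectiveness condition, where it is
  negligible.

`hf_coefficients(include_sigma_correction = FALSE)` nullifies the
conductance entirely (both `Ah_term2` and `Bh_term3`), the "without
membrane conductance" variant of the sweeps.
`strain_stiffness_toggle(enabled = FALSE)` zeroes only `chi`, isolating
the stiffening-induced peak shift in the pure-piezo analysis.

Below the middle frequency the package does not use the first-order
resistive expansion at all: `lf_response()` is **defined** as the exact
response with `C0` nullified (`Al = chi/omega_bar_m`,
`Bl = -ua Kbar_e + a1/omega_bar_m`), and a test asserts elementwise
agreement with `exact_response()` at `C0 = 0` to 1e-13. Validity
warnings are issued (but computation proceeds) below `wb = 0.3` for the
high-frequency form and above `omega_bar_m/3` for the low-frequency
form, since plotting beyond validity is a legitimate use.

On the reference cell the recomputed coefficient summands are
`Ah = 0.1136 - 0.0131 = 0.1004` and
`Bh(1) = -0.0747 + 0.9889 + 0.0015 = 0.9157`. The published component
values `Ah_term1 = 0.165`, `Al = 862` and `Bl_term2 = 12.429` are **not**
recoverable from the tabulated cell parameters (they jointly imply an
effective feedback gain `|g|` of about 54, whereas
`a N (1 - Kbar_e) gx = 36.9`); `coefficient_report()` shows both sets
side by side, and the test suite asserts only the independently
verified quantities (`ua`, `omega_bar_m`, `chi`, the `Bh(1)` total
within 2%).

Similarly, the quoted bounds on the high-frequency approximation error
("<0.0008 in amplitude, up to 0.001 radian") are not exactly
reproduced by a faithful recomputation: over `wb` in `[0.3, 3]` (400 log
points, `gamma` in {0, 0.5, 1}) the package measures a maximum relative
amplitude discrepancy of about 1.1e-3 (at the `wb = 0.3` edge, where
the expansion parameter `omega_bar_m/wb` is largest) and a maximum
phase discrepancy of about 1.4e-3 rad (near the amplified peak, where
the denominator is smallest). These are the same order as the quoted
bounds and shrink with `sigma` exactly as the expansion predicts (a
property test scales `sigma` down and asserts monotone decay);
`approximation_error_report()` reports whatever the current scenario
gives. At `gamma = 0` both solvers evaluate the same expression and the
report is identically zero.

## The time-domain oracle

`integrate_forced()` integrates the 3-state reduced system
(`p`, `p'`, `w = (beta q/4) v`) with a fixed-step classical RK4 written
in C++, from rest, under cosine forcing, and
`steady_state_amp_phase()` extracts amplitude and phase by least-squares
quadrature fit over the final five cycles. Design choices:

* **Fixed step, deterministic step count** — results are
  bit-reproducible across runs and platforms with the same BLAS-free
  arithmetic. The integrator itself is cross-checked in a unit test
  against `deSolve::ode(method = "rk4")` on the same step grid
  (agreement to 1e-10) and against the damped-oscillator closed form at
  `gamma = 0` (1e-6).
* **Transient sizing from eigenvalues.** The discarded transient is 14
  e-foldings of the *slowest* eigenmode of the closed-loop matrix (at
  least 15 cycles). A rule based only on the mechanical envelope
  (`~ omega_bar_eta` cycles) would under-discard when the electrical
  pole (`rate ~ omega_bar_m`) is slower, which it is on the reference
  cell (decay time ~75 vs ~20 reduced time units).
* **256 steps per cycle** by default: the RK4 amplitude error is then
  ~1e-7 relative, comfortably below the 1e-4 oracle-equivalence
  tolerance; a Richardson-style test asserts that step halving changes
  the extracted amplitude by less than 1e-8.
* Integration refuses unstable closed loops (positive real-part
  eigenvalue) with an explicit error: without a steady state the
  comparison is meaningless.

The oracle integrates the same *linearized* equations as the
frequency-domain solver — that is the model; it is independent in
*method* (time stepping + fitting vs complex algebra), not in physics.

## The randomized scenario generator

`random_scenario(seed)` draws log-uniform multipliers within one decade
of the reference cell for `N`, `C0`, `sigma`, `i0`, `ko`, `Ke`, `eta`,
`fr` and `|gx|` (half a decade for `q`), and sets the unit displacement
`a` from a one-decade draw of `ua` itself
(`a = sqrt(4 kBT ua/(N ko))`). Drawing `ua` rather than `a` keeps the
small-signal expansion defensible across the whole family (`ua` stays
in ~(0.014, 1.4)) instead of letting the squared dependence on `a`
produce occasionally absurd gating strengths. Draws are resampled
deterministically from the seed stream until the closed loop at
`gamma = 1` is stable with a decay rate above 1e-3 (slowest transient
within ~1e3 reduced time units), because the oracle-equivalence
property presumes a reachable steady state. The generator restores the
global RNG state on exit.

What the synthetic scenarios do **not** emulate: correlated variation
of parameters along the cochlea (length-dependent `N`, `C0`, `fr`
co-vary in real cells), nonlinear saturation of the motor and
transducer, stochastic channel noise, and any multi-cell or
traveling-wave coupling. Passing tests therefore demonstrate internal
consistency of the linear model across a physiologically scaled
parameter box, not fidelity to any particular recording.

## Numerical choices elsewhere

* **Phase convention**: `exp(+i w t)` time dependence; phases are
  `Arg(p)` unwrapped along the grid (via `signal::unwrap`), starting in
  `(-pi, pi]`.
* **Peak refinement**: `peak_metrics()` re-evaluates the model (each
  response carries its evaluator closure) and refines the grid argmax
  with Brent's method on the bracketing interval; a peak at a grid
  endpoint is flagged, not refined. The phase drop is measured between
  0.5x and 1.5x the refined peak frequency on a dense local grid.
* **Degenerate inputs**: `sigma = 0` is allowed (purely capacitive
  membrane); `C0 = 0` is allowed in the SI solver path (purely
  resistive membrane, the low-frequency limit) but cannot be expressed
  in dimensionless mode, where `chi` and `omega_bar_m` would be
  infinite; `sigma = 0` together with `omega = 0` is an error.
* **Problem sizes**: test sweeps use 400-point grids; oracle
  equivalence runs 20 seeded scenarios at 5 frequencies each; the
  figure machinery regenerates all panels from 400-point sweeps. The
  full suite runs in a few seconds on one CPU.

## Known limitations

* Strictly linear, single-mode, local: no cochlear traveling wave, no
  multiple modes of motion, no fluid coupling beyond a lumped drag.
* The bundle sensitivity is frequency-independent and tied to load
  displacement (subtectorial shear assumed equal to basilar-membrane
  displacement); active hair-bundle dynamics are not modeled.
* The published component values that are internally inconsistent with
  the tabulated parameters (`Ah_term1`, `Al`, `Bl_term2`, and the
  low-frequency `ua Kbar_e = 0.069` vs the recomputed 0.075) are
  reported but cannot be reproduced; the package treats the tabulated
  SI parameters as the source of truth.
* `gating_compliance()` is the static, voltage-clamped, unloaded limit
  only.
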