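---
title: "A lumped-parameter model of LVAD cannulation in the failing, regurgitant heart"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lumped-parameter model of LVAD cannulation in the failing, regurgitant heart}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvloop)
```

## The question

A continuous-flow left ventricular assist device (LVAD) can take its
inflow either from the left atrium (LAAO: LA-to-aorta) or from the left
ventricle (LVAO: LV-to-aorta). Atrial cannulation spares the diseased
ventricle surgically, which is attractive when the pump is a bridge to
*recovery*; ventricular cannulation unloads the ventricle directly. When
the failing heart also has a leaky valve — mitral regurgitation (MR,
backflow LV→LA during systole) or aortic regurgitation (AR, backflow
aorta→LV during diastole) — the two cannulation sites interact with the
leak in opposite ways. `cvloop` simulates this interaction in a closed
0D (lumped-parameter) circulation and reports a per-cycle panel of
hemodynamic and energetic metrics.

## Model structure

The circulation is eight compartments in a closed loop — LV, systemic
artery, systemic vein, RA, RV, pulmonary artery, pulmonary vein, LA —
connected by linear resistances, with diode valves at the mitral,
aortic, tricuspid and pulmonary positions. Atria and vessels are linear
compliances `P = (V - V_u)/C`, floored at zero transmural pressure.
Total blood volume is exactly conserved by construction; the state
vector is the eight volumes plus one cross-bridge state per ventricle.

**Ventricular pressure** is passive plus active. The passive
(end-diastolic) law is exponential,
`P_pas = s * beta * (exp(kappa (V - V0)) - 1)`, continued linearly below
`V0`; heart-failure remodeling enters as the multiplier `s = 5` on the
whole passive curve. The active part couples a reduced two-state
cross-bridge model: attachment at rate `f_app` gated by a Hill function
of the calcium transient, detachment at `g_xb`; active tension
`t_max * a * SOVF(sl)` where `SOVF` is the piecewise-linear
single-overlap fraction of thick filaments and the sarcomere length
follows cube-root volume scaling `sl = sl_ref (V/V_ref)^{1/3}`. Chamber
pressure attenuates wall tension by the Laplace-like factor
`(V_ref/V)^{1/3}`. The ATP consumption rate is the detachment flux
weighted by overlap, `E = g_xb * a * SOVF(sl)` (1/s): one ATP per
cross-bridge cycle.

**The calcium drive** replaces an electrophysiology model: a normalized
rise–decay pulse `(1 - e^{-s/tau_r}) e^{-s/tau_d}` repeated every 600 ms
(BCL), amplitude 1.0 µM over a 0.1 µM diastolic level, with the failing
myocyte's amplitude scaled to 30% (a 70% reduction). We scale amplitude
only — not the time course — which is the literal remodeling
intervention; both ventricles receive the same transient (0D reduction
of a spatially resolved drive).

**Valvular regurgitation** follows a two-branch diode law: forward flow
`dP/R` when the valve is open, and when it is closed a backward leak
equal to `SF/100` of the forward-law flux at the same pressure
difference (equivalently a backward resistance `R * 100/SF`). `SF = 5`
models a 5% leak; both branches vanish at `dP = 0`, so the right-hand
side is continuous. The study conditions are `normal` (failing heart, no
leak), `ar` (`SF` on the aortic valve) and `mr` (`SF` on the mitral
valve), one leak at a time.

**The LVAD** is an ideal flow generator: a constant 40 mL/s withdrawn
from the inlet chamber and injected into the systemic artery, with no
cannula resistance and no preload/afterload sensitivity. A suction guard
derates the pump linearly between 20% and 10% of the inlet chamber's
unstressed volume; under every shipped configuration it stays inactive
(verified in the tests), so the time-averaged pump flux is exactly
40 mL/s.

## Parameters and defaults

All parameters are user-configurable (YAML round-trip via
`write_model_yaml()` / `load_model_yaml()`); the defaults are a
canine-scale failing heart:

* Myofilament: `f_app` 60/s, `g_xb` 15/s, `ca50` 0.5 µM, Hill
  coefficient 4, `t_max` 140 mmHg-equivalent, filament geometry
  1.65/0.1/1.2 µm. Canonical myocyte magnitudes; the two-state scheme is
  the minimal model exposing a detachment flux and an overlap fraction,
  which is all the ATP-rate definition needs.
* LV: `V0` 25 mL, `beta` 0.2 mmHg, `kappa` 0.03/mL, `passive_scale` 5,
  `sl_ref` 2.2 µm at `V_ref` 100 mL. RV: a weaker copy (`gain` 0.9
  vs the calibrated LV gain, softer passive curve).
* Network: valve resistances 0.03–0.05 mmHg·s/mL, systemic arterial
  resistance 2.1 mmHg·s/mL and compliance 1.5 mL/mmHg, venous and
  pulmonary elements sized so the calibrated loop carries ~570 mL at
  congestive-failure pressures (left atrial peak ~18 mmHg, mean arterial
  ~80 mmHg).

The two quantities the defaults cannot fix a priori — the active
pressure gain and the total blood volume — are set by
`calibrate_baseline()`, a damped Broyden iteration driving the
unassisted, non-regurgitant cell to the stated failing phenotype: stroke
volume 20 mL at end-diastolic volume 100 mL, i.e. 20% ejection fraction,
measured on the steady-state cycle. The shipped defaults are already the
fixed point of this calibration.

## Numerical choices

The stiff, piecewise-smooth system (diode switching) is integrated with
`deSolve::lsoda` through a compiled C right-hand side, `rtol = atol =
1e-8`, with dense output resampled at 1 ms. A pure-R reference
implementation of the same right-hand side (`network_rhs()`) is exported
and the test suite asserts exact agreement between the two routes. Valve
switching is handled by direct piecewise evaluation — both branches
agree at zero pressure difference — rather than event detection. Each
study run simulates 20 s (≈33 cycles) and measures the cycle from 18.6
to 19.2 s; the periodicity defect between the last two cycles is below
0.5% in every cell (typically ~0.1%), and total volume is conserved to
~1e-13 relative.

Metrics are read from the extracted cycle: LAPP/LVPP as whole-cycle
maxima (identical to systolic peaks for these waveforms), stroke work as
the orientation-corrected shoelace area of the PV loop, EF from the LV
volume extrema (with an aortic forward-volume cross-check), mean ATP
rate as the cyclic trapezoid mean, and regurgitant fractions as
backward-over-forward valve volume.

## What the trend report encodes

`trend_report()` turns the study's directional findings into pass/fail
comparisons between grid cells: atrial cannulation of the
non-regurgitant failing heart traps blood in the LV (LV pressure never
reaches aortic pressure, EF and stroke work exactly zero); untreated AR
lowers LV peak pressure and raises LA peak pressure; untreated MR raises
LA peak pressure; atrial cannulation under AR overloads the LV (higher
LVPP and ATP rate than the AR control, stroke work above the
normal-condition value) while ventricular cannulation does not raise ATP
consumption; either cannulation under MR lowers ATP consumption and
raises aortic pressure; support raises peak aortic pressure; and the
pump's inlet chamber is unloaded. One report row
(`ar_laao_overload`) compares stroke work against the normal-condition
value rather than the AR control: in a closed 0D loop the AR control's
loop area is inflated by the regurgitant shuttle volume itself, so the
worsening claim is the rise above the non-regurgitant workload.

Note the distinction: the percentage changes published for 3D
finite-element models (e.g. a 47% ATP rise) quantify a spatially
resolved heart that a 0D surrogate does not reproduce. Only the
*directions* of those effects, and the desk-scale anchors (SV 20 mL,
EF 20%, 0% EF under LAAO, exact 5%/70%/40 mL/s/600 ms parameter
fidelity), are asserted here.

## Worked example

```{r example, eval = FALSE}
cal <- calibrate_baseline(cv_model())
grid <- run_grid(cal)          # 9 cells x 20 s, ~1 s total
trend_report(grid)
```

## Known limitations

* The synthetic calcium pulse has a fixed shape; failing myocytes also
  slow the transient decay, which is not modeled (amplitude-only
  scaling).
* No force–velocity or strain dependence of the detachment rate, so ATP
  rate varies only through occupancy and overlap; absolute ATP values
  are on the single-cell scale (≈2/s), not comparable to mesh-aggregated
  figures.
* Atria are passive compliances (no atrial kick); the "atrial
  contraction phase" is the interval of passive venous filling in which
  LA pressure exceeds LV pressure.
* The residual diastolic activation floor (`a` ≈ 0.012 from the 0.1 µM
  diastolic calcium) leaves 1–2 mmHg of active pressure on the diastolic
  PV limb; the test suite verifies the exact passive/active
  decomposition rather than pretending the floor is zero.
* At activation above `a` ≈ 0.5 the Laplace attenuation can locally
  dominate the passive slope, so total pressure is guaranteed monotone
  in volume only on the diastolic branch.
* No coronary branch, baroreflex, inertances, or pulsatile pump control.
```
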