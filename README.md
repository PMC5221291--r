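# cvloop

Closed-loop, lumped-parameter (0D) simulation of a failing heart
supported by a continuous-flow left ventricular assist device (LVAD),
comparing the two inflow cannulation sites — left atrium to aorta
(LAAO) and left ventricle to aorta (LVAO) — under mitral or aortic
regurgitation.

## The problem

Atrial cannulation spares the diseased ventricle and is attractive when
an LVAD is a bridge to recovery; ventricular cannulation unloads the
ventricle directly. A 5% valve leak changes the calculus: aortic
regurgitation (AR) re-floods the ventricle from a pump-pressurized
aorta, mitral regurgitation (MR) overloads the atrium the pump may be
draining. `cvloop` is for modelers and physiologists who want this
interaction in a transparent, fully configurable desk-scale model with
an auditable energetic readout.

## The model in brief

* Eight-compartment closed circulation (two ventricles, two atria,
  systemic and pulmonary arteries and veins), linear resistances and
  compliances, diode valves.
* Ventricular pressure = exponential passive law
  `s·β(e^{κ(V−V0)} − 1)` (heart failure: passive scale `s = 5`) plus
  active pressure from a reduced two-state cross-bridge model driven by
  a periodic Ca²⁺ transient (BCL 600 ms; failing amplitude 30% of
  normal), with sarcomere overlap `SOVF(sl)` and cube-root
  volume-to-length coupling.
* ATP consumption rate `E = g_xb · a · SOVF(sl)` — the cross-bridge
  detachment flux weighted by the thick-filament single-overlap
  fraction, in 1/s.
* Regurgitation: backward flux through a closed valve equals `SF/100`
  of the forward-law flux at the same pressure difference (`SF = 5` for
  a 5% leak).
* LVAD: ideal flow generator, 40 mL/s, inlet LA (LAAO) or LV (LVAO),
  outlet systemic artery.
* Stiff integration with `deSolve::lsoda` on a compiled right-hand
  side; a pure-R reference implementation is exported and tested
  against it.

`calibrate_baseline()` anchors the model to the failing phenotype
(stroke volume 20 mL at 20% ejection fraction); `run_grid()` simulates
the 3 conditions × 3 groups study; `trend_report()` evaluates the
directional findings.

## Worked example

```r
library(cvloop)
cal  <- calibrate_baseline(cv_model())   # fixed point of the shipped defaults
measure_model(apply_cell(cal, condition("normal"), study_group("control")))
#> LAPP 18.2  LVPP 95.7  AoP peak/mean 87.6/81.8 mmHg
#> EDV 98.3  ESV 78.5  SV 19.7 mL  EF 20.1%
#> stroke work 1604.2 mmHg.mL  mean ATP rate 1.900 1/s
#> regurgitant fraction MI 0.000  AO 0.000
```

The unassisted failing heart ejects 19.7 mL from an end-diastolic
volume of 98 mL (EF 20.1%) at congestive filling pressures — the
calibrated baseline. The full study and its directional findings:

```r
grid <- run_grid(cal)      # 9 cells x 20 s each, about a second in total
trend_report(grid)
#> [PASS] laao_normal_zero_ef             0.000 vs    0.000  LAAO in the non-regurgitant failing heart: no ejection (EF ~ 0, stroke work ~ 0)
#> [PASS] laao_normal_isovolumic         -0.869 vs    0.000  LAAO in the non-regurgitant heart: LV pressure never exceeds aortic pressure
#> [PASS] ar_control_lv_unloaded         95.077 vs   95.667  Untreated AR: LV peak pressure below the non-regurgitant control
#> [PASS] ar_control_la_loaded           22.263 vs   18.152  Untreated AR: LA peak pressure above the non-regurgitant control
#> [PASS] mr_control_la_loaded           21.543 vs   18.152  Untreated MR: LA peak pressure above the non-regurgitant control
#> [PASS] ar_laao_overload              114.701 vs   95.077  LAAO in AR: LV peak pressure and ATP rate above the AR control, stroke work above the normal-condition value (worsening)
#> [PASS] ar_lvao_atp                     1.881 vs    1.886  LVAO in AR: mean ATP consumption rate not above the AR control
#> [PASS] mr_lvad_recovery                1.401 vs    1.788  Either cannulation in MR: lower ATP consumption and higher mean aortic pressure than the MR control
#> [PASS] normal_lvad_aortic_rise        98.648 vs   87.642  Either cannulation in the non-regurgitant heart: peak aortic pressure above control
#> [PASS] normal_inlet_unloading          8.724 vs   18.152  Non-regurgitant heart: the pump's inlet chamber peak pressure falls (LA under LAAO, LV under LVAO)
```

Reading the first two rows: with the pump draining the atrium, the
ventricle's peak pressure stays 0.9 mmHg below aortic pressure for the
whole steady-state cycle, the aortic valve never opens, and EF and
stroke work are exactly zero — blood is trapped in the ventricle. The
`ar_laao_overload` row shows the opposite failure mode: under AR the
same cannulation raises LV peak pressure from 95 to 115 mmHg.

`plot(simulate_circulation(m))` draws the steady-state PV loop of any
configured model. A thin command-line wrapper with `calibrate`, `run`,
`grid` and `report` subcommands ships in `inst/cli/cvloop.R`.

## Scope

The package models directions of hemodynamic effects at desk scale.
Percentage changes published for spatially resolved 3D heart models
(regional ATP maps, finite-element wall mechanics) are out of scope, as
are coronary perfusion, baroreflex control and pump speed modulation.
See the methods vignette (`vignettes/lvad-cannulation.Rmd`) for model
equations, parameter defaults, numerical choices and limitations.
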