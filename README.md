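# fontansim

Lumped-parameter (0D) simulation of the **fenestrated Fontan
circulation** — for physiologists, pediatric cardiologists and
modellers who want to explore when a fenestration (a surgical orifice
between the cavopulmonary conduit and the single atrium) actually
improves single-ventricle hemodynamics.

## The model in brief

Six compartments — single ventricle (SV), single atrium (SA), and the
arterial/venous capacitors of the systemic and pulmonary beds — form a
closed circuit. Chambers are time-varying elastance elements
interpolating between a linear end-systolic relation and an
exponential end-diastolic relation,

    P(V,t) = e(t)·E_es·(V − V_0) + [1 − e(t)]·A·(exp(B·(V − V_0)) − 1),
    e(t)   = 0.5·(1 − cos(π t / T_es))   for 0 < t < 2·T_es, else 0,

with the atrium leading the ventricle by 2% of the cycle. Each
vascular bed is a modified three-element Windkessel (R_c, C_a, R_a,
C_v, R_v); valves are ideal diodes with small series resistances. The
fenestration obeys the simplified Bernoulli orifice law, inverted for
flow:

    Q_f = sign(ΔP) · (π D² / 8) · √|ΔP|      [ml/s, D in mm, ΔP in mmHg]

The system is integrated with fixed-step RK4 (0.05 ms) to a periodic
steady state, and each converged cycle is reduced to the clinical
scalars: systolic/diastolic pressure at the aortic root, central
venous (conduit) pressure, cardiac index, Q_s/Q_p/Q_f, stressed blood
volume (SBV), Wood-unit resistance indices, and arterial/venous oxygen
saturations from a two-equation Fick shunt balance. Every protocol
holds systolic pressure at 87.2 mmHg by retuning SBV on a 1-ml grid.

## Worked example

```r
library(fontansim)

tuned <- tune_sbv(fontan_params())   # baseline, 2.5-mm fenestration
tuned
#> Tuned SBV: 428 ml (10 steady-state runs)
#> Hemodynamic summary (one converged cycle)
#>   BP 87.2/42.7 mmHg, CVP 12.9 mmHg
#>   CI 3.00 L/min/m^2 (Q_s 1.74, Q_p 1.40, Q_f 0.34 L/min)
#>   SpO2 91.1%, SvO2 58.2%, SBV 428 ml
#>   PVRI 1.83, SVRI 15.9 Wood units m^2
```

The tuner found the stressed blood volume (428 ml) at which the model
reaches the systolic target; at that operating point the conduit sits
at 12.9 mmHg, just over a third of systemic flow shunts right-to-left
through the fenestration, and the venous admixture pulls arterial
saturation down from 99% to 91%.

Pathophysiology sweeps pair fenestrated and non-fenestrated models at
matched systolic pressure. At elevated pulmonary vascular resistance
(PVRI 4.01 Wood units·m², i.e. `R_a,p = 0.3001`):

```r
sw <- run_scenario(fontan_params(),
                   scenario_grid("PVR", values = 0.3001, diameters = c(0, 2.5)),
                   start_SBV = 550)
compare_fenestration(sw, at_value = 0.3001)
#>    value      dCVP dSBV       dCI     dSpO2     dDBP
#> 1 0.3001 -2.619362  -71 0.1082833 -12.75685 -1.53051
```

The fenestration lowers CVP by 2.6 mmHg and the required stressed
blood volume by 71 ml while slightly raising cardiac index — the
decompression benefit that motivates fenestrating high-PVR patients —
at the cost of a 12.8-point saturation drop. Running the `Ees`, `B` or
`SVR` scenarios instead shows the benefit all but vanishing under
systolic/diastolic ventricular dysfunction or high systemic
resistance, while the desaturation remains.

A thin command-line driver wraps the same functions:

```sh
Rscript inst/cli/fontan.R dump-defaults --out config.yaml
Rscript inst/cli/fontan.R baseline --config config.yaml
Rscript inst/cli/fontan.R scenario --name pvr --out pvr_sweep.csv
Rscript inst/cli/fontan.R compare --sweep pvr_sweep.csv --at 0.3001
```

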