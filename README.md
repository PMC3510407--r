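# glioxide

Glioblastoma is set apart from lower-grade gliomas by necrotic foci
wrapped in dense rims of tumour cells — *pseudopalisades*.  The prevailing
mechanistic account is vascular: a capillary inside the tumour thromboses,
local oxygen collapses, the surrounding cells switch to a hypoxic,
migratory phenotype and move off as a wave toward the nearest functional
vessel, leaving necrosis behind.  `glioxide` implements a continuum model
of exactly this microenvironment for modellers and quantitative biologists
who want the morphometry of that process — how wide the hypercellular band
gets, how long it persists, how big the necrotic core grows, and how much
vaso-occlusion accelerates invasion — out of a transparent, testable
simulator rather than a histology slide.

## The model

Four fields on a 1-D transect of length `L_x` between two boundary
capillaries: normoxic density `u_n`, hypoxic density `u_h`, necrotic
density `u_d` (fractions of the carrying capacity) and oxygen `O2`
(mmHg).  With `T = u_n + u_h + u_d`:

    du_n/dt = D_n u_n'' + u_n (1-T)/tau_n - S_nh u_n/tau_nh + S_hn u_h/tau_hn
    du_h/dt = D_h u_h'' + u_h (1-T)/tau_h + S_nh u_n/tau_nh - S_hn u_h/tau_hn - S_hd u_h/tau_hd
    du_d/dt =                                                                  S_hd u_h/tau_hd
    dO2/dt  = D_O2 O2'' - A_n (u_n + u_h/5) O2 / (O2_T + O2)

`S_nh`, `S_hn = 1 - S_nh` and `S_hd` are step-like switches centred on the
hypoxia threshold (7 mmHg) and the anoxia threshold (0.7 mmHg): the
go-or-grow dichotomy under oxygen control, plus anoxic death into a
space-occupying necrotic compartment.  Oxygen obeys Michaelis–Menten
uptake and transmural (Robin) exchange with the capillaries,
`flux = D_O2 (O2_v - O2)/J`; a vessel can thrombose on schedule, after
which its wall stops exchanging.  Cells never cross the walls (zero
flux).  The methods vignette
(`vignettes/pseudopalisade-model.Rmd`) derives the discretisation, the
uptake calibration and every default.

## Worked example

Thrombose the left vessel of a 300 um transect at `t = 0` and watch for a
week:

```r
library(glioxide)
params <- model_parameters()
cfg    <- scenario_config("single_occlusion", rng_seed = 1)
traj   <- run_scenario(cfg, params, days = 7)
print(traj)
metrics_summary(traj)
```

```
tissue_trajectory 'single_occlusion': 169 snapshots, t = 0 .. 7 d, 61 nodes (300 um)
  integrator: stiff; seed 1; fingerprint 68730911
                     metric     value unit
         palisade_width_max 2.800e+02   um
 palisade_width_argmax_time 1.450e+02    h
             formation_time 0.000e+00    h
                   lifetime 1.460e+02    h
        necrotic_core_width 8.000e+01   um
              invasion_time 5.396e+00    d
     switch_completion_time 3.045e+00    h
                 N_normoxic 9.006e-04 cell
                  N_hypoxic 2.091e+04 cell
                 N_necrotic 4.178e+03 cell
```

Reading: the normoxic-to-hypoxic switch in the occluded half completes
(share below 5%) after ~3 h — three e-foldings of the 1 h switch time;
the hypercellular band (`u_n + u_h > 0.45`) peaks at 280 um around day 6
and dissolves into the saturated tissue at ~146 h; an 80 um necrotic core
forms against the dead vessel; the functional vessel is invaded on day
5.4, versus day 5.9 for the no-occlusion control — occlusion accelerates
invasion.  By day 7 essentially every viable cell is hypoxic.

The same machinery is scriptable from a shell (`inst/cli/glioxide`):

```sh
Rscript inst/cli/glioxide run --preset single_occlusion --seed 1 --days 7 --outdir out/
Rscript inst/cli/glioxide sweep --distances 50,100,...,700 --outdir out/
Rscript inst/cli/glioxide calibrate
```

writing a long-format snapshot table, a metrics table and a checksummed
run manifest.

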