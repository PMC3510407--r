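---
title: "Modelling perinecrotic pseudopalisades between two capillaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling perinecrotic pseudopalisades between two capillaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glioxide)
```

## The model

Glioblastoma tissue between two parallel capillaries is described by four
fields on a one-dimensional transect of length $L_x$: the normoxic tumour
cell density $u_n$, the hypoxic density $u_h$, the necrotic density $u_d$
(all as fractions of the carrying capacity $C^{(M)}$) and the oxygen
partial pressure $O_2$ in mmHg.  The governing equations are

$$\partial_t u_n = D_n \partial_x^2 u_n + \frac{u_n (1 - T)}{\tau_n}
  - \frac{S_{nh}(O_2)\,u_n}{\tau_{nh}} + \frac{S_{hn}(O_2)\,u_h}{\tau_{hn}},$$
$$\partial_t u_h = D_h \partial_x^2 u_h + \frac{u_h (1 - T)}{\tau_h}
  + \frac{S_{nh}(O_2)\,u_n}{\tau_{nh}} - \frac{S_{hn}(O_2)\,u_h}{\tau_{hn}}
  - \frac{S_{hd}(O_2)\,u_h}{\tau_{hd}},$$
$$\partial_t u_d = \frac{S_{hd}(O_2)\,u_h}{\tau_{hd}},$$
$$\partial_t O_2 = D_{O_2} \partial_x^2 O_2
  - A_n \left(u_n + r\,u_h\right) \frac{O_2}{O_2^{(T)} + O_2},$$

with $T = u_n + u_h + u_d$.  The biology encoded here is the
migration/proliferation dichotomy: normoxic cells proliferate (doubling
time $\tau_n$) but move little ($D_n$), hypoxic cells proliferate slowly
($\tau_h = 2\tau_n$) but are ten times more motile ($D_h = 10 D_n$).
Phenotypes interconvert under oxygen control through step-like switches
centred on the hypoxia threshold $O_2^{(S)}$, fast on the way down
($\tau_{nh}$ = 1 h, HIF-1$\alpha$ accumulation) and slow on the way back
($\tau_{hn}$ = 96 h).  Hypoxic cells under persistent anoxia (below
$O_2^{(D)}$) die with mean time $\tau_{hd}$ into a necrotic compartment
that neither moves nor clears, but keeps occupying space through the
shared logistic factor $(1 - T)$.  Apoptosis is absorbed into the
effective proliferation rates and carries no separate term.  Oxygen is
consumed with Michaelis--Menten saturation (half rate at $O_2^{(T)}$);
hypoxic cells consume a fraction $r = 1/5$ of the normoxic rate.

The switching functions use the smooth complementary form

$$S_{nh}(O_2) = \tfrac12\Bigl(1 - \tanh\frac{O_2 - O_2^{(S)}}{\Delta O_2}\Bigr),
 \qquad S_{hn} = 1 - S_{nh},$$

and $S_{hd}$ analogously around $O_2^{(D)}$.  A hard-step variant
(`switch_form = "step"`) is available for sensitivity checks.  The
transition width defaults to $\Delta O_2 = 0.1$ mmHg, a sharp switch; the
literature value for this width is ambiguous (it is reported in
incompatible units), so the parameter is deliberately exposed.

### Boundary conditions

Glioma cells essentially never intravasate, so both cell densities obey
zero-flux (Neumann) walls.  Oxygen exchanges with the boundary capillaries
through a transmural (Robin) law: writing $J$ for the exchange length and
$O_2^v$ for the intravascular oxygen, the wall gradient is set so that the
diffusive flux *into* the tissue equals $D_{O_2}(O_2^v - O_2)/J$ at each
functional vessel — oxygen flows from the vessel into the tissue when the
vessel is richer and back into the vessel when the tissue is richer.  Note
the orientation: the naive one-sided form $\partial_x O_2 = (O_2^v -
O_2)/J$ applied verbatim at the *left* wall would make a feeding vessel
behave as a sink (a steady slab with consumption would need boundary
oxygen above vessel oxygen), so the implementation fixes the sign by the
inward-flux convention at both walls symmetrically.

A thrombosed vessel (after its `occlusion_time`) stops exchanging oxygen:
the wall degrades to zero flux (`occluded_mode = "sealed"`).  The
rationale is that a clot blocks the transmural pathway rather than
draining the tissue; the alternative reading, exchange against a
zero-oxygen lumen, is available as `occluded_mode = "sink"`.

### Parameters

| parameter | meaning | default | unit |
|---|---|---|---|
| `C_M` | carrying capacity | 1e6 | cell/cm^2 |
| `D_n`, `D_h` | cell diffusivities | 6.6e-12, 6.6e-11 | cm^2/s |
| `D_O2` | oxygen diffusivity | 1e-5 | cm^2/s |
| `tau_n`, `tau_h` | doubling times | 24, 48 | h |
| `tau_nh`, `tau_hn` | switch times down/up | 1, 96 | h |
| `tau_hd` | anoxic death time | 48 | h |
| `O2_S`, `O2_T`, `O2_D` | hypoxia, Michaelis--Menten, anoxia thresholds | 7, 2.5, 0.7 | mmHg |
| `delta_O2` | switch transition width | 0.1 | mmHg |
| `O2_v`, `J` | vessel oxygen, exchange length | 60, 0.1 | mmHg, cm |
| `A_n` | volumetric uptake at full normoxic density | 3.14 | mmHg/s |
| `uptake_ratio` | hypoxic/normoxic uptake | 0.2 | -- |

All of these except `A_n` are literature point estimates for human glioma.
An alternative cell-motility estimate exists in which the hypoxic
diffusivity is derived from a measured invasion rate of 29 mm^2/year
($D_h \approx 9.2\times10^{-9}$ cm^2/s, with $D_n = 0.1 D_h$); that choice
makes fronts two orders of magnitude faster than the day-scale dynamics
modelled here, so the slower literature pair above is the default and the
fast pair can be passed explicitly if wanted.

### Calibrating the oxygen uptake `A_n`

Per-cell oxygen consumption is measured in mol/(cell s); converting it
into the volumetric mmHg/s the oxygen equation needs requires an assumed
tissue slab thickness and a gas-to-pressure conversion, both uncertain to
an order of magnitude (an ideal-gas route gives $\approx 0.19$ mmHg/s, a
dissolved-oxygen/Henry-law route $\approx 7.7$ mmHg/s for the same
measurement).  The package therefore anchors `A_n` to a robust tissue
observation instead: in vascularised tumours hypoxia sets in roughly
150 um from a vessel.  `calibrate_uptake()` solves the steady oxygen
profile of a full-density normoxic slab,
$D_{O_2} O_2'' = A_n O_2/(O_2^{(T)}+O_2)$, via its first integral, and
bisects on $A_n$ until the profile crosses $O_2^{(S)}$ exactly 150 um from
the wall.  With the wall held at the perivascular level (60 mmHg) this
gives $A_n = 3.14$ mmHg/s, which is frozen as the default; an independent
relaxation-to-steady-state solve reproduces the crossing distance, and the
value sits between the two unit-conversion routes above.

The calibration wall condition matters.  Using the transmural Robin law
(J = 0.1 cm) in the calibration slab instead yields $A_n \approx 0.13$
mmHg/s — but with that uptake a single functional vessel keeps an entire
300 um domain near 50 mmHg, so no hypoxia, no phenotype switch and no
necrosis can ever occur and the model family loses the phenomenon it
exists to describe.  The perivascular (Dirichlet) calibration is therefore
the default and the Robin variant remains available
(`vessel_bc = "robin"`).

### A structural tension worth knowing about

With the transmural exchange length $J$ = 0.1 cm, the flux a vessel can
deliver is capped at $D_{O_2} O_2^v / J \approx 6\times10^{-3}$
mmHg cm/s.  Day-scale anoxia next to an occluded vessel requires tissue
demand *above* this cap (otherwise the surviving vessel quietly resupplies
the whole transect), while a two-vessel tissue that is to *stay* normoxic
requires total demand *below* twice the cap.  Near-capacity tissue at
$A_n$ = 3.14 mmHg/s demands roughly an order of magnitude more than the
cap, so in this model family a fully seeded domain eventually becomes
hypoxic even with both vessels functional.  Consequences visible in the
shipped defaults: the no-occlusion control is invaded faster than a purely
normoxic front would manage (the occluded-vs-control *ordering* is robust,
their separation is compressed), and the anoxic zone next to the occluded
vessel — hence the necrotic core — is wider than histological cores.
Conversely, lowering `A_n` below about 1 mmHg/s delays or abolishes
necrosis altogether.  There is no single uptake value that yields both
deep perivascular anoxia and a two-vessel tissue that stays normoxic under
this exchange law; resolving that would require either a stronger
exchange (smaller `J`) or oxygen sources beyond the two boundary
capillaries, both outside the present scope.

## Numerics

The spatial discretisation is vertex-centred second-order finite
differences with spacing `dx` = 5 um (nodes at $0, dx, \dots, L_x$, vessels
exactly on the end nodes).  Boundary closures use reflecting ghost nodes,
which keeps the scheme second order; the discretely conserved quantity is
then the trapezoidal mass (wall nodes at half weight), which the
conservation tests check to round-off.  The Robin walls enter through a
ghost value chosen so the centred wall gradient equals the exchange law,
contributing $2 D_{O_2}(O_2^v - O_2)/(J\,dx)$ to the wall node tendency.

Two time integrators advance the same compiled right-hand side:

* `"rk4"` — the classical explicit fourth-order Runge--Kutta scheme at a
  fixed `dt` = 0.01 s.  `check_stability()` enforces
  $dt \le dx^2 / (2\max D) = 0.0125$ s on the default grid.  This is the
  reference scheme but needs ~$10^8$ steps for a two-week horizon.
* `"stiff"` — `deSolve::lsodes` (sparse-Jacobian BDF) on the identical
  semi-discrete system, default tolerances `atol` 1e-10 / `rtol` 1e-8.
  A vessel occlusion strictly inside the horizon is a discontinuity in
  time, so the solver restarts at each occlusion instant.  Day-scale runs
  take fractions of a second at 61 nodes.

The two modes agree to better than $10^{-8}$ (sup-norm, normalised) over
six simulated hours of the occlusion scenario; the suite asserts
$10^{-3}$.  Negative excursions are monitored rather than silently
clipped: the trajectory records the most negative value seen (identically
zero in the shipped scenarios) and opt-in clipping zeroes values above
$-10^{-12}$ with a count.  In the frozen-oxygen limit the model reduces to
Fisher--KPP dynamics and the measured front speeds,
$2\sqrt{D_n/\tau_n} \approx 15.1$ and $2\sqrt{D_h/\tau_h} \approx 33.8$
um/day, are reproduced within a few percent (pulled fronts converge to
their asymptotic speed slowly, from below).

## Scenarios and what the generator does not emulate

`scenario_config()` builds three canonical experiments: a 300 um transect
with normoxic cells seeded over the left half (plateau 0.7 of capacity,
tanh-smoothed edges of 10 um) whose left vessel thromboses at $t = 0$; a
400 um variant with a small colony (0.05 of capacity, Gaussian of width
10 um) already established at the functional vessel; and a no-occlusion
control.  The initial oxygen field is i.i.d. uniform noise, mean 24 mmHg
(healthy brain tissue), half-range 6 mmHg, reproducible under `rng_seed`.
The seed height 0.7 is a free choice — high enough to motivate perivascular
thrombosis, below capacity — and the invasion-time tests verify
monotonicity in it rather than depending on its exact value.  The
inter-vessel distance sweep scales this layout proportionally between 50
and 700 um.

Deliberately not emulated: directed motility (no chemotaxis or
haptotaxis — cells leave hypoxic regions only by death plus Fickian
spread, which is the main reason the simulated hypercellular band detaches
from the occluded wall later than histology suggests), angiogenesis and
VEGF signalling, coagulation biochemistry, glucose/lactate metabolism,
2-D/3-D geometry, and oxygen consumption by non-tumour brain tissue
(assumed negligible).  Passing tests therefore certify the
reaction–diffusion mechanism and its morphometry, not a calibrated
patient-scale model.

## Morphometry

All first-crossing times interpolate linearly between snapshots (hourly by
default) to remove cadence bias; widths are node counts times `dx`, hence
multiples of 5 um.

* `hypercellular_width()` — largest connected run with
  $u_n + u_h > 0.45$.  Runs containing the functional-vessel node are
  excluded: once that vessel is recolonised its perivascular colony is
  hypercellular by any threshold but is not the migrating band.  The
  0.45 level reuses the invasion threshold (the one density level with a
  literature anchor); because the seeded plateau itself exceeds it, this
  metric reads the seeded region as hypercellular from $t=0$, which
  inflates widths and zeroes formation times in seeded scenarios — a
  sensitivity sweep over $\theta \in \{0.35, 0.45, 0.55\}$ leaves the
  picture unchanged, and a threshold *relative* to the contemporaneous
  density maximum would be the natural refinement.
* `necrotic_core_width()` — run with $u_d > 0.10$ containing the
  occluded-vessel node.
* `palisade_lifetime()` — first/last times the band width is at least
  20 um (4 nodes); merging into the domain-wide saturated state collapses
  the measured width through the colony-exclusion rule and so ends the
  lifetime; bands outliving the horizon are flagged censored.
* `invasion_time()` — first time $u_n + u_h$ at the functional-vessel
  node exceeds 0.45.
* `switch_completion_time()` — first time the normoxic share
  $\sum u_n / \sum (u_n + u_h)$ over the occluded half drops below 5%.
  Since the switch is exponential with time constant $\tau_{nh}$, a 5%
  completion criterion necessarily reads $\approx 3\tau_{nh}$ even when
  oxygen collapses instantly; the characteristic (e-folding) time of the
  measured decay is $\tau_{nh}$ itself.

## Problem sizes

Everything ships desk-scale: 61–141 nodes, horizons of 6 hours to 20
days, three oxygen-noise seeds per quantitative claim, one seed per sweep
member (the dynamics are almost deterministic — the noise is forgotten
within minutes).  A full 14-member distance sweep in stiff mode runs in a
few seconds; the RK4 reference is used for short cross-validation
horizons.
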