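---
title: "Modelling ribose synthesis inside carbonaceous planetesimals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ribose synthesis inside carbonaceous planetesimals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(formosim)
```

## The problem

Ribose — the sugar backbone unit of RNA — has been detected in CM2 and CR2
carbonaceous chondrites at 4.5–25 ppb by mass. A candidate abiotic source is
the formose reaction: an autocatalytic aqueous network that builds sugars
from formaldehyde, seeded and driven by glycolaldehyde. If the parent-body
asteroids of these meteorites held liquid water for a while — which their
aqueous alteration mineralogy shows they did — the formose reaction could
have produced pentoses in situ, and the measured ribose would be a frozen
remnant of that episode.

`formosim` asks whether that scenario is quantitatively consistent: given a
km-scale porous rock–ice planetesimal heated from within by radionuclide
decay, and initial reactant inventories inherited from the solar nebula,
how much ribose does the formose pathway produce, where inside the body,
and when?

The package couples four pieces:

1. a 1D thermal evolution model of the planetesimal interior
   (`simulate_thermal()`),
2. an aqueous thermochemical equilibrium of a simplified formose pathway
   (`minimize_gibbs()`, `time_iterated_equilibrium()`),
3. laboratory-derived catalyst yield factors converting total pentose to
   ribose (`apply_yield()`), and
4. a unit conversion from water-normalized molar abundance to bulk-mass
   ppb (`molar_to_mass_ppb()`), compared against the meteoritic range
   (`compare_to_meteorites()`).

## The simplified formose pathway

The full formose network has on the order of forty products and largely
unknown kinetics. The model therefore collapses it to a single net
reaction,

$$\mathrm{CH_2O(aq)} + 2\,\mathrm{C_2H_4O_2(aq)}
  \;\xrightarrow{\text{catalyst}}\; \mathrm{C_5H_{10}O_5(aq)},$$

pentose formation from one formaldehyde and two glycolaldehyde, and
re-introduces the network's selectivity afterwards through a measured
yield factor: the maximum fraction of ribose among all pentoses observed
in laboratory formose runs with each mineral catalyst —
`r paste(names(catalyst_yields()), signif(catalyst_yields(), 2), collapse = ", ")`.
Hydroxide and carbonate catalysts are used because both are common
alteration phases in carbonaceous chondrites.

### Gibbs energies and the glycolaldehyde estimate

Whether the net reaction proceeds is decided by the sign of its Gibbs
energy,
$\Delta G_r(T) = \Delta G_f(\text{ribose}) - \Delta G_f(\mathrm{CH_2O})
- 2\Delta G_f(\text{glycolaldehyde})$.
The package ships a plain-text table of aqueous $\Delta G_f(T)$ at 100 bar
(`gibbs_table()`), generated once (`data-raw/make_gibbs_table.R`) from
standard-state aqueous formation enthalpies and Gibbs energies with the
linear approximation $\Delta G_f(T) = \Delta H_{f,298} - T\,\Delta
S_{f,298}$. The table is deliberately labelled *synthetic*: it is adequate
for sign-level reaction energetics — the only use the model makes of it —
not a general thermodynamic reference. Within the tabulated span the
reaction energy is between roughly $-188$ and $-95$ kJ/mol, so pentose
formation is strongly favoured wherever liquid water exists.

Glycolaldehyde is missing from standard aqueous databases. Its formation
energy is estimated as a fixed blend of two proxies whose functional
groups together resemble it: $0.611\,\Delta G_f(\text{acetaldehyde}) +
0.382\,\Delta G_f(\text{acetic acid})$. The weights are used exactly as
calibrated (they sum to 0.993 and are not renormalized). Because the
margin on $\Delta G_r$ is two orders of magnitude larger than any
plausible error in this estimate, shifting the glycolaldehyde energy by
±20 kJ/mol changes the predicted abundances by less than 1% — a property
the test suite checks explicitly.

### Equilibrium as a one-dimensional minimization

`minimize_gibbs()` minimizes the ideal-solution Gibbs energy
$G = \sum_i n_i(\Delta G_{f,i} + RT\ln x_i)$ along the stoichiometric
coordinate of the reaction above, with non-negative amounts. Restricting
the search to this single reaction coordinate is a deliberate design
choice, not a numerical shortcut: in (C,H,O) space glycolaldehyde and
ribose are integer multiples of formaldehyde, so a minimizer free to use
*any* element-conserving transformation would also run
$2\,\mathrm{CH_2O} \to \mathrm{C_2H_4O_2}$ and convert the entire carbon
inventory to pentose. The modelled chemistry is the adopted pathway, in
which glycolaldehyde formation from formaldehyde alone is kinetically
inhibited (that is what makes glycolaldehyde the seed of the autocatalytic
cycle), so the pathway itself is the correct constraint set. A side
benefit is that elemental conservation holds identically.

Numerically, the stationarity condition $dG/d\xi = 0$ is solved with a
bracketed root finder on a logarithmic coordinate measured from whichever
end of the feasible interval the root is near. This matters: with
$\Delta G_r \approx -180$ kJ/mol the equilibrium leftover of the limiting
reactant is $\sim 10^{-12}$ of its initial amount, and a naive
parameterization would round it to zero. Activities are mole fractions for
all species (the water mole fraction is within $10^{-3}$ of unity and
water has zero net stoichiometry, so this is indistinguishable from a
unit-activity solvent convention). Convergence is validated against the
closed-form limiting-reagent oracle
$n_{5C} = \min(n_{\mathrm{CH_2O}}, n_{\mathrm{gly}}/2)$
(`limiting_reagent_conversion()`), which the minimizer must reproduce
within 1% whenever $\Delta G_r < -50$ kJ/mol.

The time-iterated mode (`time_iterated_equilibrium()`) walks a
temperature history, re-equilibrating whenever the local temperature is at
or above 273.15 K and carrying products and leftovers forward. The product
is treated as inert once formed — there is no back-reaction on
re-freezing, and with complete conversion there is nothing to back-react —
so the pentose trajectory is non-decreasing. Chemistry is gated *only* by
the liquid-water threshold; no upper temperature cutoff is applied within
the tabulated range, because favourability is already governed by the sign
of $\Delta G_r$ and the reference bodies stay well below the table's
610 K ceiling. For radial profiles the composition is equilibrated at the
*peak* temperature each depth ever reaches, attributing peak production to
peak temperature.

## Initial concentrations

Concentrations are normalized to water (mol per mol H₂O). The reference
scenario fixes formaldehyde at $6.6\times10^{-4}$ and takes glycolaldehyde
between $5\times10^{-6}$ and $4\times10^{-4}$ — the lower and upper bounds
of `table1_scenario()`. These are cometary ice abundances adjusted for the
warmer 2–3 au assembly region of carbonaceous parent bodies: formaldehyde,
far more volatile than water, carries a $10^{-3}$ depletion factor
(stored as scenario metadata), while glycolaldehyde desorbs with water and
is left at cometary values. One bookkeeping subtlety: the adopted
formaldehyde input is the *predicted* post-depletion concentration
$6.6\times10^{-4}$; only with this reading is glycolaldehyde the limiting
reactant across its entire range, which the factor-80 spread between the
lower- and upper-bound results requires.

Because the glycolaldehyde range spans nearly two decades with
order-of-magnitude endpoints, the ensemble generator
(`sample_scenarios()`) draws it log-uniformly; the median of a large
sample then sits at the geometric mean of the endpoints,
$\approx 4.5\times10^{-5}$.

## The thermal model

`simulate_thermal()` solves spherically symmetric heat conduction

$$\rho c\,\frac{\partial T}{\partial t} =
  \frac{1}{r^2}\frac{\partial}{\partial r}
  \left(k r^2 \frac{\partial T}{\partial r}\right)
  + \rho_{\mathrm{rock}}^{\mathrm{bulk}} H(t + t_{\mathrm{form}}),$$

with a zero-flux center, a fixed 150 K surface (the ambient nebula
temperature just outside the water snowline), and a uniform 150 K initial
condition. $H$ is the specific decay power of the rock fraction: ²⁶Al
(half-life 0.717 Myr) dominates, ⁶⁰Fe contributes marginally, and ⁴⁰K,
²³²Th, ²³⁵U and ²³⁸U provide the late, slow heating that produces the
second temperature plateau in large bodies. Pore space (volume fraction
$\phi = 0.2$) is ice-filled; rock occupies the rest
($\rho_{\mathrm{rock}} = 3$, $\rho_{\mathrm{ice}} = 0.917$ g/cm³). The
latent heat of the ice–water transition is deliberately not modelled, so
windows that straddle melting are approximations by construction.

Discretization is cell-centered finite volumes on a uniform radial grid
(default 300 cells) with backward Euler time stepping — unconditionally
stable, with a sparse LU factorization reused while the step is constant.
The step is fixed at 1 kyr through the first 10 Myr (resolving the
short-lived heating era) and then grows geometrically by 5% per step to
the present solar-system age, about 10,250 steps in total; a full
reference run takes a few seconds. The discrete energy balance (stored
heat + surface loss = radiogenic input) closes to round-off by
construction and is recomputable with `energy_balance()`.

### Material parameters and calibration

The bulk heat capacity is the volume-weighted sum of the component
volumetric heat capacities with $c_{\mathrm{rock}} = 1000$ and
$c_{\mathrm{ice}} = 2000$ J/kg/K. The bulk conductivity is the
volume-weighted mixture of component conductivities
($k_{\mathrm{rock}} = k_{\mathrm{ice}} = 2.6$ W/m/K) times a
microporosity correction `k_scale = 0.46`, giving 1.20 W/m/K — inside the
0.5–1.5 W/m/K range measured on carbonaceous chondrites, whose cracked,
brecciated fabric conducts far worse than consolidated rock. The ²⁶Al
specific power at CAI is $1.55\times10^{-7}$ W per kg of rock,
corresponding to the canonical initial ratio ²⁶Al/²⁷Al $= 5.25\times
10^{-5}$, a CI-chondritic aluminium mass fraction of 0.85 wt%, and
3.12 MeV retained per decay. A CM-like 1.13 wt% aluminium was considered
and rejected: it melts the core of the 150 km reference body less than
1 Myr after formation, incompatible with the ~2 Myr onset that anchors
the reference thermal histories, whereas the water-rich CI composition is
the natural end-member for strongly aqueously altered parent bodies.

These four quantities (surface temperature, heat capacities, conductivity
correction, ²⁶Al power) are the model's free material parameters. They
were calibrated once, by a coarse scan within physically standard ranges,
against the reference behaviour of the two benchmark bodies — a 150 km
body formed 3.5 Myr after CAI (melt extending to ~138 km, core melting
~2 Myr after formation, outer-shell window ≲2 Myr) and a 4 km body formed
1 Myr after CAI (shell at 2.76 km melting ~210 kyr after formation,
window ≲200 kyr) — and then frozen as package defaults. All are plain
config arguments, so alternative choices can be explored without touching
the code.

Numerical robustness: doubling the radial resolution changes the
peak-temperature profile of both reference bodies by less than 0.15 K,
and halving the fine time step moves the shell melt-onset time by ~0.6%.
The outer-shell results are the most delicate — the 2.76 km shell of the
4 km body peaks only ~2 K above melting — which is faithful to the
physics: that shell is meant to graze the melting point, which is exactly
why it refreezes fast enough to preserve its ribose.

## From molar abundance to ppb

The equilibrium pentose abundance $n$ (mol per mol H₂O) converts to a
bulk-mass concentration as
$\mathrm{ppb} = n \cdot (M_{\mathrm{ribose}}/M_{\mathrm{H_2O}}) \cdot
f_{\mathrm{ice}} \cdot 10^9$, with the ice mass fraction
$f_{\mathrm{ice}} = \phi\rho_{\mathrm{ice}} / (\phi\rho_{\mathrm{ice}} +
(1-\phi)\rho_{\mathrm{rock}}) \approx 0.071$. The bulk (rock + ice)
baseline is an explicit convention: meteorite concentrations are reported
per unit mass of meteorite, i.e. of bulk rock, not of water. On a
water-mass baseline the same lower-bound scenario would read ~850 ppb and
the comparison below would be meaningless.

## What the synthetic generator does and does not emulate

`table1_scenario()`, `sample_scenarios()` and `toy_thermal_history()`
generate, respectively, the two reference compositions, log-uniform
ensembles over the glycolaldehyde range, and constant/boxcar/ramp
temperature histories. Toy histories exist so the chemistry can be tested
against closed-form expectations (a boxcar must produce a single jump to
the limiting-reagent value at the first warm step; a ramp's melt onset
must match the linear-crossing time) independent of the PDE solver.

What passing these tests shows is that the *coupled machinery* is
correct: conservation, limiting-reagent behaviour, window analytics, unit
conversions. What they cannot show is that real parent bodies matched the
assumed initial inventories, that equilibrium (rather than kinetics)
governed the real formose network, or that ribose survived after
synthesis — the model's structural simplifications, listed below.

## Known limitations

* **No decomposition.** Ribose hydrolyses, eliminates and browns at
  temperatures well below the core peak temperatures reached here. The
  computed abundances are upper limits, and core/temporal profiles at
  late times are least trustworthy. This is also why the outer shells —
  melted briefly, then refrozen — are the most plausible provenance of
  meteoritic ribose.
* **Equilibrium chemistry with one net reaction.** No kinetics, no side
  products beyond the yield factor, no back-reaction.
* **Thermal model simplifications.** No latent heat, no convection or
  water transport, no compaction or impact heating; constant material
  properties. The reference behaviour is calibration-backed rather than
  derived from first-principles material data, which the paper-level
  inputs do not constrain uniquely.
* **The depletion factor is an assumption.** The formaldehyde inventory
  rests on solar-nebula transport modelling summarized into a single
  $10^{-3}$ factor; the two-decade glycolaldehyde range propagates
  directly (linearly, while limiting) into the predicted abundances.

## Reproducing the headline numbers

`verify_targets()` recomputes every headline quantity from scratch — the
two reference thermal runs, the window analytics at 2.76 km and 138 km,
and the analytic end-to-end plateaus (lower bound: ~61 ppb, a factor
~2.4 above the measured 25 ppb ceiling; upper bound: ~80× higher, about
two orders of magnitude above the measurements). `scripts/acceptance.R`
in the source tree wraps the same computation for scripted use. At the
default resolution the full set takes well under a minute.

```{r verify, eval = FALSE}
verify_targets(verbose = TRUE)
```
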