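---
title: "Modelling fractionated condensation of pervaporation permeates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling fractionated condensation of pervaporation permeates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aromafrac)
```

## The process and the model

Organophilic pervaporation transfers trace volatiles (aromas) and water from
an aqueous feed across a dense membrane into a low-pressure vapour, the
permeate. Recovering the aromas — and separating desirable ones from
off-flavours — is then a condensation problem: the permeate passes through a
series of condensers at decreasing temperatures, and each stage captures the
slice of the spectrum whose volatility and activity allow it to condense
there.

`aromafrac` models one such stage as an isothermal equilibrium between the
vapour and a single, dilute, aqueous condensate, in the presence of a
non-condensable carrier ("inert") gas — air in-leakage that is always present
in vacuum trains and that sets the floor on condensation. With

* $n_{w0}$, $n_{a0}$ — molar flows of water and of aroma $a$ entering the
  stage (mol/s),
* $n_{inert}$ — inert-gas molar flow (mol/s),
* $p_{perm}$ — total (permeate) pressure (Pa),
* $p_{v,i}(T)$ — saturation vapour pressure of species $i$ at the condenser
  temperature (Pa),
* $x_a$ — mole fraction of aroma $a$ in the condensate,
* $\gamma_a^\infty$ — its infinite-dilution activity coefficient in water,

the condensed fractions in the stage are

$$f_w \;=\; 1 - \frac{n_{inert}}{n_{w0}}
      \frac{p_{vw}(T)}{p_{perm}-p_{vw}(T)},
\qquad
f_a \;\cong\; 1 - \frac{n_{inert}}{n_{a0}}
      \frac{x_a\,\gamma_a^\infty\,p_{v,a}(T)}{p_{perm}-p_{vw}(T)},$$

both clamped to $[0,1]$. The water expression is the exact two-component
(water + inert) balance: the vapour leaving the stage is saturated in water,
and the inert flow carries the corresponding amount of water past the
condenser. The aroma expression applies the same balance with the
condensate-side equilibrium $y_a p_{perm} = x_a \gamma_a^\infty p_{v,a}(T)$
(a Henry-law description of a trace solute in the aqueous condensate); it is
approximate because the vapour is assumed water/inert-dominated. Because
$x_a$ — the aroma content of the condensate — depends on what condenses, the
aroma equations are closed by iteration (below). Everything depends only on
flow *ratios*, so predictions are scale-invariant, and $n_{inert}\to 0$
yields complete condensation of every condensable: both are enforced as
property tests.

A cascade (`run_cascade()`) feeds each stage the vapour outlet of the
previous one; the inert gas passes through unchanged. Per-compound
conservation (condensed across stages + final vapour = inlet) holds to
machine precision by construction and is asserted to 1e-9 over a thousand
random cascades in the test suite.

## Closing the condensate composition

Substituting $x_a = f_a n_{a0} / n_{tot}$ (with $n_{tot}$ the total molar
flow of condensate) into the aroma expression makes it *linear* in $f_a$ at
fixed $n_{tot}$, with exact solution

$$f_a = \frac{1}{1+q_a},\qquad
  q_a = \frac{n_{inert}\,\gamma_a^\infty p_{v,a}(T)}
             {(p_{perm}-p_{vw}(T))\, n_{tot}} \;\ge\; 0 .$$

The solver therefore iterates only on $n_{tot}$ (equivalently on the
condensate mole-fraction vector), initialised at "everything condenses",
solving each aroma exactly per sweep. Since $n_{tot}$ is dominated by the
water term — which does not depend on the aromas — the outer iteration is a
strong contraction and typically converges in 3–5 sweeps. We deliberately do
*not* relax the raw closed form directly: that map has slope $-q_a$ in
$f_a$, and for strongly excluded volatiles ($q_a \gg 1$) it oscillates
between 0 and 1 regardless of any fixed damping factor. The per-sweep exact
solve keeps every iterate in $(0,1]$, so the $[0,1]$ clamp documented for
the raw form never binds in practice.

Numerical choices:

* convergence when the condensate mole-fraction vector changes by less than
  `tol = 1e-12` (max absolute), hard stop with an error after 200 sweeps;
* a species with zero inlet flow has condensed fraction 0 by definition;
* if $p_{vw}(T) \ge p_{perm}$ no equilibrium condensation is possible at
  all: the stage returns an all-vapour pass-through flagged
  `water_noncondensing` rather than an error;
* if the condensate collapses to zero total flow the stage reports empty
  condensate (all fractions 0), and concentrations on it are an error.

The independent check is a full isothermal flash (Rachford–Rice with the
inert gas as a very-high-$K$ pseudo-species, no dilute approximation),
implemented in the test suite only. Closed form and flash agree within 1 %
on every condensed fraction whenever the condensate aroma content is below
$10^{-3}$ mole fraction — the regime of every application this package
targets.

## Vapour pressures

Saturation pressures come from Antoine-type records carried per compound.
Three dialects are supported — the canonical
$\log_{10}P[\mathrm{bar}] = A - B/(T[\mathrm{K}]+C)$, the classic
mmHg/°C handbook form, and a two-parameter Clausius–Clapeyron form (`CC2`,
$C=0$) for records fitted through just two data points. Loaders convert
everything to the canonical form by exact affine maps of the coefficients
(no refitting), because dialect confusion is the classic failure mode of
Antoine data; round-trips are asserted exact in the tests.

Records are extrapolated outside their tabulated range with a flagged
status: cryogenic trap stages sit far below any tabulated range, and there
the precise value is irrelevant — below a configurable cutoff (default
153.15 K) the pressure is taken as exactly 0 Pa and every species is fully
condensable, which reproduces liquid-nitrogen-trap behaviour. Above the
cutoff, extrapolation is permitted but surfaced through the
`extrapolated_pv` validity flag on stage results.

## Parameters that matter

| parameter | units | default | role |
|---|---|---|---|
| $p_{perm}$ | Pa | 1500 (bundled case) | total pressure of the condenser train |
| $T_k$ | K (°C at the file interfaces) | — | per-stage condenser temperature |
| $n_{inert}/n_{w0}$ | — | calibrated | carrier-gas ratio; sets the condensation floor |
| $\gamma^\infty$ | — | per compound | escaping tendency of a trace solute from the aqueous condensate |
| cryogenic cutoff | K | 153.15 | below this, $p_v \equiv 0$ |
| membrane thickness $\delta$ | m | 1e-6 | converts permeance to permeability; a nominal dense-active-layer value, documented as an assumption (permeance is reported alongside and is $\delta$-free) |
| feed temperature | K | 333.15 | where feed-side fugacities are evaluated for the driving force |

The inert ratio deserves emphasis: it is rarely measurable, yet every
prediction depends on it. `calibrate_inert_ratio()` recovers it from a
*single* observed condensed fraction at a known temperature by bisection
(the fraction is monotone decreasing in the ratio). All predictions for the
bundled validation case share one inert ratio calibrated this way on the
1-penten-3-ol recovery.

Condensate concentrations are reported in mg/kg and compared against
olfactive thresholds in mg/L assuming unit condensate density — the
condensate is overwhelmingly water, so the error is below 0.1 % at these
dilutions. The threshold comparison is a *strict* inequality: a
concentration exactly at the threshold is reported as not-below, the
conservative choice for quality claims.

## Pervaporation metrics

From feed concentrations (ppm by mass, water as the implicit balance
species) and measured fluxes, `pervap_metrics()` reports the molar flux, the
separation factor against water
$\beta_a = (y_a/y_w)/(x_a/x_w)$ — the against-water ratio-of-ratios form is
used rather than the binary form; in this dilute regime they agree to well
under 0.01 % — and the solution-diffusion permeability
$L_a = J_a\,\delta / (x_a\gamma_a^\infty p_{v,a}(T_{feed}) - y_a p_{perm})$.
When a row's measured feed concentration and flux imply a non-positive
driving force, that row's permeability is reported `NA` with a warning
instead of a sign-violating number; this happens for part of the bundled
panel, whose feed concentrations and fluxes are mutually inconsistent under
any dilute mass balance (see below).

## The synthetic generator

`generate_scenario()` produces seeded, fully self-consistent test worlds:
feed concentrations log-uniform on 0.001–1 ppm, $\gamma^\infty$ log-uniform
on $10^2$–$10^5$, aroma permeabilities log-uniform on
$10^{-12}$–$10^{-11}$ mol/(m s Pa), water permeability such that total
fluxes land near 0.4–1.1 kg/(m² h) — the magnitudes of measured
marine-effluent panels — and about one compound in three flagged as an
off-flavour. The `marine` preset fixes the family mix (for six aromas:
2 alcohols, 3 aldehydes, 1 ketone) to mirror the structure of the bundled
panel. Synthetic vapour-pressure records are `CC2` fits through a sampled
normal boiling point (380–470 K) with a sampled Trouton-type vaporisation
entropy (80–100 J/mol K), so no third coefficient is invented.

Fluxes are generated *forward* from the true permeabilities with the
permeate composition closed self-consistently (a scalar fixed point on the
total flux), then perturbed by mean-one lognormal noise of the requested CV.
Noise-free scenarios therefore invert back to the ground truth to machine
precision — asserted at 1e-9 relative — and noisy ones quantify estimator
error honestly. The package's pooled estimator takes the per-compound
*median* across replicate flux draws; at 10 % flux CV and 200 replicates its
median relative error is asserted below 3 %. A single noisy draw, by
contrast, carries the full ~10 % (amplified where the downstream term is a
large share of the driving force); replicates whose perturbed fluxes imply a
non-positive driving force are thermodynamically inconsistent and are
dropped as `NA` before pooling.

What the generator does *not* emulate: matrix (lipid/protein) interactions —
these enter only through the measured fluxes, as in the real process —
GC-MS quantification noise structure, concentration polarisation, or
multi-liquid-phase condensates. Passing the synthetic suites therefore shows
the *solver and estimator* are correct under the model's assumptions, not
that the assumptions hold for any particular real effluent.

## The bundled sardine case, and a caution on constants

The package ships a real-world worked example: a sardine-cooking-wastewater
permeate characterised by five measured aroma fluxes plus total flux on a
$10^{-2}$ m² organophilic membrane at 1500 Pa, with two off-flavour markers
(heptanal and (E,Z)-2,6-nonadienal) among six chemical markers. The
thermodynamic constants for this panel are *inputs compiled by this
package* from standard reference data — two-point Clausius–Clapeyron fits
through handbook boiling points and 25 °C vapour pressures, and
$\gamma^\infty$ from Henry's-law constants and aqueous solubilities
(log-midpoints where compilations disagree) — with per-record provenance in
the `source` column of `inst/extdata/sardine_compounds.csv`. They were fixed
once, from that reference data alone.

With the inert ratio calibrated on the observed 84 % first-condenser
recovery of 1-penten-3-ol at 10 °C, the model reproduces the reported
recoveries of the other non-off-flavour markers (1-octen-3-ol, 2-nonanone)
within a few percentage points — the dilute closed form makes the reason
transparent: after calibration each prediction depends only on the
$\gamma^\infty p_v(T)$ ratio between compounds.

It does **not** reproduce the reported near-total first-stage *exclusion* of
the two off-flavour aldehydes, predicting instead substantial condensation
(run `scripts/acceptance.R` for the numbers). This is a provenance problem,
not a solver problem: matching those observations would require
$\gamma^\infty p_v(283\,\mathrm{K})$ products two to four orders of
magnitude above anything supported by compiled Henry's-law, solubility or
partition data for these aldehydes. The characterisation data themselves
carry related inconsistencies — the measured feed concentrations and
permeate fluxes are irreconcilable under any dilute mass balance (hence the
`NA` permeabilities above), and the reported retention percentages and
condensate concentrations for the off-flavours disagree with each other by
roughly an order of magnitude under the same water balance. We therefore
treat the off-flavour observations as experimental reference points rather
than as model identities, keep the independently sourced constants, and
leave the corresponding checks in `test-acceptance.R` failing rather than
bend $\gamma^\infty$ values far outside their physical range to force
agreement. Users with measured activity coefficients for their own system
should supply them through the compound table — every downstream number
then follows from their data.

## Known limitations

* Single aqueous condensate at equilibrium: no organic lens, no aerosol or
  mist carry-over, no non-isothermal dynamics, no heat-transfer sizing.
* $\gamma^\infty$ is an input; the package performs no group-contribution
  estimation.
* The aroma closed form is first-order in condensate dilution; above
  $\sim10^{-3}$ aroma mole fraction in the condensate its agreement with the
  full flash degrades (monitored in the tests).
* Antoine extrapolation below tabulated ranges is flagged, not prevented;
  judge `extrapolated_pv` results accordingly.

## Problem sizes used in the shipped suites

The test and acceptance computations are desk-scale by design: the bundled
case solves one or two condenser stages over a 6-species panel
(milliseconds), the property suites sweep 1,000 random cascades of 1–3
stages and 1–5 aromas, and the estimator checks use 200 replicate flux
draws over 6-aroma panels. The full suite and the acceptance script each
complete in seconds on one CPU.
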