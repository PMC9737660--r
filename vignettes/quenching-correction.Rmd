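---
title: "Fragment fluence-weighted Birks quenching correction: model, assumptions, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment fluence-weighted Birks quenching correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionquench)
```

## The problem

Al~2~O~3~:C radioluminescence (RL) fibre probes read dose in real time, but
their light output per unit dose falls as the linear energy transfer (LET)
of the radiation rises: the dense ionization around a slow ion's track
saturates the recombination centres. Along the Bragg curve of a therapeutic
proton, helium or carbon beam the LET of the primary grows by one to two
orders of magnitude toward the peak, so a raw RL depth scan shows a
suppressed peak — a 25–50% under-reading where the dose accuracy matters
most. For helium and carbon beams a second complication appears: nuclear
fragmentation progressively replaces the primary with lighter fragments
(mostly H and He) that carry most of the distal fluence at much lower LET.

`ionquench` implements the correction scheme in which a per-species Birks
saturation factor is combined across the mixed particle field using the
depth-resolved *fluence fractions* of the primary and its fragments,
together with everything needed to exercise it end to end: signal
reduction, linearity correction, relative-efficiency curves, parameter
fitting with progressive freezing, probe-volume averaging, and an analytic
beam model standing in for Monte Carlo transport.

## The model

**Voxelized Birks law.** The light emitted from a scoring voxel traversed
by fluence $\phi_v$ of one species with fluence-averaged LET $L$ is

$$ RL_v = \frac{RL_0\,L}{1 + kB'\,L}\,\phi_v, $$

where $kB$ is the Birks constant of that species in the detector material
and $RL_0$ a dimensionless scaling. $kB$ is carried in the mass units the
parameter tables use, $\mu$g MeV$^{-1}$ cm$^{-2}$; dividing by the density
of water ($10^6\,\mu$g/cm$^3$) gives $kB' = kB \times 10^{-6}$ cm/MeV so
that $kB' L$ is dimensionless for $L$ in MeV/cm. (The source literature
prints both $\mu$g and mg for this constant; the tables all use $\mu$g,
which is adopted.)

**Correction factor.** The ratio of deposited energy to emitted light in a
voxel defines the quenching correction $\eta$. For one species it is exact:

$$ \eta = \frac{\phi_v L}{RL_v} = \frac{1 + kB'\,L}{RL_0}, $$

and `eta_single() * birks_rl()` recovers $\phi L$ to machine precision (an
invariant of the test suite). For the mixed field at depth $d$ the combined
factor is the fluence-weighted sum over species,

$$ \eta(d) = \sum_i f_{d,i}\,\frac{1 + kB_i'\,L_{d,i}}{RL_{0,i}}, $$

with $f_{d,i}$ the fluence fractions. With one species this reduces to the
pure proton form; with \{He, H\} and \{C, He, H\} it reduces to the helium
and carbon specializations (`eta_proton()`, `eta_helium()`,
`eta_carbon()`; the reductions are asserted bit-for-bit on random inputs).
The outer sum over depths that appears in the general formula is read as
"evaluate per depth": a depth-summed scalar could not produce depth-resolved
corrections.

**Correction.** A measured curve, reduced to the normalized 'RL signal'
(entrance-efficiency-scaled peak-to-plateau representation), is corrected
as $\mathrm{corr}(d) = \eta(d)\,y(d)/\eta(0)$ and renormalized so the
corrected entrance matches the reference entrance. Reported metrics are the
percent difference against the reference at the Bragg peak, the maximum
absolute difference in the plateau, and the maximum in the distal falloff
(flagged beyond the 80% distal-dose depth, where accuracy is known to
degrade; points below 10% of the peak dose are excluded from metrics).

## What the synthetic world is — and is not

The measured RL data behind the published analysis are not public, so the
package ships a generator with known ground truth. Two modelling decisions
deserve scrutiny.

**The forward model is the method's own model.** For a single species the
generator emits exactly the voxelized Birks law above. For a mixed field it
emits $RL(d) = E(d)/\eta(d)$ — deposited energy divided by the
fluence-weighted correction factor — so the published correction is by
construction its exact inverse. We chose this deliberately, and document
the alternative: a *light-additive* detector (each species' light summed
with its own Birks curve) is **not** invertible by fluence weighting at a
carbon Bragg peak, where the primary keeps only ~8–19% of the fluence while
carrying ~90% of the dose; the residual error of the fluence-weighted
correction against such a detector is tens of percent. A green
mixed-species test therefore establishes the internal consistency of the
correction machinery — fitting, freezing, weighting, normalization,
inversion — not the physical validity of fluence weighting for carbon
beams. That validity can only be settled against measured data.

**Ground-truth parameters.** The published entrance relative efficiencies
(five beams, 4.1–135 MeV/cm) pin the synthetic detector response. Because
the published efficiency-vs-LET curves collapse onto a single curve per
probe regardless of species, the ground truth uses one $(kB, RL_0)$ pair
per probe for all species, obtained by a single linear regression of
$1/\mu = (1 + kB'L)/RL_0$ on the packaged entrance-efficiency table:
3106 $\mu$g / 1.0246 ('4 µm'), 3158 / 0.9736 ('38 µm'), 3126 / 0.7700
('Single Crystal'). The regression was run once and frozen. With these
values the synthetic campaigns reproduce the published *pattern*: entrance
efficiencies of ~1.01 (protons), 0.96 (helium), 0.73–0.77 (carbon);
uncorrected peak deficits of ~25% (protons), ~50% (helium, mirroring the
reported ~30% scale), ~38% (290 MeV/u carbon); corrected peaks within 1–2%
under 1% measurement noise.

Note the deliberately different role of the *published* fitted parameters
(`default_birks_params()`, kB of 300/120/1.8 $\mu$g for H/He/C): those are
packaged as transcription fixtures for evaluating $\eta$ against the
printed tables, not as generator truth — with the $\mu$g convention they
imply sub-percent quenching for the primaries and cannot reproduce the
printed entrance efficiencies, one of several internal tensions in the
source values.

## The beam model

The transport surrogate is analytic and dependency-free:

* **Stopping power** — relativistic Bethe formula for liquid water
  ($\rho = 1$ g/cm$^3$, $I = 75$ eV), no shell or density-effect
  corrections, valid above 1 MeV/u. Ions scale as $Z^2$ times the proton
  value at equal energy per nucleon (velocity computed with the proton rest
  mass for every species, so the scaling is exact). This reproduces the
  five published entrance LET values within 0.6%.
* **Ranges** — CSDA integral of reciprocal stopping power down to the
  1 MeV/u cutoff plus a 0.024 mm residual tail; ion range =
  $(A/Z^2)\times$ proton range. Published Bragg-peak depths are matched
  within 1.6%.
* **Bragg curves** — dose $=$ surviving-primary fluence $\times$ stopping
  power of the residual energy, convolved with a Gaussian of
  $\sigma = 1.2\%$ of range (typical water straggling; configurable). Peak
  depth is the argmax on the 0.1 mm grid, shallowest bin on ties.
* **Fragmentation** — primary fluence decays exponentially (attenuation
  length $\lambda$) and collapses through the straggling survival curve at
  end of range; fragments build up in proportion to the primary loss,
  partitioned by yield fractions, inherit the primary's energy per nucleon
  at their mean creation depth, and slow down along their own residual
  range. $\lambda$ and the multiplicities were calibrated *once* against
  the packaged fluence tables (±20% on the peak-row fluence fractions) and
  frozen: $\lambda$ = 9000 / 900 / 200 mm and multiplicity 0.0016 / 2.0 /
  3.5 for proton / helium / carbon beams, carbon yields H:He = 2.5:1.
  The scored per-species LET is the ratio of straggling-smeared energy
  deposition to smeared particle count, which is what a 0.1 mm
  fluence-averaged-LET scorer sees (finite LET at the peak instead of the
  end-of-range divergence).

Features of real data the surrogate does not emulate: genuine nuclear
cross-section physics (fragment spectra are single-valued in energy, not
distributions), lateral scattering and field flatness, beam-line
contamination at the entrance (the printed tables show ~1.8% fragment
fluence in the first bin of the 400 MeV/u carbon beam; the surrogate starts
clean), dose-averaged LET, and detector dead time or stem effect.

## Fitting

`fit_birks()` fits the forward model to a normalized RL curve for one free
species with the others frozen, by bounded multi-start nonlinear least
squares (`nls`, port algorithm; kB starts log-spaced over four decades,
$RL_0$ started from the low-LET inversion; bounds $kB \ge 0$,
$RL_0 > 0$). Only depths whose free-species LET lies inside the published
validity windows enter: 3–45 (H), 20–240 (He), 90–1700 (C) MeV/cm. The
pipeline fixes the fitting order H → He (frozen H) → C (frozen H, He),
because the helium and carbon forward models contain the lighter species'
parameters. Proton parameters are fitted from both proton beams jointly,
as in the published analysis.

Identifiability at desk scale: with 1% multiplicative noise on every
0.1 mm bin of both proton beams, the median kB recovery error over 100
seeds is ~1–2%; the acceptance criterion requires ≤10%. At zero noise the
inversion is exact (sub-0.1%) when generator and fit share the ground
truth. One subtlety is pre-registered in the design notes: with a
multi-species truth, the proton-stage fit carries a ~0.1% kB bias because
the trace He fragments in a proton beam (fluence $3\times10^{-5}$, LET
~85 keV/µm) are quenched by the generator but unknown at that stage — the
same approximation the published proton-only correction makes.

## Numerical choices and edge cases

* Depth bins are half-open 0.1 mm intervals reported at bin centres;
  entrance = first bin.
* Background reduction uses the last 25 pre-irradiation and first 25
  post-irradiation samples (m = 50), per the published definition;
  configurable.
* Dose-response slopes are through-origin least squares (zero dose, zero
  signal — the published slopes carry no intercepts).
* The linearity index interpolates linearly to the 1 Gy calibration dose
  when it is not a measured point.
* Linearity corrections divide by the fitted polynomial (mapping a
  supralinear index back to 1); validity ranges are clamped to where the
  polynomial stays within (0, 10], and extrapolation is refused. The
  published helium polynomials are implausible for dose in Gy over most of
  the measured range (one is negative at 1 Gy); they are shipped verbatim
  with correspondingly narrow validity windows rather than guessing an
  unstated normalization.
* The efficiency model is a 3-parameter decay-to-plateau
  $\mu(L) = y_0 + A e^{-L/\tau}$ (the published curves flatten at high
  LET); $R^2$ is the definitional $1 - SS_{res}/SS_{tot}$.
* Probe-volume averaging is a boxcar of the active length (1.0 mm crystal,
  0.2 mm droplets) with edge renormalization; it conserves the profile
  integral to 0.1% away from edges.
* Every stochastic routine takes an explicit seed (default 20221125);
  identical seeds give byte-identical bundles.

## Known limitations

* The generator's forward model makes the fluence-weighted correction
  exact by construction (see above); it cannot adjudicate fluence versus
  light-share weighting for carbon beams.
* The published kB/RL$_0$ values are not re-derived — the measured RL data
  are unpublished — and the packaged values carry the unit and
  normalization ambiguities of the source.
* The uncorrected peak deficit of the 400 MeV/u carbon beam saturates near
  15% in this world (the primary's fluence fraction collapses to ~8% at
  the peak, capping the fluence-weighted $\eta$ excursion), smaller than
  the deficits the paper shows; the 290 MeV/u beam, with ~19% primary
  survival, reproduces the >25% regime.
* The Bethe implementation is not valid below 1 MeV/u and omits shell,
  density and effective-charge corrections; it is an anchor-accurate
  surrogate, not a dosimetric stopping-power table.
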