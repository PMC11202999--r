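---
title: "Characterizing small-molecule DNA binding from solution measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing small-molecule DNA binding from solution measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctbind)
```

## The problem

When a small molecule — a drug, a food contaminant, a plant growth
regulator — binds double-stranded DNA non-covalently, it does so in one of
three geometries: **intercalation** (insertion between base pairs, which
lengthens and stiffens the helix), **groove binding** (lodging in the minor
or major groove, leaving the helix geometry essentially intact), or
**electrostatic** association with the phosphate backbone. The geometry
matters: intercalators distort the duplex and are disproportionately
genotoxic, while groove binders usually are not.

No single solution experiment settles the geometry. The practice of the
field is a panel of inexpensive assays — UV–vis shifts, fluorescence
quenching at several temperatures, iodide quenching, single- versus
double-stranded DNA comparison, ionic-strength dependence, thermal melting,
viscometry, circular dichroism, and plasmid gel electrophoresis — each with
a standard interpretive rule, read together as a consensus. `ctbind`
implements that entire inference chain as tested, reusable code: every
numeric stage, the qualitative decision rules, an evidence-aggregating
classifier, and a synthetic-data generator with known ground truth so that
each stage is verifiable without laboratory data.

The package's worked example throughout is the characterization of
indole-3-propionic acid (IPA), a plant growth regulator that accumulates in
produce, binding calf thymus DNA (ctDNA) — a study whose every stage this
pipeline reproduces from its reported numbers.

## Fluorescence stages

### Inner-filter correction

Measured fluorescence is first corrected for attenuation of the excitation
beam and re-absorption of emission by the increasingly absorbing sample:

$$F_\mathrm{corr} = F_\mathrm{meas}\, e^{(A_\mathrm{ex}+A_\mathrm{em})/2}.$$

The exponential is the natural one. Absorbances above 0.3 trigger a warning
(the correction degrades there) but not an error. Absorbances may be
supplied per titration point; whether a laboratory measured them once or
per point, the per-point representation covers both.

### Stern–Volmer quenching

Quenching of the fluorophore by titrated DNA follows

$$F_0/F = 1 + K_{SV}[Q] = 1 + K_q \tau_0 [Q],$$

fitted by **unweighted ordinary least squares** of $F_0/F$ against $[Q]$
(no weighting scheme is standard for these plots). $F_0$ is the corrected
intensity of the zero-quencher point, not a fitted intercept — the titration
starts from ligand alone, so that point is a direct measurement.
$\tau_0 = 10^{-8}$ s is the canonical excited-state lifetime of small
organic fluorophores, making $K_q = K_{SV}/\tau_0$.

The mechanism call combines two signatures across temperatures: **static**
quenching (ground-state complex) requires $K_{SV}$ strictly decreasing with
temperature *and* $K_q$ above the diffusion-controlled collisional limit
$2.0\times10^{10}$ L mol$^{-1}$ s$^{-1}$; **dynamic** requires the opposite
pair; anything else is indeterminate. Monotonicity is judged on point
estimates (error bars are ignored, matching how such tables are read); a
perfectly flat fitted slope is snapped to exactly zero so that a
no-quenching series cannot drift into a spurious trend through floating-point
noise.

Comparative assays (iodide quenching of free versus bound ligand;
single- versus double-stranded DNA) reduce to comparing two $K_{SV}$ values.
"Negligible difference" is operationalized as agreement within **twice the
sum of the two standard errors** — a deliberately generous band that makes
the qualitative published calls reproducible without pretending to a formal
test the source assays do not support.

### Binding constant and thermodynamics

For static quenching, the association constant $K_a$ and site number $n$
come from the double-logarithm relation

$$\log_{10}\frac{F_0-F}{F} = n\log_{10}K_a +
  n\log_{10}\!\left([Q_t]-\frac{(F_0-F)[P_t]}{F_0}\right),$$

where the bracketed term is free quencher corrected for the bound fraction.
(The textbook form writes the last term as $-n\log_{10} 1/(\cdot)$; the
reciprocal only flips the sign, and the form above is the one actually
fitted.) Points with $F \ge F_0$ or a non-positive free-quencher term are
excluded and counted; at least three usable points are required. All
logarithms in the package are base-10, with the conversion factor carried
as `log(10)` exactly rather than the rounded 2.303, so that two-temperature
fits agree bit-for-bit with the closed-form van't Hoff expression.

The temperature dependence of $K_a$ yields the thermodynamics via van't
Hoff:

$$\log_{10}K_a = -\frac{\Delta H^\circ}{\ln(10)\,R\,T} +
  \frac{\Delta S^\circ}{\ln(10)\,R}, \qquad
  \Delta G^\circ = \Delta H^\circ - T\Delta S^\circ,$$

with $R = 8.314$ J mol$^{-1}$ K$^{-1}$ and Celsius converted with the exact
offset 273.15. The driving-force verdict follows the sign pattern of
$(\Delta H^\circ, \Delta S^\circ)$: the near-zero enthalpy band
($|\Delta H^\circ| < 4$ kJ mol$^{-1}$, with $\Delta S^\circ > 0$) is tested
**first** and read as electrostatic — otherwise a small negative enthalpy
would be over-interpreted — then $(-,+)$ maps to hydrogen bonding plus
hydrophobic contact, $(+,+)$ to hydrophobic, $(-,-)$ to hydrogen bonding
plus van der Waals. The $(-,+)$ assignment follows the convention of the
DNA-binding literature this pipeline serves; the classical
Ross–Subramanian reading of $(-,+)$ as electrostatic is knowingly not used,
and the 4 kJ mol$^{-1}$ band is this package's own quantification of
"enthalpy approximately zero" (no numeric band exists in the literature
rule). Both choices are documented here rather than resolved: they are
conventions, not measurements.

## Melting and viscosity

A melting curve (absorbance at 258 nm versus temperature) is normalized to
the single-strand fraction
$f_{ss} = (A - A_{20})/(A_{100} - A_{20})$ using the readings closest to
20 °C and 100 °C as duplex and denatured baselines. $T_m$ is the first
upward crossing of $f_{ss} = 0.5$, **linearly interpolated** between the
bracketing readings — the curve is read, not fitted, mirroring how such
plots are actually used; on logistic transitions of width ≥ 2 °C sampled
every 5 °C this reads the midpoint to within 0.5 °C. A complex-minus-free
shift of **+5 °C or more** (boundary inclusive) is classed intercalative;
intercalators raise $T_m$ by roughly 5–8 °C while groove binders leave it
nearly unchanged.

Viscometry reduces to flow times, $\eta = (t - t_0)/t_0$, and the classical
diagnostic plot of $(\eta/\eta_0)^{1/3}$ against the ligand/DNA
concentration ratio. Replicate flow times are averaged before entry. The
zero-ligand entry defines $\eta_0$, so the ordinate at ratio 0 is exactly 1
by construction. A least-squares slope of at least **0.1 per unit
concentration ratio** is classed intercalative: classical intercalators
roughly double the relative viscosity over a 0–1.2 ratio range (cube-root
slope ≳ 0.2) while groove binders stay essentially flat, so 0.1 sits in the
empty middle ground between the two behaviors.

## The binding-mode classifier

`classify_binding_mode()` aggregates up to ten observables with
**equal-weight voting**; ties are indeterminate. Weighting the assays
differently would require information the underlying qualitative rules do
not carry — consensus of independent assays is exactly how the field argues
the call, so the classifier formalizes that and nothing more. A verdict
needs at least **three** present evidence fields (a single assay is never
decisive in practice; three is the smallest panel that can out-vote one
discordant assay). Electrostatic can gain positive votes only from salt
sensitivity or an electrostatic thermodynamic signature, and an unaffected
salt series casts a *negative* electrostatic vote, mirroring how
ionic-strength experiments are used to exclude that mode. Plasmid-cleavage
anomalies (nicking, linearization) and non-electrostatic force verdicts are
recorded in the audit trail without voting: they speak to chemistry, not
geometry. Every present field appears in the returned contributions table
with the rule it triggered, so a verdict is always auditable.

## Trajectory observables

The four standard stability observables for a simulated DNA–ligand complex
are implemented directly on a frames × atoms × 3 coordinate array
(nanometres):

* **RMSD** — each frame is superposed on the reference by mass-weighted
  least-squares rotation + translation (Kabsch, via SVD with a determinant
  guard against reflections), then the mass-weighted deviation is taken.
* **RMSF** — frames are superposed on their mean structure (two passes:
  fit to the first frame, re-average, fit to the average), then per-atom
  fluctuations about the mean position are reported, with the ensemble
  average attached.
* **Radius of gyration** — mass-weighted RMS distance from the centre of
  mass.
* **SASA** — Shrake–Rupley with a *deterministic* Fibonacci sphere lattice
  (default 960 points, probe 0.14 nm, the water-probe convention); a lattice
  point on an expanded sphere is accessible iff outside every other
  expanded sphere. Points exactly on another sphere's surface are resolved
  by atom index, so coincident duplicate atoms count their shared surface
  once rather than zero or twice.

Atom selections are exposed (`atoms`, `fit_atoms`) and default to all
atoms, with unit masses accepted when masses are unknown. Multi-MODEL PDB
files are read through `bio3d`; a plain multi-frame XYZ reader is included.
The module computes observables on user-supplied or synthetic ensembles —
it does not run, and makes no claims about, molecular dynamics itself;
published trajectory averages from 100-ns force-field simulations are
context for interpretation, not quantities this package recomputes.

## The synthetic-data generator

Every stage has a generator with stated ground truth:

* **Titrations** use exact 1:1 mass action: the complex concentration is
  the closed-form root of $K_a(P-C)(Q-C) = C$, the bound ligand is assumed
  completely non-fluorescent (the static-quenching limit, which makes the
  double-log relation an algebraic identity at $n = 1$), stored intensities
  divide out the inner-filter factor so the correction stage restores them,
  and noise is multiplicative Gaussian. Defaults mirror a realistic design:
  $[P_t] = 3.28\times10^{-6}$ mol L$^{-1}$, an 11-point quencher grid, and
  $K_a$ of order $10^4$ L mol$^{-1}$. For $n \ne 1$ no mechanistic 1:1
  model exists, so the generator inverts the double-log relation
  phenomenologically by fixed-point iteration.
* **Melting curves** are logistic sigmoids (any symmetric sigmoid would do;
  the logistic has a closed-form midpoint) sampled at 5 °C steps, the
  conventional bath increment, between 20 and 100 °C.
* **Viscosity series** back-compute flow times from a target cube-root
  profile with slope 0.25 (intercalative) or 0.01 (groove), with timing
  jitter clamped to ±0.2 s — the resolution of a manual stopwatch assay.
* `ipa_ctdna_evidence()` packages the observed IPA–ctDNA evidence vector
  as the documentation and regression fixture.

All generator randomness flows through one locally seeded RNG that restores
the caller's stream, so a campaign is reproducible bit-exactly from its
seeds.

What the generators deliberately do **not** emulate: wavelength-resolved
spectra, instrument drift and baseline artifacts, correlated (non-Gaussian)
noise, partial fluorescence of the bound state, multi-domain melting, or
shear-rate effects in viscometry. Green tests on synthetic data therefore
demonstrate that the *inference chain* is correct and stable under the
stated noise, not that any particular laboratory's data meet the model's
assumptions.

## Numerical choices and degenerate inputs

* Flat Stern–Volmer series return slope exactly 0 with correlation 0.
* A flat melting curve ($A_{100} = A_{20}$) and a curve that never crosses
  $f_{ss} = 0.5$ are errors, not NaNs.
* Flow times at or below the buffer time are rejected (a DNA solution
  cannot flow faster than its buffer).
* JSON results are written with 17 significant digits so a write–read
  round trip is bit-exact; results carry `schema_version` 1 and the
  configuration snapshot used.
* Problem sizes in the test-suite simulations (100 noisy titrations of 11
  points; ensembles of ≤ 12 atoms; 960-point SASA lattices) were chosen as
  the smallest sizes at which the statistical claims are stable.

## Limitations

The pipeline automates the *standard* interpretive rules; systems that
violate their premises (mixed binding modes, upward-curving Stern–Volmer
plots from combined static+dynamic quenching, cooperative binding with
mechanistic $n \ne 1$, multi-phasic melting) are outside its scope and are
flagged only insofar as the rules return "indeterminate". The classifier's
equal-weight vote is a formalization of community practice, not a
calibrated probabilistic model.
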