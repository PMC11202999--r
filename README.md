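# ctbind

Spectroscopic and computational characterization of small-molecule binding
to double-stranded DNA, as an R package.

## What this is for

Small molecules absorbed from food or the environment can bind duplex DNA
in three non-covalent geometries — **intercalation** between base pairs,
**groove binding**, or **electrostatic** association with the phosphate
backbone — and the geometry largely determines the toxicological concern.
The geometry is established in practice not by one experiment but by a
panel of solution assays, each with a standard interpretive rule.
`ctbind` implements the full inference chain from raw assay tables to a
binding-mode verdict, for anyone running (or re-analyzing) such panels:

* inner-filter correction of fluorescence titrations,
  `F_corr = F_meas · e^{(A_ex + A_em)/2}`;
* Stern–Volmer analysis, `F0/F = 1 + Ksv[Q] = 1 + Kq·τ0·[Q]`, with
  static/dynamic mechanism classification from the temperature trend of
  `Ksv` and the diffusion limit `Kq > 2×10^10 L mol⁻¹ s⁻¹`;
* binding constant and site number from the double-log plot
  `log10((F0−F)/F) = n·log10(Ka) + n·log10([Qt] − (F0−F)[Pt]/F0)`;
* van't Hoff thermodynamics
  `log10(Ka) = −ΔH°/(ln10·R·T) + ΔS°/(ln10·R)`, `ΔG° = ΔH° − TΔS°`, and a
  driving-force verdict from the signs of ΔH° and ΔS°;
* melting-temperature extraction from hyperchromicity curves via
  `fss = (A − A20)/(A100 − A20)`, Tm at the `fss = 0.5` crossing;
* the cube-root viscosity diagnostic `(η/η0)^{1/3}` versus `[ligand]/[DNA]`;
* an evidence-voting classifier aggregating up to ten assays into an
  auditable intercalation/groove/electrostatic verdict;
* standalone trajectory observables (Kabsch-superposed RMSD, RMSF, radius
  of gyration, Shrake–Rupley SASA on a deterministic Fibonacci lattice)
  for multi-frame coordinate sets (multi-MODEL PDB or XYZ);
* seedable synthetic-data generators with known ground truth for every
  stage.

The bundled worked example is the characterization of the plant growth
regulator indole-3-propionic acid (IPA) binding calf thymus DNA, a
groove-binding case whose published numbers thread through the package's
tests.

## Worked example

```r
library(ctbind)

# A synthetic titration at 25 C with known ground truth (Ka = 1.75e4,
# n = 1, mild inner-filter attenuation, 0.5% noise), then the full
# fluorescence analysis:
s25 <- simulate_titration(ka = 1.75e4, f0 = 1000, ligand_conc = 3.28e-6,
                          quencher_grid = seq(0, 2e-4, length.out = 11),
                          a_ex = 0.02, a_em = 0.01,
                          noise_sd_fraction = 0.005, seed = 11)
s25 <- apply_inner_filter(s25)
binding_fit(s25)
#> Double-log binding fit at 298.15 K
#>   Ka = 1.745e+04 L/mol, n = 1.000 (r = 0.9999; 10 points used, 0 excluded)
```

The fitted `Ka` recovers the generator's ground truth within 0.3% and
`n = 1` confirms 1:1 stoichiometry. Thermodynamics from binding constants
at three temperatures:

```r
vant_hoff(c("298.15" = 1.75e4, "304.15" = 1.62e4, "310.15" = 1.27e4))
#> Van't Hoff thermodynamics
#>   dH = -20.47 kJ/mol, dS = 12.81 J/(mol K)  [hydrogen_bond_and_hydrophobic]
#>   dG(298.15 K) = -24.29 kJ/mol
#>   dG(304.15 K) = -24.36 kJ/mol
#>   dG(310.15 K) = -24.44 kJ/mol
```

Negative ΔG° at all temperatures: spontaneous binding; ΔH° < 0 with
ΔS° > 0 is the signature of hydrogen bonding plus hydrophobic contact.
Melting and viscosity on synthetic fixtures:

```r
melting_analysis(simulate_melting(83.5, 2), simulate_melting(81.1, 2))
#> Melting analysis 'simulated Tm=81.1'
#>   Tm = 81.32 C
#>   dTm = -2.00 C -> non_intercalative

viscosity_profile(simulate_viscosity("groove", jitter_sd = 0.05, seed = 3))
#> Viscosity profile: slope 0.0102 per unit [ligand]/[DNA] -> non_intercalative
```

A slightly *negative* Tm shift and a flat viscosity profile both argue
against intercalation. Finally, the consensus verdict over the full
IPA–ctDNA evidence panel:

```r
classify_binding_mode(ipa_ctdna_evidence())
#> Binding-mode verdict: groove
#>   votes: intercalation 0, groove 8, electrostatic -1
#>   - redshift_nm -> groove (slight UV shift is characteristic of groove/external binding)
#>   - ka -> groove (Ka in the 1e3-1e5 L/mol groove-binder range)
#>   ...
```

Eight of ten assays vote groove, none votes intercalation, and the
unaffected salt series actively excludes electrostatic binding — the
ligand is a groove binder.

## Layout

* `R/` — domain types and readers (`core_io`), `apply_inner_filter`,
  Stern–Volmer and comparisons (`quenching`), binding constants and
  thermodynamics (`binding_thermo`), `melting`, `viscosity`,
  `mode_classifier`, trajectory observables (`trajmetrics`), and the
  generators (`synthetic_data`).
* `vignettes/ligand-dna-binding.Rmd` — the methods account: models,
  assumptions, thresholds, numerical choices, limitations.
* `tests/testthat/` — unit, property and end-to-end tests, all runnable
  offline on generated data.
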