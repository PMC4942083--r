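# BindConf

Quantitative analysis of CSL corepressor complexes: binding thermodynamics
from isothermal titration calorimetry (ITC), structural interface
characterisation, and conformational-ensemble statistics, in one tested R
package.

## The problem

The Notch-pathway transcription factor CSL (Su(H) in *Drosophila*, RBP-J in
mammals) switches between activator and repressor complexes. Dissecting a
repressor complex such as Su(H)–Hairless quantitatively requires three
different kinds of analysis that are usually scattered across instrument
software and ad hoc scripts:

1. **Binding thermodynamics.** ITC titrations are fit to the one-site
   (Wiseman) isotherm to obtain the association constant *K*, the
   stoichiometry *n* and the enthalpy ΔH°; derived columns follow as
   ΔG° = −RT ln K, −TΔS° = ΔG° − ΔH°, mutant penalties
   ΔΔG° = RT ln(K_ref/K_mut), fold changes K_d,mut/K_d,ref, and
   double-mutant-cycle coupling energies
   ΔΔG_int = ΔΔG_AB − ΔΔG_A − ΔΔG_B (nonzero ⇒ the two residues are
   energetically coupled).
2. **Interface structure.** Shrake–Rupley solvent-accessible surface area
   (SASA), two-sided buried surface area
   BSA = SASA(A) + SASA(B) − SASA(AB), per-residue and side-chain-only
   ΔSASA, heavy-atom contact maps, and a burial filter that flags residues
   whose side chains are already buried (< 20 Å² SASA) in an apo reference
   structure.
3. **Conformational change and ensembles.** Kabsch superposition and RMSD,
   per-residue displacements (loop translations as the window maximum),
   side-chain χ1 torsions, per-atom RMSF, and principal-component analysis
   of the 3N Cα fluctuation covariance with per-frame projections and a
   two-state separation score.

Every stage is paired with a seeded synthetic-data generator whose ground
truth is analytically known (Wiseman thermograms with Gaussian noise, sphere
clusters with closed-form SASA, rigid pairs with exact loop excursions,
two-state Gaussian ensembles with known eigenstructure), so the whole
pipeline is verifiable at desk scale without downloading any structures.

## Worked example

Simulate a coactivator-style titration (K_d = 60 nM, ΔH° = −23.8 kcal/mol,
40 × 7 µL injections of 50 µM titrant into 5 µM macromolecule at 25 °C),
fit it back, and build a thermodynamic table:

```r
library(BindConf)

truth <- OneSiteParams(n = 1, K = 1 / 60e-9, dH = -23.8)
exp   <- simulateThermogram(truth, noiseRelative = 0.01, seed = 7)
fitOneSite(exp)
#> OneSiteFit (converged, 6 iterations)
#> OneSiteParams: n = 0.9985, K = 1.674e+07 1/M (Kd = 0.05974 uM), dH = -23.69 kcal/mol
#>   std errors: n 0.0024, K 6.59e+05, dH 0.0824
```

The fitted K_d (59.7 nM) recovers the generating 60 nM within the 1% heat
noise. Derived columns from association constants:

```r
fits <- list(
  Hairless  = OneSiteParams(K = 5.7e8, dH = -11.9),
  `H-L235A` = OneSiteParams(K = 1.7e7, dH = -9.6),
  `H-F237A` = OneSiteParams(K = 4.3e6, dH = -4.4))
writeThermoTable(buildThermoTable(fits, reference = "Hairless",
                                  cell = "Su(H)"), stdout())
#> cell    syringe   K_per_M  Kd_uM  dG     dH     mTdS  ddG
#> Su(H)   Hairless  5.7e+08  0.002  -11.9  -11.9  -0.0  n/a
#> Su(H)   H-L235A   1.7e+07  0.059  -9.9   -9.6   -0.3  2.1
#> Su(H)   H-F237A   4.3e+06  0.233  -9.0   -4.4   -4.6  2.9
```

Reading across a row: the F237A mutant binds 2.9 kcal/mol more weakly than
wild type — a ~140-fold affinity loss
(`roundHalfUp(foldChange(0.233, 0.002))`). A double-mutant cycle on two
candidate coupled residues:

```r
couplingEnergy(ddGFromK(5.7e8, 6.7e7),   # single mutant A: 1.27
               ddGFromK(5.7e8, 1.8e8),   # single mutant B: 0.68
               ddGFromK(5.7e8, 1.0e7))$ddG_interaction  # double: 2.40
#> [1] 0.444
```

0.44 kcal/mol of nonadditivity: the double mutant is worse than the sum of
its parts, the thermodynamic signature of coupled residues.

Structural stages work the same way from `readPDB()` /
`buriedSurfaceArea()` / `ensemblePca()`; `runRepressorReport()` wires any
combination of stages into a deterministic TSV/JSON report bundle from one
validated JSON configuration (see `inst/scripts/repressor-report.R` for a
shell entry point).

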