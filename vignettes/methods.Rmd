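---
title: "Models and methods in BindConf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in BindConf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

BindConf analyses protein–protein corepressor complexes of the CSL
transcription factor family along three axes: binding thermodynamics from
isothermal titration calorimetry (ITC), structural characterisation of the
binding interface, and conformational statistics of coordinate ensembles.
This vignette is the package's own account of the models it implements, the
conventions it fixes where the field leaves a choice open, and what its
synthetic-data tests do and do not establish.

## The one-site binding isotherm

An ITC experiment titrates a syringe ligand X (concentration `syringeConc`,
mol/L) into a cell of volume $V_0$ (liters) holding a macromolecule M
(`cellConc`), and integrates the heat of each injection (microcalories).
For $n$ equivalent independent sites with association constant $K$ (1/M)
and molar enthalpy $\Delta H$ (kcal/mol), the total heat content of the
cell at totals $M_t, X_t$ is the closed form

$$Q = \frac{n M_t \Delta H V_0}{2}\Big[b - \sqrt{b^2 - 4X_t/(nM_t)}\Big],
\qquad b = 1 + \frac{X_t}{nM_t} + \frac{1}{nKM_t},$$

the root being chosen so the bound fraction lies in
$[0, \min(1, X_t/nM_t)]$. `oneSiteTotalHeat()` clamps a discriminant that
roundoff pushes within $10^{-12} b^2$ below zero and raises an error naming
the inputs otherwise (which valid inputs cannot trigger).

**Dilution bookkeeping.** Perfusion calorimeters expel cell liquid as they
inject. After a cumulative injected volume $v$ we use the standard
displaced-volume convention
$M_t = M_{t0}\frac{1 - v/2V_0}{1 + v/2V_0}$,
$X_t = X_{t0}\frac{v/V_0}{1 + v/2V_0}$,
and per-injection heats are differenced as
$\Delta Q_i = Q_i + \frac{dV_i}{V_0}\frac{Q_i + Q_{i-1}}{2} - Q_{i-1}$ with
$Q_0 = 0$. These are bookkeeping conventions, not physics; they are
documented here because other conventions exist and produce per-mille-level
differences. A useful identity under this convention — tested in the suite —
is that titrant moles are conserved: $X_t (V_0 + v/2) = X_{t0} v$.

**Units.** Heats are stored in microcalories at the experiment boundary;
the model computes kilocalories internally and converts once
($1\,\mathrm{kcal} = 10^3\,\mathrm{cal} = 10^9\,\mu\mathrm{cal}$). The gas
constant is $R = 1.987204 \times 10^{-3}$ kcal mol$^{-1}$ K$^{-1}$ and the
default temperature 298.15 K (experiments in this system are run at 25 °C);
`thermoConstants()` is the single authoritative record.

**Cell volume.** Instrument cell volumes are rarely reported with published
tables. The default $V_0 = 1.4$ mL is typical of VP-style instruments and
is overridable per experiment; at the reference design (40 × 7 µL) the
fitted $K$ shifts by well under the fit uncertainty across plausible
volumes, because $V_0$ enters both the model and the simulated data the
same way.

## Fitting and its numerics

`fitOneSite()` minimises observed-minus-model heats over $(n, K, \Delta H)$
with Levenberg–Marquardt (`minpack.lm::nls.lm`). $K$ is fitted as
$\log_{10} K$ for conditioning, with box constraints
$K \in [1, 10^{15}]$ 1/M and $n \in [0.1, 10]$. Initialisation: $n = 1$;
$\Delta H$ from the first two injection heats normalised by the moles
injected (early injections are near-stoichiometric when binding is tight);
$K = 10/M_{t0}$, i.e. a starting $K_d$ of one tenth the cell concentration.
Standard errors come from the curvature of the least-squares surface at the
optimum, with the $K$ error propagated from the log scale by the delta
method. Non-convergence is a flagged result, never silent; all-zero heats
are an input error.

The fit is self-consistent to better than $10^{-3}$ relative on noiseless
simulated thermograms across the well-posed range of the Wiseman parameter
$c = nKM_{t0} \in [5, 500]$ (tested at $c$ = 5, 50, 500). Below $c \approx
5$ the stoichiometry is weakly identifiable — the usual practice, exposed
here as `fixN = TRUE`, is to freeze $n$ at 1. Whether the original
instrument fits floated $n$ is not stated in published tables, so both
modes are provided.

**$K$ versus $K_d$ in published tables.** Derived energies are always
computed from the association constant $K$, never from the displayed (3
decimal) $K_d$ column. Published tables in this system are internally
inconsistent at the rounding boundary: e.g. a row printing
$K = 1.9\times10^7$ next to $K_d = 0.060$ µM (reciprocal 52.6 nM), a ΔΔG°
of 1.2 that equals the difference of *rounded* ΔG° values where the
unrounded difference is 1.27, and a ΔG° of −11.2 where
$-RT\ln(1.8\times10^8) = -11.26$. BindConf keeps the exact-$K$ convention
throughout and rounds only in display writers (`writeThermoTable()`:
energies to 1 decimal; in-text fold changes round half-up to integers via
`roundHalfUp()`). Where a recovered $K_d$ is compared against such a
mixed-provenance row, the generator for that comparison is parameterised by
the printed $K_d$ itself, since that is the quantity being reproduced.

**Double-mutant cycles.** `couplingEnergy()` uses
$\Delta\Delta G_{int} = \Delta\Delta G_{AB} - \Delta\Delta G_A -
\Delta\Delta G_B$ with the sign convention that positive interaction energy
means the double mutant is worse than additive. The formula is symmetric in
A and B (tested as a property).

## Surface area and the interface

**Algorithm choice.** No installed R package provides SASA without an
external binary, and published interface areas in this field rarely name
their algorithm, so BindConf implements Shrake–Rupley with a deterministic
golden-angle spiral lattice (`spiralPoints()`): atom $i$'s solvent sphere
(radius $r_i$ + probe) is sampled at `nPoints` fixed directions and its
area is $4\pi(r_i+p)^2$ times the accessible fraction. Determinism makes
reruns bit-identical and makes per-atom ΔSASA exactly nonnegative (a point
occluded in a subset stays occluded in the superset), so per-residue buried
areas sum *exactly* to the total. Defaults: probe 1.4 Å (water), 960
points — at which the isolated-sphere error is below 1% and the two-sphere
spherical-cap closed form is matched within 2%; doubling the lattice moves
any toy-suite atom by < 1%.

**Radii.** A fixed published van der Waals table (C 1.70, N 1.55, O 1.52,
S 1.80, P 1.80 Å) with a 1.70 Å fallback that warns; a strict radii set
(`fallback = NA`) turns unknown elements into errors. Hydrogens are ignored
by all geometry by default. Synthetic sphere clusters carry prescribed
radii through synthetic element codes.

**BSA convention.** `buriedSurfaceArea()` reports the two-sided sum
$\mathrm{SASA}(A) + \mathrm{SASA}(B) - \mathrm{SASA}(A \cup B)$, with both
components extracted in their complexed conformation. Published "buried
surface area" figures are often not annotated per-side; the two-sided
convention is therefore a documented package choice, and per-side
per-residue ΔSASA (total and side-chain-only, backbone N/CA/C/O/OXT
excluded) is reported alongside so either reading can be reconstructed.

**Contacts and the burial filter.** "Contact" has no universal definition;
the default is any heavy-atom pair within 4.5 Å, configurable.
`apoBurialFilter()` implements the structural argument that a binder
reaching residues already buried in the apo state must deform its partner:
it keeps query residues whose *side-chain* SASA in an apo reference is
strictly below 20 Å². Whether whole-residue or side-chain SASA is the
right reading of published "< 20 Å²" filters is ambiguous; side-chain SASA
is used because the accompanying per-mutant burial columns in this system
are explicitly side-chain quantities. Cross-species numbering (fly query
against a mouse apo structure) goes through an explicit two-column mapping
table — no automatic alignment in this version.

## Superposition, torsions, ensembles

`kabschSuperpose()` is the SVD solution for the optimal proper rotation;
a reflection solution is corrected by flipping the smallest singular
direction, near-collinear sets (second singular value $\le 10^{-8}$ of the
first) are flagged degenerate rather than rejected, and the result is
validated orthonormal with det +1 to $10^{-9}$. Per-residue displacement
supports fitting the superposition on a rigid core while reporting all
atoms, and `segmentMax()` operationalises "the loop translates by as much
as X Å" as the window maximum of per-Cα displacement — this is exactly what
the synthetic `makeTransformedPair()` generator guarantees by
construction.

χ1 is the N–CA–CB–γ torsion with the γ atom per residue type (CG1 for
Ile/Val, OG for Ser, OG1 for Thr, SG for Cys, CG otherwise), signed by the
IUPAC convention and returned in (−180°, 180°]; glycine/alanine and
missing atoms are explicit errors. The implementation (projection/atan2) is
cross-checked against an independent acos-plus-orientation-sign oracle to
$10^{-6}$ degrees over random geometries.

Ensemble statistics (`rmsf()`, `ensemblePca()`) optionally superpose every
frame to the running mean iteratively (tolerance $10^{-6}$ Å on the mean
shift, at most 20 iterations). Whether published ensemble PCAs superpose to
a reference or to the mean is usually unstated; both modes are provided
(`superpose = TRUE` for mean-iterated, or pre-superpose frames yourself and
pass `superpose = FALSE`). The covariance is the mass-unweighted
$3N \times 3N$ matrix of Cα fluctuations with population normalisation
$1/F$, so $\mathrm{tr}(C) = \sum_i \lambda_i = \sum_i \mathrm{RMSF}_i^2$
holds exactly and is tested to $10^{-6}$ relative. Eigenvector signs are
fixed by making the largest-magnitude component positive, so projections
are reproducible; zero eigenvalues from rank-deficient (e.g. rigid)
ensembles are allowed. `stateSeparation()` reports the standardised mean
difference per component, with > 2 on PC1 flagged as distinct
conformational regions — a deliberately simple score; clustering is out of
scope.

## What the generators emulate — and what they do not

- `simulateThermogram()` produces Wiseman isotherms under the reference
  design (40 × 7 µL, 5 µM cell, 50 µM syringe, 25 °C, 1.4 mL) with iid
  Gaussian heat noise, by default 1% of the largest injection heat —
  representative of a well-behaved run on a sensitive instrument. It does
  not emulate baseline drift, injection-peak integration error, active-site
  titration errors in concentrations, or heats of dilution; recovered
  parameter accuracy on synthetic data is accordingly an upper bound on
  real-data accuracy.
- `makeSphereCluster()` gives analytically solvable SASA/BSA fixtures;
  real packing, cavities and probe-scale crevices are exercised only
  indirectly (via the Monte Carlo cross-check).
- `makeTransformedPair()` and `makeTwoStateEnsemble()` generate exact rigid
  motions, exact loop excursions and isotropic Gaussian basins with known
  eigenstructure ($\mathrm{RMSF} = \sigma\sqrt{3}$, PC1 along the
  inter-state displacement, separation $|\Delta|/\sigma$). Real
  conformational ensembles are anharmonic and anisotropic; passing these
  tests shows the estimators are correct, not that two principal
  components suffice for any particular trajectory.
- All generators are pure functions of their arguments including the seed,
  and return their ground truth alongside the data.

Test problem sizes are chosen so the whole suite runs in seconds while
keeping Monte Carlo error far from the tolerances: 20,000 frames for the
RMSF closed form (sampling error ≈ 0.3% against a 2% tolerance), 50
replicate fits for the stochastic-recovery median, 200–500 frames for
PCA/separation checks.

## Real-structure analyses

The same functions apply unchanged to deposited structures — Cα
superposition of crystallographically independent copies, interface BSA of
a bound corepressor peptide against its partner's C-terminal domain,
side-chain burial ranking of interface mutants, and the apo-burial filter
through a fly-to-mouse residue mapping. The package ships no coordinate
files and never touches the network; point `readPDB()` at locally
downloaded files to run these. mmCIF is not supported in this version, and
symmetry expansion, assemblies and SEQRES reconciliation are out of scope.

## The report pipeline

`runRepressorReport()` validates a flat JSON configuration (unknown keys
are rejected; each stage's required keys are checked before any work),
runs the requested itc / coupling / interface / conformation stages, and
writes TSV/JSON outputs with fixed decimal rounding so identical
configurations yield byte-identical files. The resolved configuration is
written next to the outputs, progress goes to standard error, and a
failing stage aborts with an error naming the stage. The package's
functions are the primary interface; `inst/scripts/repressor-report.R` is
a thin shell wrapper over the same entry point.

## Known limitations

- One-site binding only: no multi-site, sequential or competitive models,
  and no integration of raw power traces or instrument file formats.
- PDB fixed-column format only; altloc resolution keeps the
  highest-occupancy location (ties to 'A') at parse time rather than
  carrying alternates.
- Element inference from atom names is single-letter beyond a short
  two-letter list; exotic ligand atoms may need explicit element fields or
  custom radii.
- SASA is $O(N \cdot n_{points} \cdot \bar{k})$ in plain R; comfortable to
  a few thousand heavy atoms, not tuned for large complexes.
- The separation score assumes two labelled states; it is not a clustering
  method.
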