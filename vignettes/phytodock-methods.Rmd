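---
title: "Models and methods in phytodock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in phytodock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytodock)
```

phytodock chains five analysis stages that commonly follow one another
in essential-oil pharmacology: composition profiling, bioassay
statistics, docking post-processing, electronic-complementarity
scoring, and druglikeness evaluation. This vignette explains the model
behind each stage, the tunable parameters and their defaults, the
numerical choices, and what the synthetic-data generators do and do
not emulate.

## Composition profiling

A GC-MS peak's area percentage, 100·area/Σareas, is used as the
constituent's relative concentration. All 17 peaks of a packaged
chromatogram enter the denominator — the packaged raw areas reproduce
the packaged percentage column under exactly this convention, which is
why no unlisted-minor-peak correction is applied. Percentages are kept
at full precision internally and rounded to one decimal only for
display and table export, the precision at which such tables are
conventionally printed. Duplicate compound names are allowed (isomers
elute separately); peak identity is keyed on the peak index.

## Dose–response model and IC50

Radical-scavenging data of this kind is summarised with the
logarithmic model y = a·ln(x) + b fitted by ordinary least squares,
with x in µg/mL and y in percent. The logarithmic form (rather than a
four-parameter logistic) is deliberate: over the usual 1.5-decade
concentration window these assays do not resolve the asymptotes a 4PL
would need, and the log-linear fit is the form under which such assay
results are conventionally reported. The IC50 is defined at y = 50
exactly — not at half of the fitted maximum — giving the closed form
IC50 = exp((50 − b)/a).

Uncertainty reporting depends on the input. When replicate response
columns are present, each replicate series is fitted separately and
the SEM of the replicate IC50s is reported, mirroring how triplicate
assay IC50s are usually summarised (this is an assumption about the
upstream convention, stated here once). With mean-only input the
delta-method standard error from the OLS covariance is used instead.
Replicate summaries elsewhere report mean ± SEM (sample SD/√n); a
single replicate yields SEM 0 with a warning rather than an error.
A non-positive slope with responses spanning 50% flags the IC50 as
unreliable rather than failing, since downstream code may still want
the fit. Viability controls printed as 0 in legacy tables are treated
as a formatting artifact; controls are normalised to 100%.

## Docking post-processing

The affinity filter keeps ligands with docking scores less than or
equal to the cutoff, default −8.0 kcal/mol, *inclusive* — a ligand at
exactly −8.0 is a hit. The reference (co-crystallized) ligand is
excluded by name before filtering, not by score.

Pose RMSD matches atoms by file order, which docking pipelines
preserve; no graph-isomorphism symmetry correction is attempted, so a
molecule with topologically equivalent atoms (e.g. a gem-dimethyl
pair) can report an RMSD above the symmetry-corrected minimum. This is
a documented limitation. With superimposition the Kabsch least-squares
rotation is applied (via bio3d), which makes the value invariant to
any rigid transform of either pose and never larger than the in-place
RMSD; without it, deviations are measured in the shared frame, the
right choice when a re-docked pose is compared against the
crystallographic one in the same coordinate system.

Contacts are reported generically: a residue is in contact when any of
its heavy atoms is within the cutoff (default 4.5 Å) of a ligand heavy
atom. Hydrogen bonds use the standard geometric criterion —
donor–acceptor distance ≤ 3.5 Å and D–H···A angle ≥ 120° — with donors
taken as N/O bearing a hydrogen (within 1.3 Å covalent distance, or
typed polar in PDBQT input). Interaction subtypes (Pi-alkyl, Pi-sigma,
…) are intentionally not assigned; they depend on aromatic-system
perception that adds little to a hit-selection pipeline. Coordinates
are always Å in the source frame; nothing is re-centered on load. The
docking grid-box geometry (center 29.944, −1.861, 24.611; size 18, 14,
18) is carried as provenance metadata in reports and is never used to
run anything.

## Electronic complementarity

Each atom contributes a single-exponential outer-shell density term
ρ_a(r) = ρ(CNT)_a·exp(−ζ_a·r); a molecule's density at a point is the
sum of its terms. This declared model stands in for full orbital-free
quantum-chemical densities: it keeps the two properties the
complementarity analysis actually uses — monotone radial decay and a
per-element center density/atomic number normalisation — while being
transparent and overridable. The shipped per-element table (H, C, N,
O, S) sets ζ to twice the Slater valence exponent per Bohr radius
(e.g. C: 6.14 Å⁻¹) and ρ(CNT) to the Slater 1s density at the nucleus
(e.g. C: 797 e/Å³). Because this parameterization is declared rather
than fitted, regression coefficients for externally docked complexes
are not expected to reproduce values computed under other density
models; results should always be reported together with the parameter
table used, and the package's summaries do so.

At each sampled point m, CF1 = ln(ρ_E·ρ(CNT)_e/N_e) +
ln(ρ_L·ρ(CNT)_l/N_l), where e and l are the enzyme and ligand atoms
with the greatest single density contribution at m — the largest term,
which is not necessarily the nearest atom when elements differ. Ties
are broken by lowest atom index, making the computation deterministic.
SUMRLRE = R_me + R_ml sums the distances to those two atoms. Under the
single-exponential model with one atom per molecule and shared ζ,
CF1 = const − ζ·SUMRLRE identically; the test suite holds the
regression to that closed form at 1e-9.

Sampling is a deterministic cubic grid (no Monte Carlo): the ligand
bounding box padded by 4 Å, default spacing 0.3 Å, aligned to
multiples of the spacing so that equal inputs give identical point
sets. A point enters the regression when both molecular densities lie
in the band [1e-4, 1e-1] e/Å³ — the low-density intermolecular shell,
which under the default parameters sits roughly 1.5–2.6 Å from the
nearest atom — and the point is at least 1 Å from every atom. Which
intermolecular points should enter is a genuinely open choice; the
density-band grid is this package's declared one, made so the sampled
shell tracks the molecular surface rather than the box geometry.

The regression CF1 = aCF1 + bCF1·SUMRLRE is ordinary least squares;
Rcor² is the squared Pearson correlation, and Sigma is the residual
standard deviation √(SSR/(n−2)) — the usual dispersion measure for
such summaries, adopted here explicitly. A complex passes the
selection principles when Rcor² ≥ 0.81 and MAX(CF1) ∈ [−5, −2]; when a
reference complex is supplied the coefficient distances |aCF1 − a_ref|
and |bCF1 − b_ref| are reported without a hard cutoff, since closeness
to the experimental complex is a ranking criterion, not a threshold.

## Druglikeness

Molecular weights use atomic weights pinned to the 2005 IUPAC values
(C 12.0107, H 1.00794, O 15.9994), the vintage that reproduces
two-decimal reference weights of sesquiterpenes exactly. H-bond
acceptors are counted as N+O and donors as N/O atoms bearing at least
one hydrogen (each heteroatom once), the Lipinski convention. Donor
counting demands a structure whenever N/O are present, because
connectivity decides where the hydrogens sit.

MLOGP is a from-scratch implementation of the Moriguchi 13-descriptor
regression on topological counts (weighted carbon/halogen count,
N+O count, N/O proximity, unsaturation, intramolecular H-bond dummy,
aromatic polar substituents, amphotericity, the
hydrocarbon-with-≤1-double-bond dummy, non-aromatic ring dummy,
quaternary N, nitro, isothiocyanate, β-lactam; constant −1.041). Two
descriptor readings deserve mention because the original definitions
are terse: the ALK dummy is applied only to hydrocarbons with at most
one double bond and no aromatic ring (a cyclic diene is not an
"alkene" in this sense), and kekulized aromatic rings contribute their
three formal double bonds to the unsaturation count. Under these
readings the regression reproduces reference MLOGP values for
polycyclic sesquiterpene hydrocarbons to the printed precision;
oxygenated analogues come out ≈0.05 higher than some published
calculators, a spread small against the 4.15 decision threshold. The
rule-of-five verdict uses MLOGP > 4.15 as the lipophilicity violation
(not a generic logP ≤ 5), and a compound is druglike with at most one
violation, matching the "Yes; 1 violation" convention of ADME tables.
Molar refractivity uses classic Eisenlohr atomic refractions and is
reported for information only; it never enters the verdict.

## Synthetic data

The generators emulate the statistical or geometric structure each
stage assumes: log-linear dose–response with Gaussian noise (default
σ = 2%, a typical plate-reader replicate spread, at the six 2-fold
dilutions of the packaged assay), Gaussian atom clusters standing in
for a binding site and ligand at a set separation, uniform affinity
tables, and log-normal chromatogram areas (heavy-tailed, as peak
integrals are). Every generator is seeded, bit-reproducible, and
emits a truth record the tests consume. They do **not** emulate
chromatographic peak overlap, docking energetics, receptor flexibility
or cell-assay biology — so green tests demonstrate that the
*computations* are correct under the stated models, not that the
models capture every feature of real data.

Problem sizes used in the packaged checks — six-point dose–response
fits over 500 seeds, 200-point complementarity regressions over 200
seeds, toy complexes of tens of atoms at 0.4–0.5 Å grid spacing — were
chosen as the smallest sizes at which the estimators' sampling
behaviour is clearly resolved; production analyses on real complexes
would use the default 0.3 Å spacing over thousands of points.

## Known limitations

- RMSD has no symmetry correction (atom matching is by file order).
- The exponential density model is a declared stand-in; its regression
  coefficients are comparable only across complexes scored with the
  same parameter table.
- MLOGP descriptor perception (aromaticity, amphotericity) is
  rule-based on kekulized V2000 input; exotic heteroaromatics outside
  the descriptor set's coverage are rejected rather than approximated.
- The CLI's `mtt` subcommand normalises to a single supplied control
  OD; plate-layout-aware blank correction is out of scope.
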