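---
title: "Multi-conformer side-chain building from density sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-conformer side-chain building from density sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexbuild)
```

## The problem

Crystallographic electron-density maps are ensemble averages: when a side
chain populates two rotamers, the map holds density for both, but most
deposited models record only the major one.  `flexbuild` automates the
detection and explicit building of such alternative side-chain
conformations.  The workflow has three parts:

1. **Density sampling.** For each side-chain dihedral (χ) of each residue,
   the probe atom — the first atom distal to the rotating bond (Cγ for χ1,
   and so on) — is rotated rigidly through 360°, preserving its bond length
   and angle, and the sigma-scaled map is interpolated at each position.
   This yields a circular density trace per χ (a "Ringer plot").  The
   sampled grid is absolute: the sample angle *is* the χ value.
2. **Peak detection and rotamer assembly.** Local maxima of the
   circularized trace above a σ threshold are detected; their angles are
   combined across all χ of the residue into every possible combination,
   and each combination is validated against an ideal rotamer library: it
   is accepted when every χ lies within an angular tolerance of a library
   entry's modal angles, and is then named after that entry.  Among several
   matching entries the one most frequent in the PDB wins.
3. **Model building.** The input conformation becomes altloc A; each
   additional named rotamer is built as altloc B, C, … (largest density
   support first) by rigid χ rotations onto the library's modal angles.
   Occupancies are seeded from relative peak areas, written with two
   decimals summing to exactly 1.00, and near-zero conformers are pruned
   before the model is written for refinement.

The pipeline never refines: the output model, trace/peak/rotamer CSVs and
clash report are inputs to a conventional crystallographic refinement
program, which estimates the final occupancies and relaxes the geometry.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `sigmaThreshold` | 0.3 σ | trace level a maximum must reach to count as a peak; 0.35 σ (`paperEvalThreshold()`) is the stricter preset used in published benchmark evaluations |
| `tolerance` | 30° | per-χ circular deviation allowed between a peak combination and a library entry |
| `step` | 10° | dihedral sampling granularity, the granularity of the original density-sampling method |
| `minProminence` | 0.1 σ | circular prominence below which a maximum is treated as a shoulder, not a peak |
| `minSeparation` | 30° | maxima closer than this are merged, keeping the higher |
| `buildMode` | `"full"` | duplicate the entire residue per conformer (backbone initially superposed; refinement separates it); `"calpha"` shares a single backbone |
| `minOccupancy` | 0.01 | conformers seeded below this are pruned and the rest renormalized |

The threshold and tolerance are the two parameters worth tuning per data
set; `gridSearch()` crosses them and tabulates what gets built.  Both
detection parameters (`minProminence`, `minSeparation`) exist because the
peak definition on a 10°-sampled circular trace is otherwise ambiguous;
they are package decisions, not values taken from any publication, and are
exposed as arguments for exactly that reason.

Deviation handling is per-χ (every dihedral must individually pass), and
the chemically two-fold-symmetric terminal dihedrals (ASP χ2, GLU χ3,
PHE/TYR χ2) are compared with a 180° period so that indistinguishable
branches never produce duplicate conformers.  Candidates collapsing onto
the same rotamer name keep the best-geometry representative.  The input
model's own conformation is matched for naming only — it is always
retained as conformer A even when its measured χ matches no library entry,
because observed structure is never deleted.  A peak-derived rotamer that
matches the original's name is suppressed rather than built twice.

GLY and ALA have no χ; PRO's ring constrains its dihedrals.  All three are
excluded from sampling and building, as are HETATM records and waters.
Hydrogens are ignored throughout.  Waters are never moved or deleted even
when a new conformer collides with one; collisions appear in the clash
report (heavy-atom pairs more than 0.4 Å inside the sum of van der Waals
radii, between altloc-compatible atoms) but never block building — the
philosophy is to build every defensible candidate and let the
crystallographer inspect.

## Occupancy seeding

Relative peak areas on the occupancy-attribution χ — the first χ (from χ1
outward) carrying more than one peak — seed the conformer occupancies.
Areas integrate the raw σ values over the contiguous super-threshold run
containing each maximum (trapezoid rule in degrees; runs shared by two
peaks are split at the lowest sample between them).  Integrating raw
values rather than value-minus-threshold keeps areas comparable across
thresholds.  These seeds are starting values for refinement, not
estimates: the area–occupancy relation is strong for single-dihedral side
chains but degrades for weak peaks and branched residues, which is why the
`uniform` scheme is also available and why occupancies are rounded to the
two decimals the PDB format carries (remainder added to conformer A so
each residue sums to exactly 1.00).

## Validation utilities

Two map–model agreement measures are provided.  `bNorm()` computes the
normalized B factor B~norm~ = (B − B~μ~)/B~σ~, with mean and standard
deviation over all protein atoms (population standard deviation by
default).  `rscc()` computes the real-space correlation coefficient: the
Pearson correlation between observed map values and a model-computed
density over all grid points within 2 Å of the selected atoms.  RSCC ≥ 0.8
is the conventional confident-modeling level and ≥ 0.7 a minimal cutoff.
The model-computed density comes from the same Gaussian forward model the
synthetic generator uses.

## The synthetic forward model

Because deposited map/model pairs cannot be bundled, the package generates
its own ground truth.  Each heavy atom contributes one isotropic Gaussian
with amplitude proportional to its electron count and occupancy and with
variance B/(8π²) from the standard B = 8π²⟨u²⟩ relation; conformers
superpose linearly; optional i.i.d. Gaussian noise is added under a fixed
seed.  Default fixture conditions: 20 Å cubic P1 cell, 0.25 Å grid,
B = 15 Å².

```{r fixture}
fx <- makeFixture("serine_70_30", seed = 1)
fx$truth
```

Fixtures cover a single-conformer control, a 0.7/0.3 serine, a
χ3-split methionine, a tyrosine with a 12% minor conformer, a lysine split
0.74/0.26 at χ3 and a five-residue group with correlated splits.  Each
returns the single-conformer input model, the rendered map and a
machine-readable truth table.

What the forward model does **not** emulate matters for interpreting green
tests: there is no Fourier truncation ripple, no solvent, no model-phase
bias and no crystallographic symmetry beyond P1 wrapping.  A cell
containing a single residue also has a much smaller map standard deviation
than a protein-filled cell, so atomic peaks sit at tens of σ rather than
the 1–5 σ typical of real 2mFo−DFc maps.  Two noise conventions are
therefore offered: the default scales noise to the noise-free map's σ
(`noiseRef = "mapSigma"`, 0.1 by default — the regime of a good
high-resolution map, where the 0.3 σ threshold behaves as it does in
practice), while `noiseRef = "minorPeak"` scales it to the weakest
conformer's probe-atom peak, the quantity that limits detectability, for
stress tests.  Under heavy minor-peak-relative noise the 0.3 σ default
threshold sits below the trace noise floor, and occasional spurious weak
conformers (seeded at 0.01–0.03 occupancy) survive pruning — the same
phenomenon observed on real data, where seemingly genuine trace peaks can
reflect noise and a fraction of built conformers refine to zero occupancy.
The remedy on real data is the threshold/tolerance grid search plus
pruning, not a change to the defaults.

## Numerical choices

* Angles are degrees on the half-open interval [−180, 180), signed by the
  standard IUPAC convention (cross-checked against an independent dihedral
  implementation); trace sample angles live on [0, 360).
* Map interpolation is trilinear in fractional coordinates with periodic
  P1 wrapping; trilinear is monotone and exact at grid nodes, which is
  adequate at 10° angular granularity.  Maps must cover the full unit
  cell; crystallographic symmetry expansion is out of scope.
* Sigma scaling uses the population standard deviation over all stored
  grid points and refuses flat maps.
* Peak prominence is circular: the reference saddle is found by walking
  both directions to the nearest higher value, wrapping around.
* Conformer geometry is built at the library's modal angles (matching how
  rotamer-insertion tools build by name); `atMeasuredAngles = TRUE` builds
  at the observed peak angles instead.
* B factors of new conformers are copied unchanged from their source
  atoms — the simplest defensible seed for refinement.
* Existing altlocs in the input are stripped to the highest-occupancy
  conformer before sampling (mirroring how deposited alternates are
  discarded before multi-conformer rebuilding); `stripInputAltlocs =
  FALSE` keeps them and samples conformer A.
* Disulfide-bonded cysteines are sampled and built like any other CYS;
  inspect the clash report for the partner.

## Known limitations

* **Branch-atom artifacts.** For residues with a second atom bonded to the
  pivot (THR/VAL/ILE at χ1, LEU at χ2, and the two-fold branches of
  ASP/ASN/GLU/GLN/arginine heads), the trace of the probe atom passes
  through density belonging to the branch atom, producing genuine-looking
  peaks ~120° (or 180°) from the true χ.  Some of these match library
  entries and are built as weak extra conformers; the THR case in the
  `loop_multi` fixture shows this deliberately.
* **Proximal-χ dependence.** Higher-χ sampling follows the *input*
  conformer's proximal geometry, so an alternate differing at χ1 by more
  than roughly the matching tolerance leaves its distal atoms off the
  sampled circle and can be missed.  Alternates sharing proximal χ (the
  common case for the split side chains this method targets) are
  recovered; fully independent conformations are the territory of
  ensemble methods.
* Missing higher-χ peaks cause the residue to be skipped (all χ must carry
  at least one peak); this conservative rule avoids inventing distal
  geometry for lysine- and arginine-like side chains with weak outer
  density.
* Altloc labels are assigned per residue; no attempt is made to reconcile
  labels into a consistent network across neighbouring residues.

## Library provenance

The bundled `rotamer_library.csv` (residue type, rotamer name, χ1–χ4 modal
angles, PDB frequency) is a reconstruction of the penultimate rotamer
library of ideal side-chain rotamers; modal angles and relative
frequencies are approximate transcriptions, not a verbatim copy of any
edition, and threonine carries exactly the three ideal rotamers p, t, m.
The schema is documented in the README so a newer library can be
substituted via `loadRotamerLibrary(path)`.

## Test problem sizes

The shipped tests run entirely on generated data: single-residue fixtures
in 20–28 Å cells at 0.25 Å spacing (80³–112³ grids), the 20-seed serine
recovery study, and exhaustive build/measure round trips over all 143
bundled library entries.  These sizes keep the whole suite in the
low-minutes range on one CPU while still exercising every stage end to
end.
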