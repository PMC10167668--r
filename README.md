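# flexbuild

Automated multi-conformer side-chain model building from real-space
electron-density sampling.

Crystallographic maps average over every unit cell in the crystal, so a
side chain that populates two rotamers leaves density for both — yet most
deposited models record only one. `flexbuild` finds the hidden
conformations and builds them explicitly: it samples a sigma-scaled
2mFo−DFc-style map around every side-chain dihedral (χ), detects peaks in
the resulting circular density traces, assembles the peak angles into
candidate rotamers validated against an ideal rotamer library, and writes
the survivors into the model as altloc-labelled, occupancy-weighted
alternate conformers ready for crystallographic refinement. It is aimed at
crystallographers who want systematic, inspectable multi-conformer models
without manual trace reading and rebuilding.

## Method in brief

For residue *r* and dihedral χₖ, the probe atom (the first atom distal to
the rotating bond) is rotated rigidly to each angle θ ∈ {0°, 10°, …, 350°}
and the map value ρ(θ) is interpolated at its center, giving a circular
trace in σ units. Peaks are local maxima with ρ ≥ σ-threshold (default
0.3σ) and sufficient circular prominence; each peak's area integrates ρ
over its contiguous super-threshold run. Peak angles are combined across
all χ of the residue into every combination; a combination matches a
library rotamer when every per-χ circular deviation is ≤ 30° (180°-period
for the symmetric terminal dihedrals of ASP/GLU/PHE/TYR), ties going to
the rotamer most frequent in the PDB. The input conformation becomes
altloc A; each surviving rotamer is built as B, C, … in order of density
support, with occupancies seeded from relative peak areas
(occᵢ = areaᵢ / Σareaⱼ, rounded to 2 decimals, summing to exactly 1.00)
and near-zero conformers pruned. Validation helpers compute
B_norm = (B − B_μ)/B_σ over all protein atoms and real-space correlation
coefficients (RSCC) against a Gaussian-atom forward model.

A synthetic-data module generates ground-truth multi-conformer models and
Gaussian-atom CCP4 maps (amplitude ∝ electron count × occupancy, width
from B = 8π²⟨u²⟩), so the whole pipeline is testable without downloads.

## Worked example

Generate the 0.7/0.3 serine fixture (a two-conformer ground truth, its
map, and a single-conformer input model) and run the pipeline:

```r
library(flexbuild)
fx  <- makeFixture("serine_70_30", seed = 1, dir = "fxdemo")
res <- runPipeline(fx$mapPath, fx$modelPath, outDir = "demo_out")
res$rotamerReport[, c("rotamer", "support", "seedRelativeArea", "isOriginal")]
#>   rotamer    support seedRelativeArea isOriginal
#> 1       m 38.5136538      0.696435732       TRUE
#> 2       p 16.7770512      0.302383025      FALSE
#> 3       t  0.3358424      0.001181242      FALSE
res$buildReport[, c("restype", "disposition", "n_conformers")]
#>   restype        disposition n_conformers
#> 1     SER built-1-alternates            2
occupancySums(res$model)
#> A|1|
#>    1
```

Reading the output: the χ1 trace shows the original rotamer `m` at 38.5σ
and a second peak matching `p` at 16.8σ; their relative peak areas
(0.70/0.30) recover the true occupancy split and seed the built conformers
A (m, occupancy 0.70) and B (p, 0.30). A marginal 0.34σ candidate (`t`,
relative area 0.001 — the trace grazing the residue's own backbone
density) is seeded at occupancy 0.00 and pruned, so the final residue
carries exactly two conformers summing to 1.00. `demo_out/` holds the
multi-conformer PDB plus trace, peak, rotamer, build and clash CSVs.

A command-line wrapper covers the same workflow plus the recommended
threshold/tolerance grid search:

```sh
Rscript inst/scripts/flexbuild.R run  --map fx.ccp4 --model fx.pdb --out out/
Rscript inst/scripts/flexbuild.R grid --map fx.ccp4 --model fx.pdb \
        --sigma 0.3,0.35,0.5 --tolerance 20,30,40
Rscript inst/scripts/flexbuild.R fixtures --case methionine_chi3_split --out fx/
```

## Rotamer library

`inst/extdata/rotamer_library.csv` has columns `residue_type`,
`rotamer_name`, `chi1`–`chi4` (blank where a residue has fewer dihedrals)
and `frequency` (relative PDB abundance, ≤ 1 per residue type). It is an
approximate reconstruction of the penultimate rotamer library of ideal
side-chain rotamers; substitute any table with the same schema via
`loadRotamerLibrary("my_library.csv")`. See the vignette
(`vignettes/multiconformer-building.Rmd`) for the method description,
parameter guidance and known limitations.

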