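# gpcrfp

Structural comparison and interaction fingerprinting of peptide-bound
class B GPCR complexes, with matched dose–response pharmacology.

## The problem

Multi-targeting incretin analogues — GIPR/GLP-1R dual agonists such
as tirzepatide and GIPR/GLP-1R/GCGR triagonists such as peptide 20 —
are single helical peptides whose clinical behaviour traces back to
residue-level differences in how they occupy three homologous class
B1 receptors. Comparing the receptor–peptide complex structures comes
down to a small set of reusable quantitative operations, which this
package implements for structural biologists and receptor
pharmacologists:

- **Superposition metrics** — Kabsch least-squares superposition
  (reflections forbidden), Cα RMSD with author-number pairing and
  audit trail, framed named-atom displacements ("the peptide tip
  shifted by X Å, measured by the Cα of L27^P"), cross-structure atom
  offsets, and helix-axis rotation angles from the dominant principal
  component of the helix Cα cloud.
- **Surface areas** — Shrake–Rupley SASA on a deterministic
  golden-spiral lattice (no RNG; byte-reproducible), and
  ΔSASA buried/interface areas between selections, with both the
  one-sided (ΔSASA/2) and total conventions always reported.
- **Interaction fingerprints** — geometric typing of hydrogen bonds,
  salt bridges, hydrophobic contacts, π–π stacking and cation–π on
  heavy-atom criteria, rolled up into per-peptide-position
  fingerprint strings (empty positions retained) and per-position
  gained/lost/conserved diffs between complexes.
- **Pharmacology** — three-parameter logistic concentration–response
  fits (Hill slope fixed at 1): pEC50 with standard errors,
  fold-shifts, percent-of-wild-type normalization, per-experiment
  aggregation (mean ± SEM), and baseline/vehicle-corrected BRET
  area-under-curve.
- **Synthetic ground truth** — ideal peptide helices, planted typed
  contacts with manifests, seeded rigid perturbations and simulated
  assay data, so the entire pipeline is testable with no downloads.

The model at the pharmacology core is

    response = bottom + (top − bottom) / (1 + 10^(−(pEC50 + log10 c)))

with pEC50 = −log10(EC50 in molar) and fold-shift
10^(pEC50_ref − pEC50_test).

Residues are addressed the way the field writes them: author numbers
(K344), class B generic labels (6.35b), regions (ECL1, TMD), and
peptide positions (27P), attached from a TSV numbering map
(`inst/extdata/example_numbering_map.tsv` shows the format).

## Worked example

Build a toy helical peptide, plant two interactions with known
geometry, and run the full read–detect–fingerprint–area–fit chain:

```r
library(gpcrfp)

helix <- buildIdealHelix("GGGGGGGGGKGGGGGGLGGGGGGFGGGFGG")
pl <- plantContact(helix, "hbond", 3, list(distance = 2.9, angle = 165))
pl <- plantContact(pl$model, "salt_bridge", 10, list(distance = 3.5))
cx <- pl$model

ct <- detectContacts(cx, "chain P", "chain R")
ct[, c("type", "pep_resno", "rec_resno", "distance")]
#>          type pep_resno rec_resno distance
#> 1       hbond         3      1001      2.9
#> 2 salt_bridge        10      1002      3.5
```

Both planted contacts come back with their planted type and distance
— the hydrogen bond on the backbone amide of residue 3, the salt
bridge on the lysine ammonium of residue 10 — and nothing spurious.

```r
buildFingerprint(ct, 30, complexId = "toy")
#> FingerprintString [toy] : 30 positions, 2 typed contacts
#>    3: hbond(GLY1001)
#>   10: salt_bridge(ASP1002)

buriedSurfaceArea(cx, "chain P", "chain R")   # total delta-SASA, A^2
#> [1] 163.0
interfaceArea(cx, "chain P", "chain R")       # one-sided convention
#> [1] 81.5

caRmsd(cx, perturbRigid(cx, angle = 20, axis = c(0, 1, 0),
                        translation = c(3, 1, -2)), chainA = "P")
#> SuperposeResult: RMSD 3.952e-15 A over 30 paired atoms
```

The rigidly moved copy superposes back to numerically zero RMSD over
all 30 paired Cα. Finally, a simulated cAMP-style curve (true pEC50
9.2, noise SD 2% of the top, quadruplicate) refits to the planted
potency:

```r
d <- simulateDoseResponse(bottom = 0, top = 100, pec50 = 9.2,
                          doses = 10^seq(-12, -6, length.out = 8),
                          nReplicates = 4, noiseSd = 2, seed = 1)
fitLogistic3(d)
#> LogisticFit: bottom 0.436, top 100, pEC50 9.194 (EC50 6.39e-10 M), n = 32
```

An end-to-end comparison of several complexes (fingerprint TSVs,
pairwise diffs, RMSD/displacement/area metrics JSON) runs from one
YAML/JSON config via `runComparison()`; thin command-line wrappers
live in `inst/scripts/` (`run_comparison.R`, `make_fixtures.R`).

## Deposited structures

`depositedRegression(cacheDir)` recomputes the published comparison
metrics (receptor Cα RMSDs, peptide tip displacements, ECL1 glycine
offset, peptide/ECL1 buried areas, modeled peptide length) from
accession-named coordinate files. The package never downloads: fetch
the entries once, e.g.

```sh
mkdir -p ~/.cache/gpcrfp/structures && cd ~/.cache/gpcrfp/structures
for id in 7fiy 7fim 7fin 7vbh 7v35 7dty 6x18; do
  curl -O https://files.rcsb.org/download/${id}.pdb
done
```

The corresponding regression blocks in `tests/testthat/test-acceptance.R`
fail with an explicit message until that cache exists.

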