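---
title: "Methods: structural comparison and interaction fingerprinting of peptide-bound class B GPCR complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural comparison and interaction fingerprinting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcrfp)
```

## The scientific setting

Multi-targeting incretin analogues — GIPR/GLP-1R dual agonists such as
tirzepatide and GIPR/GLP-1R/GCGR triagonists such as peptide 20 — are
single helical peptides that engage three homologous class B1 GPCRs
with deliberately unequal strength. Understanding *why* a given
analogue keeps potency at one receptor and loses it at another comes
down to three quantitative questions asked of the receptor–peptide
complex structures:

1. **How far do things move?** After rigid-body superposition of two
   complexes on a shared frame (typically the receptor transmembrane
   domain, TMD), how far does a named atom — the Cα of the peptide's
   C-terminal tip, an extracellular-loop glycine, the intracellular
   tip of TM6 — travel between the two structures, and by what angle
   does the bound peptide's helix axis rotate?
2. **How much surface is shared?** How large is the buried surface
   between the peptide and, say, ECL1, or between ICL2 and the Gαs
   subunit, measured as a solvent-accessible surface-area difference
   (ΔSASA)?
3. **Which residues talk to which?** Which typed interactions
   (hydrogen bonds, salt bridges, hydrophobic contacts, π–π stacking,
   cation–π) does each peptide position make with the receptor, and
   which of those are gained or lost between two complexes?

A fourth, pharmacological question closes the loop: do the structural
changes show up as potency shifts in concentration–response assays
(cAMP accumulation, whole-cell binding, β-arrestin BRET)?

The package implements each question as a module with a typed S4
surface, and pairs them with a synthetic-data generator so every
operator is testable offline against planted ground truth.

## Structure handling

Models are read from PDB or mmCIF (via bio3d) into a `StructureModel`:
a flat atom table keyed by chain and *author* residue number, because
that is how residues are addressed in the literature (K344, G202).
Alternate locations are resolved to the highest-occupancy conformer
(ties: lexicographically first altloc identifier); only model 1 of
multi-model files is used; waters and monatomic ions are dropped by
default. Nonstandard residues — Aib, acylated lysines, γ-Glu/OEG
linker and lipid components — are retained as hetero residues on the
peptide chain: the lipidated-K10 analysis depends on them, and they
must never be silently dropped.

Class B generic numbering (the `x.yyb` Wootten-style scheme), region
tags (TM1–TM7, H8, ECL1–3, ICL1–3, ECD) and peptide positions (`nP`)
are supplied as an external TSV map rather than computed: whether a
deposition's author numbering refers to the construct or the mature
receptor differs between entries, and externalizing the map avoids
guessing. `applyNumbering()` attaches labels without touching
coordinates; selections can then address residues the way the field
writes them (`label 6.35b`, `region ECL1`).

## Superposition metrics

`kabschFit()` is the SVD solution of the least-squares rigid
superposition problem, with the determinant correction that forbids
reflections. Its correctness is not taken on faith: the test suite
compares it against a brute-force rotation-search oracle (a 30° Euler
grid refined by Nelder–Mead, knowing nothing of the SVD solution) on
random point clouds, to 10⁻⁶ Å.

`caRmsd()` pairs residues by identical author numbering on the
receptor chain — the compared class B structures share numbering, so
no sequence alignment is attempted — requires the Cα present in both
models, fits on the paired set, and reports the RMSD over that same
set, recording the pairing for audit. Published global Cα RMSDs
rarely state their atom set (ECD in or out?), so an optional region
filter (`region = "TMD"`) is exposed; the default uses all paired Cα.

`displacement()` formalizes "shifted by X Å (measured by the Cα of
…)": superpose model B on model A over a frame selection, then
measure the Euclidean distance between the two placements of a probe
atom. `crossAtomDistance()` is the same with different probe residues
in the two models (e.g. the ECL1 glycines of two different
receptors). `axisRotationAngle()` fits the dominant principal
component of each helix's Cα cloud — parameter-free and stable for
helices of ≥2 turns — and reports the acute angle between the axes;
sign and handedness are deliberately not reported, since published
rotation values are magnitudes.

## Surface areas

`sasa()` is a Shrake–Rupley implementation with test points on a
deterministic golden-spiral lattice: no random numbers, so a given
model always yields byte-identical areas. Radii are a Bondi-type set
(C 1.70, N 1.55, O 1.52, S/P 1.80, H 1.20 Å; halogens per Bondi;
unknown elements 1.80 Å with a warning). Hydrogens are excluded by
default because cryo-EM depositions are heavy-atom models. The
default probe is 1.4 Å.

The default quadrature is 1920 points per atom. That is a measured
choice: coarser lattices can change a per-atom area by more than the
package's declared convergence property (<0.5% under point doubling)
allows on two-sphere systems, while from 1920 points the property
holds across a separation scan — the test suite asserts it. The cost
is linear in the point count and irrelevant at the problem sizes
involved.

`buriedSurfaceArea(A, B)` is ΔSASA = SASA(A alone) + SASA(B alone) −
SASA(A∪B). Two conventions differ across the literature and are both
supported, always side by side in reports:

* *context*: by default the two selections are the only atoms present
  ("stripped"); a flag computes instead in full-complex context
  (each side's reference SASA computed with only the partner
  removed).
* *sidedness*: `interfaceArea()` returns ΔSASA/2 (the mean of the two
  one-sided buried areas) by default; `oneSided = FALSE` gives the
  full ΔSASA. Published "buried surface area" and "interface area"
  values do not state which convention they use, so
  `runComparison()` and `depositedRegression()` report both and let
  the regression record which matches each printed value.

## Interaction typing and fingerprints

`assignChemistry()` is an explicit rule table for the 20 standard
residues plus Aib (backbone donor/acceptor, two hydrophobic methyl
carbons): hydrogen-bond donors with their covalent antecedent,
acceptors, cationic groups (Arg guanidinium, Lys ammonium, His
imidazole — His is treated as potentially protonated), anionic groups
(Asp/Glu carboxylates, C-terminal carboxylate), aromatic rings
(Phe/Tyr/His, both Trp rings) with centroid and unit normal, and
apolar carbons/sulfurs. Residues not in the table — lipid tails,
linker components, modified lysines — fall back to element rules:
C/S hydrophobic, N/O donor-and-acceptor with a geometric antecedent.
Unknown residues are logged, never dropped.

`detectContacts()` applies heavy-atom geometric criteria (deposited
models lack hydrogens):

| type | criterion (defaults) |
|---|---|
| hydrogen bond | donor–acceptor heavy-atom distance ≤ 3.5 Å and angle(antecedent, donor, acceptor) ≥ 90° |
| salt bridge | charged N to charged O ≤ 4.0 Å |
| hydrophobic | apolar C/S pair ≤ 4.5 Å, one contact per residue pair |
| π–π | ring centroid distance ≤ 5.5 Å, inter-normal angle ≤ 30° (parallel) or 60–90° (T-shaped) |
| cation–π | cationic-group center to ring centroid ≤ 6.0 Å |

All cutoffs are overridable through `contactCriteria()`. Published
interaction tables never state their criteria, so these defaults are
a documented choice; the deposited-structure regression reports which
published contacts are reproduced under them. Two conventions are
fixed: a salt-bridge pair that also satisfies hydrogen-bond geometry
through the same charged groups is reported as salt bridge only, and
each residue pair additionally carries a single dominant label by the
precedence salt_bridge > hbond > cation_pi > pi_pi > hydrophobic
(the full multi-label set is always retained). Lysine "stacking"
against an aromatic ring lands as cation–π when the geometry
qualifies, hydrophobic otherwise.

`buildFingerprint()` rolls contacts up into one ordered entry per
peptide position 1..N; positions with no contacts are present and
empty, mirroring the "white circles" of fingerprint diagrams.
Ordering is deterministic (position, receptor label, type), so
identical models give byte-identical fingerprints.
`diffFingerprints()` takes per-position set differences (gained /
lost / conserved); peptides of different register need an explicit
position map — no silent realignment.

## Pharmacology

`fitLogistic3()` fits the three-parameter logistic

$$ y = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
       {1 + 10^{-(\mathrm{pEC}_{50} + \log_{10} c)}} $$

with the Hill slope fixed at 1 — that is what "three-parameter
logistic" means with bottom, top and EC50 free. Fitting is
Levenberg–Marquardt (`minpack.lm::nls.lm`) with a deterministic
initialization (bottom = min response, top = max response, pEC50 =
−log10 of the dose nearest half-maximal response), so identical data
give identical fits. Standard errors come from the least-squares
curvature at the optimum. Degenerate inputs produce `converged =
FALSE` rather than numbers; an EC50 more than two orders of magnitude
outside the tested window is flagged `extrapolated`. Requirements on
the data — ≥4 distinct concentrations spanning ≥2 log units — are
enforced, not assumed.

Replicates are fitted as pooled points. Potencies across independent
experiments are aggregated the way they are reported in the
literature — per-experiment fits, then mean ± SEM of the pEC50s
(`fitByExperiment()`); `foldShift()` is `10^(pEC50_ref −
pEC50_test)`, so values above 1 mean the test condition is less
potent. `bretAuc()` corrects each kinetic BRET trace to its own
pre-stimulus baseline mean and then to the vehicle trace, and
integrates by the trapezoid rule over the measured stimulus cycles;
"total stimulus time" is the span of the stimulus samples,
(n_stim − 1) × cycle duration, in units of Δratio × s.

## The synthetic generator: what it emulates and what it does not

`buildIdealHelix()` places backbone plus pseudo-side-chains on a
parametric α-helix (Cα radius 2.3 Å, rise 1.5 Å, twist 100° —
consecutive Cα ≈ 3.8 Å, i,i+4 ≈ 6.2 Å), emulating the single
continuous helix that class B agonist peptides adopt.
Lys/Arg/Asp/Glu/Phe/Tyr get extended idealized side chains (ammonium,
guanidinium, carboxylate, aromatic ring) pointing radially outward so
charged and aromatic chemistry can anchor on the peptide; Aib is
built at requested positions. The geometry is idealized, not
stereochemically refined — sufficient for geometric operators, cheap
to reason about.

`plantContact()` places a minimal partner group at a requested
geometry and records the ground truth in a manifest. A planted
geometry must satisfy the detection criteria with a ≥0.3 Å / ≥10°
margin to enter the manifest; geometry clear of the criteria by the
same margin is placed as a negative control with an empty manifest
(the detector must stay silent); the ambiguous band around a cutoff
is a construction error. For hydrogen bonds the placement azimuth is
chosen, deterministically, to maximize clearance from the rest of the
model, so a planted acceptor does not graze a neighboring backbone
amide.

`perturbRigid()` (exact rotation + translation + seeded Gaussian
coordinate noise) and `simulateDoseResponse()` (logistic mean +
seeded Gaussian noise) complete the generator. Every generator call
seeds its own private RNG stream and restores the global state:
test isolation, bit-reproducibility.

What the toys deliberately do **not** emulate: real side-chain
rotamers and sterics, solvent, membrane and lipid placement,
experimental coordinate error structure, or receptor folds. Passing
the planted-contact suite therefore demonstrates that the *geometric
operators* are correct, not that the default cutoffs optimally
reproduce any particular deposited structure's published interaction
table — that is what the deposited-structure regression (below) is
for.

## Problem sizes and reproducibility

The property-based suite runs entirely on synthetic inputs: 50 random
10-point clouds for the Kabsch/oracle comparison, two-sphere systems
for the SASA checks, 30-residue toy helices for contacts, and 1000
simulated curves (8 doses × 4 replicates, noise SD 2% of the top) for
the pEC50 calibration, with the planted 93-fold shift recovered via
four simulated independent experiments per curve — the same averaging
the assay literature reports. These sizes keep the whole suite in the
tens of seconds on one CPU while leaving the statistical criteria
well-resolved.

The deposited-structure regression (`depositedRegression()`) never
downloads: it reads accession-named coordinate files from a local
cache directory that the user populates once (see the README). In an
offline environment those regression tests fail with an explicit
message naming the missing cache — they are not skipped, because a
silently skipped regression looks like a passing one.

## Known limitations

* Contact criteria are heavy-atom proxies; protonation states,
  water-mediated bridges and halogen bonds are out of scope.
* The ΔSASA conventions (one-sided vs total; stripped vs in-context)
  must be chosen to match any published number being compared; both
  are always reported to make that choice visible.
* `caRmsd()` assumes shared author numbering; comparing receptors
  with different numbering requires an explicit map or a
  structurally equivalent frame selection.
* The three-parameter fit fixes the Hill slope at 1; strongly
  cooperative data will show lack of fit rather than a slope
  estimate (a fixed non-unit slope can be supplied, but is never
  fitted).
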