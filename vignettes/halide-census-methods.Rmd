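---
title: "Methods of the halide-binding-site census"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods of the halide-binding-site census}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halidecensus)
```

## The census model

Monoatomic halide anions (F⁻, Cl⁻, Br⁻, I⁻) interact with proteins largely
electrostatically: they are drawn to arginine guanidinium groups, lysine
ε-amino groups, backbone amides and polar hydroxyls. This package implements
a descriptive census of such binding sites over a curated set of X-ray
crystal structures. The unit of analysis is the *site*: one halide atom plus
the set of protein atoms that coordinate it.

A protein atom coordinates a halide when its centre lies within a sphere of
radius 5 Å around the anion and its element is neither carbon nor hydrogen
(nor deuterium): C–H and C–X contacts are packing, not coordination, and are
excluded throughout. Water oxygens inside the sphere are counted as the
site's solvation shell; in the with-waters mode they additionally join the
coordinating set and the coordination number, which lets solvent-mediated
contacts be compared against direct ones. Other halide atoms never count as
partners.

Per site the census computes:

* **distances** between the anion and each coordinating atom;
* **angles** between the vector to the *nearest* coordinating atom and the
  vector to every other coordinating atom (so the nearest atom itself
  carries the angle 0; a site with a single partner has only that 0). This
  reference-vector convention makes angular structure visible without
  choosing an external frame: an octahedral site shows maxima near 90° and
  180°, a bipyramidal one near 90° and 120°;
* the **coordination number** (CN), the size of the coordinating set under
  the active water mode;
* the **water count**, the number of distinct water residues whose oxygen
  lies in the sphere;
* the **fractional accessible surface area** (fASA), the anion's
  solvent-accessible surface inside the structure divided by the surface of
  the isolated probe-expanded sphere, 1 = fully exposed, 0 = fully buried;
* **residue annotations**: the unique coordinating residues, their
  helix/strand/loop context, the backbone fraction of coordinating atoms,
  and the site's residue combination (its sorted residue-name multiset).

### Curation assumptions

Only X-ray structures enter the census: NMR, electron microscopy, powder and
neutron entries are excluded, as is any entry with an unrecognised method
label (conservatively, with a warning). Entries with resolution worse than
2.0 Å, or with no resolution recorded, are dropped. Where several entries
share a normalized protein name (case-folded, whitespace-collapsed, trailing
punctuation stripped) only the best-resolution one survives, with ties going
to the lexicographically smallest PDB id. The 2.0 Å boundary is read
inclusively — a structure at exactly 2.00 Å is kept — because the filter's
intent is a high-quality dataset and 2.00 Å entries satisfy it; the
behaviour at the exact boundary is a documented choice, not a physical
threshold.

Sites are rejected when any ligand-class atom — a non-water, non-halide
HETATM, or a DNA/RNA nucleotide from the ATOM field — lies inside the
sphere, and when the coordinating set spans more than one chain. Both rules
keep the census to purely protein-coordinated, single-chain sites; the
multichain rule is applied at site level (the coordinating set), since the
site, not the entry, is the unit of analysis.

### Homologous-site merging

Crystallographic symmetry and non-crystallographic copies repeat the same
site within one entry. Sites of one entry and species are clustered greedily
in deterministic order (halide chain, residue number): a site is merged into
an earlier one when both have the identical composition key — the sorted
sequence of (residue name, atom name) pairs of the coordinating set — and
the optimal rigid-body superposition RMSD of the matched coordinates is at
most 0.5 Å. The superposition is the Kabsch least-squares proper rotation
(reflections excluded, as is standard structural practice), and the halide
itself participates as an extra matched point so that sites identical in
protein but different in anion placement are not merged.

Matching atoms across two compositionally identical sites avoids a
combinatorial assignment problem by sorting each side on (residue name,
atom name, distance-to-halide, angle), with distance and angle rounded to
the precision the coordinates support (10⁻³ Å, 10⁻² degrees). Atoms whose
sort key is fully tied — e.g. two symmetry-equivalent `SER OG` partners at
identical distance and angle — are genuinely interchangeable; for those the
RMSD is minimised over the within-group permutations (capped at 720
combinations, beyond which the sorted pairing is used as-is). Without this,
exact-tie sites can pair atoms inconsistently across copies and a true
duplicate can evade merging on floating-point noise alone.

For the same reason the *nearest-atom* reference used by the angle
computation breaks distance ties on values rounded to 10⁻⁶ Å, deferring to
a deterministic (chain, residue, atom-name) key: translated copies of a
perfectly symmetric site then choose the same reference atom.

## Accessible surface area

The anion's ASA is computed by deterministic sphere-point sampling: a
golden-spiral lattice of *n* points (default 960) on the expanded sphere of
radius r\_ion + r\_w, where r\_ion is the ionic radius (F⁻ 1.19, Cl⁻ 1.67,
Br⁻ 1.82, I⁻ 2.06 Å) and r\_w = 1.4 Å the water probe. A point is exposed
when it lies outside every context atom's expanded sphere; the area is the
exposed fraction times 4π(r\_ion + r\_w)². The golden-spiral lattice makes
the result bit-reproducible — no random rotations — and at 960 points the
isolated-sphere area is exact and a one-occluder system agrees with a
100,000-point Monte-Carlo estimate to better than 1% (both are asserted in
the test suite; doubling the density twice moves a typical occluded area by
under 1%).

The occlusion context is every non-hydrogen, non-water atom of the
structure: waters are excluded so fASA measures burial *by the protein*,
which is what distinguishes buried from surface-bound anions. Carbons do
occlude even though they never coordinate — burial is physical, not
chemical. Protein elements use a fixed van-der-Waals table (N 1.55, O 1.52,
S 1.80, P 1.80, C 1.70 Å); an element without a configured radius is a
configuration error, never a silent guess.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `halide_radii` | 1.19 / 1.67 / 1.82 / 2.06 | Å | ionic radii of F⁻/Cl⁻/Br⁻/I⁻; set the fASA reference sphere |
| `water_radius` | 1.4 | Å | solvent probe for ASA expansion and the fASA denominator |
| `sphere_radius` | 5.0 | Å | interaction sphere defining coordination |
| `rmsd_threshold` | 0.5 | Å | homologous-copy merging threshold |
| `resolution_cutoff` | 2.0 | Å | entry curation bound (inclusive) |
| `include_waters` | `FALSE` | — | whether sphere waters join the coordinating set |
| `sasa_points` | 960 | — | golden-spiral sampling density |

Halide residue codes default to the PDB chemical-component ids F⁻→`F`,
Cl⁻→`CL`, Br⁻→`BR`, I⁻→{`IOD`, `I`} — iodide has carried both codes over
PDB remediation history, so both are recognised. `HOH`, `DOD` and `WAT` are
water.

### Parsing choices

Only the first MODEL of a file is read (the census excludes NMR, so
multi-model files are edge cases, not a supported mode). Alternate
locations are resolved before extraction: per (chain, residue, insertion
code, atom name) group the highest-occupancy copy wins, ties going to the
alphabetically smallest altloc, and zero-occupancy atoms are removed.
Elements come from PDB columns 77–78 when present, otherwise from the
atom-name field (a symbol occupying column 13 is read as a two-letter
element when valid); an uninferable element is a parse error. Deuterium is
treated as hydrogen for all exclusion rules. Secondary structure is read
from HELIX/SHEET header records rather than recomputed — no DSSP dependency
— and a residue claimed by both record types is labelled helix, with a
warning.

## Aggregation conventions

Distance medians are taken over the *pooled* per-atom distances of all
sites of a species, not over per-site medians: the census reports the
anion–atom contact distribution as a single population. A `nearest_only`
switch restricts pooling to each site's nearest contact for comparison.
Angle pooling drops each site's single reference 0° entry (it is an
artefact of the convention, not an observation). Modes (CN, water count)
break exact frequency ties toward the smaller value, making them
deterministic. Histograms use half-open bins [kw, (k+1)w) with defaults of
0.1 Å for distances, 5° for angles and 0.05 for fASA, with origin 0.
Combination counts key each site by its sorted residue-name multiset, so
`ARG+SER` and `SER+ARG` are one combination.

## The synthetic-data generator

`make_site_structure()` builds single-model PDB files with exactly known
geometry: the halide at a fixed centre, coordinating atoms at the vertices
of one of nine ideal polyhedra (linear through tricapped trigonal
prismatic, CN 2–9) scaled to a chosen distance, optionally with seeded
isotropic Gaussian noise. Each coordinating atom is embedded in a minimal
dummy residue — the named atom plus a CA carbon placed radially outward —
which is enough for parsing, element rules and backbone/side-chain
classification without full residue geometry. Waters are placed at 4.2 Å in
seeded random directions with a 2 Å clash margin. Decoys place a sulfate, a
second-chain polymer atom, or a DNA nucleotide inside the sphere, each
designed to trigger exactly one rejection rule. Duplicate homologous copies
are exact translates (+40 Å per copy), so their merged RMSD is 0 by
construction.

`make_corpus()` draws per-structure parameters from the census's configured
conditions: species weighted 25 : 3229 : 206 : 246 (F : Cl : Br : I, the
curated dataset's composition), CN on 2–9 with probabilities
0.03/0.07/0.12/0.40/0.18/0.10/0.06/0.04 (mode 5, the observed preference;
CN 5 splits randomly between square-pyramidal and trigonal-bipyramidal),
per-site distances Normal(per-species pooled median — 4.09/4.11/4.17/4.28 Å
— , 0.35 Å) truncated to [3.0, 4.95] Å, and water counts peaked at the
per-species modes (I⁻ 2, Cl⁻/Br⁻ 3; F⁻ 4, chosen as the most strongly
solvated anion of the Hofmeister series, for which no mode is otherwise
established). About 10% of sites receive a second-chain contaminant
(matching the observed multichain fraction), 5% a ligand, 3% a nucleotide,
and 15% of clean structures carry a duplicated copy. A truth TSV records
every drawn value plus the expected filter outcome.

What the generator does *not* emulate: crystallographic symmetry operators,
realistic B-factors and occupancy disorder, full residue geometry and
side-chain rotamers, correlated positional error, mixed-species sites, or
electron-density ambiguity (the mis-assigned chloride/water cases real data
contain). Passing tests therefore demonstrate that the pipeline's rules and
arithmetic are correct on structures obeying the PDB format contract — they
do not certify curation behaviour on pathological real-world files beyond
the rules stated here.

## Verification strategy and problem sizes

The test suite checks extraction against an independent brute-force double
loop over all halide–atom pairs on 200 seeded fixture structures spanning
all species, CNs, water counts and decoys; ASA against the closed form and
a high-density Monte-Carlo oracle; superposition against rigid-transformed
copies, an analytic two-point case and an independent structural-biology
implementation (bio3d); and parameter recovery on a 200-structure corpus,
where at zero noise the pipeline must reproduce the generator's modal CN
exactly and its pooled median distance within 0.01 Å (the residual being
coordinate rounding at 10⁻³ Å). These corpus sizes keep the full suite
around a minute while exercising every rule; the same 200-structure setting
is what `scripts/acceptance.R` reruns end-to-end.

## Known limitations

* Secondary structure trusts the depositing author's HELIX/SHEET records;
  files without them label every residue `none`.
* The protein radius table is element-based, not atom-type-based (no
  ProtOr/NACCESS-style classifier); absolute ASA values shift slightly with
  the radius set, though the fractional measure is less sensitive.
* Name-based entry deduplication cannot detect homologues deposited under
  different molecule names; no sequence-based redundancy removal is
  attempted.
* Network fetching of structures is out of scope; the pipeline runs from
  local files and an entry-list TSV.
* Halogens covalently bound inside small-molecule ligands are a different
  chemistry and are deliberately not handled.
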