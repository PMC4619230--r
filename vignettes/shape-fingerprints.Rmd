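---
title: "Atom-pair 3D fingerprints and shape-space maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atom-pair 3D fingerprints and shape-space maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdbshape)
```

## The descriptor

`pdbshape` encodes the global 3D shape of a biomacromolecule — a
protein, peptide, nucleic acid, or multi-chain assembly read from a
PDB-format coordinate file — as a vector of 136 small integers. The
encoding rests on the through-space atom-pair principle: the set of all
pairwise distances between atoms, histogrammed softly over a fixed
distance scale, is a rigid-motion-invariant summary of shape that can
be compared across molecules spanning four orders of magnitude in size.

Heavy atoms are first classified into four categories:

* **all** — every non-hydrogen atom;
* **positive** — the lysine terminal ζ-amino nitrogen (NZ) and the
  arginine ζ-carbon (CZ), one marker atom per positively charged side
  chain;
* **negative** — the aspartate γ-carbon (CG), the glutamate δ-carbon
  (CD), and every phosphorus atom named `P` (nucleic-acid backbone and
  phosphate groups);
* **hydrophobic** — carbon atoms covalently bonded only to carbon or
  hydrogen.

For each category, every unordered pair of (sum) atoms at distance $d$
contributes a Gaussian
$w_a\,w_b\,\exp\!\big(-(b_i - d)^2 / (2\,(0.18\,d)^2)\big)$ evaluated at
34 sampling distances $b_i$ forming a geometric ladder from 1.45 Å to
342.53 Å with successive ratio ≈ 1.18 (`distance_ladder()`). The width
proportional to the distance itself makes the resolution scale-free:
bond-length separations and 300 Å capsid diameters are resolved
equally, in relative terms. The 34 raw sums of a category with $n$
atoms are divided by $n^{1.5}$ — pair counts grow quadratically with
size, so this exponent deliberately under-normalizes, leaving a mild,
intended size dependence — multiplied by 100, rounded to integers, and
finally scaled by the category weight (×2 hydrophobic, ×5 positive and
negative) so the sparser categories contribute comparably. Blocks are
concatenated as all (B1–B34), positive (B35–B68), negative (B69–B102),
hydrophobic (B103–B136).

### Sum-atom grid compression

Computing all atom pairs explicitly is quadratic in the heavy-atom
count and needless at the ladder's resolution. The default `"grid"`
mode places the molecule in its principal-axis bounding box, divides
the box into 12 × 12 × 12 cells, and represents each category within a
cell by one *sum atom* at the member centroid, weighted by the member
count (at most 1728 sum atoms, hence at most ~1.5 M pairs, per
category). The Gaussian amplitude of a pair is the product of the two
weights, so pair mass is conserved; the package's tests verify that
grid-mode and exact-mode fingerprints of the same structure differ by a
small fraction (median well under 5 %) of a typical inter-structure
distance. `"exact"` mode remains available as the reference
implementation for diagnostics. Grid mode is used for all database
work regardless of size, so distances are comparable across entries;
intra-cell pairs are not represented (pairs are taken over *distinct*
sum atoms only).

### Comparison and search

Fingerprints are compared by city-block distance
$\mathrm{CBD}(A, B) = \sum_{i=1}^{136} |A_i - B_i|$, a metric that sums
per-bit count differences. Because absolute CBD values carry no
intrinsic scale, a database is calibrated by sampling random entry
pairs and taking their median CBD, $X$; the similarity score
$S = X / (\mathrm{CBD} + X)$ then maps identity to 1 and a typical
random pair to 0.5. Nearest-neighbor search is a deterministic full
scan with ties broken by entry id.

### Similarity fingerprints and the map

Raw-bit PCA produces scattered, unevenly occupied maps, so mapping goes
through an intermediate *similarity fingerprint*: each entry's vector
of similarity scores against a fixed random panel of reference entries
(200 at database scale; `min(200, N/2)` for small collections so the
panel never exhausts the database). PCA of that matrix yields the
(PC1, PC2) plane; scores are binned onto a 300 × 300 grid using one
absolute bin width derived from the joint PC1/PC2 extremes, so the two
axes keep a common scale. Each occupied pixel carries the occupancy
count and the mean and population standard deviation (population, so a
single-entry pixel is well defined with sd 0) of the per-entry
properties: heavy-atom count, category fractions, and the molecular
volume occupancy $\mathrm{mvo} = \tfrac{4}{3}\pi d_\mathrm{avg}^3 / n$
(with $d_\mathrm{avg}$ the mean atom-to-centroid distance), a
compactness measure.

Scalar schemes are colored in HSL space: hue runs linearly from blue
(240°) through cyan, green, yellow and red to magenta (−60°) over the
pixel-average range, which is normalized between the 1st and 99th
percentile of pixel averages so a single outlier pixel cannot compress
the scale (a `"global"` min–max switch exists); saturation falls as
`1 − min(1, sd/sd_p99)`, fading heterogeneous pixels to grey;
lightness is fixed at 0.5. Shape pixels use the normalized principal
moments of inertia $(I_1/I_3, I_2/I_3)$ of the unit-mass inertia
tensor, which place every shape in the rod–disc–sphere triangle with
summits rod (0, 1), disc (0.5, 0.5) and sphere (1, 1); the R, G and B
channels encode closeness to the rod, sphere and disc summits
respectively, each normalized by the largest summit-pair distance.
Unit masses (rather than element masses) keep the descriptor purely
geometric, consistent with every other descriptor in the package.

## Input handling

`read_structure()` parses fixed-column PDB records via bio3d,
accepting `.pdb`, `.pdb1` biological-assembly files and gzipped
variants. Only the first MODEL of a multi-model file is used (one
fingerprint per entry), and only atoms with blank or `'A'`
alternate-location codes, so no site is double-counted.
`preprocess_structure()` removes hydrogens/deuteriums and water
residues (HOH/WAT/DOD), then discards HETATM atoms unless the residue
is *polymer-linked*: its (chain, residue number) falls inside the
residue-number span of the chain's ATOM records, or it appears in a
MODRES record. This keeps covalently modified residues such as
phosphoserines — whose phosphorus then also enters the negative
category via the `P` rule — while dropping free ligands, without
requiring SEQRES bookkeeping. Database admission applies a separate
filter before any HETATM discarding: entries whose HETATM atoms exceed
20 % of the heavy-atom count (strictly greater; exactly 20 % passes)
are skipped.

Hydrophobic carbons are resolved from a per-residue lookup table
covering the 20 standard amino acids and the A/C/G/U and DA/DC/DG/DT
nucleotides, derived once from ideal residue topologies (wwPDB
chemical-component reference geometries). Deposited files carry
neither bonds nor hydrogens, so residues outside the table fall back
to geometric inference: heavy atoms closer than 1.9 Å are taken as
bonded, and a carbon qualifies when all such neighbors are carbons.
The two routes agree exactly on ideal-geometry fixtures of all 20
residues (a standing test).

## Numerical choices

* **Ladder constants.** The 34 sampling distances are stored verbatim;
  a strict ×1.18 recursion from 1.45 Å drifts visibly by the 34th
  value, so the canonical printed ladder, not the recursion, is the
  ground truth.
* **Rounding.** Bit quantization rounds half-up before category
  weighting; a `"half-even"` switch exists in `fp_config()` because
  the convention is observable in single low bits. Weighting after
  rounding makes charged blocks ≡ 0 (mod 5) and the hydrophobic block
  ≡ 0 (mod 2), an invariant the tests assert.
* **Gaussian cutoff.** Contributions beyond 5 widths from a sampling
  point are below integer-rounding resolution and are skipped for
  speed; `fp_config(gaussian_cutoff = Inf)` disables the cutoff, and a
  test bounds the difference below rounding resolution.
* **Frame determinism.** Principal axes take the sign making their
  largest-magnitude component positive; a point-like structure (zero
  covariance) gets identity axes. PCA components follow the same sign
  convention, so maps are reproducible run to run. Exactly degenerate
  covariance eigenvalues (deliberately symmetric point groups) can
  still permute axes under rotation; the grid partition then shifts,
  which is why rigid-motion invariance is exact in exact mode and
  tested on generic fixtures in grid mode.
* **Grid edges.** Bin index is `floor((v - min)/w)` with the maximum
  clamped into the last bin; a zero-extent axis collapses to one bin.
  The map binning uses the same convention.
* **Degenerate inputs.** Fingerprinting requires ≥ 2 heavy atoms;
  categories with fewer than 2 members yield all-zero blocks (a
  structure without charged residues has identically zero charged
  blocks). A collinear structure has nPMI (0, 1); a single point is
  defined as (1, 1); mvo of a single atom is 0.
* **Calibration sampling.** Random pairs are drawn uniformly with
  replacement across pairs (repeats allowed, self-pairs redrawn), so
  the "1 M random pairs" recipe is meaningful at any database size;
  the default shrinks to `min(10^6, 20 N^2)`.

## The synthetic-structure generator

Grading-free testing needs inputs with known answers, so the generator
is first-class, tested code. It emulates, in order of abstraction:

* **Tagged point clouds** (`make_point_cloud()`) — arbitrary
  coordinates whose residue/atom names are chosen so category
  assignment reproduces requested tags exactly (e.g. positive → LYS
  NZ). These carry the analytically known fixtures: the two-atom
  worked example, the 12³ lattice that saturates the grid, rods and
  squares and octahedra with closed-form inertia moments.
* **Polymers** (`make_helix()`, `make_coil()`) — peptides built from
  ideal backbone internal coordinates (N–CA 1.458 Å, CA–C 1.525 Å,
  C–N 1.329 Å, trans ω), with ideal-geometry heavy-atom side chains
  attached rigidly per residue. The helix uses φ = −57°, ψ = −47°;
  the coil draws φ ∈ [−150°, −60°], ψ ∈ [−60°, 160°] per residue and
  redraws (with whole-chain restarts) until no non-bonded heavy-atom
  pair is closer than 2.0 Å. Consecutive CA–CA distances come out at
  3.80 Å.
* **Assemblies** (`assemble_multimer()`) — rigid copies on distinct
  chains, emulating deposited biological-assembly dimers and higher
  multimers.

What the generator does *not* emulate: real secondary-structure
packing, realistic B-factors/occupancies, crystallographic artifacts,
or residue-composition statistics of the full database. Passing tests
therefore demonstrate the descriptor's mathematical properties
(invariance, compression fidelity, metric behavior, retrieval of
geometrically coherent families) on protein-like inputs — not
retrieval quality on the deposited corpus, which requires the real
database.

## Problem sizes in the test-suite

The statistical suites run at sizes chosen to make their assertions
sharp yet quick on a laptop: rigid-motion invariance over 100 random
transforms of each of 20 fixtures (exact equality); grid-vs-exact
fidelity over 100 random globules of 100–2000 atoms (median deviation
under 5 % of the median inter-fixture distance); metric axioms on 1000
random vector triples; retrieval of a 10-member jittered conformer
family from 60 decoy coils (ROC AUC > 90 %); uniqueness across 500
distinct random fixtures (≥ 99 % unique fingerprints). Published
city-block distances for deposited entry pairs are asserted when the
corresponding RCSB files are present under
`inst/extdata/real_pdb/` (they are not redistributable at package
scale); conventions the original calculation left open — rounding
mode, bin boundaries — are exposed as `fp_config()` switches for that
comparison.

## Known limitations

* No mmCIF parsing and no symmetry expansion from assembly REMARK
  records: biological assemblies are consumed pre-expanded (`.pdb1`).
* Occupancies are ignored beyond altloc filtering.
* The hydrophobic rule sees only the residue-internal bond graph of
  standard residues; exotic covalent chemistry (e.g. heme thioether
  links) is handled by the geometric fallback, not curated.
* Grid-mode fingerprints of exactly symmetric point groups can depend
  on axis ordering (degenerate principal frames); generic structures
  are unaffected.
* Absolute similarity scores depend on the database through the
  calibration median $X$; only CBDs are comparable across databases.
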