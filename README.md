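# pdbshape

Global 3D-shape descriptors and shape-space maps for biomacromolecular
structures — proteins, peptides, nucleic acids, and multi-chain
assemblies in PDB-format coordinate files. The package is aimed at
structural bioinformaticians who want fast, alignment-free shape
comparison across an entire structure collection: nearest-neighbor
searches that treat a 20-residue toxin and a virus capsid on the same
footing, and 2D maps that lay out a whole database by shape.

## The descriptor

Each entry is encoded as a 136-dimensional **atom-pair 3D
fingerprint**. Heavy atoms are classified into four categories — all
atoms; positively charged markers (Lys NZ, Arg CZ); negatively charged
markers (Asp CG, Glu CD, phosphorus); hydrophobic carbons (bonded only
to C/H). For a category with *n* atoms, every unordered atom pair at
distance *d* contributes a Gaussian

    w_a · w_b · exp( −(b_i − d)² / (2·(0.18·d)²) )

sampled at 34 distances *b_i* on a geometric ladder 1.45 … 342.53 Å
(ratio ≈ 1.18). The 34 sums are divided by *n*^1.5, expressed in
percent, rounded to integers, and weighted ×2 (hydrophobic) or ×5
(charged); the four 34-bit blocks concatenate to the fingerprint. For
large entries the pair sum runs over *sum atoms*: the molecule is
fitted into a 12×12×12 grid along its principal axes and each occupied
cell contributes one weighted pseudo-atom per category (≤ 1728 sum
atoms), which reproduces exact all-pair fingerprints to within a few
bits at a fraction of the cost.

Fingerprints are compared by city-block distance
CBD(A,B) = Σ |A_i − B_i|, calibrated into a similarity score
S = X/(CBD + X) with X the median CBD of random entry pairs. A
database maps to 2D by PCA of 200-reference similarity fingerprints,
binned onto a 300×300 grid whose pixels are color-coded by occupancy,
heavy-atom count, charge/hydrophobic fractions, compactness
(molecular volume occupancy), or position in the rod–disc–sphere
triangle of normalized principal moments of inertia.

A synthetic-structure generator (ideal helices, self-avoiding coils,
tagged point clouds, multimer assembly) makes the whole pipeline
testable without any downloads.

## Worked example

```r
library(pdbshape)

dir <- file.path(tempdir(), "demo")
simulate_fixtures(dir, seed = 1)        # writes 5 synthetic PDB files
db  <- fingerprint_database(dir)        # parse, filter, fingerprint
db[, 1:8]
#> # A tibble: 5 × 8
#>   entry_id    hac    B1    B2    B3    B4    B5    B6
#>   <chr>     <int> <int> <int> <int> <int> <int> <int>
#> 1 coil1       109     9    10    14    21    26    33
#> 2 coil2       100    10    12    15    21    29    39
#> 3 dimer       186     6     8    11    17    24    35
#> 4 helix_ala    60    13    13    19    34    49    64
#> 5 helix24     195     7     8    11    18    27    39

cal <- calibrate_similarity(db, seed = 1)
nearest_neighbors(db, "helix24", k = 3, calibration = cal)
#> # A tibble: 3 × 4
#>    rank entry_id   cbd  s3dp
#>   <int> <chr>    <dbl> <dbl>
#> 1     1 helix24      0 1
#> 2     2 coil1     2577 0.519
#> 3     3 coil2     2777 0.5
```

The query returns itself at CBD 0 (score 1); the two coils are about
one calibration median away (scores near 0.5), i.e. typical random
neighbors — on five deliberately dissimilar fixtures nothing is
genuinely close. Per-entry shape descriptors behave as the geometry
suggests: the 24-residue helix is elongated and loosely packed,

```r
h <- assign_categories(preprocess_structure(
  read_structure(file.path(dir, "helix24.pdb"))))
category_counts(h)
#> # A tibble: 4 × 2
#>   category        n
#>   <chr>       <int>
#> 1 all           195
#> 2 positive        4
#> 3 negative        1
#> 4 hydrophobic    57
round(mvo(h), 2); round(npmi(h), 3)
#> [1] 22.8
#> npmi1 npmi2
#> 0.105 0.994
```

nPMI ≈ (0.1, 1) is nearly the rod summit (0, 1), as expected for a
single straight helix; the 4 positive markers are its 2 Lys + 2 Arg.

The same operations are scriptable from a shell via the installed
`pdbshape` command (`fingerprint`, `search`, `map`, `locate`,
`simulate` subcommands), each writing a JSON config snapshot next to
its outputs.

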