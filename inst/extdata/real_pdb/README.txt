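Place RCSB coordinate files here (entry id + .pdb or .pdb1, optionally
gzipped) to enable the published city-block-distance comparison in the
test suite:

  3QZH 3ROY 3QRT 2C5Y 3QQH 4EZ7   (kinase T-loop conformer monomers)
  1YPI 8TIM 4GNJ                  (triose-phosphate isomerase assembly
                                   dimers; use the .pdb1 assembly files)

No deposited coordinates are redistributed with the package.
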