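# scopekit

Computational toolkit for microwell single-cell RNA-seq with **optically
decodable mRNA capture beads** — experiments in which each cell is imaged
live in a picoliter microwell, captured on a barcoded bead, and the bead's
cell barcode is then read out *in the device* by eight cycles of two-color
fluorescent probe hybridization, so that every sequenced expression profile
can be traced back to its cell's image.

scopekit implements the full computational pipeline:

- **Barcode design** — two 96-member pools of 8-nt barcodes (roles S and Q;
  96 × 96 = 9,216 cell barcodes per device region) screened for pairwise
  Levenshtein distance ≥ 3, homopolymer runs ≤ 2 nt, 40–60% GC and low
  self-complementarity (scored on full-length 86-nt capture oligos with A-T
  pairs weighted 2/3 and C-G pairs 1), plus injective 8-bit binary code
  tables and the per-cycle Cy5/Cy3 probe pools.
- **Optical decoding** — the population-level *cycle-by-cycle* algorithm
  (log-intensity histogram, valley threshold between the two modes) and the
  per-bead *bead-by-bead* algorithm: sort the eight intensities, split at
  the largest relative fold change `f_n = (y_{n+1} − y_n)/y_n`, and retry at
  the next largest gap until the induced 8-bit code maps to a barcode.
- **Image analysis** — microwell grid detection, occupancy calling,
  the sixteen per-cell morphology/intensity features (area, intensity
  statistics, perimeter, axes, circularity = 4πA/P², Feret diameters,
  roundness = 4A/(π·major²), solidity), bead tracking across cycles and
  two-color multiplet identification.
- **Read processing** — read-1 parsing (`NN(S)NN(Q)NNNN`), single-substitution
  barcode correction against the whitelists, poly(A) trimming (tracts of
  > 7 A's), Hamming-1 UMI collapse and sparse molecule-count matrices.
- **Linking** — anchor-based similarity registration, nearest-bead cell
  pairing, exact-and-unique barcode-to-profile joins, class-balanced linking
  accuracy and multiplet sensitivity/specificity.
- **Downstream** — bimodal Gaussian-mixture thresholds, the dead-cell
  filter, factor-model imputation `log2(θβᵀ/10000 + 1)`, the Chr7−Chr10
  malignancy score with double-Gaussian thresholding, imaging meta-features
  (k = 3 feature clusters → k = 2 cell clusters) and subsampled
  Mann–Whitney/Benjamini–Hochberg differential expression.
- **Simulator** — seeded generators for every input (bead intensities with
  channel-asymmetric autofluorescence, device images, barcoded reads,
  gamma-Poisson expression with Chr7-gain/Chr10-loss aneuploidy), each with
  ground truth.

See the methods vignette (`vignettes/scopekit-methods.Rmd`) for the models,
parameter choices and limitations.

## Worked example

```r
library(scopekit)

design <- design_barcode_sets(n_per_role = 96, seed = 1)
design
#> barcode_design: 96 S + 96 Q barcodes; 384 scored candidates
head(design$s_set$sequences, 3)
#> [1] "AACAACCG" "AATCGTGG" "ACACCAAG"
design$s_set$code_map[design$s_set$sequences[1]]
#>   AACAACCG
#> "11111001"

sim   <- simulate_bead_intensities(2000, design$s_set$code_map,
                                   design$q_set$code_map, seed = 0)
bead  <- decode_bead_by_bead(sim$table,  design$s_set$code_map, design$q_set$code_map)
cycle <- decode_cycle_by_cycle(sim$table, design$s_set$code_map, design$q_set$code_map)
acc <- function(r) mean(!is.na(r$s_barcode) & r$s_barcode == sim$truth$s_barcode &
                        !is.na(r$q_barcode) & r$q_barcode == sim$truth$q_barcode)
sprintf("bead-by-bead: %.1f%%  cycle-by-cycle: %.1f%%", 100*acc(bead), 100*acc(cycle))
#> [1] "bead-by-bead: 99.9%  cycle-by-cycle: 88.4%"

out <- classify_outcomes(bead, paste0(sim$truth$s_barcode, sim$truth$q_barcode))
round(out$fractions, 4)
#> outcome1 outcome2   linked
#>   0.0000   0.0015   0.9985
```

The simulation puts a per-bead autofluorescence offset on the Cy3 channel
(the shorter-wavelength channel, where beads autofluoresce), which degrades
any shared global threshold: the per-bead fold-change decoder keeps ~99.9%
of beads while the population method drops to ~88%. `classify_outcomes`
tallies the decoding-error taxonomy — unmappable codes (outcome 1), mappable
codes absent from sequencing (outcome 2), and the linked remainder.

A thin command-line front end over the same functions lives at
`inst/cli/scopekit.R`:

```sh
Rscript inst/cli/scopekit.R design --n-per-role 96 --seed 1 --out design_out
Rscript inst/cli/scopekit.R decode --method bead --codes design_out/code_table.csv \
        --in beads.csv --out decoded.csv
```

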