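---
title: "Methods behind scopekit: optically decodable barcodes and image-linked scRNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind scopekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scopekit)
```

# The problem

Microwell single-cell RNA-seq captures each cell together with a barcoded
mRNA capture bead, but the pairing between a cell's microscope image and its
sequenced expression profile is lost unless the bead barcode can be read
*optically*, in the device, before sequencing. scopekit implements the
computational side of such an experiment: designing cell barcodes that can be
read out by cycles of two-color fluorescent probe hybridization, calling each
bead's binary code from the cycle images, extracting per-cell imaging
features, processing the barcoded reads into a molecule count matrix, joining
the two modalities, and the downstream calling procedures used on the linked
data. A simulator generates every input with ground truth, so the entire
pipeline is testable at desk scale without any external data.

# Barcode design

Each bead oligo carries two 8-nt barcodes (roles S and Q), drawn from two
96-member pools, giving 96 x 96 = 9,216 distinct cell barcodes per device
region (ten indexed regions raise the cell-indexing capacity to 92,160). The
8-nt UMI is dispersed as NN / NN / NNNN spacers between the barcode slots;
with the 32-nt PCR anchor and a 30-nt oligo(dT) tail the full oligo is 86 nt.

Candidates are screened by four rules: pairwise Levenshtein distance of at
least 3 (which for equal-length sequences also lower-bounds the Hamming
distance at 3, so any single substitution is uniquely correctable);
homopolymer runs of at most 2 nt; GC content between 40% and 60% (over 8 nt
this forces exactly 4 G/C bases); and no sequence equal to its own reverse
complement. Generation enumerates the full filtered 8-mer pool (14,600
sequences), permutes it with the user's seed, and greedily keeps sequences
that clear the distance screen — equivalent to seeded rejection sampling
without replacement, with the advantage that infeasibility is detected
exactly when the pool is exhausted. The greedy screen typically accepts
~440 sequences before exhaustion, comfortably above the 384 candidates the
default design needs.

Self-complementarity is scored on *full-length* oligos: for a candidate in
either barcode slot, combined with every partner in the other slot, the oligo
is aligned antiparallel against itself at every offset and the best
contiguous run of Watson-Crick pairs is found; each A-T pair contributes 2/3
and each C-G pair 1 to the run score, reflecting their relative binding
affinity, and the unknown UMI positions (N) pair with anything at the weaker
2/3 weight (a conservative worst case). The candidate's score is the maximum
over all such oligos, and the lowest-scoring half of the candidates is
retained, with ties at the cutoff broken lexicographically so the procedure
is deterministic. The retained sequences are split alternately by score rank
into the S and Q roles.

Each role's 96 sequences then receive distinct 8-bit binary codes drawn
(seeded) from the 254 usable codes: 00000000 is excluded because it is
indistinguishable from total hybridization failure, and 11111111 because it
is indistinguishable from a stuck-bright artifact — and neither is reachable
by the bead-by-bead decoder, which always splits the eight values into a
non-empty low and high group. For decoding cycle k (A..H), the probe pool
contains the reverse complements of all barcodes whose code bit k is 1 — Cy5
label for S probes, Cy3 for Q — 192 distinct probe oligos in total, and a
barcode's code is exactly its complement's pattern of pool memberships.

# Optical decoding

Eight hybridization cycles imaged in two channels give each bead an 8 x 2
intensity matrix. Two algorithms call the 16-bit code:

**Cycle-by-cycle** (population method): per cycle and channel, all bead
intensities are log-transformed and histogrammed into 50 bins; with M the
median, B1 and B2 are the most-populated bins at or below and above the
median's bin, and the threshold is the center of the least-populated bin
strictly between B1 and B2 — a valley-seeking rule. Bits are 1 above the
threshold. Numerical choices: natural log with inputs validated positive;
when several valley bins tie (typically all empty), the middle tied bin keeps
the threshold centrally placed; when no bin lies between B1 and B2 the
midpoint of their centers is used; when the median falls in the topmost
populated bin the split moves one bin down. There is no retry for unmappable
codes: the method is a shared global threshold and has no per-bead recourse.

**Bead-by-bead**: per bead and channel, the eight intensities are sorted
ascending (y1..y8), relative fold changes f_n = (y_{n+1} - y_n)/y_n are
computed for the seven neighbor pairs, and the largest fold change splits the
values into 0s below and 1s above. If the induced code is not in the code
table, the next-largest fold change is tried, until a code maps or the list
is exhausted (then the bead is unmappable). Values are floored at 1 a.u.
before the division; argmax ties resolve to the smallest split index. The
two channels are decoded independently and a bead is "decoded" only when
both map.

The bead-by-bead rule is scale-free and, more importantly, insensitive to a
per-bead additive baseline shared by a channel's eight cycles — exactly the
structure of bead autofluorescence, which is strong at the shorter (Cy3)
emission wavelengths. The simulator emulates this with a half-normal per-bead
offset added to all Cy3 cycles. For the offset to matter at all, its scale
must be comparable to the hybridization signal, not to the dim state: with a
20x on/off ratio and lognormal CV 0.3, an offset at the off-state scale
(~100 a.u.) leaves the channel fully separable and both decoders perfect, so
the default offset sd is 500 a.u. — a quarter of the on-state mean — which
makes the Cy3 populations genuinely overlap. Under that regime bead-by-bead
decodes ~99.9% of beads correctly while cycle-by-cycle reaches only ~83-93%,
reproducing the direction (not the magnitude) of the reported linking
improvement of the per-bead strategy.

Decoding errors have three outcomes: (1) an unmappable code; (2) a mappable
code whose barcode has no sequenced profile; (3) a mappable code matching
the *wrong* profile. Only the third causes a linking error; because just
9,216 of the 65,536 16-bit codes are used, and fewer than ~1,000 barcodes are
sequenced per region, most errors fall in outcomes 1-2, which cost yield but
not accuracy.

# Image analysis

Microwells are dark disks in bright-field: the inverted, range-normalized
image is locally mean-thresholded (invariant to global intensity offsets),
filled, labeled with 8-connectivity, and size-gated; well centers and the
median well radius define the grid. Occupancy is called on per-well mean
fluorescence with the bimodal threshold described below, gated by two
bimodality checks (Ashman's D >= 2 and an empty valley bin); if the
distribution looks unimodal, every well is called unoccupied with a warning.

Each occupied well is analyzed in its smallest bounding square: Otsu's
threshold, 8-connected components, minimum particle area 20 px^2. Wells with
no particle or more than one are excluded (the multiplet rule). For the
single particle, sixteen features are measured: area; mean, sd, min, max and
median intensity; perimeter (chain-code length along the traced contour,
diagonal steps sqrt(2)); bounding-box width and height; major and minor axes
of the moment-equivalent ellipse (4 sqrt of the population-covariance
eigenvalues); circularity 4*pi*area/perimeter^2 clamped to [0, 1]; Feret's
and minimum Feret's diameters (convex-hull calipers, measured between pixel
centers); roundness 4*area/(pi*major^2); and solidity area/hull-area clamped
to 1. Coordinates are 0-based pixels, x rightward, y downward. On analytic
shapes these match closed forms within rasterization error (the chain-code
perimeter overestimates a circle's by ~5%, which is why a digital disk's
circularity lands near 0.92 before clamping).

Beads detected in cycles B..H are matched to the nearest cycle-A bead within
a radius; unmatched detections are dropped, and a cycle-A bead missing in
some cycle has its intensity re-measured at the cycle-A position (flagged).
Two-color multiplet identification counts per-well green and magenta
particles: at least one of each is a mixed-species multiplet, two of one
color a single-species multiplet, exactly one particle a singlet.

# Read processing

Read 1 follows NN(S)NN(Q)NNNN: positions 3-10 and 13-20 are the barcodes and
positions 1-2, 11-12, 21-24 concatenate to the UMI; shorter reads are
dropped. Barcodes are corrected to an exact whitelist match or the unique
Hamming-1 neighbor (uniqueness guaranteed by the minimum pairwise Hamming
distance of 3); reads are kept only when both barcodes resolve. Read-2
poly(A) tails — tracts of more than 7 A's — are trimmed from the first tract
onward and fragments under 24 nt are discarded. Alignment is out of scope:
gene assignments arrive as a (read_id, gene, species, chromosome) table whose
producer guarantees unique exonic, stranded mapping. Reads sharing (cell
barcode, gene) collapse into molecules by connected components of the
Hamming-1 graph over their UMIs — the simplest clustering consistent with
"one substitution error correction"; exact-match collapse would only split
components. Counts go into a sparse genes x cells matrix (MatrixMarket on
disk), with optional per-region barcode suffixes for the ten-region device
layout. Species are called per cell when a species claims strictly more than
90% of reads; otherwise the cell is mixed.

# Linking

Decoding-round coordinates map onto live-imaging coordinates by a similarity
transform (translation + isotropic scale + rotation) fit exactly through two
anchor wells (upper-left and bottom-right). Two point pairs cannot determine
an affine map, so similarity is the minimal model the anchors support. Cells
pair with the nearest mapped bead within one microwell radius; a bead claims
at most one cell (closest wins, ties broken by cell id). A cell links to an
expression profile only when its bead decodes to a barcode occurring exactly
once among sequenced profiles; beads sharing a decoded barcode are excluded
as ambiguous. The link table is therefore a partial injection: no bead or
profile appears twice.

Linking accuracy in a two-species (barnyard) experiment is summarized as
class-balanced accuracy — the unweighted mean of per-class agreement rates
between imaging-based and sequencing-based species calls — and imaging-based
multiplet detection is summarized by sensitivity and specificity against the
sequencing-based mixed-species reference.

# Downstream procedures

**Bimodal threshold.** A two-component Gaussian mixture is fit by EM
(deterministic quantile initialization at the 25th/75th percentiles, common
starting sd, at most 500 iterations, log-likelihood tolerance 1e-6); the
threshold is the center of the least-populated histogram bin (50 bins, the
same granularity as the decoding histograms) strictly between the two
component means, ties resolving to the middle tied bin. Component means
closer than one bin width are rejected as degenerate. On well-separated
mixtures this lands within a bin of the misclassification-optimal cut.

**Dead-cell filter.** A single Gaussian is fit to live-stain intensities and
cells below its 5th percentile (mu - 1.645 sigma) are removed.

**Imputation and malignancy.** Given nonnegative factor matrices theta
(cells x K) and beta (genes x K) from a hierarchical Poisson factorization,
the imputed expression is log2(theta beta^T / 10000 + 1). The malignancy
score is the mean imputed expression over Chr7 genes minus the mean over
Chr10 genes — Chr7 gain with Chr10 loss being the canonical glioblastoma
aneuploidy — and the bimodal threshold on the scores separates malignant
from non-malignant cells.

**Imaging meta-features.** The 16 features are z-scored and hierarchically
clustered (average linkage, correlation distance); cutting at k = 3 yields
feature clusters that on real data correspond to cell size, shape and
staining intensity, and each cell's meta-feature is the mean of its member
z-scores. Cells are then clustered on the three meta-features (same linkage
and distance) and cut at k = 2. Constant features are dropped with a
warning.

**Differential expression.** For two cell groups: the larger group is
subsampled to the smaller's size; the deeper group's molecules are binomially
thinned per cell so mean molecules/cell match (the mechanism behind "random
subsampling" chosen here, since thinning preserves the count distribution's
shape); counts are normalized by per-cell size factors to the common mean —
a pluggable default standing in for pooling-based normalization, and
externally computed size factors are accepted; each gene gets a two-sided
Mann-Whitney U test (normal approximation with tie correction) and p values
are Benjamini-Hochberg adjusted. Genes all-zero in both groups report NA.

# The simulator and what it does (not) cover

The generator emits every pipeline input with ground truth. Bead intensities
are lognormal around 2,000 (on) and 100 (off) a.u. with CV 0.3, plus the
Cy3 autofluorescence offset discussed above; bead positions sit on a 30-px
pitch grid. Device images are dark wells (radius 10 px) on a bright field
with cell disks in two fluorescence channels, Poisson cell loading, and
additive pixel noise. Reads carry per-base substitution errors (default
0.5%) and optional poly(A) suffixes; within one (cell, gene) group UMIs are
redrawn to pairwise Hamming distance >= 2, so every emitted molecule is
identifiable and error-free processing recovers the true counts exactly
(UMI-collision losses, ~4e-4 per molecule pair with 8-nt UMIs, are
deliberately excluded from the default regime; the realized UMIs are
emitted for anyone wanting to study them). Expression is gamma-Poisson from
a K = 5 factor model with a per-cell depth factor (gamma shapes 4/4/16,
~20 expected counts per gene), 1,100 genes spread round-robin over 22
autosomes, 1,000 cells of which 40% are malignant with Chr7 x 1.5 and
Chr10 x 0.5; the emitted factor model is augmented to 3K factors so its
product equals the expected counts *including* the aneuploidy scaling,
making imputation from it exact.

What passing tests on these simulations does **not** show: real bead
intensity distributions are not exactly lognormal and probe efficiency
varies by sequence; real cells are not disks and real images need
illumination correction and stitching (out of scope); real UMI families
suffer collisions and amplification-dependent error structure; and real
expression has correlated biology far richer than a 5-factor gamma model.
The simulations establish correctness of the algorithms under their stated
models, not performance on any particular instrument.

# Problem sizes and determinism

Default verification sizes were chosen so the whole suite runs comfortably
on a laptop core: 384 scored candidates (147,456 oligo alignments, ~7 s with
the compiled kernel), 2,000 beads per decoding replicate across ten seeds,
10,000 beads for the decoder/oracle equivalence check, 1,000 x 1,100
expression simulations across five seeds, and twenty 200-gene null
replicates for the false-positive-rate check. Every stochastic step takes an
explicit integer seed and restores the caller's RNG state, so identical
seeds give byte-identical outputs.

# Known limitations

Only substitution errors are corrected in barcodes and UMIs (no indels);
the cycle-by-cycle method has no per-bead fallback by construction;
error-correcting code assignments (codes chosen to maximize pairwise code
distance) are not implemented; Feret diameters measured between pixel
centers run ~1 px below outline-polygon conventions; and the registration
model is similarity-only — non-rigid device distortion is out of scope.
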