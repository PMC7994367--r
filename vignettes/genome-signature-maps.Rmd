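---
title: "Genome-signature maps and CpG-suppression landscapes with oligosom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-signature maps and CpG-suppression landscapes with oligosom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The method

Large genomes carry a *genome signature*: the frequency profile of short
oligonucleotides is approximately constant across megabase-scale fragments
of one genome and characteristically different between species. `oligosom`
turns that observation into a comparative-genomics pipeline:

1. **Windows.** Assemblies are cut into fixed-length windows (default
   1 Mb) sliding with a step (default 100 kb). Fixed length matters:
   composition vectors are only comparable across equal amounts of
   sequence, so trailing partial windows are discarded and windows never
   cross scaffold boundaries (scaffold order and orientation are
   arbitrary in an assembly).
2. **Degenerate composition.** Each window is summarised by the
   frequencies of *degenerate* k-mer groups: a k-mer is pooled with its
   reverse complement (`AG+CT`), self-complementary k-mers (`CG`, `AT`,
   ...) stand alone. Because sequencing registers an arbitrary strand,
   this makes the vectors exactly strand-invariant; there are 2, 10, 32
   and 136 groups for k = 1..4. k-mers containing `N` are skipped, and
   windows with more than `max_n_fraction` (default 0.1) of `N` are
   excluded up front.
3. **Batch-learning SOM.** Windows are clustered on a rectangular
   lattice of weight vectors. Weights are initialised on the plane of
   the first two principal axes of the composition cloud,

   $$w_{ij} = \bar{x} + \frac{5\sigma_1}{I}\left[b_1\left(i - \tfrac{I}{2}\right) + b_2\left(j - \tfrac{J}{2}\right)\right],$$

   spanning five standard deviations of PC1. Each batch epoch assigns
   every vector to its nearest node (Euclidean distance) and replaces
   each node weight by the mean of all vectors assigned within its
   square (Chebyshev) lattice neighbourhood; the radius shrinks linearly
   from `max(I, J)/2` to 1. Batch updates make the result independent of
   input order; PCA initialisation removes the remaining randomness.
4. **Map products.** The trained map is read out as species
   *territories* (nodes pure for one species, or majority > 50%, or
   mixed "black"), rank-based per-oligonucleotide contribution heat maps
   (top/middle/bottom tertiles of the node weights), *satellite
   territories* (small connected components of a species' nodes
   disconnected from its main territory), and *shared nodes* (nodes
   holding windows of two chosen sets — a single foreign window marks a
   node, which is what makes cross-species compositional overlap
   visible).
5. **CpG suppression.** Two indexes quantify the depletion of the CG
   dinucleotide: the odds ratio `f(CG) / (f(C) f(G))` (observed over
   expected under base-composition independence) and the `CG/GC` count
   ratio, which is 1 when dinucleotide occurrence merely reflects base
   composition. Both are invariant under reverse complement. Sliding
   window profiles of any degenerate group along a chromosome are
   summarised by an ordinary least-squares quadratic trend and peak
   calls on the residuals.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `window`, `step` | 1 Mb, 100 kb | bases | megabase windows average over local repeats and give smooth chromosome landscapes; the 10:1 overlap traces continuity along a chromosome |
| `max_n_fraction` | 0.1 | fraction | assemblies carry gap runs; a window mostly made of `N` has a meaningless composition |
| `k` | 2-4 | — | signatures sharpen with k; dimensionality grows as ~4^k/2, so 1-Mb windows support k ≤ 4 comfortably |
| `avg_per_node` | 10 | windows/node | node budget = n/avg; ~10 members per node resolves fine structure on large collections |
| majority threshold | > 0.5 | fraction | a node is coloured for a species only on strict majority |
| tertile bounds | ceil(n/3), ceil(2n/3) | ranks | heat-map classes over non-empty nodes; ties inherit the class of the first tied node in a stable (value desc, i, j) sort |
| `min_size`, `max_fraction_of_main` | 3, 0.25 | nodes | a satellite must be big enough to be real and small relative to the main territory |
| `min_prominence` | 2 × residual SD | group % | peaks must clear the noise about the quadratic baseline |
| `terminal_fraction` | 0.05 | fraction of chromosome | separates chromosome-end peaks from internal ones |

## What the synthetic generator emulates

`species_model()` defines a species as a first-order Markov chain: a base
composition `pi`, a CG-suppression target `s` (the `C -> G` transition is
pinned to `s * pi_G`, so `s` is a target CG odds ratio; the exact
prediction from the stationary distribution is stored in the model), and
an optional strand-symmetric dinucleotide `bias` so that species can
differ in which complementary pairs they favour at equal G+C% — real
species do, and mononucleotide composition alone would make signature
separation a trivial G+C% split.

`chromosome_plan()` adds two chromosome-scale structures:

* a **parabolic composition gradient**: the per-position transition
  matrix mixes a center and an edge model with weight
  `w(x) = (2x/L - 1)^2`, reproducing the rise of CG toward both
  chromosome ends. The `gradient_variant()` helper derives the edge
  model (default G+C +3 percentage points, `s` +0.15). Gradients also
  give each genome realistic within-species heterogeneity; a flat chain
  makes every 1-Mb window identical to within ~1e-4, which no real
  chromosome does, and a map of such windows degenerates to one node
  per species.
* **repeat blocks**: `n_copies` of a repeat unit (default
  `synthetic_repeat_unit()`: 520 bp, ~60% G+C, CG enriched ~2x over
  independence) in tandem with short background spacers — kb-scale
  repeats forming Mb-scale CG-rich blocks.

Truth segments accompany every record, and `label_windows()` projects
them onto windows.

What the generator does **not** emulate: repeat-family evolution
(copies are exact), indels and assembly errors, higher-than-first-order
signatures, and isochore structure beyond the single parabolic gradient.
Passing tests therefore show the pipeline recovers planted structure of
these kinds; they do not certify behaviour on biological complications
the generator omits.

## Study-scale choices in the experiments

The packaged experiments (test suite and `scripts/acceptance.R`) run at
desk scale: 3 species × 30 Mb for separation, 10 Mb genomes for
suppression recovery, 20 Mb chromosomes for landscapes, ~40-65 Mb
two-species collections for satellite and shared-node recovery. These
sizes keep a full run in minutes while leaving every window with ≥ 1e6
dinucleotides, so sampling noise is far below every effect studied.

The species-separation experiment uses `avg_per_node = 30` instead of
the default 10. This is deliberate: node purity under label
exchangeability is inflated above `1/n_species` by roughly
`sqrt(1/m)` for m members per node (the expected maximum of a
multinomial); at m = 10 a three-species chance-level map still scores
~0.45, which would mask the distinction between genuine separation and
exchangeable labels. At m = 30 the chance level sits near 0.40 while
true separation scores ~1, so the purity statistic is informative in
both directions.

## Numerical choices

* **Bit-exact order independence.** Batch summation order is fixed by
  sorting input rows lexicographically over all composition columns
  before training; permuting the input then reproduces the trained grid
  bit for bit, not merely to tolerance.
* **Deterministic PCA.** Eigenvector signs are fixed by forcing each
  eigenvector's largest-magnitude component positive, so maps reproduce
  across linear-algebra backends.
* **Ties.** Best-matching-node ties break to the smallest `(i, j)`;
  heat-map tie blocks take the class of their first member in the
  stable sort.
* **Empty neighbourhoods** keep their previous weights (no
  interpolation).
* **Degenerate fits.** Fewer than three distinct profile midpoints fall
  back to an exact line (`a = 0`); the default peak threshold is floored
  at `1e-8` of the mean profile value so an exactly-fitting profile
  yields no peaks from float noise.
* **Pooling before division.** Genome-wide Obs/Exp is computed on
  pooled counts over windows/records, never as a mean of per-window
  ratios; dinucleotides are never counted across record boundaries.

## Open design points, as decided here

* Windows shorter than the window size (sub-window scaffolds) are
  skipped, not concatenated: concatenation would manufacture junction
  k-mers from unrelated sequence.
* The mononucleotide map also uses degenerate groups (`A+T`, `C+G`);
  using 4 raw bases would leak strand information that every other k
  suppresses.
* The lattice dimensions are `I = round(sqrt(B * sigma1/sigma2))`,
  `J = ceiling((sigma2/sigma1) I)` for node budget B, both clipped to
  ≥ 2; `I, J` are lattice dimensions and the budget is `n/avg_per_node`.
* Territory connectivity uses 8-neighbour (Moore) adjacency: diagonal
  chains produced by dense sliding steps should read as one structure.
* The chromosome-trend baseline is a degree-2 polynomial; the curvature
  sign is reported without presuming a direction, and the tests assert
  it matches the construction of the planted gradient.

## Limitations

Satellite extraction formalises what is a visual judgement on published
maps; its size thresholds are conventions, not estimates. A satellite
whose composition lies *between* a species' main manifold and the rest
of the map can legitimately connect to the main territory through its
own boundary windows and will then not be reported — on real data as in
simulation. Shared-node detection requires the shared content to
dominate whole windows; a repeat family occupying a small fraction of
every window shifts compositions without creating co-occupied nodes.
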