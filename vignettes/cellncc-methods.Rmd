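---
title: "Counting cells by normalized cross-correlation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting cells by normalized cross-correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellncc)
```

## The detection model

A lensless (in-line holographic) image of a blood sample renders each cell
as a small, roughly radially symmetric shadow. Detection works by template
matching: for each K×L patch `ω` in a cell-image library, the normalized
cross-correlation

$$R(i,j) = \frac{\sum_{x,y}\,(\omega_{xy}-\bar\omega)\,(f_{x+i,y+j}-\bar f_{ij})}
{\sqrt{\sum_{x,y}(\omega_{xy}-\bar\omega)^2\;\sum_{x,y}(f_{x+i,y+j}-\bar f_{ij})^2}}$$

is evaluated at every valid anchor `(i, j)` of the M×N sample image,
producing an (M−K+1)×(N−L+1) surface per template. NCC is invariant to
affine intensity changes of either image, which is what makes it robust to
the background-intensity and brightness variations these images exhibit.
An anchor whose maximum over the library strictly exceeds a threshold is
marked; connected groups of marks are clusters; the count is the number of
clusters.

Conventions used throughout: matrices are row-major with 1-based (row,
col) anchors at the template's top-left corner; the surface is valid-mode
(no padding). A sample window with zero intensity variance makes the
correlation undefined — the package defines it as 0 (maximally
uninformative) rather than NaN, so flat image regions can never be marked.
Marking is strict (`> T`, ties excluded).

`ncc_at_point()` is the direct double-summation form and serves as the
reference implementation; `ncc_surface()` computes whole surfaces with
summed-area tables for window means/energies and a shift-and-accumulate
cross term, all in double precision. The two agree to well below 1e−6; the
test suite enforces this on randomized sample/template pairs against an
independently coded per-pixel oracle. Deviation energies obtained from
summed-area tables can go slightly negative by cancellation; they are
clamped at zero, and values are clipped into [−1, 1].

## Clustering and its one tunable

A cell spans several adjacent anchors whose NCC exceeds the threshold, so
single cells appear as mark clusters with an expected extent of about
m×n = 3×3 anchors. Clusters are connected components under a Chebyshev
link radius of 1 (8-connectivity). Components larger than m×n are still
counted as one cell — the extent is a physical expectation, not a
splitting rule — and a warning reports them (on the synthetic scenes,
footprints of strongly matched cells routinely reach 4–5 anchors across,
which is harmless because separations are much larger).

When a skip pattern thins evaluation, the surviving marks of one cell may
no longer be 8-adjacent: a stride-2 lattice leaves marks 2 apart. The link
radius therefore widens to `max(m, n) − 1` whenever a pattern is active,
which is exactly the largest gap a pattern can open inside an m×n cluster
footprint. The same radius defines when two templates' detections count as
the same cell during influence attribution.

## Skip patterns and the detection-probability model

The four preset masks (`preset_pattern()`):

| preset | geometry | density | runtime reduction | skipped of 9 (best/worst) |
|---|---|---|---|---|
| P1 | evaluate alternate rows | 1/2 | 50% | 3 / 6 |
| P2 | checkerboard | 1/2 | 50% | 4 / 5 |
| P3 | stride 2 both axes | 1/4 | 75% | 5 / 8 |
| P4 | stride 3 both axes | 1/9 | 89% | 8 / 8 |

The geometries are a reconstruction: they are pinned down by requiring
each mask's (runtime reduction, best-case skipped points in a 3×3 window)
pair to equal (50%, 3), (50%, 4), (75%, 5), (89%, 8) respectively. The
alternate-row/checkerboard assignment between P1 and P2 is forced by the
skipped counts (3 vs 4), not by the reductions, which tie at 50%. Both
bounds are exposed (`skipped_in_cluster()`) so the best-case convention is
auditable; custom masks can be supplied as 0/1 grids.

Accuracy cost is quantified by a conditional detection probability. In the
critical region where NCC values sit near the threshold, model each of the
t cluster points as marked independently with probability `p_mark` (taken
as 0.5 there — a near-threshold value is equally likely to fall on either
side). If the pattern skips s of the t points, the probability that at
least one of the t−s evaluated points is marked, *given* that at least one
of the t would have been,

$$P_{k|org} = \frac{1-(1-p)^{\,t-s}}{1-(1-p)^{\,t}},$$

is 98.6%, 97.1%, 93.9% and 50.1% for P1–P4 at p = 0.5, t = 9. The exponent
in the numerator is the number of *evaluated* points, t−s; writing s there
instead would give 87.7% for P1's s = 3, inconsistent with the probability
being 1 at s = 0 and with the values above. `simulate_detection()`
validates the closed form by seeded Monte-Carlo (the test suite requires
agreement within 3 binomial standard errors at 2×10⁵ draws, and checks the
small-t closed form by exhaustive enumeration over all 2^t mark
configurations).

## Influence and pruning

Manually collected libraries contain duplicated and similar templates that
add evaluations without adding detections. *Influence* makes this
measurable: iterating templates in library order, a cluster detected by
template k is attributed to k only if it overlaps no cluster already
attributed to an earlier template; influence is each template's attributed
share of the total. An exact duplicate of an earlier template attributes
nothing — sequential first-detection is what makes "redundant" well
defined. (An arg-max-NCC attribution was considered and rejected as the
default: it splits credit between near-duplicates and hides their
redundancy; the sequential rule matches how removal actually behaves.)

`prune_library()` removes in two stages, both verified by re-counting the
calibration samples rather than trusted from the attribution bookkeeping:
first all zero-influence templates at once (every attributed cluster
belongs to a kept template, so the re-count is preserved — asserted in the
tests), then greedily the lowest-influence remaining template, re-scoring
influence after each removal, while the cumulative re-counted loss stays
within the budget (default 8.5%). Ties break toward earlier library order,
making the result deterministic. The pruner never empties the library.
Re-counts reuse cached per-template surfaces, so greedy recomputation
costs pointwise maxima only.

Runtime is accounted as NCC evaluations — (evaluated anchors) × (library
size), an exact, hardware-independent ledger — rather than wall-clock.
Pruning a library from 150 to 20 templates cuts evaluations by 87%; a
pattern multiplies by its density (P1: ×0.5).

## The threshold model and compensation

Both optimizations can only lose marks, and near the working point the
count responds approximately linearly to the threshold. `fit_count_model()`
fits `C(T) = αT + β` by ordinary least squares through total counts on a
grid of thresholds — default 8 equispaced points on [0.60, 0.67], the
range from the working threshold down to the weakest value still
indicating a strong correlation; one max-over-library surface per sample
is reused across the grid. `compensate_threshold()` inverts the line at
the un-optimized pipeline's count and clamps into [0.60, T_hi], flagging
the clamp: a loss that persists at T = 0.60 cannot be compensated by the
threshold alone. If the counts never vary across the grid, α = 0 is
reported with a warning and `run_optimize()` keeps the original threshold
— there is nothing to compensate and nothing to invert.

## The synthetic benchmark

`generate_scene()` emulates the relevant features of lensless blood-sample
images: each cell is a radially symmetric shadow (dark Gaussian disk plus
a brighter diffraction-like ring) from four shape variants whose
parameters are perturbed ~4% per cell; the background carries a linear
intensity gradient (0.06/0.10 of full scale across rows/cols) and i.i.d.
Gaussian noise. Defaults — 300×400 px, 60 cells, minimum center separation
14 px, 13×13 templates — keep scenes desk-sized while leaving room for a
threshold response with genuine slope. The noise level (sd 0.03 on a unit
intensity scale) was set so that an exact planted-shape template
correlates above 0.8 at essentially every true center, putting the
working threshold 0.67 in a regime of reliable but not saturated
detection. The shape-variant parameters were chosen so that cross-variant
template correlations straddle the threshold (≈0.1–0.7): libraries then
show the full influence spectrum — dominant templates, partially shadowed
similar ones, and exact duplicates.

`derive_library()` crops templates centered on true cells and appends the
two kinds of redundancy a manually collected library accumulates: exact
duplicates (copies of earlier entries) and jittered near-duplicates
(re-crops offset by up to 1 px; a sliding search compensates small crop
offsets, so these are behaviourally near-identical — the point of the
jitter is redundancy, not degradation). Base cells are sampled round-robin
across the shape variants present, as a curator marking "representative"
cells would, which guarantees every appearance class is covered even by a
small library. Entry order is shuffled, so which member of a duplicate
pair scores zero influence depends on the draw — only the pair property is
deterministic.

What the generator does *not* emulate: real in-line holography (true
fringe structure, defocus), overlapping or touching cells, debris and
non-cell objects, spatially correlated noise, and illumination anomalies
beyond a linear gradient. Passing the synthetic suite therefore
demonstrates the algorithms and their bookkeeping — oracle-exact NCC,
conservative thinning, budget-respecting pruning, exact compensation
round-trips — not field accuracy on instrument data, for which the
original threshold would need re-calibration against manual counts.

## Problem sizes and determinism

The packaged evaluation runs 10 scenes of 60 cells with a 12-template
library (4 base + 4 jittered + 4 duplicate): large enough that the
optimized-vs-original comparison averages over ~600 cells, small enough to
run in seconds per scene. Every random draw (scene content, library
composition, Monte-Carlo) flows from explicit integer seeds; fixed seeds
reproduce bit-identical scenes. On these conditions the fully optimized
pipeline (pruned library + alternate-row pattern + compensated threshold)
stays within 1% of the original pipeline's count on average while
performing ~8× fewer NCC evaluations.

## Known limitations

* Detection is translation-only: no rotation/scale-invariant matching and
  no sub-pixel localization; centroids are anchor-grid means.
* The evaluation-count ledger is the runtime model; actual wall-clock
  gains depend on the implementation exploiting the skipped anchors.
* The independence assumption behind the detection-probability model
  ignores the spatial correlation of neighbouring NCC values; it is exact
  for the Bernoulli model it states (and validated against it), and the
  conservative clustering radius absorbs most of the discrepancy in
  practice.
* Influence is relative to the calibration samples; pruning against
  unrepresentative samples can remove templates a different sample mix
  needs.
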