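---
title: "Slice-propagation segmentation of individual teeth: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slice-propagation segmentation of individual teeth: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toothprop)
```

## The problem

In dental (cone-beam) CT, individual teeth must be separated from the
alveolar bone that holds them before implant planning or orthodontic
modelling can proceed. The obstacle is intensity: tooth dentin and socket
bone occupy nearly the same Hounsfield range, so no global threshold
separates them, and a naive seeded region growing leaks from the tooth into
its socket. What *does* hold is geometric continuity - at 0.2 mm slice
spacing a tooth's cross-section changes only slightly between neighbouring
axial slices.

`toothprop` exploits that continuity. The user marks, on one well-contrasted
reference slice, at least one seed pixel per tooth and a bounding box around
the dentition. Segmentation information - a per-tooth intensity threshold
(the *T-value*) and the per-tooth shape - then propagates slice by slice in
both axial directions, each slice re-estimating its own threshold under the
shape constraint inherited from its neighbour.

## The per-slice pipeline

For each slice, per tooth, in order:

1. **Median denoising.** A square median filter (default 3 px, reflected
   edges) suppresses impulse noise while preserving straight edges.
2. **Seed derivation.** Seeds for the current slice are the previous mask
   eroded by one pixel, kept where the current slice still exceeds the
   previous T-value; the in-mask pixel nearest the centroid is the fallback.
   Erosion guards against boundary drift.
3. **Threshold search.** Let `A(T)` be the area of the seed-connected
   component of the thresholded slice. `A` is non-increasing in `T`, and the
   working threshold is the *greatest* `T` with
   `A(T) >= (1 - tau) * area(previous mask)` (default `tau = 0.10`): the
   leak-safest threshold that still keeps the inherited shape and size.
   Because CT is integer-valued, the search runs by bisection on the integer
   HU grid with a 1 HU terminal bracket, making it exactly equal to an
   exhaustive scan; the previous slice's T-value supplies the first probe
   (warm start), which shortens the search but cannot change its result.
   The bracket is anchored below at the initial T-value derived from the
   volume histogram (the deepest valley between the tissue and bone modes),
   and above at 3000 HU.
4. **Seeded region growing.** Queue-based first-in-first-out growth: a
   pixel joins the region iff it is 4-adjacent to it, lies in the bounding
   box, reaches the threshold, and differs from the region mean by less than
   `delta`. The mean is frozen at the seed mean by default, which makes the
   result provably independent of seed order and partitioning (the
   determinism contract behind `scatter_seeds()`); a classic running-mean
   mode is available with a fixed lexicographic FIFO order.
5. **Hole filling (inverse region growing).** Dentin and pulp are darker
   than the enamel/dentin shell, so thresholding leaves interior holes. The
   background is grown from the bounding-box boundary by pure connectivity;
   its complement within the box is the mask with every enclosed cavity
   recovered.
6. **Branch removal.** Any growth outside the previous mask dilated by
   `dilation_radius` pixels (default 3, working range 2-5) is pruned, and
   only the seed-connected component survives. This is the explicit guard
   against leaks into socket bone, and it yields a global invariant: every
   propagated mask is contained in the dilation of its neighbour toward the
   reference slice.
7. **Size check and retry.** With `r` the area ratio to the previous slice,
   a result is *over* (`r > 1.3`) or *under* (`r` below the continuity
   bound) and triggers up to `max_retries` threshold adjustments of
   `retry_t_step` (default 20 HU) before the attempt with `r` closest to 1
   is accepted. Two refinements proved necessary in practice:
   - the under bound reuses `tau`: the realized (grown, filled, pruned) mask
     is held to the same `(1 - tau)` continuity the threshold search imposes
     on its raw-threshold surrogate `A(T)`. Without this, a threshold that is
     marginally feasible on the surrogate can erode the realized mask by a
     few percent per slice - too little for a +/-30 % check to notice, but
     compounding geometrically across slices;
   - when no threshold in the bracket is feasible (a transient shape jump),
     the previous T-value is carried over and the event logged, rather than
     terminating the tooth.

A tooth whose mask comes out empty is terminated (root apex or crown end).
Pixels claimed by two teeth are assigned to the tooth whose previous mask is
nearer (Euclidean distance transform; ties to the lower id), and each mask is
then reduced to its seed-connected component - since the seeds come from the
previous mask, this also guarantees every reconstructed tooth is a single
3D-connected object.

## Parameters

| Parameter | Default | Unit | Role |
|---|---|---|---|
| `area_tolerance` (tau) | 0.10 | - | allowed shape shrinkage per slice in the threshold search |
| `bisection_tol` | 1 | HU | terminal bracket width; exact on integer CT |
| `t_max` | 3000 | HU | upper search bound |
| `bone_premask_hu` | 1400 | HU | optional mandible pre-extraction threshold |
| `delta` | 60 | HU | region-growing deviation bound (3 x default phantom noise) |
| `connectivity` | 4 (2D) / 6 (3D) | - | conservative leak prevention |
| `median_kernel` | 3 | px | denoising window |
| `dilation_radius` | 3 | px | branch-removal shape slack (range 2-5) |
| `size_change_max` | 0.3 | - | over-segmentation trigger |
| `max_retries` / `retry_t_step` | 5 / 20 HU | - | retry loop budget |

`delta` is the one parameter a user is most likely to touch on real data: it
should sit around three standard deviations of the within-tooth intensity
spread after denoising.

## The phantom: what it emulates and why

The synthetic generator builds the scene the method was designed for: an
axial U-shaped mandible arch of socket bone over soft tissue and air, with
14 tube-like teeth whose elliptical cross-sections shrink gradually away
from the reference slice (`taper`, default 0.4 % radius per slice) - the
defaults are a 128 x 128 x 64 grid, a 150 HU tooth-over-socket gap and
20 HU Gaussian noise, a deliberately scaled-down stand-in for clinical
512 x 512 x 400 volumes. Material intensities follow the clinical ordering
air < tissue < socket < tooth, with the socket at 1300 HU.

Each tooth interior contains a dark core: a pulp kernel at
`intensity_pulp`, surrounded (in the default `ramp` profile) by a
circumpulpal dentin mantle whose intensity rises linearly from the socket
level at the pulp boundary to the shell level at the core boundary. Two
facts motivated the graded mantle, both worked out before any end-to-end
run. First, it is physically right: dentin mineral density genuinely falls
toward the pulp chamber, which is exactly why thresholded teeth show
interior holes. Second, a fixed-point analysis of the control loop shows
that the greatest-feasible-threshold rule always *saturates* its area
constraint - it erodes whatever `tau` allows, every slice. If the tooth
interior is uniformly bright, the eroded pixels are the (median-biased)
rim pixels, whose loss hole-filling cannot undo, and the few-percent bite
compounds geometrically along the tooth. With a graded interior the
threshold instead parks inside the dentin band, the eroded pixels are
enclosed and fully recovered by hole filling, and the equilibrium error
drops to the discretisation level (about 1 % of volume). The piecewise
constant `flat` profile is retained for exact-arithmetic unit tests.

What the phantom deliberately does **not** emulate: metal/beam-hardening
artifacts (a stated open problem for this class of methods), partial-volume
edge blur, anisotropic voxels, anatomical root branching, and the maxilla.
Passing the phantom suite therefore demonstrates the control loop's
correctness and stability under low contrast, interior holes, shape drift
and noise - not robustness to restorative metalwork or real anatomical
variation.

## Numerical choices and degenerate inputs

- **Frozen region mean.** The growing criterion compares candidates to
  `mean(A)`; whether that mean updates during growth is ambiguous in the
  classic formulation. The default freezes it at the seed mean:
  reproducibility (order and partition independence) outweighs fidelity to
  an ambiguous detail. The running mode exists behind a flag with a fixed
  deterministic order.
- **Integer bisection.** Thresholds move on the integer HU grid, so with a
  1 HU tolerance bisection is exact, and the warm start provably cannot
  change the answer - both properties are tested against exhaustive scans.
- **Deepest-valley ties.** When several bins tie for the valley minimum
  between the tissue and bone modes, the midpoint of the longest tied run
  wins (first run on a further tie). A unimodal histogram raises an error
  rather than guessing; the initial T-value can then be supplied manually.
- **Degenerate hole filling.** A mask covering its whole bounding-box
  boundary fills to the entire box; the event is reported.
- **Index conventions.** Everything in R is 1-based with closed bounding
  boxes; the JSON seed schema and raw-volume sidecars are 0-based with
  half-open boxes, converted exactly once at the I/O boundary.
- **Problem sizes in tests.** Unit tests run on 48-voxel phantoms with four
  teeth; the end-to-end and degradation suites use the full default phantom
  (three replicate noise draws; contrast gaps 300/150/75/40 HU). These sizes
  were chosen to exercise every code path at comfortable interactive speed.

## Known limitations

- **Small structures.** A 3 x 3 median filter rounds off objects only a few
  pixels wide; teeth below roughly 8 px diameter (at default settings) are
  systematically under-segmented. The scaled phantom keeps teeth above that
  limit; clinical 0.2 mm voxels put real teeth far above it.
- **Metal artifacts** are out of scope, as is DICOM series assembly (convert
  to NIfTI/NRRD first; intensities are assumed already HU-calibrated).
- **Seeding is manual** by design (semiautomatic method); a bad seed on the
  reference slice is a hard, named error rather than a silent degradation.
- The optional 1400 HU bone pre-mask assumes clinical calibration; it is off
  by default and not useful on the phantom, whose socket sits at 1300 HU.
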