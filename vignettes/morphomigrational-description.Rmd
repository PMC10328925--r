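---
title: "The morphomigrational description: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The morphomigrational description: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphomig)
```

## The model

A migrating adherent cell changes shape and position as one coupled
process. `morphomig` describes a single cell's time-lapse, supplied as one
binary mask per frame, by four per-frame quantities:

* the **signed morphomigrational angle (sMM)** between the fitted major
  axis and the centroid displacement to the next frame, with a sign that
  tracks which side of the axis the displacement falls on;
* the **major-axis dynamics (Δϕ)**, the signed angle between the fitted
  axes of consecutive frames;
* the **turning angle (α)** between consecutive displacements;
* the **elongation (ε = 1 − a/b)** of the fitted ellipse.

Everything is derived from the ellipse of identical second moments: the
ellipse sharing the mask's centroid and central second moments. With
eigenvalues λ₁ ≥ λ₂ of the pixel-coordinate covariance matrix
[[μ₂₀, μ₁₁], [μ₁₁, μ₀₂]], the full axis lengths are b = 4√λ₁ and
a = 4√λ₂ (for an exactly elliptical region these are its true axis
lengths) and the orientation is ½·atan2(2μ₁₁, μ₂₀ − μ₀₂). The fit is
deterministic and parameter-free, which is why it is preferred here over
boundary least-squares fits. Eigenvalues come from the closed-form solution
of the 2×2 problem, not an iterative decomposition; the test suite checks
the result against an independent `eigen()`-based oracle to 1e-9 relative.

Pixels are treated as unit point masses at their integer centre
coordinates — the convention of standard region-property implementations.
Weighting by pixel area instead would change nothing for the axis ratio and
orientation at the shape sizes this method is meant for.

## Coordinate and sign conventions

Images are used in screen coordinates: x is the column index increasing
rightward, y the row index increasing downward. All signed angles
(`signed_angle()`) are positive when the rotation appears clockwise on the
displayed image; this one convention fixes the handedness of α, of Δϕ and
of the sMM side test simultaneously. Because the literature rarely states
the handedness of axis-rotation measures, the sign of Δϕ alone is
configurable (`track_config(dphi_clockwise_positive = FALSE)`).

The fitted axis is undirected (orientation mod 180°), so comparing axes
across frames requires giving each a direction. `propagate_axis_directions()`
chooses the direction of frame n's axis so that u(n)·u(n−1) ≥ 0; an exact
perpendicular tie resolves to Δϕ = +90°. This continuity rule is what
bounds Δϕ to [−90°, 90°]: a reported Δϕ of −75.9° means the axis rotated
75.9° anti-clockwise on screen, never "by 104.1° the other way".

The sMM sign needs a side reference. The side of a step is the sign of the
2-D cross product u×d between the propagated axis direction and the
displacement. The reference is the side at the first valid step whose side
is nonzero, and it is never reset: a positive sMM means "the displacement
is on the same side of the major axis as it was at the start of the
track". Motion exactly along the axis has side 0 and is reported as +0;
steps before a reference exists are flagged `flag_no_reference_side`. This
side-tracking is one consistent algorithmic reading of the verbal
definition ("same side as in the first frame"); it is the minimal one, and
it makes the sign pattern invariant under flipping all propagated axis
directions (the reference flips with them).

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `pixel_size_um` | 1 | µm/px | physical calibration |
| `frame_interval_s` | 1 | s | time calibration |
| `min_displacement_px` | 0.25 | px | steps shorter than this are flagged `zero_displacement`; sub-quarter-pixel centroid shifts are segmentation noise and would otherwise produce wild angles |
| `low_elongation_cutoff` | 0.1 | — | at or below this ε the fitted orientation is unreliable (flag `low_elongation`); equals the upper edge of the "low" elongation band so flag and band agree |
| `dphi_clockwise_positive` | TRUE | — | handedness of Δϕ |
| `bands` | see below | — | coarse-grain band table |
| `rules` | see below | — | behaviour-rule thresholds |

## Coarse-grain bands

`coarse_bands()` maps values onto verbal categories on the absolute value,
with the sign reported separately (the negative and positive ranges carry
identical labels). Intervals are right-closed; the first also contains its
lower edge, so the bands partition each domain exactly:

* sMM: very low [0°, 15°], low (15°, 45°], moderate (45°, 70°], high (70°, 90°]
* α: low [0°, 60°], moderate (60°, 90°], high (90°, 135°], very high (135°, 180°]
* Δϕ: very low [0°, 10°], low (10°, 20°], moderate (20°, 45°], high (45°, 60°], very high (60°, 90°]
* ε: low [0, 0.1], moderate (0.1, 0.6], high (0.6, 1]

The classifier is memoryless — no smoothing or hysteresis across frames —
and the band table travels in the YAML config, so a lab can re-band without
touching code. Informal prose sometimes calls a value of 13.5° "low"; the
band table is the authority here, and 13.5° is *very low*.

## The behaviour rule engine

Identifying behaviours from descriptor patterns inverts a mapping that is
usually made by eye, so it is under-determined: the defaults encoded in
`annotate_behaviours()` are one consistent choice, ordered so that the most
specific signatures win. Per step, the first matching rule applies:
rounded-chaotic (ε low) dominates everything, because a near-circular
shape's axis is meaningless; the rear-retraction signature (one-step jump
of |sMM| from very low to high, with low α and high preceding Δϕ) precedes
the U-turn rule; U-turns precede the windowed stretching rules; gradual
redirection precedes the three plain displacement rules.

Two thresholds deserve explanation:

* **Sign noise** (`sign_noise_deg = 15`): near zero, the sign of sMM and of
  α is dominated by rasterization and segmentation noise. Sign changes on
  sub-threshold steps therefore never break a "constant sign" condition,
  and a gradual redirection must show turning angles above the threshold —
  otherwise straight askew motion, whose α hovers around 0° with random
  sign, would masquerade as a consistent slow turn.
* **Elongation tolerance** (`eps_increase_tol = 0.01`): "ε increasing over
  a window" means the first-to-last increase exceeds the tolerance and no
  intermediate step decreases by more than it, which keeps the stretching
  rules robust to the ±0.005 jitter of rasterized elongations.

Within a lateral-stretching window the reversal steps themselves satisfy
the higher-priority U-turn rule and are labelled as such; the flanking
window steps carry the stretching label. This is deliberate: the reversal
*is* a U-turn, and the segment structure (stretching — U-turns —
stretching) preserves the information.

## The synthetic generator

`simulate_scenario()` produces the package's test substrate: rasterized
ellipses (plus one composite tailed shape) whose centroid, orientation and
elongation follow scripted trajectories, each an idealisation of one
behaviour archetype. Shapes use a pixel-centre inclusion test with no
anti-aliasing, so masks are exactly binary and every geometric ground truth
is analytic. The default canvas is 512×512 with major axes ≥ 40 px, the
regime where moment-fit errors (< 1° orientation, < 0.02 ε) are negligible
against the band widths. Scenario scripts are deterministic given the seed.

Design notes on individual scenarios:

* the lateral movers head 8° off-axis rather than exactly along it, so the
  displacement has a definite side and sMM a definite sign;
* `rounding_cell` ramps ε from 0.30 to 0.04 within four frames, crossing
  the 0.1 band edge in a single step, so no frame sits ambiguously at the
  boundary;
* `perpendicular_stretch` ramps ε linearly (0.008/frame), giving every
  window the same detectable elongation increase;
* `tail_retraction` keeps a tapering tail (which dominates the second
  moments and holds the fitted axis along the travel direction) up to the
  event frame and withdraws it at that frame. A gradual tail shrinkage
  would flip the axis at some interior frame with intermediate Δϕ; the
  one-step withdrawal produces the clean signature the scenario exists to
  test — geometry flipping from parallel to perpendicular while the course
  is unchanged;
* `disc_random_walk` draws seeded uniform headings and steers back toward
  the canvas centre near the border, keeping it deterministic.

What the generator does **not** emulate: membrane fluctuations, protrusion
texture, segmentation artifacts beyond the optional smoothed
dilation/erosion boundary-noise field, cell–cell contact, or shapes more
complex than ellipse-plus-tail. Passing the scenario suites therefore shows
that the descriptor chain and rule engine are correct on clean geometry and
robust to mild boundary noise — not that the default rule thresholds are
optimal for any particular cell type.

## Numerical choices and degenerate inputs

* Empty frames abort the run: the per-frame chain (n−1, n, n+1) has no gap
  semantics, so skipping frames would silently change every adjacent
  descriptor.
* Components are 8-connected; under the `largest` policy, ties go to the
  component whose first row-major pixel comes first (documented,
  deterministic).
* Degenerate masks (single pixels, 1-px lines) get semi-axes clamped to
  half a pixel and a `degenerate` flag instead of an error.
* Exact ties: perpendicular axis propagation resolves to +90°; a signed
  angle of exactly 180° is reported as +180° (the domain is (−180°, 180°]).
* Integer translation of all masks leaves moments, orientation, ε, area
  and Δϕ bit-identical; centroids round once per frame in the mean, so
  displacement-derived angles agree to ~1e-13 degrees rather than bit for
  bit.
* Undefined is not zero: sMM/Δϕ do not exist at the last frame, α not at
  the first or last, and nothing exists across a zero-displacement step.
  These are `NA` in tables and empty fields in the CSV.

## Problem sizes

The verification suites run at deliberately modest sizes — 50 random blobs
for the oracle comparison, 100 rasterized ellipses for parameter recovery,
scenario tracks of 28–36 frames on 512×512 canvases — chosen because the
measured errors are already one to two orders of magnitude below the
tolerances they are compared against, so larger runs would add runtime, not
information.

## Known limitations

The method consumes masks; segmentation quality is inherited, not checked.
One cell per frame is assumed (a selection policy reduces multi-component
frames, but tracking multiple cells is out of scope). The sMM family is
interval-dependent: `resample_track()` lets you recompute the description
at coarser sampling, and results at different intervals are different views
of the motion, not comparable numbers. The behaviour vocabulary is a fixed
set of eight archetypes plus UNCLASSIFIED; discovering new classes, or
mining behaviour sequences across cell populations, is future work.
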