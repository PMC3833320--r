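---
title: "Methods: accumulative-computation segmentation and fuzzy fall recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: accumulative-computation segmentation and fuzzy fall recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fallwatch)
```

fallwatch recognises human falls in fixed-camera colour or infrared frame
sequences in two stages: a *motion segmentation* stage that turns frames
into one person bounding box per frame, and a *recognition* stage that
turns windows of boxes into a fall score, a fall-pattern label and
post-fall inactivity alarms. This vignette records the model, its
assumptions, the tunable parameters, and the design decisions that were
genuinely open, so that a maintainer can see why the package behaves as it
does.

## 1. The LIAC segmentation model

Each 8-bit channel is quantized into `n_bands` equal intensity bands
(band = `floor(v * N / 256)`), and *motion* is defined as a pixel changing
band between consecutive frames. Per channel and band the engine keeps a
charge ("permanence") memory in `[q_min, q_max]` updated in four phases per
frame:

1. **Charge/discharge** (`liac_update_charge()`): a pixel that just entered
   the band saturates to `q_max`; a pixel in the band at both instants
   loses `discharge` (floored at `q_min`); a pixel not in the band drops to
   `q_min`.
2. **Lateral-inhibition recharge** (`liac_recharge()`): saturated pixels
   emit charge to every partially charged pixel reachable through
   4-connected paths of charged pixels; fully discharged pixels block the
   propagation; each pixel gains `recharge` at most once per frame.
3. **Homogenisation** (`liac_homogenize()`): every 4-connected component of
   pixels with charge at least `hom_min` is set to the floor of its mean
   charge, diluting isolated background motion and giving object parts a
   common value.
4. **Fusion**: maximum over bands per channel, then (for colour) the
   pixelwise minimum over channels — the greyscale counterpart of ANDing
   the per-channel binarisations, and an exact AND once the result is
   thresholded.

Two phases deserve an explicit note because the verbal description of the
model admits more than one reading:

* **Precedence of discharge over saturation.** A pixel that *leaves* a band
  could be argued to "change band" there and saturate that band's memory.
  We give the not-in-band discharge precedence: a vacated band drops to
  `q_min`. Saturating vacated bands would leave permanent ghost silhouettes
  behind every moving object.
* **Frozen recharge snapshot.** Sources (`q == q_max`), transparency
  (`q > q_min`) and reachability are all evaluated on the charge image as
  it stood before the phase, then increments are applied at once. This
  makes the phase order-independent, idempotent per frame ("recharge at
  most once") and directly testable against a graph-reachability oracle.

Quantization is uniform scalar quantization with bin width `256 / N`; no
codebook is learned, which keeps the stage deterministic and
parameter-free beyond `N`. Colour input is processed in the stored RGB
space without conversion.

### Parameters and profiles

| parameter | units | default | role |
|---|---|---|---|
| `n_bands` | bands | 8 | motion sensitivity: more bands = finer intensity changes count as motion |
| `q_min`, `q_max` | charge | 0, 255 | memory range; `q_max` also the saturation value |
| `discharge` | charge/frame | 32 | memory length; lower values keep longer motion trails |
| `recharge` | charge/frame | 32 | lateral support for connected, partially charged pixels |
| `hom_min` | charge | 1 | minimum charge to join a homogenisation component |
| `threshold` | charge | 128 | binarisation level of the fused image |

With `discharge == recharge` (the constructor default, a balanced choice in
the middle of the charge range) any charged pixel connected to fresh motion
breaks even each frame, so the engine preserves the full motion history as
a trail while motion continues — useful for visualising where an object has
been. Fall *indicators*, however, need the box around the person *now*, so
the pipeline configuration (`default_config()`) ships a **tracking
profile**: `discharge = 128`, `recharge = 16`. Charges then survive roughly
two frames past their last motion, the reported box hugs the union of the
last two silhouette positions, and homogenisation lifts the silhouette
interior (a mixture of freshly saturated and one-frame-old pixels) above
the threshold as a single component. Both profiles satisfy every invariant;
they differ only in memory length.

## 2. Post-processing

The fused charge image is binarised at `threshold` (inclusive above:
`q >= threshold` maps to 255 — the model only fixes "over"/"below", so the
equality side is a convention and is documented here), then opened
morphologically with a 3×3 square element (one erosion, one dilation,
outside-image treated as background) — the smallest standard opening, which
removes isolated pixels and spots thinner than three pixels. Foreground
blobs are labelled with 8-connectivity — deliberately more permissive than
the 4-connected lateral inhibition, since diagonally touching limb pixels
belong to one person — and filtered by inclusive height, width and
compactness limits (defaults: height ≥ 20 px up to the image height,
width ≥ 10 px, compactness in \[0.2, 1\]). The largest surviving blob is
the person ROI; ties break to the smaller `y`, then `x`, so the choice is
deterministic.

## 3. Fall indicators

Frames are grouped into non-overlapping windows of
`round(fall_time_ms / interval_ms)` frames (sliding windows are available
behind a flag, but consecutive periods are the default because the decision
stream is then an unambiguous partition of time). With the 200 ms capture
interval and the 1.2 s fall time used throughout the package's experiments,
a window is 6 frames. From the first and last ROI of a window,
`compute_indicators()` derives:

* `whr = last.w / last.h` — low for an upright person, roughly 1.5–7 for a
  lying one;
* `height_change = first.h / last.h` — *initial over final*. The model's
  two verbal definitions disagree on the orientation of this ratio; we
  follow the initial/final reading because recorded fall windows show
  values above 1 while the box height shrinks, which only that orientation
  produces;
* `h_vel = |first.h − last.h| / first.h` and
  `v_vel = |first.w − last.w| / first.w` — velocity ratios normalised by
  their maximum attainable value in one fall time. Note the naming
  convention: the "horizontal" velocity is driven by the *height* change
  and the "vertical" one by the *width* change, i.e. each is named for the
  body axis that rotates into that direction during a fall. The package
  follows that convention as given rather than renaming;
* `direction` — 1 when the top-left corner moved right, 0 otherwise (ties
  count as 0). A single bit cannot distinguish leftward lateral falls from
  frontal ones, which is why pattern labels 3 and 6 need the optional
  signed displacement input (below);
* `position_change` — 1 when the top-left corner *rose*, the signature of
  rolling off a bed from a lying posture.

Windows whose first or last frame has no ROI are skipped with a warning: a
motion segmenter cannot see a perfectly still person, so missing boxes are
an expected state, not an error. "Calibration" of the person reduces to
recording the first valid ROI as a baseline; it does not enter the
indicator formulas.

## 4. The fuzzy inference system

`fall_system()` builds a Mamdani system: min for AND, `1 − μ` for NOT,
clipping implication, max aggregation, centroid defuzzification by the
trapezoid rule on a 0.05-step grid over the Fall domain \[0, 100\].

**Term shapes.** The linguistic terms are fixed by their supports
(velocities: LOW \[0, 0.35\], MEDIUM \[0.25, 0.65\], HIGH \[0.6, 1.25\];
width-to-height ratio: LOW \[0, 0.8\], MEDIUM \[0.7, 2.5\], HIGH
\[2.1, 6.0\]; Fall: NO \[0, 45\], YES \[35, 100\]), but supports alone do
not determine shapes. Interior terms are symmetric triangles over their
supports; edge terms are shoulder trapezoids flat toward the domain edge,
ramping across the printed overlap with their neighbour. The decisive
property of this choice: a symmetrically clipped triangle keeps its
centroid at its peak, so whenever only the YES term fires — at *any*
activation level — the defuzzified score is exactly the YES peak 67.5, and
a pure NO activation gives 22.5. Those two fixed points anchor the system's
observable behaviour independently of rule-activation details.

**HeightChange.** Only one anchor is stated for this variable: a 30% height
loss marks the HIGH boundary, motivated by body proportions (a standing
person's width is near a quarter of their height, so a fall changes the box
height drastically). A 30% loss corresponds to an initial/final ratio of
about `1 / 0.7 ≈ 1.43`, which we place on the HIGH plateau: LOW is flat to
1.05 and gone by 1.10, MEDIUM is the triangle (1.05, 1.20, 1.35), HIGH
ramps over \[1.30, 1.40\] and stays flat to the domain edge 2.5. The
ambiguity (ratio vs percentage, and which side of it) is real; these
boundaries make the recorded standing-fall windows HIGH, sitting-fall
windows MEDIUM and kneeling windows MEDIUM-at-most, which is the behaviour
the classification needs.

**The rule base.** The original system's rules were never published, so the
package ships a minimal reference rule base (`inst/rules/reference.rules`,
editable DSL) reconstructed from the *described* behaviour: standing falls
are caught by HIGH height change with non-LOW velocity (the OR over the two
velocities is encoded as two conjunctive rules); sitting falls by a HIGH
width-to-height ratio reached through a non-LOW height change; falls from
lying by a HIGH ratio with a risen corner; kneeling and stillness are
rejected by explicit NO rules. Consequently the *intermediate* scores of
the recorded experiments (values like 65.44 or 38.6 produced by the
unpublished rules) are not reproducible and are not claimed; the
reproducible surface is the set of outcomes forced by the term geometry —
the 67.5 single-term score, the ≤ 45 NO-range rejection, and the pattern
labels.

**Decision and patterns.** `is_fall = score > 40`, the midpoint of the
NO/YES overlap \[35, 45\]; the boundary itself is not a fall. The fall
pattern is a crisp decision tree rather than a defuzzified output (the
labels are categorical, and a centroid between category codes would be
meaningless): a risen corner with a clearly lying box (μ~HIGH~(whr) > 0.5)
is label 7; otherwise the origin is standing when μ~HIGH~(height change) ≥
μ~MEDIUM~, else sitting; `direction = 1` selects lateral-right (2/5),
otherwise backward/forward (1/4). Lateral-left labels (3/6) are emitted
only when the caller supplies the optional signed displacement `dx < 0` —
the six standard indicators alone cannot encode "left", and the recorded
left-fall examples are mutually inconsistent on the direction bit, so no
decision function over the six inputs could reproduce them.

## 5. Inactivity monitoring

After a positive window the monitor enters inactivity mode; a window whose
box is upright again (μ~LOW~(whr) > 0.5) recovers to detection mode; if
instead `inactivity_limit_ms` (default 30 000 ms) elapses with no stand-up,
the terminal alarm state is entered. With 1.2 s windows the alarm therefore
fires at the first window boundary at or past 30 s. The clock is the frame
clock, so behaviour is identical on recorded and simulated time.

## 6. The synthetic-scene generator

`gen_fall_sequence()` renders a single person as a filled rectangle on a
uniform background, animated linearly from a start to an end posture over
one fall time (frame `onset` is already one step into the fall, so every
fall frame contains motion, as a real fall does). Study conditions follow
the recorded experiments where stated — 200 ms capture interval, 1.2 s fall
time, hence 6-frame windows — and otherwise use one fixed choice of
realistic geometry: a 96×72 image with an 18×54 px upright person,
bottom-aligned to a ground line; a standing fall ends in a
`0.9 h × 0.9 w` lying box (widening symmetrically for frontal falls,
displaced +6 px for lateral-right ones); a sitting person starts at 60% of
standing height; the lying-fall scenario raises the box corner by 10 px;
kneeling shrinks the height to 75% over twice the fall time; the walking
scenario translates at 2 px/frame for two windows before falling. Noise is
additive Gaussian (default sd 2, clamped to \[0, 255\]), and *all*
randomness flows from the single explicit seed — generation restores the
global RNG state.

One rendering decision matters for segmentation: the person carries a
seeded per-pixel texture attached to body coordinates (uniform in
±45 around the body intensity, nearest-neighbour-mapped onto the current
box). A flat rectangle would expose only its edges to a band-change motion
detector; a textured one re-maps the pattern under every body pixel
whenever the box moves or deforms, so the whole silhouette registers as
motion — the property real clothed bodies have. What the generator does
*not* emulate: articulated limbs, occlusion, shadows, illumination drift,
camera vibration and sensor-specific noise. Passing tests on these scenes
therefore validate the charge dynamics, the box tracking and the
classifier logic, not performance on recorded video.

## 7. Numerical choices and degenerate inputs

* Defuzzification grid 0.05 over \[0, 100\]; the grid contains both term
  peaks, and refinement to 0.005 moves any centroid by less than 0.05. If
  no rule fires the score is defined as 0.
* Homogenisation uses `floor` of the mean, so a component's total charge
  changes by at most its pixel count; charges stay integral when they
  start integral.
* Ties: ROI selection breaks area ties by smaller `y` then `x`;
  `direction` treats a zero displacement as 0; the binarisation boundary
  is inclusive-above; `is_fall` is exclusive at the crossover.
* First frame: charges initialise to `q_min` and no saturation occurs, so
  a sequence's first window can never report motion evidence that was
  never observed.
* Degenerate inputs fail fast with named errors: empty sequences, mixed
  frame sizes, non-8-bit images, two-channel fusion, windows shorter than
  two frames, rules naming unknown variables or terms, and a monitor clock
  running backwards.

## 8. Problem sizes used by the test-suite

The suite exercises the engine at sizes chosen to keep the brute-force
oracles exact and the property loops dense: charge-phase oracles on 6×6–8×8
images (igraph reachability and component labelling, explicit fine-grid
centroids at step 0.001), full-pipeline runs on 96×72 scenes of 18–24
frames, pattern-recovery sweeps over all eight scenarios × 20 seeds on
noise-free indicator streams, and box-tracking regression (IoU ≥ 0.5 on at
least 90% of motion frames) on walking-fall scenes at noise sd 5. These
sizes are the package's own validation design; the engine itself is
size-agnostic.

## 9. Known limitations

* Single-person scenes only: the ROI selector keeps the largest blob and
  has no identity tracking.
* A motionless person is invisible to the segmenter by construction;
  detection windows that begin before any motion are skipped, so the first
  possible detection is one window after motion starts.
* The reference rule base reproduces the *described* behaviour of the
  original detector, not its unpublished intermediate scores.
* Left-fall patterns need the optional signed-displacement input.
* The rule DSL is a small IF/AND/NOT/THEN subset, not a full fuzzy control
  language implementation.
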