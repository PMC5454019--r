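---
title: "Methods: object-based colocalization with sensitized-emission FRET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: object-based colocalization with sensitized-emission FRET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretcoloc)
```

# The measurement model

Three-filter sensitized-emission FRET records three channels over one field:
donor emission at donor excitation (`DF`), acceptor emission at acceptor
excitation (`AF`), and acceptor emission at donor excitation (`rawFRET`).
The raw FRET channel mixes true sensitized emission with spectral
bleed-through of both fluorophores, removed by the Youvan correction

$$FRET_c = rawFRET - d \cdot DF - a \cdot AF$$

with `d` and `a` the dimensionless leak fractions of donor and acceptor into
the raw FRET channel. Because $FRET_c$ scales with the local fluorophore
amounts, between-site comparisons use the Xia normalization

$$NFRET = \frac{FRET_c}{\sqrt{DF \cdot AF}}.$$

Assumptions worth making explicit:

* **Proportional bleed-through.** Leakage is assumed linear in the source
  channel with no offset, which is why the default factor estimator is a
  least-squares slope *through the origin* over thresholded, unsaturated
  foreground pixels of a single-stain control. Median per-pixel ratio and
  ratio-of-sums estimators are available for heavy-tailed controls.
  No background subtraction is applied by default; the slope form tolerates
  background that itself bleeds proportionally.
* **No donor-quenching model.** The correction removes bleed-through; it
  does not attempt FRET efficiency (E%) estimation, which would require
  donor-lifetime or acceptor-photobleaching measurements.
* **Negative $FRET_c$ is informative.** In non-interacting samples $FRET_c$
  fluctuates around zero; clipping negatives would bias object means upward
  and manufacture false positives. All statistics therefore keep negative
  values; clipping happens only in the pseudo-color rendering.
* **Undefined is not zero.** NFRET is undefined where `DF = 0` or `AF = 0`;
  those pixels are `NA` and excluded from aggregation, never coerced to 0,
  which would masquerade as a measured null. The same policy holds for the
  object Pearson coefficient of constant-intensity objects and for the
  acceptor:donor ratio with a zero donor mean. CSV export writes such
  fields empty.

# Segmentation

Objects are recognized per channel by a global histogram threshold
(`auto_threshold()`), with one and the same method required for donor and
acceptor so the two masks are comparable. Implemented methods: the
moment-preserving (Tsai) method — the default, which behaves well for
bright aggregates over dark background —, Otsu, the image mean, the
triangle method, and a manual cutoff. Histograms are built at native bit
depth; a constant image degenerates to an empty mask with a warning. The
threshold objective can plateau across empty histogram gaps, in which case
any value on the plateau yields the same mask; ties are resolved to the
lowest level, deterministically.

Touching objects are split by the standard binary watershed
(`watershed_split()`): the Euclidean distance map of the mask is flooded
from its regional maxima (ultimate eroded points), and basins that meet are
cut apart by a one-pixel background line (of two 4-adjacent pixels with
different labels, the higher label's pixel is backgrounded — deterministic,
and sufficient for 4-connectivity separation). The distance map and
flooding come from EBImage (`distmap`, `watershed`); maxima whose
distance-map depth difference is below `tolerance` (default 0.5 px) merge
into one seed, which suppresses plateau ripple over-segmentation. This
depth-based merge replaces a fixed 2-px spatial merge radius: it is the
native tie-handling of the flooding implementation, deterministic, and
passes the canonical two-overlapping-discs geometry.

Component labeling is 8-connected (a 4-connected pass merged across
diagonal contacts by union-find), components below `min_size` (default
10 px) are dropped as noise specks, and labels are renumbered `1..n` in
raster-scan order of each component's first pixel, so identical inputs
always produce identical labelings. Pixel coordinates are 0-based,
row-major, origin top-left, throughout.

Channel masks are combined pixel-wise into the union (regions with either
marker) and intersection (colocalizing regions). Watershed runs per channel
*before* combination by default: splitting reflects each marker's own
geometry, and the union then merges whatever truly abuts across channels.
The opposite order is available via `watershed = FALSE` plus manual
composition of the exported masks.

# Per-object statistics

All metrics are computed on the raw integer channels promoted to double,
with no pre-smoothing. The object Pearson coefficient correlates (DF, AF)
pixel pairs within one object; it is computed on the uncorrected stain
channels, not on $FRET_c$, since sensitized emission perturbs the stain
channels only marginally compared to staining variation. The whole-image
Pearson (no object restriction) is reported alongside as the classical,
artifact-prone global statistic.

The color-mix coefficient is the per-pixel ratio of the weaker to the
stronger channel averaged over the object (0 when both are 0); a
ratio-of-object-means variant exists. Pixel-level averaging is the default
because it is the reading under which intermediate values between 0 and 1
arise naturally within one object. Per-object NFRET defaults to the mean of
defined per-pixel NFRET values; the ratio-of-means form
$\overline{FRET_c} / \sqrt{\overline{DF}\cdot\overline{AF}}$ is available
and coincides with it on uniform objects. The colocalization area fraction
is $100 \cdot |intersection| / |union|$ per image (0 for an empty union)
and, per union object, the percentage of the object's area inside the
intersection mask.

Saturation handling: every pixel at the maximum code value of the
*declared* bit depth (4095 for 12-bit data, regardless of the 16-bit TIFF
container) is flagged. The audit verdict uses a tolerance of 0 by default —
correct acquisition excludes any saturation — and exclusion is
object-wise: an object touching any saturated pixel keeps its row but is
flagged and omitted from aggregate means. Pixel-wise exclusion was
rejected as the default because partially-censored objects would carry
silently biased statistics; the flag keeps the decision visible and
reversible.

Union objects are the default measurement set (the "combined regions");
per-channel object tables are emitted alongside for marker-specific
questions.

# Classification and tabulation

The conventional deposition call is made explicit: an object whose weaker
channel mean does not exceed its presence threshold (default: that
channel's segmentation threshold) holds `one_protein`; otherwise it is
`two_colocalizing` when the color-mix coefficient exceeds
`colormix_threshold` (default 0.5, deliberately exposed since the original
call this emulates was visual) and `two_combined` otherwise. Raising the
color-mix cutoff can only shrink the colocalizing count (monotonicity is
property-tested). Percentages in the count tables are *truncated* to one
decimal, not rounded — the convention under which 25/267 prints as 9.3 and
5/13 as 38.4 — and always recompute exactly from their integer counts.

# The synthetic test bed

`scene_spec()`/`generate_scene()` simulate what the pipeline needs to
discriminate, with full ground truth:

* disc-shaped aggregates (deposit-like blobs) with a logistic edge falloff
  (scale 0.3 px), radius 5–9 px in the scenario library, placed by random
  sequential adsorption with a minimum center distance (generation errors
  out on infeasible packing);
* object intensities of mean 1500 and standard deviation 250 (12-bit
  scale) over a uniform background of 20 counts. The ~17 % intensity CV is
  typical staining heterogeneity; it also keeps automated thresholds
  several standard deviations below the object mode, so mask truncation
  does not distort per-object correlations, and it makes the whole target
  correlation range $\rho \in [-1, 1]$ reachable by the latent mixing
  (with a much tighter CV, the shared disc geometry alone would impose a
  positive floor on the measurable correlation);
* a shared tissue texture: a smooth random field (correlation length 40 px,
  sd 15 counts) added to both channels, modeling nonspecific staining and
  tissue autofluorescence. Both channels see the same tissue, so this
  component is exactly what overexposure amplifies into apparent
  colocalization; its long correlation length keeps it near-constant within
  any single object, leaving per-object statistics untouched;
* per-channel out-of-focus glow: each channel's structure blurred at
  sd 8 px and re-added at amplitude 0.15. A side effect worth knowing: in
  scenes of strictly distinct markers, the other channel's glow forms a
  shallow bowl inside each object (rims sit closer to neighboring
  structures than centers), which biases the mean object Pearson slightly
  below zero rather than exactly to zero — a property real tissue shares;
* co-located pairs share center and radius, and their pixel intensities are
  drawn from a shared latent field plus independent channel noise. The
  mixing weight is solved per object so that the correlation *measured on
  the thresholded object* equals the requested ρ: an analytic
  variance-component solve (edge-profile variance, Poisson, Gaussian and
  quantization noise) seeds the value, a pilot render determines the pixel
  set an automated moments threshold actually selects, and — because the
  realized correlation over a fixed pixel set is linear in the mixing
  weight — one secant step plus three fixed-point corrections land on the
  target. All renders replay one seeded noise stream, so generation remains
  a pure function of the spec;
* the raw FRET channel follows the forward model
  $rawFRET = d \cdot DF + a \cdot AF + S \cdot \mathbb{1}_{pair}$ with an
  additive sensitized-emission amplitude `S` inside co-located objects
  only. Donor quenching is deliberately not modeled: the Youvan/Xia
  arithmetic never uses it, and adding it would only rescale `DF`;
* Poisson shot noise (optional Gaussian read noise), rounding to integer
  codes, and an overexposure model: a ceiling below `2^bit_depth − 1`
  emulates acquiring at gain `(2^bit_depth − 1)/ceiling` — values clip at
  the ceiling and rescale to the full code range, so clipped pixels sit at
  the detector maximum where the saturation audit sees them.

The scenario library fixes five conditions (seeds derived from one base
seed): `distinct_localization` (55 + 55 disjoint objects, ρ = 0, S = 0),
`true_interaction` (100 co-located pairs, ρ = 0.7, S = 150),
`overexposed` (the identical distinct field at ceiling 30 of 4095, ~137×
gain — deep enough that the shared diffuse tissue signal saturates in both
channels, the regime that produces broad false-positive overlap),
and `donor_only` / `acceptor_only` calibration controls (40 objects each,
d = 0.15, a = 0.05, ≥ 10⁴ foreground pixels). Fields are 320 × 320 px —
large enough for ≥ 100 objects per condition, small enough that the whole
validation suite runs in well under a minute.

What the simulator does **not** emulate — and hence what passing tests do
not certify on real data: optical point-spread blurring of the object
boundary itself, chromatic misregistration between channels, spatially
varying illumination, fluorophore photophysics (spectra, quantum yields,
bleaching, lifetimes), 3-D structure projected through the focal volume,
and biologically irregular object shapes. Results on real acquisitions
additionally depend on threshold-method choice, which the package
deliberately leaves explicit.

# Numerical choices and degenerate inputs

* Thresholds compare with strict `>`; masks of constant images are empty
  (with a warning) rather than full.
* Watershed separation lines remove a one-pixel band only where basins
  actually meet; a convex object passes through unchanged. Flooding and
  relabeling are deterministic; repeated runs are byte-identical, which the
  batch runner exploits (same config + seed ⇒ identical concatenated CSV).
* Pearson requires area ≥ 2 and nonzero variance in both channels;
  otherwise `NA`.
* The factor estimators require ≥ 50 usable foreground pixels and clip
  negative fitted slopes to 0 with a warning; factors ≥ 1 warn (a control
  that leaks as much as it emits indicates a mislabeled or contaminated
  control).
* FCS 3.0 export stores float32 little-endian (`$DATATYPE F`), chosen over
  integer storage to preserve negative $FRET_c$ and sub-unit coefficients;
  events with undefined values in a selected column are dropped with a
  warning, since FCS has no missing-value representation. A CSV twin is
  always written.
* Real-valued FRETc/NFRET maps are exported as 32-bit TIFF with an affine
  value mapping (offset/scale) and undefined-pixel indices recorded in a
  JSON sidecar; `read_float_tiff()` inverts the mapping. Precision is
  range/2³², ample for display and downstream thresholding.

# Known limitations

Bleed-through factors are treated as per-run constants (one calibration per
batch); slide-to-slide drift is not modeled. The classifier's color-mix
cutoff is a declared convention, not an inferred boundary. Whole-image and
object Pearson coefficients are both reported, but only the object form is
recommended for inference. The watershed operates in 2-D; z-stacks must be
projected or processed per plane upstream.
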