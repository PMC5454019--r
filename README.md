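# fretcoloc

Object-based colocalization and three-filter (sensitized-emission) FRET
analysis for fluorescence microscopy, in R.

## The problem

Double-immunolabeling microscopy is routinely used to ask whether two
proteins colocalize, but two well-known artifacts make the naive reading of
"yellow overlap" unreliable: detector overexposure saturates both channels
over broad areas and manufactures apparent colocalization, and whole-image
pixel-intensity correlation is inflated by shared background structure even
when the two markers occupy strictly distinct compartments. `fretcoloc`
implements the corrective workflow: segment the stained structures into
objects, compute intensity statistics per object rather than per image, and
pair the colocalization readout with sensitized-emission FRET, which reports
actual molecular proximity (< 10 nm) rather than mere co-occurrence in a
pixel.

The package is aimed at microscopists and image analysts with
donor/acceptor/raw-FRET channel triples (e.g. Alexa-488 / Cy3 confocal
acquisitions of tissue sections) and at methods developers who need a fully
synthetic, ground-truthed test bed for colocalization pipelines.

## The model

With `DF` the donor emission under donor excitation, `AF` the acceptor
emission under acceptor excitation, and `rawFRET` the acceptor emission
under donor excitation, the bleed-through-corrected FRET image (Youvan) is

```
FRETc = rawFRET − d·DF − a·AF
```

where `d` and `a` are the fractions of donor and acceptor fluorescence
leaking into the raw FRET channel, each estimated as a slope through the
origin on a single-stain control. Because FRETc scales with fluorophore
amounts, comparisons across sites use the normalized form (Xia)

```
NFRET = FRETc / sqrt(DF · AF)
```

Objects are found by automated histogram thresholding (moments, Otsu, mean,
triangle, or manual) with one shared method for both channels, split at
necks by a Euclidean-distance-map watershed that leaves one-pixel separation
lines, and combined into union ("either marker") and intersection
("both markers") regions. Each object row carries: area, centroid, mean
channel intensities, mean FRETc and NFRET, the object Pearson correlation of
(DF, AF) pixels, the acceptor:donor ratio, a color-mix coefficient
(per-pixel `min/max` ratio, 1 = complete mix, 0 = single marker), the
colocalization area fraction, and a saturation flag.

## Worked example

No microscope data is needed: the built-in simulator generates seeded
donor/acceptor/rawFRET triples with known ground truth (object geometry,
co-location pairing, pixel-level intensity correlation ρ, true bleed-through
`d`/`a`, true sensitized emission).

```r
library(fretcoloc)
scenarios <- scenario_library(base_seed = 1951)

# calibrate bleed-through from single-stain controls (truth: d = 0.15, a = 0.05)
d_frag <- estimate_donor_factor(generate_scene(scenarios$donor_only)$stack)
a_frag <- estimate_acceptor_factor(generate_scene(scenarios$acceptor_only)$stack)
factors <- combine_factors(d_frag, a_frag)
factors
#> <bleedthrough_factors> d = 0.1505, a = 0.0514 (slope/moments; n = 14027/14223 px)

# a positive-control field: co-localized pairs, rho = 0.7, sensitized emission on
ana <- analyze_triple(generate_scene(scenarios$true_interaction)$stack, factors)
glance(ana)[, c("n_objects", "mean_object_pearson", "mean_nfret", "mean_colormix")]
#> # A tibble: 1 × 4
#>   n_objects mean_object_pearson mean_nfret mean_colormix
#> 1       100               0.698     0.0961         0.897

head(tidy(ana)[, c("object_id", "area_px", "mean_NFRET", "pearson", "label")], 3)
#>   object_id area_px mean_NFRET pearson label
#> 1         1     181     0.0965   0.715 two_colocalizing
#> 2         2     129     0.0929   0.661 two_colocalizing
#> 3         3      92     0.0975   0.723 two_colocalizing

# the negative condition: same imaging, but spatially distinct structures
neg <- analyze_triple(generate_scene(scenarios$distinct_localization)$stack, factors)
glance(neg)[, c("mean_object_pearson", "mean_nfret", "whole_image_pearson")]
#> # A tibble: 1 × 3
#>   mean_object_pearson mean_nfret whole_image_pearson
#> 1             -0.0445    -0.0151              -0.116
```

The recovered factors match the generating truth to the third decimal; the
interacting scene shows object Pearson ≈ 0.7 (the generating ρ) with
clearly positive NFRET, while the distinct scene sits at zero on both axes.
`autoplot(ana)` draws the cytometry-style NFRET-versus-Pearson scatter;
`plot_fretc(ana$fret$fretc)` renders the gain-amplified pseudo-color FRETc
image. `run_batch()` processes a manifest of TIFF triples with one shared
configuration and writes per-image CSVs, a concatenated table, a
classification summary and an FCS 3.0 export for cytometry software
(`write_cytometry()`). A command-line front end with the same verbs lives
in `inst/scripts/fretcoloc`
(`simulate | calibrate | analyze | batch | render`).

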