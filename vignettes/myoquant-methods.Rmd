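---
title: "Color-threshold quantification of myocardial infarct and fibrosis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Color-threshold quantification of myocardial infarct and fibrosis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myoquant)
```

## The problem

After a myocardial infarction, dead muscle is replaced by a collagen-rich
scar. Histological stains give that scar a color distinct from viable
myocardium: Masson's trichrome (MTS) renders collagen blue against red
muscle, picrosirius red (PSR) renders it dominantly red against a paler
counterstain, TTC leaves non-viable tissue off-white against deep-red
living muscle, and H&E — which barely contrasts the infarct natively —
can be made to reveal it with a simple channel transform. `myoquant`
exploits these color differences with purely pixel-wise RGB threshold
rules: no color deconvolution, no texture model, no learned classifier.
The deliberate simplicity is the point — each rule is auditable, its
thresholds are user-adjustable, and its behavior is provable on synthetic
images.

## The stain rules

Every rule is a total function of one pixel's 8-bit `(R, G, B)` values:

* **MTS** — infarct iff `R <= mts_r_max` (default 150) **and**
  `B / max(R, 1) >= mts_br_ratio_min` (default 1.2). The red limit removes
  muscle (exemplar infarct red 41 vs 251 in muscle); the blue/red ratio
  suppresses faintly blue pixels. The `max(R, 1)` divisor guards division
  at `R = 0`; a consequence is that pure black is *not* blue-dominant and
  classifies negative. Dark non-tissue pixels are in any case removed by
  the tissue mask before counting.
* **TTC** — infarct iff the *population* standard deviation (divisor 3) of
  `{R, G, B}` is at most `ttc_std_max` (default 30). Off-white infarct has
  nearly equal channels (exemplar `(133, 136, 134)`, sd ≈ 1.25); viable
  red tissue does not (`(187, 69, 61)`, sd ≈ 57.6). With only three
  channels the choice of population vs sample divisor merely rescales the
  threshold; population was fixed for definiteness. Any gray pixel —
  including white slide background — passes this rule, which is why the
  classification is always restricted to the tissue mask.
* **PSR** — with `mean_GB = (G + B) / 2`, infarct iff `R > mean_GB`
  **and** `R - mean_GB >= psr_thd` (default 50). The conjunction makes
  `psr_thd` an effective user control: the two reference pixels
  (`(240, 129, 143)` margin 104; `(204, 191, 174)` margin 21.5) are
  separable by any `psr_thd` in `(21.5, 104]`. A literal-disjunction
  variant is available behind `psr_literal_or = TRUE`, but under it the
  threshold is inert for every red-dominant pixel.
* **H&E** — a two-step transform precedes thresholding. Step 1 zeroes each
  channel value above `he_channel_cap` (default 200), applied per channel.
  Step 2 keeps only green-dominant pixels: if `R < G` or `B < G` the pixel
  becomes `(0, G, 0)`, otherwise `(0, 0, 0)`. A pixel is then infarct iff
  its surviving green is at least `he_g_min` (default 120, between the
  exemplar infarct green 174 and non-infarct green 99).

Thresholds are defaults, not constants: all are config-exposed
(`stain_config()`, or a flat YAML file via `read_stain_config()`) and every
run record echoes the effective values.

## Tissue masking and post-processing

The whole-section mask is the denominator of every relative quantity. No
mechanism being prescribed for it, the package uses near-white
thresholding: a pixel is tissue iff `min(R, G, B) < white_floor` (default
235), followed by morphological closing (disk radius 3), hole filling and
removal of components under `min_object_px` (default 64). Hole filling
makes pale interior structures — an off-white TTC infarct core, bubbles,
lumina — count in the section denominator; `fill_holes = FALSE` excludes
them instead. The provisional mask is padded with background before the
morphology and cropped back, so the result is invariant both to white
border padding and to tight cropping.

All structuring elements use one fixed disk discretization
(`disk_brush()`): offsets with `dr^2 + dc^2 <= r^2`, so radius 1 is the
5-pixel plus and radius 2 a 13-pixel disk.

The infarct mask is dilated before quantification (default disk radius 2;
radius 0 disables it for sensitivity analysis). The dilation radius is a
package default, not a reported value. Artifacts such as bubbles are
removed by user-supplied exclusion polygons (JSON vertex lists, 0-based
row/col) applied with a boundary-inclusive even-odd rule; exclusion is
deliberately user-directed, not automatic.

## Quantification and serial-section volumes

With square pixels of edge `P` (µm), `n` infarct pixels of `N` section
pixels give relative size `100·n/N` %, infarct area `P²·n` and section
area `P²·N`. For whole-heart volumes each section of thickness `h1`
contributes `A·h1`, and the unsectioned tissue of thickness `h2` removed
after it contributes `A·h2` under the adjacency assumption (the removed
slab shares the neighboring section's areas). Totals are sums over
sections; volumes are reported in mm³ with all µm→mm conversions
centralized in one module. Whether the trailing removed slab after the
final section belongs in the sum is genuinely ambiguous; it is included by
default (uniform formula) with `trailing_gap = FALSE` to drop it — the
*relative* volume percentage is unaffected whenever `h1` and `h2` are
uniform across sections. Percentages are displayed to one decimal; CSV
outputs keep full precision.

## Diffuse fibrosis

`analyze_fibrosis()` applies the identical MTS collagen rule within the
tissue mask and reports `100·|fibrosis|/|tissue|`, with two deliberate
departures from the infarct pipeline: dilation defaults to 0 (dilating
1-px strands would systematically inflate diffuse fractions) and no
minimum-component filter is applied to strands (they are legitimately
tiny; robustness comes from the color rule, not morphology).
`fibrosis_distribution_map()` grids the tissue bounding box and reports
per-cell fractions, making the spatial distribution of fibrosis
assertable rather than merely visible.

## The phantom generator

Synthetic phantoms stand in for tissue scans so that every stage has known
ground truth. A phantom is a 256×256 canvas (the package's standard test
problem size) with:

* near-white background, mean `(250, 250, 250)`;
* a section: ellipse (semi-axes 0.38·W, 0.42·H) with a low-frequency
  radial boundary perturbation (`1 + 0.04·sin(3θ + φ)`);
* an infarct disc, sized by bisection to a target fraction of section
  pixels (realized fraction recorded in metadata, within 0.1 % of target)
  or placed at the section center with an explicit radius so its analytic
  area `πr²` is known;
* optional bubbles — background-colored discs painted into the image only,
  so ground truth is unaffected, as with real mounting artifacts;
* for MTS, optional fibrotic strands: 1-px random walks accumulated until
  a target fraction of tissue pixels is hit;
* independent per-channel Gaussian noise truncated to `[0, 255]`:
  sd 8 for tissue classes, sd 3 for background. Scanned slide background
  is nearly uniform; giving it tissue-level noise would make a white-floor
  background rule unphysically leaky, which no scanner produces.

Class mean colors anchor the documented exemplar pixels of each rule
(e.g. MTS infarct `(41, 80, 190)` carries the exemplar red 41; TTC and PSR
means are the exemplar triplets themselves). Channels not pinned by an
exemplar, and both H&E means — chosen so the post-transform greens are
174 and 99 — are synthetic companions and documented as such.

What the phantoms do **not** emulate: stain texture (fibers, nuclei),
uneven illumination, stain batch variation, compression artifacts, or
partial-volume boundary pixels. Since every rule is pixel-wise, passing on
phantoms demonstrates the algorithmic contract (rules, masking,
arithmetic) — it does not certify segmentation accuracy on real tissue,
where staining quality dominates.

Serial stacks use a quadratic rise-and-fall radius profile
`r_i = r_max·√(w_i)`, `w_i = 1 - x_i²`, giving a closed-form stack volume
`Σ πr_i²·P²·(h1 + h2)` against which recovery is tested (20 sections,
h1 = 5 µm, h2 = 10 µm, within 5 %; the residual error is rasterization
plus the ~0.4 percentage-point noise-induced false-positive rate of the
H&E rule at sd 8).

## Numerical and design choices

* Coordinates are 0-based, row-major, half-open everywhere in the API;
  conversion to R's 1-based indexing happens only internally.
* Slide splitting is horizontal-band only; bands are validated
  (non-overlap, in-range) with offending indices named.
  `suggest_bands()` marks a row as tissue when >1 % of its pixels fall
  under the white floor, merges runs across the smallest gaps down to the
  requested count, and errors (reporting the detected count) when too few
  bands exist.
* All area/volume arithmetic is exact for integer counts; tests assert it
  at floating-point equality, not with loose tolerances.
* PNG is the default interchange format (lossless); JPEG is accepted on
  read only, with a warning.
* Determinism: phantoms are fully determined by their seed; run records
  (JSON) echo every effective parameter plus the package version.

## Limitations

The method inherits the limitations of color thresholding: poorly or
unevenly stained sections weaken the color contrast the rules rely on,
and the H&E transform is unsuited to sparse fibrosis (the non-infarct
region retains scattered green). The tissue mask assumes a near-white
background; dark-field or coverslip-edge artifacts need exclusion
polygons. Volume integration uses the adjacency assumption only — no
stereological corrections.
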