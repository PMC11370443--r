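# myoquant

Color-threshold detection, isolation and quantification of myocardial
infarct and diffuse cardiac fibrosis in scanned histological sections.

## What it does and for whom

After a myocardial infarction the scar stains a different color from
viable myocardium: blue under Masson's trichrome (MTS), dominantly red
under picrosirius red (PSR), off-white under TTC viability staining, and —
after a simple channel transform — green under H&E. `myoquant` turns those
color differences into reproducible numbers for researchers who today
hand-trace infarcts in image-analysis software: per-section infarct
percentage and physical area, whole-heart infarct volume from serial
sections, and diffuse-fibrosis fractions on MTS sections. It also splits
multi-section slide scans into single-section images and generates
synthetic phantoms with known ground truth so every stage of the pipeline
is testable without tissue data.

## The rules at its core

Each stain has a pixel-wise rule on 8-bit `(R, G, B)` values (all
thresholds are user-adjustable defaults):

| Stain | Infarct/collagen rule (defaults) |
|-------|----------------------------------|
| MTS | `R ≤ 150` **and** `B / max(R, 1) ≥ 1.2` |
| TTC | population sd of `{R, G, B}` `≤ 30` |
| PSR | `R > mean(G, B)` **and** `R − mean(G, B) ≥ 50` |
| H&E | two-step transform (cap channels at 200; keep green-dominant pixels as `(0, G, 0)`) then `G ≥ 120` |

Classification is restricted to a whole-section tissue mask
(`min(R, G, B) < 235` plus closing, hole filling and small-object
removal), which is also the denominator of all relative quantities.
Per-section quantities with pixel size `P` (µm): relative size
`100·n_infarct/n_section` %, areas `P²·n`. Whole-heart volumes integrate
serial sections: each section of thickness `h1` contributes `A·h1`, the
removed tissue of thickness `h2` after it contributes `A·h2` with the
adjacent section's areas.

## Worked example

```r
library(myoquant)

# a synthetic MTS section, 25% infarct, realistic channel noise
ph  <- generate_phantom("MTS", infarct_frac = 0.25, seed = 7)
res <- run_infarct(ph$image, stain = "MTS", px_um = 10, dilate_radius = 0)
res
#> infarct: 8230 / 32887 px (25.0%), 0.8230 / 3.2887 mm^2
```

8230 of 32887 tissue pixels classify as infarct — a relative infarct size
of 25.0 %, matching the phantom's ground truth (25.03 %). At 10 µm pixels
that is 0.823 mm² of infarct in a 3.29 mm² section.

```r
# serial-section volume: 20 sections, h1 = 5 um, h2 = 10 um removed between
st <- generate_serial_stack(stain = "HE", n_sections = 20, seed = 7)
rv <- run_volume(st$manifest, images = lapply(st$phantoms, `[[`, "image"),
                 stain = "HE", dilate_radius = 0)
rv
#> heart volumes over 20 sections
#>   infarct: 0.1907 mm^3
#>   tissue:  0.9865 mm^3
#>   relative infarct volume: 19.3%

# diffuse fibrosis on an MTS section with 9.7% strand density
phf <- generate_phantom("MTS", infarct_frac = 0, fibrosis_frac = 0.097,
                        seed = 7)
analyze_fibrosis(phf$image, stain_config("MTS"))
#> fibrosis: 9.7% of 32887 tissue pixels
```

The recovered stack volume is within ~2 % of the closed-form disc-stack
volume the generator encodes, and the fibrosis fraction matches the
constructed strand density to well under 0.1 percentage points.

A command-line front-end (`inst/cli/myoquant.R`) wraps the same functions:

```sh
Rscript inst/cli/myoquant.R infarct --input sec.png --stain MTS --px-um 10 --outdir out/
Rscript inst/cli/myoquant.R split --input slide.png --suggest 5 --outdir out/
Rscript inst/cli/myoquant.R volume --manifest manifest.csv --stain HE --outdir out/
```

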