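test_that("phantom generation is deterministic and hits its target fraction", {
  a <- generate_phantom("MTS", seed = 77)
  b <- generate_phantom("MTS", seed = 77)
  expect_identical(a$image, b$image)
  expect_identical(a$infarct_truth, b$infarct_truth)
  c <- generate_phantom("MTS", seed = 78)
  expect_false(identical(a$image, c$image))
  # realized infarct fraction within 1% of target, and recorded
  for (frac in c(0.1, 0.25, 0.4)) {
    ph <- generate_phantom("PSR", infarct_frac = frac, seed = 5)
    expect_lt(abs(ph$meta$realized_infarct_frac - frac), 0.01)
  }
  expect_true(all(!a$infarct_truth | a$tissue_truth))  # infarct in tissue
})

test_that("zero-noise phantoms are classified pixel-perfectly per stain", {
  for (stain in STAINS) {
    ph <- generate_phantom(stain, noise_sd = 0, bg_noise_sd = 0, seed = 3)
    mask <- classify_image(ph$image, stain_config(stain), ph$tissue_truth)
    expect_identical(mask, ph$infarct_truth, label = stain)
  }
})

test_that("palette means classify as their class under default thresholds", {
  for (stain in STAINS) {
    pal <- phantom_palette(stain)
    cfg <- stain_config(stain)
    img <- array(c(rbind(pal$infarct, pal$normal)), dim = c(2L, 1L, 3L))
    got <- classify_image(img, cfg)
    expect_true(got[1, 1], label = paste(stain, "infarct mean"))
    expect_false(got[2, 1], label = paste(stain, "normal mean"))
  }
})

test_that("fibrosis strand density is realized to within one point", {
  ph <- generate_phantom("MTS", infarct_frac = 0, fibrosis_frac = 0.10,
                         seed = 12)
  expect_lt(abs(ph$meta$realized_fibrosis_frac - 0.10), 0.01)
  expect_true(all(!ph$fibrosis_truth | ph$tissue_truth))
  expect_error(generate_phantom("TTC", fibrosis_frac = 0.1), "MTS")
})

test_that("serial stacks carry analytic areas matching their rasters", {
  st <- generate_serial_stack(n_sections = 6, noise_sd = 0, seed = 9)
  expect_equal(nrow(st$manifest), 6L)
  raster_px <- vapply(st$phantoms, function(p) sum(p$infarct_truth),
                      numeric(1))
  # analytic disc area vs rasterized count (px_um = 10)
  nonzero <- st$analytic_infarct_area_um2 > 0
  expect_equal(raster_px[nonzero] * 100,
               st$analytic_infarct_area_um2[nonzero], tolerance = 0.02)
  # constant profile: closed-form total volume k * A * (h1 + h2)
  stc <- generate_serial_stack(n_sections = 4, profile = rep(0.5, 4),
                               noise_sd = 0, seed = 9)
  man <- data.frame(infarct_area_um2 = vapply(stc$phantoms, function(p)
                      sum(p$infarct_truth) * 100, numeric(1)),
                    section_area_um2 = vapply(stc$phantoms, function(p)
                      sum(p$tissue_truth) * 100, numeric(1)),
                    h1_um = stc$manifest$h1_um, h2_um = stc$manifest$h2_um)
  hv <- heart_volumes(man)
  expect_equal(hv$v_infarct_mm3,
               4 * man$infarct_area_um2[1] * 15 / 1e9, tolerance = 1e-3)
  # single-section stack
  st1 <- generate_serial_stack(n_sections = 1, seed = 2)
  expect_equal(nrow(st1$manifest), 1L)
})

test_that("rise-and-fall profile gives unimodal ground-truth percentages", {
  st <- generate_serial_stack(n_sections = 12, noise_sd = 0, seed = 14)
  pct <- vapply(st$phantoms, function(p)
    100 * sum(p$infarct_truth) / sum(p$tissue_truth), numeric(1))
  peak <- which.max(pct)
  expect_true(all(diff(pct[1:peak]) >= 0))
  expect_true(all(diff(pct[peak:length(pct)]) <= 0))
})

test_that("phantom input validation rejects impossible specs", {
  expect_error(generate_phantom("MTS", infarct_frac = 1.2), "infarct_frac")
  expect_error(generate_phantom("ZZZ"), "unknown stain")
  expect_error(generate_phantom("MTS", bubbles = list(c(1, 2))), "bubble")
})
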