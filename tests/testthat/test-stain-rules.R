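# The exemplar pixel values used here are the documented per-stain
# reference colors for infarct and non-infarct tissue.

cfg_for <- function(stain) stain_config(stain)

test_that("exemplar pixels classify as documented under default thresholds", {
  # MTS: infarct R = 41 passes the R limit, non-infarct R = 251 fails it
  expect_true(classify_mts(c(41, 80, 190), cfg_for("MTS")))
  expect_false(classify_mts(c(251, 120, 130), cfg_for("MTS")))
  # TTC: near-equal channels (pop. sd ~1.25) vs red-dominant (sd ~57.6)
  expect_true(classify_ttc(c(133, 136, 134), cfg_for("TTC")))
  expect_false(classify_ttc(c(187, 69, 61), cfg_for("TTC")))
  # PSR: margin over mean(G,B) is 104 vs 21.5 against thd = 50
  expect_true(classify_psr(c(240, 129, 143), cfg_for("PSR")))
  expect_false(classify_psr(c(204, 191, 174), cfg_for("PSR")))
  # H&E: post-transform G = 174 survives, G = 99 is removed
  expect_true(classify_he(c(0, 174, 0), cfg_for("HE")))
  expect_false(classify_he(c(0, 99, 0), cfg_for("HE")))
})

test_that("TTC uses the population standard deviation (divisor 3)", {
  # hand-computed: mean 134.333..., pop. sd = sqrt(14/3)/sqrt(3) = 1.2472
  m <- mean(c(133, 136, 134))
  s <- sqrt(sum((c(133, 136, 134) - m)^2) / 3)
  expect_equal(s, 1.247219, tolerance = 1e-6)
  expect_true(classify_ttc(c(133, 136, 134), stain_config("TTC",
                                                          ttc_std_max = s)))
  expect_false(classify_ttc(c(133, 136, 134),
                            stain_config("TTC", ttc_std_max = s - 0.01)))
  # zero-variance gray pixel always passes: tissue mask must gate it
  expect_true(classify_ttc(c(200, 200, 200), cfg_for("TTC")))
})

test_that("MTS guards division at R = 0 and keeps the ratio inclusive", {
  # pure black: guarded ratio 0/1 fails blue dominance -> not infarct;
  # dark non-blue pixels are still gated by the tissue mask in pipelines
  expect_false(classify_mts(c(0, 0, 0), cfg_for("MTS")))
  expect_true(classify_mts(c(0, 0, 255), cfg_for("MTS")))
  # ratio bound is inclusive and uses B / max(R, 1)
  expect_true(classify_mts(c(100, 0, 120), cfg_for("MTS")))   # 1.2 exactly
  expect_false(classify_mts(c(100, 0, 119), cfg_for("MTS")))
})

test_that("PSR conjunction makes thd effective; literal OR is available", {
  cfg <- cfg_for("PSR")
  expect_false(classify_psr(c(100, 100, 100), cfg))   # margin 0, not R > mgb
  expect_false(classify_psr(c(150, 120, 120), cfg))   # margin 30 < 50
  expect_true(classify_psr(c(171, 120, 120), cfg))    # margin 51
  cfg_or <- stain_config("PSR", psr_literal_or = TRUE)
  expect_true(classify_psr(c(150, 120, 120), cfg_or)) # R > mgb suffices
  # the separating window between the two exemplars: thd in (21.5, 104]
  for (thd in c(22, 60, 104)) {
    c2 <- stain_config("PSR", psr_thd = thd)
    expect_true(classify_psr(c(240, 129, 143), c2))
    expect_false(classify_psr(c(204, 191, 174), c2))
  }
})

test_that("transform_he implements the two steps and its output invariant", {
  cfg <- cfg_for("HE")
  img <- array(0L, dim = c(2L, 2L, 3L))
  img[1, 1, ] <- c(220L, 174L, 140L)   # R capped, green-dominant -> (0,174,0)
  img[1, 2, ] <- c(230L, 99L, 180L)    # -> (0,99,0), below he_g_min
  img[2, 1, ] <- c(120L, 99L, 110L)    # R,B >= G after cap -> all zero
  out <- transform_he(img, cfg)
  expect_equal(out[1, 1, ], c(0L, 174L, 0L))
  expect_equal(out[1, 2, ], c(0L, 99L, 0L))
  expect_equal(out[2, 1, ], c(0L, 0L, 0L))
  expect_equal(out[2, 2, ], c(0L, 0L, 0L))   # all-zero fixed point
  # every output pixel is (0, g, 0)
  rnd <- random_rgb(32, 32, 7)
  t2 <- transform_he(rnd, cfg)
  expect_true(all(t2[, , 1] == 0) && all(t2[, , 3] == 0))
})

test_that("classify_image applies the stain rule within the tissue mask", {
  ph <- generate_phantom("PSR", canvas = c(96L, 96L), seed = 9)
  cfg <- cfg_for("PSR")
  all_false <- matrix(FALSE, 96, 96)
  expect_equal(classify_image(ph$image, cfg, all_false), all_false)
  mask <- classify_image(ph$image, cfg, ph$tissue_truth)
  expect_true(all(!mask | ph$tissue_truth))   # mask subset of tissue
  # uniform infarct-palette image with all-true tissue -> all true
  uni <- array(rep(c(240L, 129L, 143L), each = 4L), dim = c(2L, 2L, 3L))
  expect_true(all(classify_image(uni, cfg)))
  expect_error(classify_image(ph$image, structure(list(stain = "XX"),
                                                  class = "stain_config")),
               "unknown stain")
})

test_that("vectorized rules agree bit-exactly with the per-pixel oracle", {
  for (stain in STAINS) {
    cfg <- cfg_for(stain)
    for (seed in 1:3) {
      img <- random_rgb(48, 48, seed * 100 + match(stain, STAINS))
      expect_identical(classify_image(img, cfg), naive_classify(img, cfg),
                       label = sprintf("%s seed %d", stain, seed))
    }
  }
})

test_that("relaxing a permissive threshold never shrinks the mask", {
  phs <- lapply(STAINS, function(s)
    generate_phantom(s, canvas = c(96L, 96L), seed = 21))
  names(phs) <- STAINS
  sweep <- list(
    MTS = lapply(seq(110, 230, length.out = 4),
                 function(v) stain_config("MTS", mts_r_max = v)),
    TTC = lapply(seq(10, 80, length.out = 4),
                 function(v) stain_config("TTC", ttc_std_max = v)),
    PSR = lapply(seq(80, 20, length.out = 4),
                 function(v) stain_config("PSR", psr_thd = v)),
    HE  = lapply(seq(170, 80, length.out = 4),
                 function(v) stain_config("HE", he_g_min = v)))
  for (stain in STAINS) {
    prev <- NULL
    for (cfg in sweep[[stain]]) {
      m <- classify_image(phs[[stain]]$image, cfg, phs[[stain]]$tissue_truth)
      if (!is.null(prev))
        expect_true(all(m[prev]), label = sprintf("%s nesting", stain))
      prev <- m
    }
  }
})
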