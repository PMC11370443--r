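test_that("crop_roi is pixel-exact and keeps the re-embedding offset", {
  ph <- generate_phantom("MTS", canvas = c(64L, 64L), seed = 3)
  full <- crop_roi(ph$image, c(0, 64, 0, 64))
  expect_equal(as.vector(full), as.vector(ph$image))
  # rectangle bounding the ground-truth infarct keeps every infarct pixel
  rows <- range(which(rowSums(ph$infarct_truth) > 0))
  cols <- range(which(colSums(ph$infarct_truth) > 0))
  rect <- c(rows[1] - 1, rows[2], cols[1] - 1, cols[2])
  crop <- crop_roi(ph$image, rect)
  expect_equal(attr(crop, "offset"),
               c(top = rows[1] - 1, left = cols[1] - 1))
  expect_equal(sum(ph$infarct_truth[rows[1]:rows[2], cols[1]:cols[2]]),
               sum(ph$infarct_truth))
  expect_error(crop_roi(ph$image, c(5, 5, 0, 10)), "invalid rectangle")
  expect_error(crop_roi(ph$image, c(0, 80, 0, 10)), "invalid rectangle")
})

test_that("dilate_mask uses the documented disk and behaves monotonically", {
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  expect_identical(dilate_mask(m, 0), m)
  plus <- matrix(FALSE, 5, 5)
  plus[3, 2:4] <- TRUE; plus[2:4, 3] <- TRUE
  expect_identical(dilate_mask(m, 1), plus)       # 5-pixel plus
  expect_equal(sum(disk_brush(2)), 13)            # radius-2 disk
  # extensivity and growth in radius on a random mask
  set.seed(5)
  rnd <- matrix(runif(400) < 0.1, 20, 20)
  prev <- rnd
  for (r in 0:3) {
    d <- dilate_mask(rnd, r)
    expect_true(all(d[rnd]))
    expect_true(all(d[prev]))
    prev <- d
  }
})

test_that("dilation commutes with mask translation", {
  m <- matrix(FALSE, 30, 30); m[10:12, 8:9] <- TRUE; m[20, 20] <- TRUE
  shift <- function(x, dr, dc) {
    out <- matrix(FALSE, nrow(x), ncol(x))
    out[(1 + dr):nrow(x), (1 + dc):ncol(x)] <-
      x[1:(nrow(x) - dr), 1:(ncol(x) - dc)]
    out
  }
  expect_identical(dilate_mask(shift(m, 3, 4), 2),
                   shift(dilate_mask(m, 2), 3, 4))
})

test_that("exclusion polygons clear their interior, idempotently", {
  mask <- matrix(TRUE, 20, 20)
  expect_identical(apply_exclusions(mask, list()), mask)
  whole <- list(rbind(c(0, 0), c(0, 19), c(19, 19), c(19, 0)))
  expect_false(any(apply_exclusions(mask, whole)))
  tri <- list(rbind(c(2, 2), c(2, 10), c(10, 2)))
  once <- apply_exclusions(mask, tri)
  expect_identical(apply_exclusions(once, tri), once)        # idempotent
  expect_false(once[3, 3])   # interior cleared
  expect_false(once[3, 10])  # boundary vertex row: on-edge counts inside
  expect_true(once[11, 11])  # outside untouched
  # order independence over two polygons
  sq <- list(rbind(c(12, 12), c(12, 16), c(16, 16), c(16, 12)))
  expect_identical(apply_exclusions(mask, c(tri, sq)),
                   apply_exclusions(mask, c(sq, tri)))
  expect_error(apply_exclusions(mask, list(rbind(c(0, 0), c(1, 1)))),
               "polygon 1")
})

test_that("even-odd interior agrees with an independent point-in-polygon", {
  skip_if_not_installed("pracma")
  set.seed(13)
  verts <- rbind(c(3, 2), c(1, 10), c(8, 16), c(14, 9), c(11, 3))
  mask <- matrix(TRUE, 18, 18)
  cleared <- !apply_exclusions(mask, list(verts))
  pts <- expand.grid(r = 0:17, c = 0:17)
  ref <- pracma::inpolygon(pts$c, pts$r, verts[, 2], verts[, 1],
                           boundary = TRUE)
  expect_identical(as.vector(cleared), as.vector(matrix(ref, 18, 18)))
})

test_that("bubble exclusion restores the TTC infarct fraction", {
  # a bubble is off-white like TTC infarct: it is misclassified until the
  # user excludes it with a polygon
  ph <- generate_phantom("TTC", bubbles = list(c(60, 60, 6)), seed = 15)
  cfg <- stain_config("TTC")
  tissue <- make_tissue_mask(ph$image)
  mask <- classify_image(ph$image, cfg, tissue)
  pct_with_bubble <- 100 * sum(mask) / sum(tissue)
  truth_pct <- 100 * ph$meta$realized_infarct_frac
  expect_gt(pct_with_bubble, truth_pct + 0.1)
  poly <- list(rbind(c(52, 52), c(52, 68), c(68, 68), c(68, 52)))
  pct_fixed <- 100 * sum(apply_exclusions(mask, poly)) / sum(tissue)
  expect_lt(abs(pct_fixed - truth_pct), 0.5)
})

test_that("render_overlay paints a deterministic counting-friendly figure", {
  ph <- generate_phantom("MTS", canvas = c(64L, 64L), seed = 2)
  tissue <- ph$tissue_truth
  infarct <- ph$infarct_truth
  ov <- render_overlay(ph$image, infarct, tissue)
  white <- ov[, , 1] == 255L & ov[, , 2] == 255L & ov[, , 3] == 255L
  expect_identical(white, infarct)
  # empty infarct -> no white pixels at all
  ov0 <- render_overlay(ph$image, matrix(FALSE, 64, 64), tissue)
  expect_equal(sum(ov0 == 255L), 0)
  # all-tissue infarct -> tissue entirely white
  ov1 <- render_overlay(ph$image, tissue, tissue)
  w1 <- ov1[, , 1] == 255L & ov1[, , 2] == 255L & ov1[, , 3] == 255L
  expect_identical(w1, tissue)
})

test_that("exclusion JSON files round-trip", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines(
    '[{"label":"bubble1","vertices":[[2,2],[2,8],[8,8],[8,2]]}]', path)
  excl <- read_exclusions(path)
  expect_named(excl, "bubble1")
  expect_equal(dim(excl$bubble1), c(4L, 2L))
  mask <- matrix(TRUE, 12, 12)
  out <- apply_exclusions(mask, excl)
  expect_false(out[5, 5])
  expect_true(out[11, 11])
  expect_error(read_exclusions("missing.json"), "missing.json")
})
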