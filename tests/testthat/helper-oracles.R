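# Independent reference implementations used as oracles: straightforward
# per-pixel double loops, kept deliberately separate from the vectorized
# production code paths.

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

naive_rule_pixel <- function(stain, r, g, b, cfg) {
  switch(stain,
    MTS = {
      div <- if (r == 0) 1 else r
      r <= cfg$mts_r_max && (b / div) >= cfg$mts_br_ratio_min
    },
    TTC = {
      m <- (r + g + b) / 3
      s <- sqrt(((r - m)^2 + (g - m)^2 + (b - m)^2) / 3)
      s <= cfg$ttc_std_max
    },
    PSR = {
      mgb <- (g + b) / 2
      r > mgb && (r - mgb) >= cfg$psr_thd
    },
    HE = {
      # two-step transform then green threshold, scalar arithmetic
      if (r > cfg$he_channel_cap) r <- 0
      if (g > cfg$he_channel_cap) g <- 0
      if (b > cfg$he_channel_cap) b <- 0
      g2 <- if (r < g || b < g) g else 0
      g2 >= cfg$he_g_min
    })
}

naive_classify <- function(img, cfg) {
  h <- dim(img)[1]; w <- dim(img)[2]
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h))
    for (j in seq_len(w))
      out[i, j] <- naive_rule_pixel(cfg$stain, img[i, j, 1], img[i, j, 2],
                                    img[i, j, 3], cfg)
  out
}

random_rgb <- function(h, w, seed) {
  set.seed(seed)
  arr <- array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
  storage.mode(arr) <- "integer"
  arr
}

# A multi-section slide: zero-noise phantom sections stacked vertically
# with white gaps. Returns the slide image and the 0-based half-open row
# intervals actually containing tissue.
make_slide <- function(n_sections, gap = 24L, stain = "MTS", seed = 1L) {
  phs <- lapply(seq_len(n_sections), function(i)
    generate_phantom(stain, canvas = c(80L, 120L), noise_sd = 0,
                     bg_noise_sd = 0, seed = seed + i))
  white <- array(250L, dim = c(gap, 120L, 3L))
  pieces <- list(white)
  truth <- vector("list", n_sections)
  offset <- gap
  for (i in seq_len(n_sections)) {
    pieces <- c(pieces, list(phs[[i]]$image), list(white))
    rows <- range(which(rowSums(phs[[i]]$tissue_truth) > 0))
    truth[[i]] <- c(offset + rows[1] - 1L, offset + rows[2])  # 0-based HO
    offset <- offset + 80L + gap
  }
  slide <- do.call(abind_rows, pieces)
  list(image = slide, tissue_rows = truth, phantoms = phs,
       band_starts = seq(gap, by = 80L + gap, length.out = n_sections))
}

# rbind for H x W x 3 arrays
abind_rows <- function(...) {
  parts <- list(...)
  w <- dim(parts[[1]])[2]
  h <- sum(vapply(parts, function(p) dim(p)[1], numeric(1)))
  out <- array(0L, dim = c(h, w, 3L))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  storage.mode(out) <- "integer"
  out
}
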