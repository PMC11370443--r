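# Stain-specific per-pixel infarct rules. Each rule is a pure function of
# one pixel's 8-bit (R, G, B) values; classify_image() applies it to every
# pixel of an image, restricted to a tissue mask. All rules operate in raw
# RGB; no color-space conversion is performed.

# Accept a length-3 pixel or an n x 3 matrix; return an n x 3 matrix.
as_pixel_matrix <- function(pixel) {
  if (is.null(dim(pixel))) {
    if (length(pixel) != 3L)
      stop("'pixel' must be (R, G, B) or an n x 3 matrix", call. = FALSE)
    pixel <- matrix(pixel, ncol = 3L)
  }
  if (ncol(pixel) != 3L)
    stop("'pixel' must have 3 columns (R, G, B)", call. = FALSE)
  if (anyNA(pixel) || min(pixel) < 0 || max(pixel) > 255)
    stop("channel values must be in [0, 255]", call. = FALSE)
  pixel
}

# Rule workhorses on channel vectors/matrices (R, G, B same shape).

rule_mts <- function(R, G, B, cfg) {
  R <= cfg$mts_r_max & B / pmax(R, 1) >= cfg$mts_br_ratio_min
}

rule_ttc <- function(R, G, B, cfg) {
  mu <- (R + G + B) / 3
  s <- sqrt(((R - mu)^2 + (G - mu)^2 + (B - mu)^2) / 3)   # population sd
  s <= cfg$ttc_std_max
}

rule_psr <- function(R, G, B, cfg) {
  mgb <- (G + B) / 2
  if (cfg$psr_literal_or)
    R > mgb | (R - mgb) >= cfg$psr_thd
  else
    R > mgb & (R - mgb) >= cfg$psr_thd
}

#' Classify Masson's-trichrome pixels as infarct/collagen
#'
#' A pixel is infarct when `R <= mts_r_max` and `B / max(R, 1) >= `
#' `mts_br_ratio_min`: scar collagen stains blue (low red, blue-dominant),
#' muscle red. The `max(R, 1)` divisor guards `R = 0`; pure black therefore
#' classifies as infarct, so background/non-tissue pixels must be excluded
#' by the tissue mask before counting (see [classify_image()]).
#'
#' @param pixel `(R, G, B)` vector or `n x 3` matrix of 8-bit values
#' @param cfg a [stain_config()]
#' @return logical, `TRUE` for infarct
#' @export
classify_mts <- function(pixel, cfg) {
  p <- as_pixel_matrix(pixel)
  unname(rule_mts(p[, 1], p[, 2], p[, 3], cfg))
}

#' Classify TTC pixels as infarct
#'
#' TTC leaves infarct off-white (R, G, B nearly equal) while viable tissue
#' turns deep red; a pixel is infarct when the population standard deviation
#' (divisor 3) of its three channel values is at most `ttc_std_max`. Any
#' gray pixel has zero deviation, so the near-white slide background must be
#' excluded by the tissue mask.
#'
#' @inheritParams classify_mts
#' @return logical, `TRUE` for infarct
#' @export
classify_ttc <- function(pixel, cfg) {
  p <- as_pixel_matrix(pixel)
  unname(rule_ttc(p[, 1], p[, 2], p[, 3], cfg))
}

#' Classify picrosirius-red pixels as infarct/collagen
#'
#' Collagen stains a dominant red: with `mean_GB = (G + B) / 2`, a pixel is
#' infarct when `R > mean_GB` and `R - mean_GB >= psr_thd`. Setting
#' `psr_literal_or = TRUE` in the config switches the conjunction to a
#' disjunction, under which `psr_thd` only matters for pixels whose red
#' does not already dominate.
#'
#' @inheritParams classify_mts
#' @return logical, `TRUE` for infarct
#' @export
classify_psr <- function(pixel, cfg) {
  p <- as_pixel_matrix(pixel)
  unname(rule_psr(p[, 1], p[, 2], p[, 3], cfg))
}

#' Two-step green-revealing transform for H&E images
#'
#' H&E gives the infarct little native contrast; this transform reveals it.
#' Step 1 zeroes, independently in each channel, every value exceeding
#' `he_channel_cap`. Step 2 keeps only green-dominant pixels: if `R < G` or
#' `B < G` the pixel becomes `(0, G, 0)`, otherwise `(0, 0, 0)`. Every
#' output pixel is therefore `(0, g, 0)` or all-zero.
#'
#' @param img `H x W x 3` image array
#' @param cfg a [stain_config()]
#' @return transformed image array of the same shape
#' @export
transform_he <- function(img, cfg) {
  check_rgb(img)
  img[img > cfg$he_channel_cap] <- 0L          # step 1, per channel
  R <- channel(img, 1); G <- channel(img, 2); B <- channel(img, 3)
  keep <- R < G | B < G                        # step 2
  out <- array(0L, dim = dim(img))
  g <- G
  g[!keep] <- 0L
  out[, , 2] <- g
  out
}

#' Classify post-transform H&E pixels as infarct
#'
#' Applied to [transform_he()] output: a pixel is infarct when its surviving
#' green value satisfies `G >= he_g_min` (inclusive).
#'
#' @inheritParams classify_mts
#' @return logical, `TRUE` for infarct
#' @export
classify_he <- function(pixel, cfg) {
  p <- as_pixel_matrix(pixel)
  unname(p[, 2] >= cfg$he_g_min)
}

#' Classify every pixel of an image with the stain-appropriate rule
#'
#' Applies the per-pixel rule for `cfg$stain` (for H&E, [transform_he()]
#' followed by the green threshold) and restricts the result to the tissue
#' mask: non-tissue pixels are always `FALSE`, so the returned mask is a
#' subset of `tissue`.
#'
#' @param img `H x W x 3` image array
#' @param cfg a [stain_config()]
#' @param tissue `H x W` logical tissue mask (default: all pixels)
#' @return `H x W` logical infarct mask
#' @export
classify_image <- function(img, cfg, tissue = NULL) {
  check_rgb(img)
  if (!inherits(cfg, "stain_config"))
    stop("'cfg' must be a stain_config", call. = FALSE)
  if (is.null(tissue)) tissue <- matrix(TRUE, dim(img)[1], dim(img)[2])
  check_mask(tissue, "tissue")
  check_same_shape(img, tissue, c("img", "tissue"))
  R <- channel(img, 1); G <- channel(img, 2); B <- channel(img, 3)
  raw <- switch(cfg$stain,
    MTS = rule_mts(R, G, B, cfg),
    TTC = rule_ttc(R, G, B, cfg),
    PSR = rule_psr(R, G, B, cfg),
    HE  = channel(transform_he(img, cfg), 2) >= cfg$he_g_min,
    stop(sprintf("unknown stain '%s'", cfg$stain), call. = FALSE)
  )
  mask <- matrix(raw, dim(img)[1], dim(img)[2])
  mask & tissue
}
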