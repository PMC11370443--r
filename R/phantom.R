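# Synthetic stained-section phantoms with known ground truth.
#
# A phantom is a near-white slide background carrying one tissue section
# (a boundary-perturbed ellipse), a contiguous infarct region (a disc
# intersected with the section), optional bubbles (background-colored holes
# in the image, not in the ground truth) and, for MTS, sparse fibrotic
# strands. Per-class mean colors come from the stain palettes below; each
# channel gets independent additive Gaussian noise, truncated to [0, 255].

#' Default per-class color palettes for each stain
#'
#' The infarct and normal means anchor the documented exemplar pixels of
#' each stain rule: MTS infarct R = 41 vs normal R = 251; TTC
#' (133, 136, 134) vs (187, 69, 61); PSR (240, 129, 143) vs
#' (204, 191, 174). Channels not pinned by an exemplar, and both H&E means
#' — chosen so that the post-transform green values are the exemplar 174
#' (infarct) and 99 (normal) — are synthetic companions. The background is
#' near-white slide.
#'
#' @param stain one of `"MTS"`, `"HE"`, `"TTC"`, `"PSR"`
#' @return list with numeric `(R, G, B)` means `infarct`, `normal`,
#'   `background`
#' @export
phantom_palette <- function(stain) {
  pal <- switch(stain,
    MTS = list(infarct = c(41, 80, 190),  normal = c(251, 120, 130)),
    TTC = list(infarct = c(133, 136, 134), normal = c(187, 69, 61)),
    PSR = list(infarct = c(240, 129, 143), normal = c(204, 191, 174)),
    HE  = list(infarct = c(220, 174, 140), normal = c(230, 99, 180)),
    stop(sprintf("unknown stain '%s'", stain), call. = FALSE))
  pal$background <- c(250, 250, 250)
  pal
}

# Rasterize the boundary-perturbed ellipse section on a 0-based pixel grid.
raster_section <- function(canvas, perturb_amp, phase) {
  h <- canvas[1]; w <- canvas[2]
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  b <- 0.42 * h; a <- 0.38 * w
  row <- matrix(0:(h - 1), h, w)
  col <- matrix(0:(w - 1), h, w, byrow = TRUE)
  yy <- (row - cy) / b; xx <- (col - cx) / a
  rho <- sqrt(yy^2 + xx^2)
  theta <- atan2(yy, xx)
  rho <= 1 + perturb_amp * sin(3 * theta + phase)
}

# Squared distance of every pixel center to (r0, c0), 0-based.
raster_dist2 <- function(canvas, r0, c0) {
  h <- canvas[1]; w <- canvas[2]
  row <- matrix(0:(h - 1), h, w)
  col <- matrix(0:(w - 1), h, w, byrow = TRUE)
  (row - r0)^2 + (col - c0)^2
}

# Find the disc radius whose intersection with the section covers the
# target fraction of section pixels (monotone in radius -> bisection).
solve_infarct_radius <- function(d2, section, frac, tol = 5e-4) {
  n_t <- sum(section)
  lo <- 0; hi <- sqrt(max(d2)) + 1
  for (i in 1:50) {
    mid <- (lo + hi) / 2
    f <- sum(d2 <= mid^2 & section) / n_t
    if (abs(f - frac) < tol) return(mid)
    if (f < frac) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Sparse fibrotic strands: 1-px random walks confined to the tissue mask,
# accumulated until the target pixel fraction is reached.
raster_strands <- function(tissue, target_frac) {
  h <- nrow(tissue); w <- ncol(tissue)
  strand <- matrix(FALSE, h, w)
  target <- round(target_frac * sum(tissue))
  if (target <= 0) return(strand)
  idx <- which(tissue)
  npix <- 0L
  guard <- 0L
  while (npix < target && guard < 50000L) {
    guard <- guard + 1L
    start <- if (length(idx) > 1L) sample(idx, 1L) else idx
    r <- (start - 1L) %% h + 1L
    c <- (start - 1L) %/% h + 1L
    theta <- runif(1, 0, 2 * pi)
    len <- sample(20:60, 1L)
    rr <- r; cc <- c
    for (s in seq_len(len)) {
      rr <- rr + sin(theta); cc <- cc + cos(theta)
      theta <- theta + rnorm(1, 0, 0.25)
      ri <- round(rr); ci <- round(cc)
      if (ri < 1 || ri > h || ci < 1 || ci > w || !tissue[ri, ci]) break
      if (!strand[ri, ci]) {
        strand[ri, ci] <- TRUE
        npix <- npix + 1L
      }
      if (npix >= target) break
    }
  }
  strand
}

#' Generate a synthetic stained-section phantom
#'
#' Deterministic given `seed`. The section is a boundary-perturbed ellipse
#' on a near-white background; the infarct is a disc (intersected with the
#' section) sized either to a target area fraction of the section
#' (`infarct_frac`, solved by bisection) or to an explicit radius in pixels
#' (`infarct_radius`, placed at the section center so its analytic area
#' `pi * r^2` is known). Bubbles are background-colored discs painted into
#' the image only — the ground-truth masks are unaffected, mimicking real
#' mounting artifacts. For MTS, `fibrosis_frac > 0` adds sparse 1-px
#' fibrotic strands painted in the infarct (collagen) palette.
#'
#' Noise is independent per-channel additive Gaussian, truncated to
#' `[0, 255]`: `noise_sd` for the tissue classes and `bg_noise_sd` for the
#' slide background (scanned slide background is nearly uniform, so its
#' default is smaller).
#'
#' @param stain one of `"MTS"`, `"HE"`, `"TTC"`, `"PSR"`
#' @param canvas `(H, W)` canvas size in pixels (default `c(256, 256)`)
#' @param infarct_frac target infarct area fraction of the section, in
#'   `[0, 1)` (default 0.25); ignored when `infarct_radius` is given
#' @param infarct_radius optional explicit infarct disc radius in pixels
#' @param noise_sd tissue-class channel noise sd (default 8)
#' @param bg_noise_sd background channel noise sd (default 3)
#' @param bubbles list of `c(row, col, radius)` background-colored discs
#' @param fibrosis_frac target fibrotic-strand fraction of the section
#'   (MTS only, default 0)
#' @param perturb_amp section boundary perturbation amplitude (default 0.04)
#' @param palettes optional palette list overriding [phantom_palette()]
#' @param seed integer RNG seed (default 1)
#' @return object of class `phantom`: list with `image` (`H x W x 3`
#'   integer array), `tissue_truth`, `infarct_truth`, `fibrosis_truth`
#'   (logical matrices) and `meta` (spec echo plus realized fractions)
#' @export
generate_phantom <- function(stain,
                             canvas = c(256L, 256L),
                             infarct_frac = 0.25,
                             infarct_radius = NULL,
                             noise_sd = 8,
                             bg_noise_sd = 3,
                             bubbles = list(),
                             fibrosis_frac = 0,
                             perturb_amp = 0.04,
                             palettes = NULL,
                             seed = 1L) {
  if (!stain %in% STAINS)
    stop(sprintf("unknown stain '%s'", stain), call. = FALSE)
  if (infarct_frac < 0 || infarct_frac >= 1)
    stop("'infarct_frac' must be in [0, 1)", call. = FALSE)
  if (fibrosis_frac < 0 || fibrosis_frac >= 1)
    stop("'fibrosis_frac' must be in [0, 1)", call. = FALSE)
  if (fibrosis_frac > 0 && stain != "MTS")
    stop("fibrotic strands are generated for MTS phantoms only",
         call. = FALSE)
  pal <- if (is.null(palettes)) phantom_palette(stain) else palettes
  set.seed(seed)

  h <- canvas[1]; w <- canvas[2]
  phase <- runif(1, 0, 2 * pi)
  section <- raster_section(canvas, perturb_amp, phase)
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  a <- 0.38 * w

  if (!is.null(infarct_radius)) {
    r0 <- cy; c0 <- cx                   # centered: analytic area holds
    radius <- infarct_radius
  } else {
    r0 <- cy; c0 <- cx + 0.2 * a         # offset regional infarct
    radius <- if (infarct_frac > 0) {
      solve_infarct_radius(raster_dist2(canvas, r0, c0), section,
                           infarct_frac)
    } else 0
  }
  infarct <- if (radius > 0)
    raster_dist2(canvas, r0, c0) <= radius^2 & section
  else matrix(FALSE, h, w)

  fibrosis <- if (fibrosis_frac > 0)
    raster_strands(section & !infarct, fibrosis_frac)
  else matrix(FALSE, h, w)

  # class map: 0 background, 1 normal tissue, 2 infarct/collagen
  cls <- matrix(0L, h, w)
  cls[section] <- 1L
  cls[infarct | fibrosis] <- 2L
  for (b in bubbles) {
    if (length(b) != 3L)
      stop("each bubble must be c(row, col, radius)", call. = FALSE)
    cls[raster_dist2(canvas, b[1], b[2]) <= b[3]^2] <- 0L
  }

  means <- rbind(pal$background, pal$normal, pal$infarct)
  sds <- c(bg_noise_sd, noise_sd, noise_sd)
  img <- array(0L, dim = c(h, w, 3L))
  for (ch in 1:3) {
    mu <- means[cls + 1L, ch]
    sd <- sds[cls + 1L]
    img[, , ch] <- clip8(matrix(mu + rnorm(h * w, 0, sd), h, w))
  }
  storage.mode(img) <- "integer"

  meta <- list(stain = stain, canvas = canvas, seed = seed,
               noise_sd = noise_sd, bg_noise_sd = bg_noise_sd,
               perturb_amp = perturb_amp,
               infarct_radius = radius,
               infarct_center = c(row = r0, col = c0),
               target_infarct_frac =
                 if (is.null(infarct_radius)) infarct_frac else NA_real_,
               realized_infarct_frac = sum(infarct) / sum(section),
               target_fibrosis_frac = fibrosis_frac,
               realized_fibrosis_frac = sum(fibrosis) / sum(section),
               n_bubbles = length(bubbles))
  structure(list(image = img, tissue_truth = section,
                 infarct_truth = infarct, fibrosis_truth = fibrosis,
                 meta = meta),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  m <- x$meta
  cat(sprintf("%s phantom %dx%d, infarct %.1f%%, fibrosis %.1f%% (seed %d)\n",
              m$stain, m$canvas[1], m$canvas[2],
              100 * m$realized_infarct_frac,
              100 * m$realized_fibrosis_frac, m$seed))
  invisible(x)
}

#' Generate a serial-section phantom stack with a rise-and-fall infarct
#'
#' Emulates serial sectioning of one heart: every section shares the base
#' section shape; the infarct is a centered disc whose radius follows
#' `r_i = r_max * sqrt(w_i)` with a quadratic rise-and-fall weight profile
#' `w_i` (or a caller-supplied `profile` of weights in `[0, 1]`), so the
#' analytic infarct area of section `i` is `pi * r_i^2 * px_um^2` and the
#' closed-form stack volume is `sum(pi * r_i^2) * px_um^2 * (h1 + h2)`.
#'
#' @param stain stain identifier (default `"HE"`, the stain used for
#'   serial-volume work)
#' @param n_sections number of sections (default 20)
#' @param h1_um section thickness in um (default 5)
#' @param h2_um removed-tissue thickness between sections in um (default 10)
#' @param px_um pixel edge length in um (default 10)
#' @param r_max_frac peak infarct radius as a fraction of the smaller
#'   section semi-axis (default 0.6)
#' @param profile optional numeric vector of `n_sections` weights in
#'   `[0, 1]` replacing the default quadratic rise-and-fall
#' @param canvas,noise_sd,perturb_amp passed to [generate_phantom()]
#' @param seed integer RNG seed; section `i` uses `seed + i`
#' @return list with `phantoms` (list of `phantom`), `manifest` (data frame
#'   `section_id`, `h1_um`, `h2_um`, `px_um`), and
#'   `analytic_infarct_area_um2` (per-section closed-form areas)
#' @export
generate_serial_stack <- function(stain = "HE",
                                  n_sections = 20L,
                                  h1_um = 5,
                                  h2_um = 10,
                                  px_um = 10,
                                  r_max_frac = 0.6,
                                  profile = NULL,
                                  canvas = c(256L, 256L),
                                  noise_sd = 8,
                                  perturb_amp = 0.04,
                                  seed = 1L) {
  if (n_sections < 1L) stop("'n_sections' must be >= 1", call. = FALSE)
  if (is.null(profile)) {
    x <- if (n_sections == 1L) 0 else
      (seq_len(n_sections) - (n_sections + 1) / 2) / ((n_sections - 1) / 2)
    profile <- 1 - x^2
  }
  if (length(profile) != n_sections)
    stop(sprintf("'profile' has length %d but n_sections is %d",
                 length(profile), n_sections), call. = FALSE)
  if (any(profile < 0) || any(profile > 1))
    stop("'profile' weights must be in [0, 1]", call. = FALSE)
  semi_min <- min(0.42 * canvas[1], 0.38 * canvas[2]) * (1 - perturb_amp)
  r_max <- r_max_frac * semi_min
  radii <- r_max * sqrt(profile)
  phantoms <- lapply(seq_len(n_sections), function(i) {
    generate_phantom(stain, canvas = canvas, infarct_radius = radii[i],
                     noise_sd = noise_sd, perturb_amp = perturb_amp,
                     seed = seed + i)
  })
  manifest <- data.frame(section_id = seq_len(n_sections),
                         h1_um = h1_um, h2_um = h2_um, px_um = px_um)
  list(phantoms = phantoms, manifest = manifest,
       analytic_infarct_area_um2 = pi * radii^2 * px_um^2)
}
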