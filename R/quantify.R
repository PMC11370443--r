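# Quantification: relative infarct size, physical areas, and serial-section
# volume integration with the removed-tissue assumption.
#
# Unit conventions (centralized here): pixel size in micrometres (um),
# section/removed-tissue heights in um, areas in um^2 (with mm^2
# convenience columns), volumes reported in mm^3.

UM3_PER_MM3 <- 1e9
UM2_PER_MM2 <- 1e6

#' Relative infarct size of one section
#'
#' The percentage of infarct pixels relative to the whole-section pixel
#' count: `100 * n_infarct / n_section`.
#'
#' @param n_infarct infarct pixel count
#' @param n_section whole-section pixel count (must be positive)
#' @return percentage in `[0, 100]`
#' @export
relative_infarct_size <- function(n_infarct, n_section) {
  if (any(n_section <= 0))
    stop("'n_section' must be positive", call. = FALSE)
  if (any(n_infarct < 0) || any(n_infarct > n_section))
    stop("'n_infarct' must satisfy 0 <= n_infarct <= n_section",
         call. = FALSE)
  100 * n_infarct / n_section
}

#' Physical area of a pixel count
#'
#' Pixels are assumed square, so `area = px_size^2 * n` in the squared unit
#' of `px_size`.
#'
#' @param n pixel count (>= 0)
#' @param px_size pixel edge length (> 0), e.g. in um
#' @return area in `px_size` units squared
#' @export
pixel_area <- function(n, px_size) {
  if (any(px_size <= 0)) stop("'px_size' must be positive", call. = FALSE)
  if (any(n < 0)) stop("'n' must be non-negative", call. = FALSE)
  px_size^2 * n
}

#' Quantify one section from its masks
#'
#' @param infarct,tissue `H x W` logical masks in the same frame
#' @param px_um pixel edge length in micrometres
#' @return a one-row data frame: `n_infarct`, `n_section`, `relative_pct`,
#'   `infarct_area_um2`, `section_area_um2`, `infarct_area_mm2`,
#'   `section_area_mm2`
#' @export
section_quant <- function(infarct, tissue, px_um) {
  check_mask(infarct, "infarct"); check_mask(tissue, "tissue")
  check_same_shape(infarct, tissue, c("infarct", "tissue"))
  n_i <- sum(infarct & tissue)
  n_t <- sum(tissue)
  a_i <- pixel_area(n_i, px_um)
  a_t <- pixel_area(n_t, px_um)
  data.frame(n_infarct = n_i, n_section = n_t,
             relative_pct = relative_infarct_size(n_i, n_t),
             infarct_area_um2 = a_i, section_area_um2 = a_t,
             infarct_area_mm2 = a_i / UM2_PER_MM2,
             section_area_mm2 = a_t / UM2_PER_MM2)
}

#' Section and removed-tissue volumes from one area
#'
#' The volume contributed by a section is its area times the section height
#' `h1`; the unsectioned tissue removed between adjacent sections is assumed
#' to share the adjacent section's area, contributing area times the removed
#' height `h2`.
#'
#' @param A area (>= 0), any unit
#' @param h1 section height (> 0), same length unit as `A`'s edge
#' @param h2 removed-tissue height (>= 0)
#' @return numeric `c(V_s = A * h1, V_rs = A * h2)`
#' @export
section_volumes <- function(A, h1, h2) {
  if (any(A < 0) || any(h1 <= 0) || any(h2 < 0))
    stop("need A >= 0, h1 > 0, h2 >= 0", call. = FALSE)
  c(V_s = A * h1, V_rs = A * h2)
}

#' Relative volume percentage
#'
#' @param v_infarct,v_tissue infarct and whole-tissue volumes (same unit)
#' @return `100 * v_infarct / v_tissue`
#' @export
relative_volume_pct <- function(v_infarct, v_tissue) {
  if (any(v_tissue <= 0)) stop("'v_tissue' must be positive", call. = FALSE)
  100 * v_infarct / v_tissue
}

#' Integrate serial-section areas into whole-heart volumes
#'
#' For each section `i`, the infarct contributes
#' `A_s[i] * h1[i] + A_s[i] * h2[i]` (section slab plus the adjacent
#' removed-tissue slab at the section's own area) and the whole tissue
#' analogously with `A_t[i]`; totals are sums over sections. By default the
#' removed-tissue slab after the final section is included (uniform
#' formula); `trailing_gap = FALSE` drops the last `h2` terms. The relative
#' volume percentage is insensitive to this choice when `h1` and `h2` are
#' uniform across sections.
#'
#' @param manifest data frame with columns `infarct_area_um2`,
#'   `section_area_um2`, `h1_um`, `h2_um` (one row per section, in
#'   anatomical order), and optionally `section_id`
#' @param trailing_gap include the removed slab after the last section
#'   (default `TRUE`)
#' @return list of class `heart_volumes`: `v_infarct_mm3`, `v_tissue_mm3`,
#'   `relative_volume_pct`, and `per_section` (data frame with `V_si`,
#'   `V_rsi`, `V_ti`, `V_rti` in mm^3)
#' @export
heart_volumes <- function(manifest, trailing_gap = TRUE) {
  req <- c("infarct_area_um2", "section_area_um2", "h1_um", "h2_um")
  if (!is.data.frame(manifest) || nrow(manifest) < 1L)
    stop("'manifest' must be a non-empty data frame", call. = FALSE)
  missing <- setdiff(req, names(manifest))
  if (length(missing))
    stop(sprintf("manifest lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  with(manifest, {
    if (any(h1_um <= 0) || any(h2_um < 0))
      stop("need h1_um > 0 and h2_um >= 0 in every section", call. = FALSE)
    if (any(infarct_area_um2 < 0) || any(section_area_um2 < 0) ||
        any(infarct_area_um2 > section_area_um2))
      stop("need 0 <= infarct_area_um2 <= section_area_um2", call. = FALSE)
  })
  n <- nrow(manifest)
  h2 <- manifest$h2_um
  if (!trailing_gap) h2[n] <- 0
  per <- data.frame(
    section_id = if (!is.null(manifest$section_id)) manifest$section_id
                 else seq_len(n),
    V_si  = manifest$infarct_area_um2 * manifest$h1_um / UM3_PER_MM3,
    V_rsi = manifest$infarct_area_um2 * h2 / UM3_PER_MM3,
    V_ti  = manifest$section_area_um2 * manifest$h1_um / UM3_PER_MM3,
    V_rti = manifest$section_area_um2 * h2 / UM3_PER_MM3)
  v_s <- sum(per$V_si + per$V_rsi)
  v_t <- sum(per$V_ti + per$V_rti)
  if (v_t <= 0)
    stop("total tissue volume is zero; check manifest areas", call. = FALSE)
  structure(list(v_infarct_mm3 = v_s,
                 v_tissue_mm3 = v_t,
                 relative_volume_pct = relative_volume_pct(v_s, v_t),
                 per_section = per),
            class = "heart_volumes")
}

#' @export
print.heart_volumes <- function(x, ...) {
  cat(sprintf("heart volumes over %d sections\n", nrow(x$per_section)))
  cat(sprintf("  infarct: %.4f mm^3\n  tissue:  %.4f mm^3\n",
              x$v_infarct_mm3, x$v_tissue_mm3))
  cat(sprintf("  relative infarct volume: %.1f%%\n", x$relative_volume_pct))
  invisible(x)
}
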