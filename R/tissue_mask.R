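# Whole-section tissue mask: the denominator for all relative quantities.

#' Mask the whole tissue section
#'
#' A pixel is provisionally tissue when `min(R, G, B) < white_floor`, i.e.
#' anything that is not near-white slide background (all four supported
#' stains leave the background unstained). The provisional mask is then
#' cleaned by morphological closing (disk radius 3, see [disk_brush()]),
#' hole filling (so pale interior regions — an off-white TTC infarct core,
#' bubbles, ventricular lumen — still count in the section denominator) and
#' removal of connected components smaller than `min_object_px`.
#'
#' @param img `H x W x 3` image array
#' @param white_floor channel floor for background (default 235)
#' @param min_object_px smallest connected component kept (default 64)
#' @param fill_holes fill enclosed holes (default `TRUE`); disable to keep
#'   lumina/bubbles out of the section denominator
#' @return `H x W` logical tissue mask
#' @export
make_tissue_mask <- function(img, white_floor = 235, min_object_px = 64,
                             fill_holes = TRUE) {
  check_rgb(img)
  tissue <- pmin(channel(img, 1), channel(img, 2), channel(img, 3)) <
    white_floor
  if (!any(tissue))
    stop("no tissue found (image is entirely near-white); lower 'white_floor'",
         call. = FALSE)
  # pad with background before morphology so the mask is invariant to how
  # tightly the section was cropped (no structuring-element border effects)
  k <- 4L
  h <- nrow(tissue); w <- ncol(tissue)
  m <- matrix(0, h + 2L * k, w + 2L * k)
  m[k + seq_len(h), k + seq_len(w)] <- as.numeric(tissue)
  m <- EBImage::closing(m, disk_brush(3))
  if (fill_holes) m <- EBImage::fillHull(m)
  m <- m[k + seq_len(h), k + seq_len(w)]
  lab <- EBImage::bwlabel(m)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_object_px)
  out <- matrix(lab %in% keep & lab > 0, nrow(tissue), ncol(tissue))
  if (!any(out))
    stop(sprintf(
      "no tissue component of at least %d px found; adjust thresholds",
      min_object_px), call. = FALSE)
  out
}

#' Intersect an infarct mask with the tissue mask
#'
#' Returns `infarct & tissue` and warns with the number of infarct pixels
#' found outside the tissue mask (zero when the pipeline composed the masks
#' correctly).
#'
#' @param infarct,tissue `H x W` logical masks in the same frame
#' @return `H x W` logical mask, `infarct & tissue`
#' @export
mask_union_check <- function(infarct, tissue) {
  check_mask(infarct, "infarct")
  check_mask(tissue, "tissue")
  check_same_shape(infarct, tissue, c("infarct", "tissue"))
  outside <- sum(infarct & !tissue)
  if (outside > 0)
    warning(sprintf("%d infarct pixel(s) fall outside the tissue mask",
                    outside), call. = FALSE)
  infarct & tissue
}
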