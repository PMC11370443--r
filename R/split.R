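# Splitting a multi-section slide scan into single-section images.
# Bands are horizontal row intervals, 0-based and half-open [top, bottom),
# ordered top to bottom.

#' Construct and validate a slide split layout
#'
#' @param bands a list of length-2 numeric vectors `c(top, bottom)` or an
#'   `n x 2` matrix of 0-based half-open row intervals, ordered top to bottom
#' @param height optional image height used to bound-check the bands
#' @return an object of class `split_layout`: an integer `n x 2` matrix with
#'   columns `top`, `bottom`
#' @export
split_layout <- function(bands, height = NULL) {
  if (is.list(bands)) bands <- do.call(rbind, bands)
  if (!is.matrix(bands) || ncol(bands) != 2L || nrow(bands) < 1L)
    stop("'bands' must be a non-empty list or matrix of (top, bottom) pairs",
         call. = FALSE)
  storage.mode(bands) <- "integer"
  colnames(bands) <- c("top", "bottom")
  bad <- which(bands[, 1] < 0L | bands[, 1] >= bands[, 2])
  if (length(bad))
    stop(sprintf("invalid band interval(s) at index: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  if (!is.null(height)) {
    bad <- which(bands[, 2] > height)
    if (length(bad))
      stop(sprintf("band(s) exceed image height %d at index: %s", height,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (nrow(bands) > 1L) {
    overlap <- which(bands[-1L, 1] < bands[-nrow(bands), 2])
    if (length(overlap))
      stop(sprintf("bands overlap or are unordered at index: %s",
                   paste(overlap + 1L, collapse = ", ")), call. = FALSE)
  }
  structure(bands, class = c("split_layout", "matrix"))
}

#' Split a slide image into single-section sub-images
#'
#' Crops each band's rows (all columns) pixel-exactly, never resampling: a
#' full-cover layout's outputs vertically concatenate back to the input.
#'
#' @param img `H x W x 3` image array
#' @param layout a [split_layout()] (or anything it accepts)
#' @return list of `H_i x W x 3` image arrays, one per band, top to bottom
#' @export
split_slide <- function(img, layout) {
  check_rgb(img)
  layout <- split_layout(unclass(layout), height = dim(img)[1])
  lapply(seq_len(nrow(layout)), function(i) {
    rows <- (layout[i, 1] + 1L):layout[i, 2]   # 0-based half-open -> R rows
    img[rows, , , drop = FALSE]
  })
}

#' Suggest split bands from slide content
#'
#' A pixel is background when `min(R, G, B) >= white_floor` (near-white
#' slide); a row is a tissue row when more than `row_frac` of its pixels are
#' non-background. Runs of consecutive tissue rows are candidate bands;
#' if more runs than `count` are found, runs separated by the smallest gaps
#' are merged first. Band edges are padded by `pad` rows (clipped to the
#' image).
#'
#' @param img `H x W x 3` image array
#' @param count number of bands wanted
#' @param white_floor background channel floor (default 235)
#' @param row_frac minimum non-background fraction for a tissue row
#'   (default 0.01)
#' @param pad rows of margin added above/below each band (default 2)
#' @return a [split_layout()] with `count` bands
#' @export
suggest_bands <- function(img, count, white_floor = 235, row_frac = 0.01,
                          pad = 2L) {
  check_rgb(img)
  if (length(count) != 1L || count < 1L)
    stop("'count' must be a positive integer", call. = FALSE)
  bg <- pmin(channel(img, 1), channel(img, 2), channel(img, 3)) >= white_floor
  tissue_row <- rowMeans(!bg) > row_frac
  runs <- rle(tissue_row)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  bands <- cbind(starts[keep], ends[keep])      # 1-based inclusive rows
  if (nrow(bands) < count)
    stop(sprintf("found only %d tissue band(s), need %d; adjust white_floor/row_frac",
                 nrow(bands), count), call. = FALSE)
  while (nrow(bands) > count) {                 # merge across smallest gap
    gaps <- bands[-1L, 1] - bands[-nrow(bands), 2]
    i <- which.min(gaps)
    bands[i, 2] <- bands[i + 1L, 2]
    bands <- bands[-(i + 1L), , drop = FALSE]
  }
  h <- dim(img)[1]
  top <- pmax(bands[, 1] - 1L - pad, 0L)        # to 0-based half-open
  bottom <- pmin(bands[, 2] + pad, h)
  split_layout(cbind(top, bottom), height = h)
}
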