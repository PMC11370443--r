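# Lossless raster I/O. Images are H x W x 3 integer arrays in [0, 255].

#' Read a raster image as an 8-bit RGB array
#'
#' PNG and TIFF are read losslessly; JPEG is accepted with a warning about
#' compression artifacts (it should never be used to store masks or images
#' destined for pixel counting). Grayscale rasters are replicated to three
#' channels; an alpha channel, if present, is dropped.
#'
#' @param path path to a PNG, TIFF or JPEG file
#' @return an `H x W x 3` integer array with values in `[0, 255]`
#' @seealso [write_image()]
#' @export
read_image <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    stop("'path' must be a single file path", call. = FALSE)
  if (!file.exists(path))
    stop(sprintf("cannot read image: file '%s' does not exist", path),
         call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    switch(ext,
      png  = png::readPNG(path),
      tif  = ,
      tiff = tiff::readTIFF(path),
      jpg  = ,
      jpeg = {
        if (!requireNamespace("jpeg", quietly = TRUE))
          stop("reading JPEG requires the 'jpeg' package", call. = FALSE)
        warning(sprintf(
          "'%s' is JPEG-compressed; pixel values may carry compression artifacts",
          path), call. = FALSE)
        jpeg::readJPEG(path)
      },
      stop(sprintf("unsupported image extension '%s' for '%s'", ext, path),
           call. = FALSE)
    ),
    error = function(e) stop(sprintf("cannot decode image '%s': %s",
                                     path, conditionMessage(e)),
                             call. = FALSE)
  )
  img <- normalize_raster(raw)
  if (dim(img)[1] < 1L || dim(img)[2] < 1L)
    stop(sprintf("image '%s' has zero size", path), call. = FALSE)
  img
}

# Convert the [0,1] double array returned by the readers to an 8-bit
# H x W x 3 integer array: replicate grayscale, drop alpha.
normalize_raster <- function(raw) {
  if (is.matrix(raw)) raw <- array(raw, dim = c(dim(raw), 1L))
  nch <- dim(raw)[3]
  if (nch == 1L) {
    raw <- array(rep(raw[, , 1L], 3L), dim = c(dim(raw)[1:2], 3L))
  } else if (nch == 2L) {                     # gray + alpha
    raw <- array(rep(raw[, , 1L], 3L), dim = c(dim(raw)[1:2], 3L))
  } else if (nch >= 4L) {                     # drop alpha
    raw <- raw[, , 1:3, drop = FALSE]
  }
  img <- clip8(raw * 255)
  storage.mode(img) <- "integer"
  img
}

#' Write an 8-bit RGB array to a lossless image file
#'
#' The extension selects the encoder: `.png` (default choice) or
#' `.tif`/`.tiff`, both lossless, so a re-read yields a bit-identical raster.
#' Lossy extensions are refused.
#'
#' @param img `H x W x 3` array with values in `[0, 255]`
#' @param path destination path ending in `.png`, `.tif` or `.tiff`
#' @return `path`, invisibly
#' @export
write_image <- function(img, path) {
  check_rgb(img)
  ext <- tolower(tools::file_ext(path))
  dir <- dirname(path)
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  arr <- img / 255
  switch(ext,
    png  = png::writePNG(arr, path),
    tif  = ,
    tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8L),
    stop(sprintf(
      "refusing to write lossy/unknown format '.%s'; use .png or .tiff", ext),
      call. = FALSE)
  )
  invisible(path)
}

#' Write a binary mask as a single-channel 0/255 PNG
#'
#' @param mask logical matrix
#' @param path destination `.png` path
#' @return `path`, invisibly
#' @export
write_mask <- function(mask, path) {
  check_mask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a 0/255 mask PNG back to a logical matrix
#'
#' @param path mask PNG path
#' @return logical matrix (pixel is TRUE where value > 127)
#' @export
read_mask <- function(path) {
  img <- read_image(path)
  channel(img, 1L) > 127
}
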