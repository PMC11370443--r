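# Internal validators and small shared helpers.

#' Validate an RGB image array
#'
#' @param img object to check
#' @param arg name used in error messages
#' @return the image, invisibly
#' @keywords internal
check_rgb <- function(img, arg = "img") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(sprintf("'%s' must be an H x W x 3 array", arg), call. = FALSE)
  if (dim(img)[1] < 1L || dim(img)[2] < 1L)
    stop(sprintf("'%s' has zero height or width", arg), call. = FALSE)
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop(sprintf("'%s' must have channel values in [0, 255]", arg),
         call. = FALSE)
  invisible(img)
}

check_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask))
    stop(sprintf("'%s' must be a logical matrix", arg), call. = FALSE)
  invisible(mask)
}

check_same_shape <- function(a, b, what = c("mask", "mask")) {
  da <- dim(a)[1:2]; db <- dim(b)[1:2]
  if (!identical(da, db))
    stop(sprintf("shape mismatch: %s is %dx%d but %s is %dx%d",
                 what[1], da[1], da[2], what[2], db[1], db[2]), call. = FALSE)
  invisible(NULL)
}

# Extract channel matrices from an image array.
channel <- function(img, i) img[, , i, drop = TRUE]

#' Euclidean disk structuring element
#'
#' Square (2r+1) x (2r+1) 0/1 matrix with 1 where dr^2 + dc^2 <= r^2.
#' Radius 1 gives the 5-pixel plus; radius 0 a single pixel. This fixed
#' discretization is used for every morphological operation in the package.
#'
#' @param radius non-negative integer radius in pixels
#' @return numeric 0/1 matrix
#' @export
disk_brush <- function(radius) {
  if (length(radius) != 1L || is.na(radius) || radius < 0)
    stop("'radius' must be a single non-negative number", call. = FALSE)
  r <- as.integer(round(radius))
  d <- seq(-r, r)
  outer(d, d, function(dr, dc) as.numeric(dr^2 + dc^2 <= r^2))
}

# Round and clip to 8-bit integer range.
clip8 <- function(x) {
  x <- round(x)
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}
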