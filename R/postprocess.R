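# Mask post-processing: ROI cropping, dilation, user-directed artifact
# exclusion and overlay rendering.

#' Crop a rectangular region of interest
#'
#' Rectangle is `(top, bottom, left, right)`, 0-based and half-open. The
#' crop is pixel-exact; the `(top, left)` offset is retained in the
#' `"offset"` attribute so masks computed on the crop can be re-embedded in
#' the full frame.
#'
#' @param img `H x W x 3` image array
#' @param rect numeric `(top, bottom, left, right)`
#' @return cropped image array, with attribute `offset = c(top, left)`
#' @export
crop_roi <- function(img, rect) {
  check_rgb(img)
  if (length(rect) != 4L || anyNA(rect))
    stop("'rect' must be (top, bottom, left, right)", call. = FALSE)
  rect <- as.integer(rect)
  h <- dim(img)[1]; w <- dim(img)[2]
  if (rect[1] < 0L || rect[3] < 0L || rect[2] > h || rect[4] > w ||
      rect[1] >= rect[2] || rect[3] >= rect[4])
    stop(sprintf("invalid rectangle (%d,%d,%d,%d) for a %dx%d image",
                 rect[1], rect[2], rect[3], rect[4], h, w), call. = FALSE)
  out <- img[(rect[1] + 1L):rect[2], (rect[3] + 1L):rect[4], , drop = FALSE]
  attr(out, "offset") <- c(top = rect[1], left = rect[3])
  out
}

#' Dilate a binary mask with a disk structuring element
#'
#' Uses the package's fixed Euclidean disk discretization ([disk_brush()]);
#' radius 1 is the 5-pixel plus, radius 0 is the identity. Dilation is
#' extensive (output is a superset of the input) and increasing in radius.
#'
#' @param mask `H x W` logical mask
#' @param radius non-negative dilation radius in pixels
#' @return dilated `H x W` logical mask
#' @export
dilate_mask <- function(mask, radius) {
  check_mask(mask)
  if (length(radius) != 1L || is.na(radius) || radius < 0)
    stop("'radius' must be a single non-negative number", call. = FALSE)
  if (radius == 0 || !any(mask)) return(mask)
  m <- EBImage::dilate(matrix(as.numeric(mask), nrow(mask), ncol(mask)),
                       disk_brush(radius))
  matrix(m > 0, nrow(mask), ncol(mask))
}

# Even-odd point-in-polygon for 0-based pixel-center coordinates.
# Points exactly on a polygon edge count as inside. Vertices are an
# n x 2 matrix of (row, col).
points_in_polygon <- function(rows, cols, verts, eps = 1e-9) {
  n <- nrow(verts)
  vy <- verts[, 1]; vx <- verts[, 2]
  vy2 <- vy[c(2:n, 1)]; vx2 <- vx[c(2:n, 1)]
  inside <- logical(length(rows))
  boundary <- logical(length(rows))
  for (k in seq_len(n)) {
    y1 <- vy[k]; x1 <- vx[k]; y2 <- vy2[k]; x2 <- vx2[k]
    crosses <- (y1 > rows) != (y2 > rows)
    if (any(crosses)) {
      xin <- x1 + (rows[crosses] - y1) * (x2 - x1) / (y2 - y1)
      hit <- cols[crosses] < xin
      inside[crosses] <- xor(inside[crosses], hit)
    }
    # on-segment test
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    if (len2 < eps) {
      on <- abs(rows - y1) < eps & abs(cols - x1) < eps
    } else {
      t <- ((rows - y1) * dy + (cols - x1) * dx) / len2
      py <- y1 + pmin(pmax(t, 0), 1) * dy
      px <- x1 + pmin(pmax(t, 0), 1) * dx
      on <- (rows - py)^2 + (cols - px)^2 < eps
    }
    boundary <- boundary | on
  }
  inside | boundary
}

validate_polygon <- function(verts, i, h, w) {
  if (is.list(verts)) verts <- do.call(rbind, verts)
  verts <- as.matrix(verts)
  if (!is.numeric(verts) || ncol(verts) != 2L || nrow(verts) < 3L ||
      anyNA(verts))
    stop(sprintf(
      "exclusion polygon %d is malformed: need >= 3 (row, col) vertices", i),
      call. = FALSE)
  if (min(verts) < 0 || max(verts[, 1]) > h - 1 || max(verts[, 2]) > w - 1)
    stop(sprintf("exclusion polygon %d has vertices outside the image", i),
         call. = FALSE)
  verts
}

#' Remove user-defined artifact regions from a mask
#'
#' Sets to `FALSE` every pixel whose center lies inside (or exactly on the
#' boundary of) any exclusion polygon, using the even-odd rule. This is how
#' artifacts such as bubbles misclassified as infarct are removed; the
#' operation is idempotent and order-independent over polygons.
#'
#' @param mask `H x W` logical mask
#' @param excl list of polygons, each an `n x 2` matrix (or list of pairs)
#'   of 0-based `(row, col)` vertices; typically from [read_exclusions()]
#' @return mask with excluded pixels cleared
#' @export
apply_exclusions <- function(mask, excl) {
  check_mask(mask)
  if (length(excl) == 0L) return(mask)
  h <- nrow(mask); w <- ncol(mask)
  for (i in seq_along(excl)) {
    verts <- validate_polygon(excl[[i]], i, h, w)
    r0 <- max(floor(min(verts[, 1])), 0)
    r1 <- min(ceiling(max(verts[, 1])), h - 1)
    c0 <- max(floor(min(verts[, 2])), 0)
    c1 <- min(ceiling(max(verts[, 2])), w - 1)
    rows <- rep(r0:r1, times = c1 - c0 + 1L)
    cols <- rep(c0:c1, each = r1 - r0 + 1L)
    inside <- points_in_polygon(rows, cols, verts)
    mask[cbind(rows[inside] + 1L, cols[inside] + 1L)] <- FALSE
  }
  mask
}

#' Read exclusion polygons from a JSON file
#'
#' Expected form: `[{"label": "bubble1", "vertices": [[r, c], ...]}, ...]`
#' with 0-based row/col vertex coordinates.
#'
#' @param path JSON file path
#' @return named list of vertex matrices
#' @export
read_exclusions <- function(path) {
  if (!file.exists(path))
    stop(sprintf("exclusion file '%s' does not exist", path), call. = FALSE)
  spec <- jsonlite::fromJSON(path, simplifyMatrix = TRUE,
                             simplifyDataFrame = FALSE)
  out <- lapply(spec, function(p) {
    v <- p$vertices
    if (is.list(v)) v <- do.call(rbind, v)
    as.matrix(v)
  })
  names(out) <- vapply(seq_along(spec), function(i) {
    if (!is.null(spec[[i]]$label)) spec[[i]]$label else sprintf("region%d", i)
  }, character(1))
  out
}

#' Render the segmentation overlay figure
#'
#' Deterministic palette: slide background black, tissue a flat dark red
#' `(136, 28, 28)`, infarct pixels painted white — so the number of white
#' pixels in the overlay equals the number of infarct-mask pixels.
#'
#' @param img `H x W x 3` image array (used only for its frame)
#' @param infarct,tissue `H x W` logical masks
#' @return `H x W x 3` overlay image array
#' @export
render_overlay <- function(img, infarct, tissue) {
  check_rgb(img)
  check_mask(infarct, "infarct"); check_mask(tissue, "tissue")
  check_same_shape(img, infarct, c("img", "infarct"))
  check_same_shape(img, tissue, c("img", "tissue"))
  out <- array(0L, dim = dim(img))
  for (i in 1:3) {
    ch <- matrix(0L, nrow(tissue), ncol(tissue))
    ch[tissue] <- c(136L, 28L, 28L)[i]
    ch[infarct] <- 255L
    out[, , i] <- ch
  }
  out
}
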