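# End-to-end pipelines binding the modules together: single-section infarct
# analysis and serial-section volume quantification. These are the
# programmatic equivalents of the command-line subcommands in
# inst/cli/myoquant.R.

#' Run the full infarct analysis on one section image
#'
#' Pipeline: read (or accept) the image, optionally crop an ROI, mask the
#' whole section, classify infarct pixels with the stain rule, clear
#' user-supplied exclusion polygons, dilate the infarct mask (default disk
#' radius 2; 0 disables) restricted to the tissue mask, quantify, and
#' render an overlay. When `outdir` is given, the masks (0/255 PNG), the
#' overlay PNG, a one-row CSV and a JSON run record with every effective
#' parameter are written there.
#'
#' @param input image file path or an `H x W x 3` array
#' @param stain stain identifier, used when `cfg` is `NULL`
#' @param cfg a [stain_config()]; overrides `stain`
#' @param px_um pixel edge length in micrometres (default 1)
#' @param roi optional `(top, bottom, left, right)` crop rectangle
#' @param exclusions optional polygon list or JSON path
#'   (see [read_exclusions()])
#' @param dilate_radius infarct mask dilation radius (default 2)
#' @param white_floor,min_object_px,fill_holes tissue-mask parameters
#' @param outdir optional output directory
#' @param prefix file-name prefix for outputs (default `"section"`)
#' @return list of class `infarct_result`: `quant` (one-row data frame from
#'   [section_quant()]), `infarct`, `tissue` (masks), `overlay` (image),
#'   `params` (effective parameter record)
#' @export
run_infarct <- function(input, stain = NULL, cfg = NULL, px_um = 1,
                        roi = NULL, exclusions = NULL, dilate_radius = 2,
                        white_floor = 235, min_object_px = 64,
                        fill_holes = TRUE, outdir = NULL,
                        prefix = "section") {
  if (is.null(cfg)) {
    if (is.null(stain))
      stop(sprintf("either 'cfg' or 'stain' is required; stains: %s",
                   paste(STAINS, collapse = ", ")), call. = FALSE)
    cfg <- stain_config(stain)
  }
  img <- if (is.character(input)) read_image(input) else input
  check_rgb(img)
  if (!is.null(roi)) img <- crop_roi(img, roi)
  if (is.character(exclusions)) exclusions <- read_exclusions(exclusions)

  tissue <- make_tissue_mask(img, white_floor = white_floor,
                             min_object_px = min_object_px,
                             fill_holes = fill_holes)
  infarct <- classify_image(img, cfg, tissue)
  if (!is.null(exclusions) && length(exclusions))
    infarct <- apply_exclusions(infarct, exclusions)
  if (dilate_radius > 0)
    infarct <- dilate_mask(infarct, dilate_radius) & tissue
  infarct <- mask_union_check(infarct, tissue)

  quant <- section_quant(infarct, tissue, px_um)
  overlay <- render_overlay(img, infarct, tissue)
  params <- c(unclass(cfg),
              list(px_um = px_um, dilate_radius = dilate_radius,
                   white_floor = white_floor,
                   min_object_px = min_object_px,
                   fill_holes = fill_holes,
                   n_exclusions = length(exclusions),
                   package_version =
                     as.character(utils::packageVersion("myoquant"))))
  res <- structure(list(quant = quant, infarct = infarct, tissue = tissue,
                        overlay = overlay, params = params),
                   class = "infarct_result")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_mask(infarct, file.path(outdir, paste0(prefix, "_infarct.png")))
    write_mask(tissue, file.path(outdir, paste0(prefix, "_tissue.png")))
    write_image(overlay, file.path(outdir, paste0(prefix, "_overlay.png")))
    write.csv(quant, file.path(outdir, paste0(prefix, "_quant.csv")),
              row.names = FALSE)
    jsonlite::write_json(params,
                         file.path(outdir, paste0(prefix, "_run.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' @export
print.infarct_result <- function(x, ...) {
  q <- x$quant
  cat(sprintf("infarct: %d / %d px (%.1f%%), %.4f / %.4f mm^2\n",
              q$n_infarct, q$n_section, q$relative_pct,
              q$infarct_area_mm2, q$section_area_mm2))
  invisible(x)
}

#' Run serial-section infarct volume quantification
#'
#' Runs [run_infarct()] on every section of an ordered manifest and
#' integrates the per-section areas into whole-heart volumes with
#' [heart_volumes()]. The manifest is a data frame (or CSV path) with
#' columns `section_id`, `image` (path, unless `images` supplies arrays),
#' `h1_um`, `h2_um`, `px_um`. A failing section aborts the run naming its
#' `section_id`.
#'
#' @param manifest data frame or CSV path, see Details
#' @param images optional list of image arrays overriding `manifest$image`
#'   (useful for in-memory phantom stacks)
#' @param outdir optional output directory for per-section CSV and the
#'   heart summary CSV
#' @param trailing_gap passed to [heart_volumes()]
#' @param ... further arguments passed to [run_infarct()] (e.g. `stain`,
#'   `cfg`, `dilate_radius`)
#' @return list of class `volume_result`: `per_section` (data frame),
#'   `volumes` (a [heart_volumes()] result)
#' @export
run_volume <- function(manifest, images = NULL, outdir = NULL,
                       trailing_gap = TRUE, ...) {
  if (is.character(manifest)) manifest <- read.csv(manifest)
  if (!is.data.frame(manifest) || nrow(manifest) < 1L)
    stop("'manifest' must be a non-empty data frame or CSV path",
         call. = FALSE)
  req <- c("section_id", "h1_um", "h2_um", "px_um")
  missing <- setdiff(req, names(manifest))
  if (length(missing))
    stop(sprintf("manifest lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (is.null(images) && is.null(manifest$image))
    stop("manifest needs an 'image' column or 'images' must be supplied",
         call. = FALSE)

  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    input <- if (!is.null(images)) images[[i]] else manifest$image[i]
    res <- tryCatch(
      run_infarct(input, px_um = manifest$px_um[i], ...),
      error = function(e)
        stop(sprintf("section '%s' failed: %s", manifest$section_id[i],
                     conditionMessage(e)), call. = FALSE))
    cbind(section_id = manifest$section_id[i], res$quant,
          h1_um = manifest$h1_um[i], h2_um = manifest$h2_um[i])
  })
  per_section <- do.call(rbind, rows)
  vols <- heart_volumes(per_section, trailing_gap = trailing_gap)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write.csv(per_section, file.path(outdir, "sections.csv"),
              row.names = FALSE)
    write.csv(data.frame(V_infarct_mm3 = vols$v_infarct_mm3,
                         V_tissue_mm3 = vols$v_tissue_mm3,
                         relative_volume_pct = vols$relative_volume_pct),
              file.path(outdir, "heart_summary.csv"), row.names = FALSE)
  }
  structure(list(per_section = per_section, volumes = vols),
            class = "volume_result")
}

#' @export
print.volume_result <- function(x, ...) {
  print(x$volumes)
  invisible(x)
}
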