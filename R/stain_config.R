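# Per-stain classification thresholds.

#' Stains supported by the classifier
#' @export
STAINS <- c("MTS", "HE", "TTC", "PSR")

#' Stain classification configuration
#'
#' Bundles the stain identifier with every rule threshold. Defaults are the
#' package's documented pre-set for each stain and can all be adjusted:
#'
#' * `mts_r_max` (default 150): a Masson's-trichrome pixel must have
#'   `R <= mts_r_max` to be infarct/collagen — scar collagen stains blue, so
#'   its red channel is low (exemplary infarct R is 41 vs 251 in muscle).
#' * `mts_br_ratio_min` (default 1.2): blue dominance requirement
#'   `B / max(R, 1) >= mts_br_ratio_min`, suppressing faintly blue muscle.
#' * `ttc_std_max` (default 30): TTC infarct is off-white, so the population
#'   standard deviation of the three channel values of a pixel is small;
#'   viable deep-red tissue has a large one.
#' * `psr_thd` (default 50): picrosirius-red margin threshold; a pixel is
#'   collagen when `R > mean(G, B)` and `R - mean(G, B) >= psr_thd`.
#' * `psr_literal_or` (default `FALSE`): replace the conjunction by
#'   `R > mean(G, B) OR R - mean(G, B) >= psr_thd` (which makes `psr_thd`
#'   inert whenever red dominates; kept for comparison only).
#' * `he_channel_cap` (default 200): H&E pre-transform step 1 zeroes any
#'   channel value exceeding this cap.
#' * `he_g_min` (default 120): minimum surviving green intensity for a
#'   post-transform H&E pixel to count as infarct.
#'
#' @param stain one of `"MTS"`, `"HE"`, `"TTC"`, `"PSR"`
#' @param mts_r_max,mts_br_ratio_min,ttc_std_max,psr_thd,he_channel_cap,he_g_min
#'   rule thresholds, see Details
#' @param psr_literal_or logical, see Details
#' @return an object of class `stain_config` (a named list)
#' @export
stain_config <- function(stain,
                         mts_r_max = 150,
                         mts_br_ratio_min = 1.2,
                         ttc_std_max = 30,
                         psr_thd = 50,
                         he_channel_cap = 200,
                         he_g_min = 120,
                         psr_literal_or = FALSE) {
  if (length(stain) != 1L || !stain %in% STAINS)
    stop(sprintf("unknown stain '%s'; must be one of %s",
                 paste(stain, collapse = ","),
                 paste(STAINS, collapse = ", ")), call. = FALSE)
  for (v in c("mts_r_max", "ttc_std_max", "psr_thd",
              "he_channel_cap", "he_g_min")) {
    x <- get(v)
    if (length(x) != 1L || is.na(x) || x < 0 || x > 255)
      stop(sprintf("'%s' must be a single value in [0, 255]", v),
           call. = FALSE)
  }
  if (mts_br_ratio_min <= 0)
    stop("'mts_br_ratio_min' must be > 0", call. = FALSE)
  if (psr_thd < 0) stop("'psr_thd' must be >= 0", call. = FALSE)
  structure(list(stain = stain,
                 mts_r_max = mts_r_max,
                 mts_br_ratio_min = mts_br_ratio_min,
                 ttc_std_max = ttc_std_max,
                 psr_thd = psr_thd,
                 he_channel_cap = he_channel_cap,
                 he_g_min = he_g_min,
                 psr_literal_or = isTRUE(psr_literal_or)),
            class = "stain_config")
}

#' @export
print.stain_config <- function(x, ...) {
  cat(sprintf("stain_config: %s\n", x$stain))
  for (n in setdiff(names(x), "stain"))
    cat(sprintf("  %-18s %s\n", n, format(x[[n]])))
  invisible(x)
}

#' Read a stain configuration from a flat YAML file
#'
#' The file holds flat `key: value` pairs; `stain` is required, every other
#' key must be a [stain_config()] argument. Missing keys keep their
#' documented defaults.
#'
#' @param path YAML file path
#' @return a `stain_config`
#' @export
read_stain_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file '%s' does not exist", path), call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals$stain))
    stop(sprintf("config file '%s' must set 'stain'", path), call. = FALSE)
  known <- names(formals(stain_config))
  extra <- setdiff(names(vals), known)
  if (length(extra))
    stop(sprintf("unknown config key(s): %s", paste(extra, collapse = ", ")),
         call. = FALSE)
  do.call(stain_config, vals)
}
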