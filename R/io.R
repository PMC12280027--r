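# File formats: multi-page TIFF sections with JSON sidecars, label-mask
# TIFFs, YAML run configuration.

#' Default pipeline configuration
#'
#' All tunable parameters of the analysis with their default values.
#' Units are micrometres for radii/areas/diameters. A reference copy in
#' YAML form is shipped at
#' `system.file("extdata", "default_config.yaml", package = "isletmorph")`.
#'
#' @return Named list: `pixel_size` (um/px), `channel_map`,
#'   `threshold_method` ("otsu" or "fixed") with `fixed_thresholds`,
#'   `closing_radius_um` / `mean_radius_um` (hormone-channel
#'   preprocessing), `islet_closing_radius_um` (whole-islet shape
#'   refinement), `min_islet_area_um2` (size filter, default 1000),
#'   `nucleus_max_diameter_um` (default 10), `nucleus_mean_radius_um`,
#'   `watershed_h` (px), `fractional_mode` ("tissue" or "exocrine"),
#'   `min_alpha_area_um2`, `stats_policy`, `s0`, `n_permutations`,
#'   `fdr`, `seed`.
#' @export
default_config <- function() {
  list(pixel_size = 0.65,
       channel_map = c(nuclei = 1L, glucagon = 2L, insulin = 3L, marker = 4L),
       threshold_method = "otsu",
       fixed_thresholds = list(glucagon = NULL, insulin = NULL, marker = NULL),
       closing_radius_um = 1.3,
       mean_radius_um = 1.3,
       islet_closing_radius_um = 3,
       min_islet_area_um2 = 1000,
       nucleus_max_diameter_um = 10,
       nucleus_mean_radius_um = 0.65,
       watershed_h = 1,
       fractional_mode = "tissue",
       min_alpha_area_um2 = 0,
       stats_policy = "auto",
       s0 = 0.01,
       n_permutations = 250,
       fdr = 0.05,
       seed = 1L)
}

#' Read a pipeline configuration from YAML
#'
#' Unset keys fall back to [default_config()]; unknown keys are an error.
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  def <- default_config()
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  out <- utils::modifyList(def, cfg)
  if (!is.null(out$channel_map)) out$channel_map <- unlist(out$channel_map)
  out
}

#' Write a pipeline configuration to YAML
#'
#' @param config Configuration list.
#' @param path Output YAML file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  cfg <- config
  cfg$channel_map <- as.list(cfg$channel_map)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write a multichannel section as multi-page TIFF plus JSON sidecar
#'
#' One 16-bit grayscale page per channel (intensities rounded and stored
#' as value/65535); the sidecar records channel names, pixel size and any
#' metadata, so [read_section()] round-trips the section exactly for
#' integer intensities up to 65535.
#'
#' @param section A `MultiChannelSection`.
#' @param path Output TIFF path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_section <- function(section, path) {
  stopifnot(inherits(section, "MultiChannelSection"))
  pages <- lapply(section$channels, function(m) {
    v <- round(m)
    if (any(v > 65535)) stop("intensities exceed the 16-bit range")
    v / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  sidecar <- list(channels = names(section$channels),
                  pixel_size = section$pixel_size, meta = section$meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multichannel section from TIFF plus sidecar
#'
#' @param path TIFF path (one page per channel).
#' @param sidecar Sidecar JSON path (default `<path>.json`); alternatively
#'   supply `channels` and `pixel_size` directly.
#' @param channels Optional character vector naming the pages in order.
#' @param pixel_size Optional calibration (um/px); required when no
#'   sidecar is available (no silent default).
#' @return A `MultiChannelSection`.
#' @export
read_section <- function(path, sidecar = paste0(path, ".json"),
                         channels = NULL, pixel_size = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (file.exists(sidecar) && is.null(channels)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    channels <- sc$channels
    if (is.null(pixel_size)) pixel_size <- sc$pixel_size
  }
  if (is.null(channels))
    stop("no sidecar found and no 'channels' given: channel names required")
  if (length(channels) != length(pages))
    stop(sprintf("channel map names %d channel(s) but the file has %d page(s)",
                 length(channels), length(pages)))
  if (is.null(pixel_size))
    stop("pixel size not available from sidecar or argument; refusing to guess")
  need <- c("nuclei", "glucagon", "insulin")
  miss <- setdiff(need, channels)
  if (length(miss))
    stop("missing required channel(s): ", paste(miss, collapse = ", "))
  chans <- lapply(pages, function(p) round(p * 65535))
  names(chans) <- channels
  multichannel_section(chans, pixel_size)
}

#' Write a label or binary mask as 16-bit TIFF
#'
#' @param mask Integer label matrix or logical mask.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  m <- if (is.logical(mask)) mask * 1L else mask
  if (max(m) > 65535) stop("more than 65535 labels cannot be stored in 16 bits")
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a label mask written by [write_mask()]
#'
#' @param path TIFF path.
#' @return Integer matrix.
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Write a per-nucleus table as CSV
#'
#' Columns: label, centroid_x, centroid_y, area_um2, eq_diameter_um and,
#' when assigned, compartment.
#'
#' @param nuclei A `NucleusSet`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_nuclei <- function(nuclei, path) {
  stopifnot(inherits(nuclei, "NucleusSet"))
  tab <- nuclei$table
  out <- data.frame(label = tab$label, centroid_x = tab$cx,
                    centroid_y = tab$cy, area_um2 = tab$area_um2,
                    eq_diameter_um = tab$eq_diameter_um)
  if ("compartment" %in% names(tab)) out$compartment <- tab$compartment
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a colocalisation result as JSON plus an optional scatter CSV
#'
#' @param result A `ColocResult` from [manders()].
#' @param path Output JSON path.
#' @param scatter Optional data.frame from [scatter_data()]; written as CSV
#'   at `<path base>_scatter.csv`.
#' @return `path`, invisibly.
#' @export
write_coloc <- function(result, path, scatter = NULL) {
  stopifnot(inherits(result, "ColocResult"))
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE, digits = NA)
  if (!is.null(scatter))
    utils::write.csv(scatter, sub("\\.json$", "", path) |>
                       paste0("_scatter.csv"), row.names = FALSE)
  invisible(path)
}
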