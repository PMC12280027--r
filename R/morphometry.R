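# Per-section morphometric metrics derived from a CompartmentSet, a
# NucleusSet and an optional marker channel.

#' Fractional area of a compartment
#'
#' @param area Compartment area (um^2).
#' @param denominator_area Reference area (um^2): total tissue (default
#'   convention) or exocrine area.
#' @return Percentage `100 * area / denominator_area`.
#' @export
fractional_area <- function(area, denominator_area) {
  stopifnot_scalar(area, "area", nonneg = TRUE)
  stopifnot_scalar(denominator_area, "denominator_area")
  if (denominator_area <= 0) stop("denominator area must be > 0")
  100 * area / denominator_area
}

#' Mean area per islet
#'
#' @param total_area Total compartment area over the section (um^2).
#' @param islet_count Number of retained islets.
#' @return `total_area / islet_count` in um^2, or `NA` when there are no
#'   islets.
#' @export
mean_area_per_islet <- function(total_area, islet_count) {
  if (islet_count <= 0) return(NA_real_)
  total_area / islet_count
}

#' Islet density
#'
#' @param islet_count Number of retained islets.
#' @param tissue_area Tissue area in um^2.
#' @return Islets per mm^2.
#' @export
islet_density <- function(islet_count, tissue_area) {
  if (tissue_area <= 0) stop("tissue area must be > 0")
  islet_count / (tissue_area / 1e6)
}

#' Islet diameters (maximum Feret)
#'
#' Longest-axis diameter of each labelled islet: the maximum pairwise
#' distance between boundary pixel centres, in micrometres. A single-pixel
#' object has diameter 0 by convention.
#'
#' @param whole_islet Integer islet label matrix.
#' @param pixel_size Micrometres per pixel.
#' @return Named numeric vector of diameters (um), one per islet label.
#' @export
islet_diameters <- function(whole_islet, pixel_size) {
  k <- max(whole_islet)
  if (k == 0L) return(stats::setNames(numeric(0), character(0)))
  idx <- which(whole_islet > 0L)
  v <- whole_islet[idx]
  rows <- ((idx - 1L) %% nrow(whole_islet)) + 1L
  cols <- ((idx - 1L) %/% nrow(whole_islet)) + 1L
  out <- vapply(seq_len(k), function(i) {
    s <- v == i
    if (!any(s)) return(NA_real_)
    max_feret_px(cbind(cols[s], rows[s])) * pixel_size
  }, numeric(1L))
  stats::setNames(out, seq_len(k))
}

#' Estimated cell size from compartment area and nucleus count
#'
#' @param compartment_area Area of the compartment (um^2).
#' @param nuclei_count Number of nuclei assigned to the compartment.
#' @return `area / count` (um^2 per cell) or `NA` when the count is 0.
#' @export
estimated_cell_size <- function(compartment_area, nuclei_count) {
  if (nuclei_count <= 0) return(NA_real_)
  compartment_area / nuclei_count
}

#' Nuclei count as a percentage of total islet nuclei
#'
#' @param count Nuclei in the compartment.
#' @param total_islet_nuclei Total nuclei within islets.
#' @return Percentage, or `NA` when the total is 0.
#' @export
normalized_nuclei_count <- function(count, total_islet_nuclei) {
  if (total_islet_nuclei <= 0) return(NA_real_)
  if (count > total_islet_nuclei)
    stop("compartment count exceeds the islet total")
  100 * count / total_islet_nuclei
}

#' Proportion of islets containing alpha cells
#'
#' An islet is alpha-positive when its glucagon-positive area (alpha-only
#' plus bihormonal pixels) is at least `min_alpha_area` (default: any
#' positive pixel).
#'
#' @param compartments A `CompartmentSet`.
#' @param min_alpha_area Minimum glucagon-positive area (um^2).
#' @return Percentage of islets, or `NA` when there are no islets.
#' @export
alpha_positive_islet_fraction <- function(compartments, min_alpha_area = 0) {
  stopifnot(inherits(compartments, "CompartmentSet"))
  stopifnot_scalar(min_alpha_area, "min_alpha_area", nonneg = TRUE)
  k <- max(compartments$whole_islet)
  if (k == 0L) return(NA_real_)
  apos <- compartments$alpha_only | compartments$bihormonal
  lab <- compartments$whole_islet[apos]
  a_area <- tabulate(lab[lab > 0L], k) * compartments$pixel_size^2
  pos <- if (min_alpha_area > 0) a_area >= min_alpha_area else a_area > 0
  100 * sum(pos) / k
}

#' Marker quantification within compartments
#'
#' Mean-filters and thresholds the marker channel, then reports marker-
#' positive areas within the islet, alpha-only and bihormonal compartments
#' and integrated marker intensities per compartment area. Intensity for a
#' compartment is the sum of raw marker-channel intensities over the
#' compartment mask divided by the compartment area in mm^2 (AU/mm^2).
#'
#' @param marker Marker channel matrix.
#' @param compartments A `CompartmentSet`.
#' @param mean_radius Mean-filter radius (um) applied before thresholding.
#' @param method,value Threshold method and fixed value, as in
#'   [threshold_channel()].
#' @return Named list of marker metrics (areas um^2, percentages,
#'   intensities AU/mm^2) plus the threshold used.
#' @export
marker_metrics <- function(marker, compartments, mean_radius = 1.3,
                           method = c("otsu", "fixed"), value = NULL) {
  if (is.null(marker)) stop("marker channel is missing")
  stopifnot(inherits(compartments, "CompartmentSet"),
            all(dim(marker) == dim(compartments$tissue)))
  ps <- compartments$pixel_size
  pre <- preprocess_channel(marker, closing_radius = 0,
                            mean_radius = mean_radius, pixel_size = ps)
  mk <- suppressWarnings(threshold_channel(pre, method, value,
                                           mask = compartments$tissue))
  fp <- compartments$whole_islet > 0L
  alpha <- compartments$alpha_only
  area <- function(m) sum(m) * ps^2
  intensity <- function(mask) {
    a <- area(mask)
    if (a <= 0) return(NA_real_)
    sum(marker[mask]) / (a / 1e6)
  }
  k <- max(compartments$whole_islet)
  list(threshold = attr(mk, "threshold"),
       marker_area_um2 = area(mk & fp),
       marker_area_total_um2 = area(mk & compartments$tissue),
       marker_mean_area_per_islet_um2 = mean_area_per_islet(area(mk & fp), k),
       marker_pct_of_islet = if (area(fp) > 0) 100 * area(mk & fp) / area(fp) else NA_real_,
       marker_pct_of_alpha = if (area(alpha) > 0) 100 * area(mk & alpha) / area(alpha) else NA_real_,
       marker_intensity_alpha_au_mm2 = intensity(alpha),
       marker_intensity_islet_au_mm2 = intensity(fp))
}

#' All per-section morphometric metrics
#'
#' Computes the complete metric set for one section: compartment areas and
#' fractional areas (tissue or exocrine denominator), mean areas per
#' islet, islet count/density/diameters, proportions of islet area,
#' nucleus counts and estimated cell sizes, the alpha-positive islet
#' fraction and (when a marker channel is present) marker metrics.
#'
#' @param compartments A `CompartmentSet`.
#' @param nuclei A `NucleusSet` with compartment assignments (see
#'   [assign_nuclei()]); may be `NULL` to skip nucleus-derived metrics.
#' @param marker Optional marker channel matrix.
#' @param fractional_mode Denominator for fractional areas: `"tissue"`
#'   (default, total section area) or `"exocrine"`.
#' @param min_alpha_area Threshold for calling an islet alpha-positive
#'   (um^2).
#' @return A one-row data.frame of named metrics (unit-suffixed columns).
#' @export
section_metrics <- function(compartments, nuclei = NULL, marker = NULL,
                            fractional_mode = c("tissue", "exocrine"),
                            min_alpha_area = 0) {
  stopifnot(inherits(compartments, "CompartmentSet"))
  fractional_mode <- match.arg(fractional_mode)
  ps <- compartments$pixel_size
  area <- function(m) sum(m) * ps^2
  fp <- compartments$whole_islet > 0L
  k <- max(compartments$whole_islet)
  a_islet <- area(fp); a_alpha <- area(compartments$alpha_only)
  a_beta <- area(compartments$beta_only); a_bih <- area(compartments$bihormonal)
  a_tissue <- area(compartments$tissue); a_exo <- area(compartments$exocrine)
  denom <- if (fractional_mode == "tissue") a_tissue else a_exo
  diam <- islet_diameters(compartments$whole_islet, ps)

  counts <- c(alpha = 0L, beta = 0L, bihormonal = 0L)
  if (!is.null(nuclei) && "compartment" %in% names(nuclei$table)) {
    tb <- table(nuclei$table$compartment)
    for (nm in names(counts)) counts[nm] <- as.integer(tb[nm])
    counts[is.na(counts)] <- 0L
  }
  n_islet_nuc <- sum(counts)

  out <- data.frame(
    tissue_area_um2 = a_tissue,
    exocrine_area_um2 = a_exo,
    islet_count = k,
    islet_density_per_mm2 = islet_density(k, a_tissue),
    islet_area_um2 = a_islet,
    alpha_area_um2 = a_alpha,
    beta_area_um2 = a_beta,
    bihormonal_area_um2 = a_bih,
    islet_fractional_area_pct = fractional_area(a_islet, denom),
    alpha_fractional_area_pct = fractional_area(a_alpha, denom),
    beta_fractional_area_pct = fractional_area(a_beta, denom),
    bihormonal_fractional_area_pct = fractional_area(a_bih, denom),
    mean_islet_area_um2 = mean_area_per_islet(a_islet, k),
    alpha_mean_area_per_islet_um2 = mean_area_per_islet(a_alpha, k),
    beta_mean_area_per_islet_um2 = mean_area_per_islet(a_beta, k),
    bihormonal_mean_area_per_islet_um2 = mean_area_per_islet(a_bih, k),
    alpha_prop_of_islet_pct = if (a_islet > 0) 100 * a_alpha / a_islet else NA_real_,
    beta_prop_of_islet_pct = if (a_islet > 0) 100 * a_beta / a_islet else NA_real_,
    bihormonal_prop_of_islet_pct = if (a_islet > 0) 100 * a_bih / a_islet else NA_real_,
    mean_islet_diameter_um = if (k > 0) mean(diam) else NA_real_,
    alpha_positive_islet_pct = alpha_positive_islet_fraction(compartments, min_alpha_area),
    nuclei_alpha_count = counts[["alpha"]],
    nuclei_beta_count = counts[["beta"]],
    nuclei_bihormonal_count = counts[["bihormonal"]],
    nuclei_islet_count = n_islet_nuc,
    norm_nuclei_alpha_pct = normalized_nuclei_count(counts[["alpha"]], n_islet_nuc),
    norm_nuclei_beta_pct = normalized_nuclei_count(counts[["beta"]], n_islet_nuc),
    est_cell_size_alpha_um2 = estimated_cell_size(a_alpha, counts[["alpha"]]),
    est_cell_size_beta_um2 = estimated_cell_size(a_beta, counts[["beta"]]),
    row.names = NULL)

  if (!is.null(marker)) {
    mm <- marker_metrics(marker, compartments)
    out$marker_area_um2 <- mm$marker_area_um2
    out$marker_fractional_area_pct <- fractional_area(mm$marker_area_total_um2, denom)
    out$marker_mean_area_per_islet_um2 <- mm$marker_mean_area_per_islet_um2
    out$marker_pct_of_islet <- mm$marker_pct_of_islet
    out$marker_pct_of_alpha <- mm$marker_pct_of_alpha
    out$marker_intensity_alpha_au_mm2 <- mm$marker_intensity_alpha_au_mm2
    out$marker_intensity_islet_au_mm2 <- mm$marker_intensity_islet_au_mm2
  }
  out
}
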