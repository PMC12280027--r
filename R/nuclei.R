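# Nucleus segmentation, size filtering, and compartment assignment.

new_nucleus_set <- function(labels, table, pixel_size) {
  structure(list(labels = labels, table = table, pixel_size = pixel_size),
            class = "NucleusSet")
}

#' @export
print.NucleusSet <- function(x, ...) {
  cat(sprintf("NucleusSet: %d nuclei; mean equivalent diameter %.2f um\n",
              nrow(x$table),
              if (nrow(x$table)) mean(x$table$eq_diameter_um) else NA_real_))
  if ("compartment" %in% names(x$table) && nrow(x$table))
    print(table(x$table$compartment))
  invisible(x)
}

#' Segment nuclei by distance-transform watershed
#'
#' Foreground by Otsu threshold of the (optionally smoothed) nuclei
#' channel, then splitting of touching nuclei by a watershed on the
#' Euclidean distance transform; seeds are the h-maxima of the distance
#' map (`h` = watershed tolerance, default 1 px).
#'
#' @param raster Nuclei (DAPI) channel matrix.
#' @param pixel_size Micrometres per pixel.
#' @param mean_radius Pre-smoothing mean-filter radius (um); 0 disables.
#' @param h Watershed tolerance in pixels (minimum height of a distance
#'   maximum above its merge point to seed a separate nucleus).
#' @return A `NucleusSet`: integer label matrix plus a per-nucleus table
#'   (label, centroid `cx`/`cy` in pixels, `area_um2`, `eq_diameter_um`
#'   with equivalent diameter 2*sqrt(area/pi)). A blank channel yields an
#'   empty set, not an error.
#' @export
segment_nuclei <- function(raster, pixel_size, mean_radius = 0.65, h = 1) {
  stopifnot(is.matrix(raster))
  stopifnot_scalar(pixel_size, "pixel_size", positive = TRUE)
  empty <- function() new_nucleus_set(
    matrix(0L, nrow(raster), ncol(raster)),
    data.frame(label = integer(), cx = numeric(), cy = numeric(),
               area_um2 = numeric(), eq_diameter_um = numeric()),
    pixel_size)
  if (max(raster) <= min(raster)) return(empty())
  sm <- if (mean_radius > 0) {
    k <- disc_brush(um_to_px(mean_radius, pixel_size))
    EBImage::imageData(EBImage::filter2(raster, k / sum(k), boundary = "replicate"))
  } else raster
  fg <- suppressWarnings(threshold_channel(sm))
  if (!any(fg)) return(empty())
  dm <- EBImage::distmap(fg * 1L)
  lab <- EBImage::imageData(EBImage::watershed(dm, tolerance = h, ext = 1L))
  tab <- label_table(lab)
  tab$area_um2 <- tab$area_px * pixel_size^2
  tab$eq_diameter_um <- 2 * sqrt(tab$area_um2 / pi)
  tab$area_px <- NULL
  new_nucleus_set(matrix(as.integer(lab), nrow(lab), ncol(lab)), tab, pixel_size)
}

#' Remove over-sized nucleus detections
#'
#' Objects with equivalent diameter strictly greater than `max_diameter`
#' are removed (artefact and clump rejection).
#'
#' @param nuclei A `NucleusSet`.
#' @param max_diameter Maximum retained equivalent diameter (um),
#'   default 10.
#' @return The filtered `NucleusSet` (labels of removed objects zeroed).
#' @export
filter_nuclei <- function(nuclei, max_diameter = 10) {
  stopifnot(inherits(nuclei, "NucleusSet"))
  stopifnot_scalar(max_diameter, "max_diameter", positive = TRUE)
  drop <- nuclei$table$label[nuclei$table$eq_diameter_um > max_diameter]
  if (length(drop)) {
    nuclei$labels[nuclei$labels %in% drop] <- 0L
    nuclei$table <- nuclei$table[!(nuclei$table$label %in% drop), , drop = FALSE]
    rownames(nuclei$table) <- NULL
  }
  nuclei
}

#' Assign nuclei to islet compartments by centroid membership
#'
#' Each nucleus is assigned to the compartment containing its centroid
#' pixel: `alpha`, `beta` or `bihormonal` within islets, `exocrine` in
#' tissue outside islets. Centroids falling outside the tissue mask are
#' assigned `exocrine` with a warning.
#'
#' @param nuclei A `NucleusSet`.
#' @param compartments A `CompartmentSet` on the same pixel grid.
#' @return The `NucleusSet` with a `compartment` factor column added
#'   (levels alpha, beta, bihormonal, islet_other, exocrine).
#' @export
assign_nuclei <- function(nuclei, compartments) {
  stopifnot(inherits(nuclei, "NucleusSet"), inherits(compartments, "CompartmentSet"))
  tab <- nuclei$table
  lev <- c("alpha", "beta", "bihormonal", "islet_other", "exocrine")
  if (nrow(tab) == 0L) {
    tab$compartment <- factor(character(0), levels = lev)
    nuclei$table <- tab
    return(nuclei)
  }
  ri <- pmin(pmax(round(tab$cy), 1L), nrow(compartments$tissue))
  ci <- pmin(pmax(round(tab$cx), 1L), ncol(compartments$tissue))
  idx <- cbind(ri, ci)
  comp <- rep("exocrine", nrow(tab))
  comp[compartments$whole_islet[idx] > 0L] <- "islet_other"
  comp[compartments$alpha_only[idx]] <- "alpha"
  comp[compartments$beta_only[idx]] <- "beta"
  comp[compartments$bihormonal[idx]] <- "bihormonal"
  outside <- !compartments$tissue[idx] & comp == "exocrine"
  if (any(outside))
    warning(sprintf("%d nucleus centroid(s) outside the tissue mask; assigned exocrine",
                    sum(outside)))
  tab$compartment <- factor(comp, levels = lev)
  nuclei$table <- tab
  nuclei
}
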