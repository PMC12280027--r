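# Segmentation: hormone channels -> whole-islet map and cell compartments.
# Operator sequence: grayscale closing + mean filter per channel, Otsu
# threshold, union of the hormone masks closed and size-filtered into
# labelled whole islets, then compartmentalisation into alpha-only /
# beta-only / bihormonal territories and exocrine tissue.

#' Morphological closing and mean filtering of a channel raster
#'
#' Grayscale closing with a disc structuring element (fills small dark gaps
#' and links nearby objects) followed by a disc mean filter (noise
#' reduction). A radius of 0 disables the corresponding step.
#'
#' @param raster Numeric matrix.
#' @param closing_radius,mean_radius Radii in micrometres; converted to
#'   whole pixels via `pixel_size` (default 1.3 um = 2 px at the default
#'   0.65 um/px calibration).
#' @param pixel_size Micrometres per pixel.
#' @return Filtered matrix of the same dimensions.
#' @export
preprocess_channel <- function(raster, closing_radius = 1.3, mean_radius = 1.3,
                               pixel_size = 0.65) {
  stopifnot(is.matrix(raster))
  stopifnot_scalar(closing_radius, "closing_radius", nonneg = TRUE)
  stopifnot_scalar(mean_radius, "mean_radius", nonneg = TRUE)
  r_cl <- um_to_px(closing_radius, pixel_size)
  r_mn <- um_to_px(mean_radius, pixel_size)
  if (2L * max(r_cl, r_mn) + 1L > min(dim(raster)))
    stop("filter radius exceeds the image size")
  out <- raster
  scale <- max(out)
  if (r_cl > 0L && scale > 0) {
    # EBImage grayscale morphology clips to [0,1]: rescale around it
    out <- EBImage::imageData(EBImage::closing(out / scale, disc_brush(r_cl))) * scale
  }
  if (r_mn > 0L) {
    k <- disc_brush(r_mn)
    out <- EBImage::imageData(EBImage::filter2(out, k / sum(k),
                                               boundary = "replicate"))
    out <- pmax(out, 0)
  }
  out
}

#' Otsu threshold of a raster
#'
#' Exhaustive search over `levels` evenly spaced cut points between the
#' raster minimum and maximum, maximising the between-class variance of
#' the two classes `x <= t` and `x > t`.
#'
#' @param raster Numeric matrix.
#' @param levels Number of histogram bins (default 256).
#' @param mask Optional logical matrix restricting the histogram (e.g. the
#'   tissue footprint, so empty slide does not dominate the background
#'   class); the threshold still applies to the whole raster.
#' @return The threshold (intensity units). For a constant raster the
#'   maximum value is returned with a warning (empty mask under `>`).
#' @export
otsu_threshold <- function(raster, levels = 256L, mask = NULL) {
  v <- if (is.null(mask)) as.numeric(raster) else as.numeric(raster[mask])
  if (length(v) == 0L) {
    warning("empty mask: no pixels to threshold")
    return(max(as.numeric(raster)))
  }
  lo <- min(v); hi <- max(v)
  if (hi <= lo) {
    warning("constant raster: degenerate histogram, returning its value")
    return(hi)
  }
  h <- tabulate(pmin(levels, floor((v - lo) / (hi - lo) * levels) + 1L), levels)
  p <- h / sum(h)
  mids <- lo + (seq_len(levels) - 0.5) * (hi - lo) / levels
  w1 <- cumsum(p)
  mu1 <- cumsum(p * mids)
  mu_t <- mu1[levels]
  bc <- (mu_t * w1 - mu1)^2 / (w1 * (1 - w1))
  bc[!is.finite(bc)] <- -Inf
  k <- which.max(bc)             # smallest maximising cut on ties
  lo + k * (hi - lo) / levels    # upper edge of bin k
}

#' Threshold a channel into a binary mask
#'
#' @param raster Numeric matrix.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param value Threshold for `method = "fixed"`.
#' @param mask Optional histogram restriction passed to [otsu_threshold()].
#' @return Logical matrix `raster > threshold`, with the threshold used
#'   stored in attribute `"threshold"`.
#' @export
threshold_channel <- function(raster, method = c("otsu", "fixed"),
                              value = NULL, mask = NULL) {
  method <- match.arg(method)
  t <- if (method == "otsu") otsu_threshold(raster, mask = mask) else {
    stopifnot_scalar(value, "value")
    value
  }
  structure(raster > t, threshold = t)
}

#' Segment the tissue footprint of a section
#'
#' Thresholds the sum projection over all channels and fills holes,
#' yielding the whole-tissue mask used as the fractional-area and
#' islet-density denominator. The Otsu threshold is computed on the
#' log-transformed projection (`log1p`), which separates slide background
#' from tissue autofluorescence robustly even when a small fraction of
#' very bright hormone signal dominates the linear histogram.
#'
#' @param section A `MultiChannelSection`.
#' @return Logical tissue mask with attribute `"threshold"` (on the
#'   intensity scale of the summed projection).
#' @export
segment_tissue <- function(section) {
  stopifnot(inherits(section, "MultiChannelSection"))
  proj <- Reduce(`+`, section$channels)
  if (max(proj) <= min(proj)) {
    warning("blank section: empty tissue mask")
    return(structure(matrix(FALSE, nrow(proj), ncol(proj)), threshold = max(proj)))
  }
  t_log <- otsu_threshold(log1p(proj))
  m <- proj > expm1(t_log)
  filled <- EBImage::imageData(EBImage::fillHull(m * 1L)) > 0L
  structure(filled, threshold = expm1(t_log))
}

# 8-connected components of a logical mask, labelled 1..K. EBImage's
# bwlabel is 4-connected; diagonal adjacencies are merged afterwards with
# a union-find over label ids.
label_components <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(mask * 1L))
  k <- max(lab)
  if (k <= 1L) return(matrix(as.integer(lab), nrow(lab), ncol(lab)))
  nr <- nrow(lab); nc <- ncol(lab)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1L, -1L])),   # down-right
    cbind(as.vector(lab[-1L, -nc]), as.vector(lab[-nr, -1L])))   # up-right
  pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L & pairs[, 1L] != pairs[, 2L], ,
                 drop = FALSE]
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (i in seq_len(nrow(pairs))) unite(pairs[i, 1L], pairs[i, 2L])
  }
  root <- vapply(seq_len(k), find, integer(1L))
  relab <- match(root, sort(unique(root)))
  out <- matrix(0L, nr, nc)
  pos <- lab > 0L
  out[pos] <- relab[lab[pos]]
  out
}

#' Assemble labelled whole islets from the hormone masks
#'
#' Whole islets are the 8-connected components of the closed union of the
#' glucagon and insulin masks; components smaller than `min_area` are
#' removed (retain area >= `min_area`) and the survivors relabelled 1..K.
#'
#' @param alpha_mask,beta_mask Logical matrices (thresholded glucagon /
#'   insulin channels).
#' @param min_area Minimum retained islet area in um^2 (default 1000).
#' @param pixel_size Micrometres per pixel.
#' @param closing_radius Disc radius (um) of the shape-refining closing
#'   applied to the union before labelling.
#' @return Integer label matrix (0 = background, 1..K = islets).
#' @export
assemble_islets <- function(alpha_mask, beta_mask, min_area = 1000,
                            pixel_size = 0.65, closing_radius = 3) {
  stopifnot(is.matrix(alpha_mask), is.matrix(beta_mask),
            all(dim(alpha_mask) == dim(beta_mask)))
  u <- (alpha_mask | beta_mask)
  r_cl <- um_to_px(closing_radius, pixel_size)
  if (r_cl > 0L && any(u))
    u <- EBImage::imageData(EBImage::closing(u * 1L, disc_brush(r_cl))) > 0L
  lab <- label_components(u)
  if (max(lab) == 0L) return(lab)
  areas <- tabulate(lab[lab > 0L]) * pixel_size^2
  keep <- which(areas >= min_area)
  relab <- integer(max(lab))
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  pos <- lab > 0L
  out[pos] <- relab[lab[pos]]
  out
}

#' Partition islets into alpha-only, beta-only and bihormonal compartments
#'
#' Within the islet footprint, bihormonal = glucagon AND insulin,
#' alpha-only = glucagon minus insulin, beta-only = insulin minus glucagon.
#' Footprint pixels carrying neither hormone signal (interior gaps filled
#' by the islet closing) are assigned to the nearest hormone-positive
#' class by distance transform, so the three compartments partition the
#' footprint exactly.
#'
#' @param whole_islet Integer islet label matrix from [assemble_islets()].
#' @param alpha_mask,beta_mask Logical hormone masks.
#' @param tissue Optional logical tissue mask (defaults to the islet
#'   footprint united with both hormone masks).
#' @param pixel_size Micrometres per pixel.
#' @return An object of class `CompartmentSet`: list with `whole_islet`
#'   (label matrix), logical masks `alpha_only`, `beta_only`, `bihormonal`,
#'   `tissue`, `exocrine`, and `pixel_size`.
#' @export
compartmentalize <- function(whole_islet, alpha_mask, beta_mask,
                             tissue = NULL, pixel_size = 0.65) {
  stopifnot(all(dim(whole_islet) == dim(alpha_mask)),
            all(dim(whole_islet) == dim(beta_mask)))
  fp <- whole_islet > 0L
  bih <- fp & alpha_mask & beta_mask
  a_only <- fp & alpha_mask & !beta_mask
  b_only <- fp & beta_mask & !alpha_mask
  gap <- fp & !alpha_mask & !beta_mask
  if (any(gap)) {
    # nearest-class assignment: distance to the complement of each class
    d_list <- lapply(list(a_only, b_only, bih), function(m) {
      if (!any(m)) return(matrix(Inf, nrow(m), ncol(m)))
      EBImage::imageData(EBImage::distmap(1L - m * 1L))
    })
    gi <- which(gap)
    dmat <- cbind(d_list[[1L]][gi], d_list[[2L]][gi], d_list[[3L]][gi])
    cls <- max.col(-dmat, ties.method = "first")  # ties: alpha, beta, bihormonal
    a_only[gi[cls == 1L]] <- TRUE
    b_only[gi[cls == 2L]] <- TRUE
    bih[gi[cls == 3L]] <- TRUE
  }
  if (is.null(tissue)) tissue <- fp | alpha_mask | beta_mask
  structure(list(whole_islet = whole_islet, alpha_only = a_only,
                 beta_only = b_only, bihormonal = bih, tissue = tissue,
                 exocrine = derive_exocrine(tissue, whole_islet),
                 pixel_size = pixel_size),
            class = "CompartmentSet")
}

#' Exocrine tissue mask
#'
#' @param tissue Logical tissue mask.
#' @param whole_islet Integer islet label matrix.
#' @return Logical mask: tissue with the whole-islet footprint removed.
#' @export
derive_exocrine <- function(tissue, whole_islet) {
  stopifnot(all(dim(tissue) == dim(whole_islet)))
  tissue & !(whole_islet > 0L)
}

#' @export
print.CompartmentSet <- function(x, ...) {
  ps2 <- x$pixel_size^2
  cat(sprintf(paste0("CompartmentSet: %d islet(s); areas (um^2): islet %.0f, ",
                     "alpha-only %.0f, beta-only %.0f, bihormonal %.0f, tissue %.0f\n"),
              max(x$whole_islet), sum(x$whole_islet > 0L) * ps2,
              sum(x$alpha_only) * ps2, sum(x$beta_only) * ps2,
              sum(x$bihormonal) * ps2, sum(x$tissue) * ps2))
  invisible(x)
}

#' Run the full segmentation sequence on a section
#'
#' Convenience wrapper: tissue segmentation, per-channel preprocessing and
#' Otsu thresholding of the glucagon and insulin channels, whole-islet
#' assembly with size filtering, and compartmentalisation.
#'
#' @param section A `MultiChannelSection` with `glucagon` and `insulin`
#'   channels.
#' @param config A pipeline configuration from [default_config()];
#'   individual entries may be overridden.
#' @return A `CompartmentSet` with attribute `"thresholds"` (named numeric:
#'   tissue, glucagon, insulin).
#' @export
segment_section <- function(section, config = default_config()) {
  stopifnot(inherits(section, "MultiChannelSection"))
  ps <- section$pixel_size
  tissue <- segment_tissue(section)
  pre <- lapply(section$channels[c("glucagon", "insulin")], preprocess_channel,
                closing_radius = config$closing_radius_um,
                mean_radius = config$mean_radius_um, pixel_size = ps)
  # hormone histograms are restricted to tissue so that empty slide does
  # not dominate the background class of the threshold
  a_m <- threshold_channel(pre$glucagon, config$threshold_method,
                           config$fixed_thresholds[["glucagon"]], mask = tissue)
  b_m <- threshold_channel(pre$insulin, config$threshold_method,
                           config$fixed_thresholds[["insulin"]], mask = tissue)
  lab <- assemble_islets(a_m, b_m, min_area = config$min_islet_area_um2,
                         pixel_size = ps,
                         closing_radius = config$islet_closing_radius_um)
  comp <- compartmentalize(lab, a_m, b_m, tissue = tissue | (lab > 0L),
                           pixel_size = ps)
  attr(comp, "thresholds") <- c(tissue = attr(tissue, "threshold"),
                                glucagon = attr(a_m, "threshold"),
                                insulin = attr(b_m, "threshold"))
  comp
}
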