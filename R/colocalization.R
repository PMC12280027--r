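# Manders overlap analysis between two channels of a section.

#' Automatic per-channel thresholds for colocalisation
#'
#' Otsu thresholds computed independently for each channel; a fixed
#' override may be supplied for either channel.
#'
#' @param rasterA,rasterB Numeric matrices of equal dimensions.
#' @param fixedA,fixedB Optional fixed thresholds overriding the automatic
#'   value.
#' @return Named numeric vector `c(tA, tB)`. Constant channels yield a
#'   threshold equal to their value (empty suprathreshold mask) with a
#'   warning.
#' @export
auto_threshold_pair <- function(rasterA, rasterB, fixedA = NULL, fixedB = NULL) {
  stopifnot(is.matrix(rasterA), is.matrix(rasterB),
            all(dim(rasterA) == dim(rasterB)))
  tA <- if (is.null(fixedA)) otsu_threshold(rasterA) else fixedA
  tB <- if (is.null(fixedB)) otsu_threshold(rasterB) else fixedB
  c(tA = tA, tB = tB)
}

#' Manders colocalisation coefficients
#'
#' Intensity-weighted thresholded Manders coefficients. With suprathreshold
#' masks `A+ = {rasterA > tA}` and `B+ = {rasterB > tB}`:
#' `M1 = sum(rasterA over A+ intersect B+) / sum(rasterA over A+)` (the
#' proportion of channel-A signal lying within channel B's suprathreshold
#' mask) and `M2` with the roles swapped. Thresholds gate the masks only;
#' no background is subtracted from the summed intensities.
#'
#' @param rasterA,rasterB Numeric matrices of equal dimensions.
#' @param tA,tB Thresholds (default 0: all positive pixels).
#' @return Object of class `ColocResult`: list with `M1`, `M2` (each in
#'   [0,1], `NA` when the corresponding channel has no suprathreshold
#'   signal) and the thresholds used.
#' @export
manders <- function(rasterA, rasterB, tA = 0, tB = 0) {
  stopifnot(is.matrix(rasterA), is.matrix(rasterB),
            all(dim(rasterA) == dim(rasterB)))
  aPos <- rasterA > tA
  bPos <- rasterB > tB
  sumA <- sum(rasterA[aPos]); sumB <- sum(rasterB[bPos])
  M1 <- if (sumA > 0) sum(rasterA[aPos & bPos]) / sumA else NA_real_
  M2 <- if (sumB > 0) sum(rasterB[aPos & bPos]) / sumB else NA_real_
  structure(list(M1 = M1, M2 = M2, tA = tA, tB = tB), class = "ColocResult")
}

#' @export
print.ColocResult <- function(x, ...) {
  cat(sprintf("Manders coefficients: M1 = %.4f, M2 = %.4f (thresholds %.3g / %.3g)\n",
              x$M1, x$M2, x$tA, x$tB))
  invisible(x)
}

#' Paired pixel-intensity sample for colocalisation scatter plots
#'
#' @param rasterA,rasterB Numeric matrices of equal dimensions.
#' @param max_points Maximum number of pixel pairs; when the image has
#'   fewer pixels all are returned in raster order.
#' @param seed Seed for the uniform subsample (deterministic).
#' @return A data.frame with columns `a` and `b`.
#' @export
scatter_data <- function(rasterA, rasterB, max_points = 1e5, seed = 1) {
  stopifnot(is.matrix(rasterA), is.matrix(rasterB),
            all(dim(rasterA) == dim(rasterB)))
  n <- length(rasterA)
  idx <- if (max_points >= n) seq_len(n) else
    with_rng(seed, sort(sample.int(n, max_points)))
  data.frame(a = as.numeric(rasterA[idx]), b = as.numeric(rasterB[idx]))
}
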