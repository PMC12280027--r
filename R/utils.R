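# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. All package randomness funnels through this.
with_rng <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Derive a child seed from a parent seed and an index, kept within 32-bit range.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1009 + 7919 * as.double(index)) %% 2147483587)
}

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single non-missing number", name), call. = FALSE)
  if (positive && x <= 0) stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonneg && x < 0) stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}

# Odd-sized disc structuring element of pixel radius r (r = 0 -> 1x1 identity).
disc_brush <- function(r_px) {
  if (r_px <= 0) return(matrix(1, 1, 1))
  EBImage::makeBrush(2L * as.integer(r_px) + 1L, shape = "disc")
}

um_to_px <- function(r_um, pixel_size) max(0L, as.integer(round(r_um / pixel_size)))

# TRUE where (row - cy)^2 + (col - cx)^2 <= r^2, applied in place on `mask`.
paint_disc <- function(mask, cx, cy, r) {
  nr <- nrow(mask); nc <- ncol(mask)
  r0 <- max(1L, floor(cy - r)); r1 <- min(nr, ceiling(cy + r))
  c0 <- max(1L, floor(cx - r)); c1 <- min(nc, ceiling(cx + r))
  if (r0 > r1 || c0 > c1) return(mask)
  rows <- r0:r1; cols <- c0:c1
  sub <- outer((rows - cy)^2, (cols - cx)^2, "+") <= r^2
  mask[rows, cols] <- mask[rows, cols] | sub
  mask
}

# Maximum Feret diameter (pixel units) of a set of pixel centres given as
# a two-column matrix (col, row). Uses the convex hull; single pixel -> 0.
max_feret_px <- function(xy) {
  n <- nrow(xy)
  if (n <= 1L) return(0)
  if (n == 2L) return(sqrt(sum((xy[1L, ] - xy[2L, ])^2)))
  h <- grDevices::chull(xy[, 1L], xy[, 2L])
  pts <- xy[h, , drop = FALSE]
  d2 <- 0
  for (i in seq_len(nrow(pts) - 1L)) {
    dd <- (pts[-seq_len(i), 1L] - pts[i, 1L])^2 + (pts[-seq_len(i), 2L] - pts[i, 2L])^2
    d2 <- max(d2, dd)
  }
  sqrt(d2)
}

# Label centroids/areas from a labelled integer matrix. Returns a data.frame
# with one row per positive label present (label, area_px, cx, cy).
label_table <- function(lab) {
  idx <- which(lab > 0L)
  if (length(idx) == 0L)
    return(data.frame(label = integer(), area_px = integer(),
                      cx = numeric(), cy = numeric()))
  v <- lab[idx]
  rows <- ((idx - 1L) %% nrow(lab)) + 1L
  cols <- ((idx - 1L) %/% nrow(lab)) + 1L
  area <- tabulate(v)
  labs <- which(area > 0L)
  cx <- rowsum(as.numeric(cols), v)[, 1L] / area[labs]
  cy <- rowsum(as.numeric(rows), v)[, 1L] / area[labs]
  data.frame(label = labs, area_px = area[labs], cx = unname(cx), cy = unname(cy))
}
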