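#' Parameters for a synthetic immunofluorescence pancreas section
#'
#' Builds the parameter set consumed by [generate_section()]. Defaults are
#' calibrated to a non-pregnant ("control") human donor section: roughly
#' 6 islets of mean area ~6250 um^2 scattered in ~2.4 mm^2 of tissue
#' (whole-islet fractional area ~1.6% of tissue), alpha cells occupying
#' ~6% of islet area, bihormonal territory ~2%, and a marker (e.g. GLP-1)
#' covering ~22% of the alpha territory.
#'
#' @param width,height Canvas size in pixels.
#' @param pixel_size Calibration, micrometres per pixel.
#' @param n_islets Number of islets to place.
#' @param islet_radius_range Length-2 numeric, main-disc radius range (um).
#'   Each islet is a lobulated union of a main disc and three satellite
#'   discs, so rendered islet area is ~1.25x the main-disc area.
#' @param alpha_fraction,beta_fraction,bihormonal_fraction Proportions of
#'   islet area assigned to alpha-only, beta-only and bihormonal territory;
#'   must be in [0,1] and sum to at most 1 (any remainder is assigned to
#'   beta so that the territories tile the islet).
#' @param nuclei_density Nuclei per 1000 um^2 inside islet territory.
#' @param exocrine_nuclei_density Nuclei per 1000 um^2 in exocrine tissue.
#' @param nucleus_radius Rendered nucleus radius (um).
#' @param marker_positive_fraction_of_alpha Fraction of the alpha territory
#'   rendered positive in the marker channel.
#' @param signal_level,background_level Intensity (arbitrary units) added on
#'   positive territory / tissue autofluorescence baseline.
#' @param marker_signal_level Signal level for the marker channel.
#' @param noise_sd Standard deviation of additive Gaussian noise (AU).
#' @param field_amplitude Peak-to-trough amplitude of a smooth low-frequency
#'   background field added within tissue (AU).
#' @param tissue_scale Multiplier on the tissue-ellipse semi-axes (donor
#'   anatomy size; must keep the ellipse on the canvas, <= 1.08).
#' @param seed Integer seed; the same parameters and seed reproduce the
#'   section bit-for-bit.
#' @return An object of class `SectionParams`.
#' @export
section_params <- function(width = 3000, height = 3000, pixel_size = 0.65,
                           n_islets = 6, islet_radius_range = c(32, 47),
                           alpha_fraction = 0.06, beta_fraction = 0.92,
                           bihormonal_fraction = 0.02,
                           nuclei_density = 8, exocrine_nuclei_density = 1,
                           nucleus_radius = 2.5,
                           marker_positive_fraction_of_alpha = 0.22,
                           signal_level = 400, background_level = 15,
                           marker_signal_level = 400,
                           noise_sd = 8, field_amplitude = 4,
                           tissue_scale = 1, seed = 1) {
  stopifnot_scalar(width, "width", positive = TRUE)
  stopifnot_scalar(height, "height", positive = TRUE)
  stopifnot_scalar(pixel_size, "pixel_size", positive = TRUE)
  stopifnot_scalar(n_islets, "n_islets", nonneg = TRUE)
  if (length(islet_radius_range) != 2L || any(islet_radius_range <= 0) ||
      islet_radius_range[1L] > islet_radius_range[2L])
    stop("'islet_radius_range' must be an increasing pair of positive radii (um)")
  fr <- c(alpha_fraction, beta_fraction, bihormonal_fraction,
          marker_positive_fraction_of_alpha)
  if (any(fr < 0) || any(fr > 1))
    stop("territory fractions must lie in [0, 1]")
  if (alpha_fraction + beta_fraction + bihormonal_fraction > 1 + 1e-9)
    stop("alpha + beta + bihormonal fractions must not exceed 1")
  stopifnot_scalar(nuclei_density, "nuclei_density", nonneg = TRUE)
  stopifnot_scalar(exocrine_nuclei_density, "exocrine_nuclei_density", nonneg = TRUE)
  stopifnot_scalar(nucleus_radius, "nucleus_radius", positive = TRUE)
  stopifnot_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  stopifnot_scalar(field_amplitude, "field_amplitude", nonneg = TRUE)
  stopifnot_scalar(tissue_scale, "tissue_scale", positive = TRUE)
  if (tissue_scale > 1.08)
    stop("'tissue_scale' must be <= 1.08 to keep the tissue on the canvas")
  p <- list(width = as.integer(width), height = as.integer(height),
            pixel_size = pixel_size, n_islets = as.integer(n_islets),
            islet_radius_range = as.numeric(islet_radius_range),
            alpha_fraction = alpha_fraction, beta_fraction = beta_fraction,
            bihormonal_fraction = bihormonal_fraction,
            nuclei_density = nuclei_density,
            exocrine_nuclei_density = exocrine_nuclei_density,
            nucleus_radius = nucleus_radius,
            marker_positive_fraction_of_alpha = marker_positive_fraction_of_alpha,
            signal_level = signal_level, background_level = background_level,
            marker_signal_level = marker_signal_level,
            noise_sd = noise_sd, field_amplitude = field_amplitude,
            tissue_scale = tissue_scale, seed = as.integer(seed))
  class(p) <- "SectionParams"
  p
}

#' Construct a multichannel section from channel rasters
#'
#' @param channels Named list of numeric matrices of identical dimensions;
#'   names must include at least `nuclei`, `glucagon` and `insulin`
#'   (`marker` optional).
#' @param pixel_size Micrometres per pixel.
#' @param meta Optional list of free-form metadata (seed, provenance).
#' @return An object of class `MultiChannelSection`.
#' @export
multichannel_section <- function(channels, pixel_size, meta = list()) {
  if (!is.list(channels) || is.null(names(channels)) || any(names(channels) == ""))
    stop("'channels' must be a named list of matrices")
  dims <- lapply(channels, dim)
  if (any(!vapply(channels, is.matrix, logical(1L))))
    stop("all channels must be matrices")
  if (length(unique(vapply(dims, paste, character(1L), collapse = "x"))) != 1L)
    stop("all channels must share the same dimensions")
  if (any(vapply(channels, function(m) any(m < 0), logical(1L))))
    stop("channel intensities must be non-negative")
  stopifnot_scalar(pixel_size, "pixel_size", positive = TRUE)
  structure(list(channels = channels, pixel_size = pixel_size, meta = meta),
            class = "MultiChannelSection")
}

#' @export
print.MultiChannelSection <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("MultiChannelSection: %d x %d px at %.3g um/px; channels: %s\n",
              d[1L], d[2L], x$pixel_size, paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

# Place islet centres by rejection sampling inside the tissue ellipse,
# enforcing centre separation >= 1.1*(ri+rj) + 2*max(ri, rj) px so rendered
# blobs are disjoint and at least two islet radii apart.
place_islets <- function(n, radii_px, ell, max_extent) {
  cx <- numeric(0); cy <- numeric(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(4000L)) {
      # uniform in the ellipse shrunk by the blob extent
      a <- ell$a - max_extent[i]; b <- ell$b - max_extent[i]
      if (a <= 0 || b <= 0) break
      repeat {
        u <- stats::runif(1L, -1, 1); v <- stats::runif(1L, -1, 1)
        if (u * u + v * v <= 1) break
      }
      x <- ell$cx + a * u; y <- ell$cy + b * v
      if (length(cx) > 0L) {
        sep <- 1.1 * (radii_px[seq_along(cx)] + radii_px[i]) +
          2 * pmax(radii_px[seq_along(cx)], radii_px[i])
        if (any((cx - x)^2 + (cy - y)^2 < sep^2)) next
      }
      cx <- c(cx, x); cy <- c(cy, y); placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf(paste0("cannot place %d non-overlapping, well-separated islets ",
                          "on this canvas; reduce n_islets or islet size, ",
                          "or enlarge the canvas"), n), call. = FALSE)
  }
  list(cx = cx, cy = cy)
}

# Greedy blue-noise sampler: up to `count` points inside `mask` (logical
# matrix) with pairwise distance >= min_sep px. Returns matrix [x, y].
sample_points_min_sep <- function(mask, count, min_sep) {
  idx <- which(mask)
  if (length(idx) == 0L || count <= 0L) return(cbind(x = numeric(0), y = numeric(0)))
  nr <- nrow(mask)
  cand <- idx[sample.int(length(idx), min(length(idx), 25L * count))]
  gx <- new.env(hash = TRUE, parent = emptyenv())
  cell <- max(min_sep, 1)
  keep_x <- numeric(count); keep_y <- numeric(count); k <- 0L
  for (p in cand) {
    x <- ((p - 1L) %/% nr) + 1L
    y <- ((p - 1L) %% nr) + 1L
    cxi <- floor(x / cell); cyi <- floor(y / cell)
    ok <- TRUE
    for (dx in -1:1) {
      for (dy in -1:1) {
        key <- paste0(cxi + dx, "_", cyi + dy)
        pts <- gx[[key]]
        if (!is.null(pts) &&
            any((pts[, 1L] - x)^2 + (pts[, 2L] - y)^2 < min_sep^2)) {
          ok <- FALSE; break
        }
      }
      if (!ok) break
    }
    if (ok) {
      key <- paste0(cxi, "_", cyi)
      gx[[key]] <- rbind(gx[[key]], c(x, y))
      k <- k + 1L
      keep_x[k] <- x; keep_y[k] <- y
      if (k >= count) break
    }
  }
  cbind(x = keep_x[seq_len(k)], y = keep_y[seq_len(k)])
}

#' Generate a synthetic multichannel pancreas section with ground truth
#'
#' Renders a tissue ellipse containing lobulated islets, tiles every islet
#' into alpha-only / bihormonal / beta-only cell territories (alpha placed
#' peripherally with the bihormonal arc adjoining it), scatters nuclei with
#' a minimum-separation constraint, and composes nuclei / glucagon /
#' insulin / marker channels with additive Gaussian noise and a smooth
#' background field. Ground-truth masks and areas are taken from the
#' noise-free render, so every true area equals its pixel count times
#' `pixel_size^2` exactly.
#'
#' @param params A [section_params()] object.
#' @return A list with elements `section` (a `MultiChannelSection`) and
#'   `truth` (a `GroundTruth` list: `masks`, per-islet `islet_table`,
#'   `areas` in um^2, `nuclei` centres with compartment labels,
#'   `n_islets`, `pixel_size`).
#' @export
generate_section <- function(params) {
  stopifnot(inherits(params, "SectionParams"))
  with_rng(params$seed, {
    ps <- params$pixel_size
    nr <- params$height; nc <- params$width
    ell <- list(cx = (nc + 1) / 2, cy = (nr + 1) / 2,
                a = 0.46 * nc * params$tissue_scale,
                b = 0.44 * nr * params$tissue_scale)

    tissue <- outer(((seq_len(nr) - ell$cy) / ell$b)^2,
                    ((seq_len(nc) - ell$cx) / ell$a)^2, "+") <= 1

    islet_lab <- matrix(0L, nr, nc)
    alpha <- matrix(FALSE, nr, nc); beta <- matrix(FALSE, nr, nc)
    bih <- matrix(FALSE, nr, nc); marker <- matrix(FALSE, nr, nc)

    n_isl <- params$n_islets
    islet_rows <- vector("list", n_isl)
    if (n_isl > 0L) {
      radii_um <- stats::runif(n_isl, params$islet_radius_range[1L],
                               params$islet_radius_range[2L])
      radii_px <- radii_um / ps
      extent <- 1.15 * radii_px + 2
      ctr <- place_islets(n_isl, radii_px, ell, extent)

      for (i in seq_len(n_isl)) {
        r <- radii_px[i]
        # local bounding box with a 1-px background margin
        half <- ceiling(1.2 * r) + 2L
        r0 <- max(1L, floor(ctr$cy[i] - half)); r1 <- min(nr, ceiling(ctr$cy[i] + half))
        c0 <- max(1L, floor(ctr$cx[i] - half)); c1 <- min(nc, ceiling(ctr$cx[i] + half))
        loc <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
        lcx <- ctr$cx[i] - c0 + 1; lcy <- ctr$cy[i] - r0 + 1
        loc <- paint_disc(loc, lcx, lcy, r)
        ang <- stats::runif(3L, 0, 2 * pi)
        for (k in 1:3)
          loc <- paint_disc(loc, lcx + 0.6 * r * cos(ang[k]),
                            lcy + 0.6 * r * sin(ang[k]), 0.5 * r)

        npx <- sum(loc)
        n_a <- round(params$alpha_fraction * npx)
        n_bi <- round(params$bihormonal_fraction * npx)
        if (n_a + n_bi > npx) n_bi <- npx - n_a

        dm <- EBImage::distmap(loc)
        pix <- which(loc)
        lrow <- ((pix - 1L) %% nrow(loc)) + 1L
        lcol <- ((pix - 1L) %/% nrow(loc)) + 1L
        theta0 <- stats::runif(1L, 0, 2 * pi)
        a_idx <- integer(0); bi_idx <- integer(0)
        if (n_a + n_bi > 0L) {
          # carve territories from a peripheral band several times wider
          # than their joint area so the alpha/bihormonal arcs stay thick
          # relative to the segmentation filter scale
          band_n <- min(npx, max(n_a + n_bi, ceiling(6 * (n_a + n_bi))))
          ob <- order(dm[pix], pix)[seq_len(band_n)]   # outermost band
          th <- (atan2(lrow[ob] - lcy, lcol[ob] - lcx) - theta0) %% (2 * pi)
          oth <- ob[order(th, pix[ob])]
          a_idx <- oth[seq_len(n_a)]
          if (n_bi > 0L) bi_idx <- oth[n_a + seq_len(n_bi)]
        }
        n_mk <- round(params$marker_positive_fraction_of_alpha * n_a)
        mk_idx <- if (n_mk > 0L) a_idx[seq_len(n_mk)] else integer(0)

        # `pos` indexes into the blob pixel list (lrow/lcol)
        sel <- function(pos) {
          cbind(r0 + lrow[pos] - 1L, c0 + lcol[pos] - 1L)
        }
        all_rc <- cbind(r0 + lrow - 1L, c0 + lcol - 1L)
        islet_lab[all_rc] <- i
        if (length(a_idx)) alpha[sel(a_idx)] <- TRUE
        if (length(bi_idx)) bih[sel(bi_idx)] <- TRUE
        if (length(mk_idx)) marker[sel(mk_idx)] <- TRUE

        diam_px <- max_feret_px(cbind(lcol, lrow))
        islet_rows[[i]] <- data.frame(
          islet = i, area_um2 = npx * ps^2,
          diameter_um = diam_px * ps,
          alpha_area_um2 = n_a * ps^2,
          bihormonal_area_um2 = n_bi * ps^2,
          beta_area_um2 = (npx - n_a - n_bi) * ps^2,
          marker_area_um2 = n_mk * ps^2)
      }
      beta <- islet_lab > 0L & !alpha & !bih
    }
    islet_fp <- islet_lab > 0L
    tissue <- tissue | islet_fp   # islets always count as tissue

    # nuclei: per islet-territory and exocrine, minimum separation so that
    # rendered discs stay resolvable by the watershed
    r_n <- params$nucleus_radius / ps
    min_sep <- 2 * r_n + 1.5
    comp_masks <- list(alpha = alpha, beta = beta, bihormonal = bih,
                       exocrine = tissue & !islet_fp)
    dens <- c(alpha = params$nuclei_density, beta = params$nuclei_density,
              bihormonal = params$nuclei_density,
              exocrine = params$exocrine_nuclei_density)
    nuclei_list <- list()
    for (nm in names(comp_masks)) {
      m <- comp_masks[[nm]]
      cnt <- round(dens[[nm]] * sum(m) * ps^2 / 1000)
      if (cnt > 0L) {
        # centres are kept one nucleus radius inside the territory so the
        # rendered disc (and its centroid) lies fully within it
        m_in <- if (any(m)) EBImage::imageData(
          EBImage::erode(m * 1L, disc_brush(ceiling(r_n)))) > 0L else m
        if (!any(m_in)) m_in <- m
        pts <- sample_points_min_sep(m_in, cnt, min_sep)
        if (nrow(pts) > 0L)
          nuclei_list[[nm]] <- data.frame(x = pts[, 1L], y = pts[, 2L],
                                          compartment = nm)
      }
    }
    nuclei <- if (length(nuclei_list)) do.call(rbind, nuclei_list) else
      data.frame(x = numeric(0), y = numeric(0), compartment = character(0))
    rownames(nuclei) <- NULL

    dapi_mask <- matrix(FALSE, nr, nc)
    if (nrow(nuclei) > 0L) {
      # all nuclei share one radius: paint them in a single index assignment
      rr <- ceiling(r_n)
      off <- expand.grid(dy = -rr:rr, dx = -rr:rr)
      off <- off[off$dx^2 + off$dy^2 <= r_n^2, , drop = FALSE]
      py <- rep(nuclei$y, each = nrow(off)) + off$dy
      px <- rep(nuclei$x, each = nrow(off)) + off$dx
      ok <- py >= 1L & py <= nr & px >= 1L & px <= nc
      dapi_mask[cbind(py[ok], px[ok])] <- TRUE
    }

    bg <- params$background_level * tissue
    ch <- list(
      nuclei = bg + params$signal_level * dapi_mask,
      glucagon = bg + params$signal_level * (alpha | bih),
      insulin = bg + params$signal_level * (beta | bih),
      marker = bg + params$marker_signal_level * marker)

    if (params$field_amplitude > 0) {
      phase <- stats::runif(2L, 0, 2 * pi)
      fld <- params$field_amplitude *
        (1 + outer(sin(2 * pi * seq_len(nr) / nr + phase[1L]),
                   cos(2 * pi * seq_len(nc) / nc + phase[2L]))) / 2
      fld <- fld * tissue
      ch <- lapply(ch, function(m) m + fld)
    }
    if (params$noise_sd > 0) {
      ch <- lapply(ch, function(m)
        pmax(m + matrix(stats::rnorm(nr * nc, 0, params$noise_sd), nr, nc), 0))
    }

    islet_table <- if (n_isl > 0L) do.call(rbind, islet_rows) else
      data.frame(islet = integer(0), area_um2 = numeric(0),
                 diameter_um = numeric(0), alpha_area_um2 = numeric(0),
                 bihormonal_area_um2 = numeric(0), beta_area_um2 = numeric(0),
                 marker_area_um2 = numeric(0))

    truth <- structure(list(
      masks = list(islet = islet_lab, alpha = alpha, beta = beta,
                   bihormonal = bih, marker = marker, tissue = tissue),
      islet_table = islet_table,
      areas = list(islet = sum(islet_fp) * ps^2, alpha = sum(alpha) * ps^2,
                   beta = sum(beta) * ps^2, bihormonal = sum(bih) * ps^2,
                   marker = sum(marker) * ps^2, tissue = sum(tissue) * ps^2),
      n_islets = n_isl, nuclei = nuclei, pixel_size = ps),
      class = "GroundTruth")

    list(section = multichannel_section(ch, ps, meta = list(seed = params$seed)),
         truth = truth)
  })
}
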