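# Segmentation operators: morphology, thresholding, islet assembly,
# compartment partition.

test_that("preprocessing matches an explicit dilate-erode oracle and preserves constants", {
  m <- matrix(10, 11, 11); m[3:9, 3:9] <- 100; m[6, 6] <- 10  # 1-px dark hole
  out <- preprocess_channel(m, closing_radius = 1, mean_radius = 0, pixel_size = 1)
  k <- EBImage::makeBrush(3, "disc")
  oracle <- EBImage::imageData(EBImage::erode(EBImage::dilate(m / 100, k), k)) * 100
  expect_equal(out, oracle)
  expect_equal(out[6, 6], 100)  # hole filled

  cm <- matrix(7, 15, 15)
  expect_equal(preprocess_channel(cm, 2, 2, 1), cm)      # constants preserved
  expect_identical(preprocess_channel(m, 0, 0, 1), m)    # zero radii = identity
  expect_error(preprocess_channel(m, closing_radius = 50, pixel_size = 1),
               "radius exceeds")
})

test_that("otsu threshold equals brute-force search over discrete levels", {
  set.seed(42)
  r <- matrix(sample(0:255, 600, TRUE,
                     prob = c(rep(3, 80), rep(1, 100), rep(4, 76))), 20)
  brute <- function(v) {
    best <- -Inf; bt <- 0
    for (t in 0:254) {
      w1 <- mean(v <= t)
      if (w1 == 0 || w1 == 1) next
      bc <- w1 * (1 - w1) * (mean(v[v > t]) - mean(v[v <= t]))^2
      if (bc > best) { best <- bc; bt <- t }
    }
    bt
  }
  t_bf <- brute(as.vector(r))
  t_pkg <- otsu_threshold(r)
  expect_identical(r > t_pkg, r > t_bf)

  # separable bimodal raster: mask = bright pixels; fixed(50) agrees
  b <- matrix(c(0, 100, 0, 100, 100, 0), 2, 3)
  expect_identical(unclass(threshold_channel(b)), b == 100,
                   ignore_attr = TRUE)
  expect_identical(as.logical(threshold_channel(b, "fixed", 50)),
                   as.logical(threshold_channel(b)))
  expect_warning(t0 <- otsu_threshold(matrix(5, 3, 3)), "constant")
  expect_equal(t0, 5)
})

test_that("islet assembly filters by size and uses 8-connectivity", {
  a <- matrix(FALSE, 100, 100); a[1:30, 1:30] <- TRUE        # 900 um^2 at 1 um/px
  b <- matrix(FALSE, 100, 100); b[50:99, 60:81] <- TRUE      # 1100 um^2
  lab <- assemble_islets(a, b, min_area = 1000, pixel_size = 1,
                         closing_radius = 0)
  expect_identical(max(lab), 1L)
  areas <- tabulate(lab[lab > 0L])
  expect_true(all(areas >= 1000))

  # touching alpha and beta blobs merge into one label (8-connectivity)
  a2 <- matrix(FALSE, 50, 50); a2[10:20, 10:20] <- TRUE
  b2 <- matrix(FALSE, 50, 50); b2[21:31, 21:31] <- TRUE      # corner contact
  expect_identical(max(assemble_islets(a2, b2, min_area = 0, pixel_size = 1,
                                       closing_radius = 0)), 1L)

  # empty masks give zero islets
  e <- matrix(FALSE, 20, 20)
  expect_identical(max(assemble_islets(e, e, pixel_size = 1)), 0L)

  # lowering min_area never decreases the islet count
  lab_lo <- assemble_islets(a, b, min_area = 0, pixel_size = 1,
                            closing_radius = 0)
  expect_gte(max(lab_lo), max(lab))
})

test_that("compartmentalization partitions the footprint exactly", {
  A <- matrix(FALSE, 30, 30); A[5:14, 5:14] <- TRUE
  B <- matrix(FALSE, 30, 30); B[5:14, 10:19] <- TRUE   # offset by 5 px
  lab <- assemble_islets(A, B, min_area = 0, pixel_size = 1, closing_radius = 0)
  cs <- compartmentalize(lab, A, B, pixel_size = 1)
  expect_identical(sum(cs$bihormonal), 50L)
  expect_identical(sum(cs$alpha_only) + sum(cs$beta_only) + sum(cs$bihormonal),
                   sum(lab > 0L))
  # idempotence: recompartmentalizing its own masks is a fixed point
  cs2 <- compartmentalize(lab, cs$alpha_only | cs$bihormonal,
                          cs$beta_only | cs$bihormonal, pixel_size = 1)
  expect_identical(cs2$alpha_only, cs$alpha_only)
  expect_identical(cs2$beta_only, cs$beta_only)
  expect_identical(cs2$bihormonal, cs$bihormonal)

  # alpha only: no bihormonal; disjoint masks: bihormonal empty
  csA <- compartmentalize(assemble_islets(A, matrix(FALSE, 30, 30),
                                          min_area = 0, pixel_size = 1,
                                          closing_radius = 0),
                          A, matrix(FALSE, 30, 30), pixel_size = 1)
  expect_identical(sum(csA$bihormonal), 0L)
  expect_identical(csA$alpha_only, A)
})

test_that("exocrine is the tissue minus the islet footprint", {
  tis <- matrix(TRUE, 100, 100)                            # 10,000 px tissue
  lab <- matrix(0L, 100, 100)
  lab[11:20, 11:20] <- 1L                                  # 100 px islet
  exo <- derive_exocrine(tis, lab)
  expect_identical(sum(exo), 10000L - 100L)
  expect_identical(derive_exocrine(tis, matrix(0L, 100, 100)), tis)
  expect_identical(sum(derive_exocrine(lab > 0L, lab)), 0L)
})

test_that("tissue segmentation contains hormone signal and handles blank input", {
  gs <- generate_section(tiny_params(seed = 3, noise_sd = 8, field = 4))
  tis <- segment_tissue(gs$section)
  cfg <- tiny_config()
  comp <- segment_section(gs$section, cfg)
  # every hormone-positive pixel lies within the recovered tissue mask
  expect_true(all(comp$tissue[comp$alpha_only | comp$beta_only | comp$bihormonal]))

  blank <- multichannel_section(list(nuclei = matrix(0, 10, 10),
                                     glucagon = matrix(0, 10, 10),
                                     insulin = matrix(0, 10, 10)), 1)
  expect_warning(tb <- segment_tissue(blank), "blank")
  expect_false(any(tb))
})

test_that("partition invariant holds on random synthetic sections", {
  for (seed in 1:8) {
    gs <- generate_section(tiny_params(seed = seed, noise_sd = 8, field = 4))
    comp <- segment_section(gs$section, tiny_config())
    expect_identical(sum(comp$alpha_only) + sum(comp$beta_only) +
                       sum(comp$bihormonal), sum(comp$whole_islet > 0L))
    expect_false(any(comp$alpha_only & comp$beta_only))
    expect_identical(comp$exocrine, comp$tissue & !(comp$whole_islet > 0L))
  }
})
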