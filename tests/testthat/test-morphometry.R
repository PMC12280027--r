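# Morphometric metrics: arithmetic oracles, Feret diameters, scale
# equivariance, marker quantification.

test_that("area ratios and densities follow their definitions", {
  expect_equal(fractional_area(300, 10000), 3.0)
  expect_equal(fractional_area(0, 10000), 0)
  expect_error(fractional_area(10, 0), "> 0")

  expect_equal(mean_area_per_islet(4000, 2), 2000)
  expect_equal(mean_area_per_islet(1234.5, 1), 1234.5)
  expect_true(is.na(mean_area_per_islet(0, 0)))

  expect_equal(islet_density(5, 10 * 1e6), 0.5)   # 5 islets in 10 mm^2
  expect_equal(islet_density(0, 1e6), 0)
  expect_error(islet_density(1, 0), "> 0")

  expect_equal(estimated_cell_size(500, 10), 50)
  expect_true(is.na(estimated_cell_size(500, 0)))

  expect_equal(normalized_nuclei_count(20, 100), 20)
  expect_equal(normalized_nuclei_count(100, 100), 100)
  expect_true(is.na(normalized_nuclei_count(0, 0)))
  expect_error(normalized_nuclei_count(5, 2), "exceeds")
})

test_that("islet diameter is the maximum Feret over pixel centres", {
  lab <- matrix(0L, 20, 20)
  lab[5, 3:13] <- 1L                      # 11 x 1 px horizontal line
  expect_equal(unname(islet_diameters(lab, 1)["1"]), 10)

  lab2 <- matrix(0L, 10, 10); lab2[4, 4] <- 1L
  expect_equal(unname(islet_diameters(lab2, 1)["1"]), 0)  # single pixel

  # disc of radius r: diameter within 1 px of 2r (brute-force oracle)
  r <- 9
  disc <- isletmorph:::paint_disc(matrix(FALSE, 30, 30), 15, 15, r)
  labd <- matrix(0L, 30, 30); labd[disc] <- 1L
  d_pkg <- unname(islet_diameters(labd, 1)["1"])
  pts <- which(disc, arr.ind = TRUE)
  d_bf <- sqrt(max(outer(pts[, 1], pts[, 1], "-")^2 +
                   outer(pts[, 2], pts[, 2], "-")^2))
  expect_equal(d_pkg, d_bf)
  expect_lt(abs(d_pkg - 2 * r), 1)

  # pixel size scales diameters linearly
  expect_equal(unname(islet_diameters(lab, 2)["1"]), 20)
})

test_that("alpha-positive islet fraction enumerates islets correctly", {
  lab <- matrix(0L, 40, 40)
  lab[2:9, 2:9] <- 1L; lab[2:9, 20:27] <- 2L; lab[25:32, 20:27] <- 3L
  a <- matrix(FALSE, 40, 40); a[3, 3] <- TRUE; a[4, 22] <- TRUE  # islets 1, 2
  b <- lab > 0L & !a
  cs <- compartmentalize(lab, a, b, pixel_size = 1)
  expect_equal(alpha_positive_islet_fraction(cs), 100 * 2 / 3, tolerance = 1e-9)
  # all positive when every islet has alpha signal
  a2 <- a; a2[26, 22] <- TRUE
  cs2 <- compartmentalize(lab, a2, lab > 0L & !a2, pixel_size = 1)
  expect_equal(alpha_positive_islet_fraction(cs2), 100)
  # min-area criterion can exclude barely-positive islets
  expect_equal(alpha_positive_islet_fraction(cs, min_alpha_area = 2), 0)
})

test_that("marker metrics follow pixel-counting and intensity definitions", {
  lab <- matrix(0L, 40, 40); lab[11:26, 11:26] <- 1L       # 256 px islet
  a <- matrix(FALSE, 40, 40); a[11:26, 11:18] <- TRUE      # alpha 128 px
  cs <- compartmentalize(lab, a, lab > 0L & !a, tissue = matrix(TRUE, 40, 40),
                         pixel_size = 1)
  marker <- matrix(0, 40, 40)
  marker[11:18, 11:18] <- 300                              # 64 px inside alpha
  mm <- marker_metrics(marker, cs, mean_radius = 0, method = "fixed", value = 100)
  expect_equal(mm$marker_area_um2, 64)
  expect_equal(mm$marker_pct_of_alpha, 50)                 # 64 of 128
  expect_equal(mm$marker_pct_of_islet, 25)
  # intensity: sum of marker values over alpha / alpha area in mm^2
  expect_equal(mm$marker_intensity_alpha_au_mm2, 64 * 300 / (128 / 1e6))

  blank <- matrix(0, 40, 40)
  mm0 <- marker_metrics(blank, cs, mean_radius = 0, method = "fixed", value = 10)
  expect_equal(mm0$marker_area_um2, 0)
  expect_equal(mm0$marker_intensity_alpha_au_mm2, 0)
  expect_error(marker_metrics(NULL, cs), "missing")
})

test_that("section metrics are deterministic and scale-equivariant", {
  gs <- generate_section(tiny_params(seed = 6))
  comp <- segment_section(gs$section, tiny_config())
  nuc <- assign_nuclei(filter_nuclei(segment_nuclei(
    gs$section$channels$nuclei, 1.5)), comp)
  m1 <- section_metrics(comp, nuc, marker = gs$section$channels$marker)
  m2 <- section_metrics(comp, nuc, marker = gs$section$channels$marker)
  expect_identical(m1, m2)

  # doubling pixel size quadruples areas, doubles diameters, fixes percents
  comp2 <- comp; comp2$pixel_size <- 3
  nuc2 <- nuc; nuc2$pixel_size <- 3
  m3 <- section_metrics(comp2, nuc, marker = gs$section$channels$marker)
  expect_equal(m3$islet_area_um2, m1$islet_area_um2 * 4)
  expect_equal(m3$mean_islet_diameter_um, m1$mean_islet_diameter_um * 2)
  expect_equal(m3$islet_fractional_area_pct, m1$islet_fractional_area_pct)
  expect_equal(m3$alpha_prop_of_islet_pct, m1$alpha_prop_of_islet_pct)

  # proportions of islet partition to 100
  expect_equal(m1$alpha_prop_of_islet_pct + m1$beta_prop_of_islet_pct +
                 m1$bihormonal_prop_of_islet_pct, 100, tolerance = 1e-9)

  # tissue denominator never smaller than exocrine: tissue-fractional <=
  # exocrine-fractional for the same section
  m_exo <- section_metrics(comp, nuc, fractional_mode = "exocrine")
  expect_lte(m1$islet_fractional_area_pct, m_exo$islet_fractional_area_pct)
})
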