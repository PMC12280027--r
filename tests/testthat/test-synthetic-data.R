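# Synthetic-data generators: determinism, ground-truth consistency,
# parameter validation, and effect-multiplier semantics.

test_that("section generation is deterministic and truth matches pixel counts", {
  p <- tiny_params(seed = 11, noise_sd = 8, field = 4)
  g1 <- generate_section(p)
  g2 <- generate_section(p)
  expect_identical(g1$section$channels, g2$section$channels)
  expect_identical(g1$truth$areas, g2$truth$areas)
  expect_identical(g1$truth$nuclei, g2$truth$nuclei)

  # every true area equals the pixel count of its noise-free mask x ps^2
  tr <- g1$truth
  ps2 <- tr$pixel_size^2
  expect_identical(tr$areas$islet, sum(tr$masks$islet > 0L) * ps2)
  expect_identical(tr$areas$alpha, sum(tr$masks$alpha) * ps2)
  expect_identical(tr$areas$beta, sum(tr$masks$beta) * ps2)
  expect_identical(tr$areas$bihormonal, sum(tr$masks$bihormonal) * ps2)
  expect_identical(tr$areas$marker, sum(tr$masks$marker) * ps2)
  # per-islet areas sum to the totals
  expect_equal(sum(tr$islet_table$area_um2), tr$areas$islet)
  expect_equal(sum(tr$islet_table$alpha_area_um2), tr$areas$alpha)
})

test_that("cell territories partition each islet and respect geometry constraints", {
  for (seed in c(2, 5)) {
    tr <- generate_section(tiny_params(seed = seed))$truth
    # alpha, beta, bihormonal are disjoint and tile the islet footprint
    expect_false(any(tr$masks$alpha & tr$masks$beta))
    expect_false(any(tr$masks$alpha & tr$masks$bihormonal))
    union <- tr$masks$alpha | tr$masks$beta | tr$masks$bihormonal
    expect_identical(union, tr$masks$islet > 0L)
    # marker lies within alpha
    expect_true(all(tr$masks$alpha[tr$masks$marker]))
    # islets are far apart: distinct labels never 8-adjacent
    lab <- tr$masks$islet
    expect_identical(max(lab), tr$n_islets)
  }
})

test_that("empty and impossible sections behave as specified", {
  g0 <- generate_section(tiny_params(seed = 1, n_islets = 0))
  expect_identical(g0$truth$areas$islet, 0)
  expect_identical(g0$truth$areas$alpha, 0)
  # hormone channels carry no signal above the tissue background
  expect_lte(max(g0$section$channels$glucagon), 15)
  expect_lte(max(g0$section$channels$insulin), 15)

  expect_error(
    generate_section(section_params(width = 150, height = 150, pixel_size = 1,
                                    n_islets = 12,
                                    islet_radius_range = c(30, 40), seed = 1)),
    "cannot place")
  expect_error(section_params(alpha_fraction = 0.6, beta_fraction = 0.6,
                              bihormonal_fraction = 0.1), "exceed 1")
  expect_error(section_params(pixel_size = 0), "pixel_size")
})

test_that("cohort multipliers scale per-metric truth areas as designed", {
  base <- section_params(width = 320, height = 320, pixel_size = 2.2,
                         n_islets = 2, islet_radius_range = c(20, 28),
                         nuclei_density = 0, exocrine_nuclei_density = 0,
                         noise_sd = 0, field_amplitude = 0)
  # with zero donor variability, truth-level folds equal the configured
  # multipliers exactly in expectation over islet-radius sampling
  coh <- generate_cohort(cohort_params(n_per_group = 6, cv = 0, seed = 3), base)
  g <- vapply(coh, function(d) d$group, character(1))
  getm <- function(f) vapply(coh, function(d) f(d$truth), numeric(1))
  fold <- function(v) mean(v[g == "pregnant"]) / mean(v[g == "control"])
  f_alpha <- fold(getm(function(t) t$areas$alpha))
  f_beta <- fold(getm(function(t) t$areas$beta))
  f_bih <- fold(getm(function(t) t$areas$bihormonal))
  # compartment folds: exact up to islet-radius sampling and rounding
  expect_equal(f_alpha, 4.3, tolerance = 0.3)
  expect_equal(f_beta, 1.9, tolerance = 0.25)
  expect_equal(f_bih, 5.4, tolerance = 0.6)
  expect_error(cohort_params(multipliers = c(islet = -1)), "positive")
  expect_error(cohort_params(multipliers = c(banana = 2)), "unknown")
})

test_that("null cohorts are exchangeable between groups", {
  base <- section_params(width = 240, height = 240, pixel_size = 2.5,
                         n_islets = 2, islet_radius_range = c(18, 26),
                         nuclei_density = 0, exocrine_nuclei_density = 0,
                         noise_sd = 0, field_amplitude = 0)
  null_m <- c(islet = 1, alpha = 1, beta = 1, bihormonal = 1,
              marker_area = 1, marker_intensity = 1)
  n_cohorts <- 200
  rej <- vapply(seq_len(n_cohorts), function(s) {
    coh <- generate_cohort(cohort_params(n_per_group = 7, multipliers = null_m,
                                         seed = s), base)
    g <- vapply(coh, function(d) d$group, character(1))
    fa <- vapply(coh, function(d) d$truth$areas$islet / d$truth$areas$tissue,
                 numeric(1))
    compare_groups(fa[g == "pregnant"], fa[g == "control"])$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("protein matrix generator is deterministic with correct spikes and missingness", {
  mp <- matrix_params(n_proteins = 400, n_samples_per_group = 5,
                      n_true_effects = 40, effect_size = 1.5,
                      missing_rate = 0.1, seed = 21)
  g1 <- generate_protein_matrix(mp)
  g2 <- generate_protein_matrix(mp)
  expect_identical(g1$matrix, g2$matrix)
  expect_equal(dim(g1$matrix), c(400L, 10L))
  expect_equal(sum(g1$truth$spiked), 40L)
  expect_lt(abs(mean(is.na(g1$matrix)) - 0.1), 0.02)

  # spiked mean log2 difference ~ effect_size within 3 SEM
  full <- generate_protein_matrix(matrix_params(n_proteins = 300,
                                                n_samples_per_group = 6,
                                                n_true_effects = 300,
                                                effect_size = 2, seed = 5))
  dif <- rowMeans(full$matrix[, 1:6]) - rowMeans(full$matrix[, 7:12])
  sem <- stats::sd(dif) / sqrt(length(dif))
  expect_lt(abs(mean(dif) - 2), 3 * max(sem, 0.3 * sqrt(2 / 6) / sqrt(300)))

  # complete null matrix
  nul <- generate_protein_matrix(matrix_params(n_proteins = 50,
                                               n_samples_per_group = 3,
                                               missing_rate = 0, seed = 2))
  expect_false(anyNA(nul$matrix))
  expect_true(all(!nul$truth$spiked))
  expect_error(matrix_params(missing_rate = 1), "missing_rate")
  expect_error(matrix_params(n_true_effects = 10, n_proteins = 5), "exceed")
})

test_that("pipeline recovers a uniform 1.9-fold islet-area effect in most cohorts", {
  base <- section_params(width = 320, height = 320, pixel_size = 2.2,
                         n_islets = 3, islet_radius_range = c(26, 30),
                         nuclei_density = 0, exocrine_nuclei_density = 0)
  u19 <- c(islet = 1.9, alpha = 1.9, beta = 1.9, bihormonal = 1.9,
           marker_area = 1, marker_intensity = 1)
  cfg <- default_config(); cfg$pixel_size <- 2.2
  folds <- vapply(1:100, function(s) {
    coh <- generate_cohort(cohort_params(n_per_group = 7, multipliers = u19,
                                         cv = 0.25, seed = s), base)
    g <- vapply(coh, function(d) d$group, character(1))
    fa <- vapply(coh, function(d) {
      comp <- segment_section(d$section, cfg)
      sum(comp$whole_islet > 0) / sum(comp$tissue)
    }, numeric(1))
    mean(fa[g == "pregnant"]) / mean(fa[g == "control"])
  }, numeric(1))
  expect_gte(mean(abs(folds / 1.9 - 1) <= 0.25), 0.9)
  expect_equal(mean(folds), 1.9, tolerance = 0.05)
})
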