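# Differential abundance: completeness filter, S0 statistic, permutation FDR.

test_that("prepare_matrix applies the per-group completeness filter", {
  m <- rbind(c(8, 4, 2, 16, 8, 4),
             c(8, NA, 2, 16, 8, 4),
             c(8, 4, 2, NA, NA, NA))
  rownames(m) <- c("full", "half", "gone")
  g <- rep(c("a", "b"), each = 3)
  pm <- prepare_matrix(m, g, log2_transform = TRUE)
  expect_identical(rownames(pm$matrix), "full")
  expect_equal(pm$n_dropped, 2L)
  expect_equal(unname(pm$matrix["full", 1]), 3)    # log2(8)
  expect_error(prepare_matrix(m, g, compare = c("a", "zz")), "present")
})

test_that("s0 statistic reduces to the pooled t and shrinks with s0", {
  a <- c(1.1, 2.3, 0.8); b <- c(2.0, 3.1, 2.8)
  st <- s0_statistic(a, b, s0 = 0)
  expect_equal(st$d, unname(stats::t.test(a, b, var.equal = TRUE)$statistic),
               tolerance = 1e-12)
  expect_equal(st$log2fc, mean(a) - mean(b))
  expect_equal(s0_statistic(c(1, 2), c(1, 2), 0.5)$d, 0)

  dv <- vapply(c(0, 0.01, 0.1, 1, 10),
               function(s) abs(s0_statistic(a, b, s)$d), numeric(1))
  expect_true(all(diff(dv) < 0))
  expect_error(s0_statistic(c(1, 1), c(2, 2), s0 = 0), "zero variance")
  expect_gt(abs(s0_statistic(c(1, 1), c(2, 2), s0 = 0.01)$d), 0)
})

test_that("permutation FDR is deterministic, symmetric and monotone", {
  gm <- generate_protein_matrix(matrix_params(n_proteins = 200,
                                              n_samples_per_group = 5,
                                              n_true_effects = 20,
                                              effect_size = 2, seed = 17))
  r1 <- suppressMessages(permutation_fdr(gm$matrix, gm$groups, seed = 4))
  r2 <- suppressMessages(permutation_fdr(gm$matrix, gm$groups, seed = 4))
  expect_identical(r1, r2)

  # swapping the group labels negates d and log2FC, leaves q unchanged
  swapped <- ifelse(gm$groups == "group_a", "group_b", "group_a")
  r3 <- suppressMessages(permutation_fdr(gm$matrix, swapped, seed = 4))
  expect_equal(r3$d, -r1$d)
  expect_equal(r3$log2fc, -r1$log2fc)
  expect_equal(r3$q, r1$q)

  # q is monotone non-increasing in |d|
  o <- order(abs(r1$d), decreasing = TRUE)
  expect_true(all(diff(r1$q[o]) >= -1e-12))

  # spiked proteins dominate the discoveries
  expect_gt(mean(r1$q[gm$truth$spiked] < 0.05), 0.9)
  expect_lt(mean(r1$q[!gm$truth$spiked] < 0.05), 0.05)
})

test_that("degenerate and exhaustive-permutation cases are handled", {
  m <- matrix(5, 30, 8); rownames(m) <- sprintf("p%02d", 1:30)
  g <- rep(c("a", "b"), each = 4)
  r <- suppressMessages(permutation_fdr(m, g))
  expect_true(all(r$d == 0)); expect_true(all(r$q == 1))

  # fewer distinct assignments than requested: all are used, with a note
  expect_message(r2 <- permutation_fdr(matrix(rnorm(30 * 8), 30,
                                              dimnames = list(sprintf("p%02d", 1:30), NULL)),
                                       g, n_permutations = 250),
                 "distinct")
  expect_equal(attr(r2, "n_permutations"), choose(8, 4))
  expect_error(permutation_fdr(matrix(NA_real_, 2, 4), rep(c("a", "b"), 2)),
               "missing")
})

test_that("volcano table classifies at the -log10 FDR = 1.3 boundary", {
  res <- structure(data.frame(protein = c("x", "y", "z"),
                              log2fc = c(2, -1, 0.5),
                              d = c(5, -4, 1),
                              q = c(0.01, 0.05, 1),
                              neg_log10_fdr = -log10(c(0.01, 0.05, 1)),
                              class = "ns"),
                   class = c("DiffResult", "data.frame"))
  vt <- volcano_table(res)
  expect_equal(vt$class, c("up", "ns", "ns"))  # q = 0.05 exactly is ns
  expect_equal(vt$neg_log10_fdr[3], 0)
  expect_gt(vt$neg_log10_fdr[1], 1.3)
})
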