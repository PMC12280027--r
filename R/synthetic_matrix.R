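#' Parameters for a synthetic log-normal protein intensity matrix
#'
#' Emulates a label-free quantification output: per-protein baseline log2
#' abundances drawn from a normal distribution, replicate noise within
#' groups, a subset of proteins shifted by a fixed log2 fold change in one
#' group, and values missing completely at random.
#'
#' @param n_proteins Number of proteins (rows).
#' @param n_samples_per_group Samples per group (two groups).
#' @param baseline_log2_mean,baseline_log2_sd Mean and SD of per-protein
#'   baseline log2 intensities.
#' @param within_sd Within-group (replicate) SD on the log2 scale.
#' @param n_true_effects Number of spiked proteins (<= `n_proteins`).
#' @param effect_size Log2 fold change added to group A for spiked proteins.
#' @param missing_rate Proportion of entries set missing at random, in [0,1).
#' @param seed Integer seed.
#' @return An object of class `MatrixParams`.
#' @export
matrix_params <- function(n_proteins = 1000, n_samples_per_group = 6,
                          baseline_log2_mean = 23, baseline_log2_sd = 2,
                          within_sd = 0.3, n_true_effects = 0,
                          effect_size = 2, missing_rate = 0, seed = 1) {
  stopifnot_scalar(n_proteins, "n_proteins", positive = TRUE)
  stopifnot_scalar(n_samples_per_group, "n_samples_per_group", positive = TRUE)
  stopifnot_scalar(within_sd, "within_sd", nonneg = TRUE)
  stopifnot_scalar(n_true_effects, "n_true_effects", nonneg = TRUE)
  if (n_true_effects > n_proteins)
    stop("'n_true_effects' must not exceed 'n_proteins'")
  stopifnot_scalar(missing_rate, "missing_rate", nonneg = TRUE)
  if (missing_rate >= 1) stop("'missing_rate' must be < 1")
  structure(list(n_proteins = as.integer(n_proteins),
                 n_samples_per_group = as.integer(n_samples_per_group),
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 within_sd = within_sd,
                 n_true_effects = as.integer(n_true_effects),
                 effect_size = effect_size, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "MatrixParams")
}

#' Generate a synthetic protein abundance matrix with known spikes
#'
#' @param params A [matrix_params()] object.
#' @return A list with `matrix` (log2 intensities, proteins x samples, with
#'   `NA` for missing values), `groups` (character vector of sample group
#'   labels `"group_a"`/`"group_b"`), and `truth` (data.frame: protein,
#'   spiked flag, true log2 fold change group A minus group B).
#' @export
generate_protein_matrix <- function(params) {
  stopifnot(inherits(params, "MatrixParams"))
  with_rng(params$seed, {
    np <- params$n_proteins; ns <- params$n_samples_per_group
    base <- stats::rnorm(np, params$baseline_log2_mean, params$baseline_log2_sd)
    m <- matrix(stats::rnorm(np * 2L * ns, 0, params$within_sd), np, 2L * ns) + base
    spiked <- seq_len(params$n_true_effects)
    if (length(spiked))
      m[spiked, seq_len(ns)] <- m[spiked, seq_len(ns)] + params$effect_size
    if (params$missing_rate > 0) {
      miss <- stats::runif(length(m)) < params$missing_rate
      m[miss] <- NA_real_
    }
    rownames(m) <- sprintf("P%05d", seq_len(np))
    groups <- rep(c("group_a", "group_b"), each = ns)
    colnames(m) <- sprintf("%s_%d", groups, c(seq_len(ns), seq_len(ns)))
    truth <- data.frame(protein = rownames(m),
                        spiked = seq_len(np) %in% spiked,
                        true_log2fc = ifelse(seq_len(np) %in% spiked,
                                             params$effect_size, 0))
    list(matrix = m, groups = groups, truth = truth)
  })
}
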