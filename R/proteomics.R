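# Differential protein abundance: S0-moderated two-sample statistic with
# permutation-based FDR (SAM-style), as applied to label-free proteomics
# matrices grouped into islet/exocrine x pregnant/control samples.

#' Prepare a protein matrix for a two-group comparison
#'
#' Optionally log2-transforms raw intensities and removes every protein
#' with a missing value in either compared group (strict per-group
#' completeness; no imputation). Proteins missing everywhere are dropped
#' and counted in the attached filter log.
#'
#' @param x Numeric matrix, proteins x samples (rownames = protein ids).
#' @param groups Character vector of group labels, one per column.
#' @param compare Length-2 character: the two group labels to compare
#'   (default: the first two distinct labels).
#' @param log2_transform Apply `log2` to the values first (raw
#'   intensities); values <= 0 become missing.
#' @return Object of class `ProteinMatrix`: list with `matrix` (filtered
#'   log2 values restricted to the compared samples), `groups`, `compare`,
#'   and `n_dropped` (proteins removed by the completeness filter).
#' @export
prepare_matrix <- function(x, groups, compare = NULL, log2_transform = FALSE) {
  stopifnot(is.matrix(x), length(groups) == ncol(x))
  if (is.null(compare)) compare <- sort(unique(groups))[1:2]
  if (length(compare) != 2L || !all(compare %in% groups))
    stop("'compare' must name two group labels present in 'groups'")
  if (any(table(groups[groups %in% compare]) < 2L))
    stop("each compared group needs at least 2 samples")
  if (log2_transform) {
    x[!is.na(x) & x <= 0] <- NA_real_
    x <- log2(x)
  }
  sel <- groups %in% compare
  xs <- x[, sel, drop = FALSE]
  gs <- groups[sel]
  ok <- rowSums(is.na(xs)) == 0L
  structure(list(matrix = xs[ok, , drop = FALSE], groups = gs,
                 compare = compare, n_dropped = sum(!ok)),
            class = "ProteinMatrix")
}

#' S0-moderated two-sample statistic
#'
#' SAM-style moderated statistic `d = (mean_a - mean_b) / (s + s0)` where
#' `s` is the pooled two-sample standard error and `s0` a small positive
#' constant damping low-variance proteins. With `s0 = 0`, `d` is the
#' ordinary pooled two-sample t statistic.
#'
#' @param a,b Numeric vectors (log2 intensities), >= 2 values each.
#' @param s0 Moderation constant (>= 0), default 0.01.
#' @return List with `d` and `log2fc` (= mean(a) - mean(b)).
#' @export
s0_statistic <- function(a, b, s0 = 0.01) {
  stopifnot_scalar(s0, "s0", nonneg = TRUE)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  s <- sqrt(sp2 * (1 / na + 1 / nb))
  if (s + s0 == 0)
    stop("zero variance in both groups with s0 = 0: statistic undefined")
  fc <- mean(a) - mean(b)
  list(d = fc / (s + s0), log2fc = fc)
}

# Vectorised d and log2FC for all rows of a matrix given a logical
# assignment of columns to group A.
row_s0_stat <- function(m, inA, s0) {
  na <- sum(inA); nb <- sum(!inA)
  ma <- rowMeans(m[, inA, drop = FALSE])
  mb <- rowMeans(m[, !inA, drop = FALSE])
  va <- rowSums((m[, inA, drop = FALSE] - ma)^2) / (na - 1)
  vb <- rowSums((m[, !inA, drop = FALSE] - mb)^2) / (nb - 1)
  s <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2) * (1 / na + 1 / nb))
  fc <- ma - mb
  list(d = fc / (s + s0), log2fc = fc)
}

#' Permutation-based FDR for differential protein abundance
#'
#' Computes the S0-moderated statistic for every protein, builds its null
#' distribution by permuting group labels (all distinct assignments when
#' there are fewer than requested, otherwise a seeded subsample without
#' replacement), and estimates for each protein a q-value: the median,
#' over permutations, of the number of null statistics at least as extreme
#' as the protein's |d|, divided by the number of observed statistics at
#' least that extreme, clipped to [0,1] and made monotone non-increasing
#' along the |d| ranking.
#'
#' @param x A `ProteinMatrix` from [prepare_matrix()], or a complete
#'   numeric matrix (then `groups` is required).
#' @param groups Group labels when `x` is a plain matrix.
#' @param s0 Moderation constant, default 0.01.
#' @param n_permutations Requested label permutations (>= 100 advised;
#'   default 250).
#' @param seed Seed for the permutation subsample.
#' @param fdr Significance threshold on the q-value (default 0.05).
#' @return Object of class `DiffResult`: data.frame with protein, log2fc,
#'   d, q, neg_log10_fdr and class (`up`/`down`/`ns`), ordered as the
#'   input rows; attributes record s0, the number of distinct permutations
#'   used, and the seed.
#' @export
permutation_fdr <- function(x, groups = NULL, s0 = 0.01, n_permutations = 250,
                            seed = 1, fdr = 0.05) {
  if (inherits(x, "ProteinMatrix")) {
    m <- x$matrix; groups <- x$groups; compare <- x$compare
  } else {
    stopifnot(is.matrix(x), !is.null(groups), length(groups) == ncol(x))
    if (anyNA(x)) stop("matrix contains missing values; run prepare_matrix() first")
    m <- x; compare <- sort(unique(groups))[1:2]  # alphabetical: group A first
  }
  inA <- groups == compare[1L]
  na <- sum(inA); nb <- sum(!inA)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 samples")
  np <- nrow(m)

  obs <- row_s0_stat(m, inA, s0)
  n_total <- ncol(m)
  n_distinct <- choose(n_total, na)

  perm_sets <- with_rng(seed, {
    if (n_distinct <= n_permutations) {
      utils::combn(n_total, na, simplify = FALSE)
    } else {
      seen <- new.env(hash = TRUE, parent = emptyenv())
      out <- vector("list", n_permutations); k <- 0L
      while (k < n_permutations) {
        cand <- sort(sample.int(n_total, na))
        key <- paste(cand, collapse = ",")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE; k <- k + 1L; out[[k]] <- cand
        }
      }
      out
    }
  })
  n_used <- length(perm_sets)
  if (n_distinct <= n_permutations)
    message(sprintf("only %d distinct label assignments exist; using all of them",
                    n_used))

  abs_obs <- abs(obs$d)
  ord <- order(abs_obs, decreasing = TRUE)       # ranking by |d|
  thr <- abs_obs[ord]
  # observed positives at each protein's own threshold (ties share a count)
  obs_pos <- vapply(thr, function(t) sum(abs_obs >= t), numeric(1L))

  fp <- matrix(0, np, n_used)
  for (j in seq_len(n_used)) {
    inAp <- seq_len(n_total) %in% perm_sets[[j]]
    dn <- sort(abs(row_s0_stat(m, inAp, s0)$d))
    # count of null |d*| >= t for each observed threshold t
    fp[, j] <- np - findInterval(thr, dn, left.open = TRUE)
  }
  med_fp <- apply(fp, 1L, stats::median)
  q_raw <- pmin(1, pmax(0, med_fp / obs_pos))
  # monotone non-increasing in |d|: at any threshold, use the smallest
  # q achievable at or below it in the ranking
  q_mono <- rev(cummin(rev(q_raw)))
  q <- numeric(np)
  q[ord] <- q_mono

  cls <- rep("ns", np)
  cls[q < fdr & obs$log2fc > 0] <- "up"
  cls[q < fdr & obs$log2fc < 0] <- "down"
  res <- data.frame(
    protein = if (!is.null(rownames(m))) rownames(m) else sprintf("P%05d", seq_len(np)),
    log2fc = obs$log2fc, d = obs$d, q = q,
    neg_log10_fdr = -log10(pmax(q, 1e-300)), class = cls,
    row.names = NULL)
  structure(res, class = c("DiffResult", "data.frame"), s0 = s0,
            n_permutations = n_used, seed = seed, fdr = fdr)
}

#' Volcano-plot table from a differential-abundance result
#'
#' @param result A `DiffResult` from [permutation_fdr()].
#' @param fdr Class boundary on the q-value (default 0.05, i.e.
#'   -log10 FDR > 1.3; a protein exactly at the boundary is `ns`).
#' @return Data.frame with protein, log2fc, neg_log10_fdr and class.
#' @export
volcano_table <- function(result, fdr = 0.05) {
  stopifnot(inherits(result, "DiffResult"))
  cls <- rep("ns", nrow(result))
  cls[result$q < fdr & result$log2fc > 0] <- "up"
  cls[result$q < fdr & result$log2fc < 0] <- "down"
  data.frame(protein = result$protein, log2fc = result$log2fc,
             neg_log10_fdr = result$neg_log10_fdr, class = cls,
             row.names = NULL)
}
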