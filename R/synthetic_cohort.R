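#' Parameters for a synthetic two-group donor cohort
#'
#' Default effect multipliers are the pregnancy fold changes reported for
#' human donors: whole-islet area x1.9, alpha-cell area x4.3, beta-cell
#' area x1.9, bihormonal area x5.4, marker (GLP-1) share of alpha area
#' x2.39 and marker intensity x1.33.
#'
#' @param n_per_group Donors (sections) per group, >= 2.
#' @param multipliers Named numeric vector of positive effect multipliers
#'   applied to the "pregnant" group; recognised names: `islet`, `alpha`,
#'   `beta`, `bihormonal`, `marker_area`, `marker_intensity`. Missing
#'   entries default to the values above; set all to 1 for a null cohort.
#' @param cv Between-donor coefficient of variation of islet size
#'   (lognormal, mean 1). Territory and marker fractions receive an
#'   independent lognormal jitter with half this CV.
#' @param seed Integer cohort seed; each donor section is generated on its
#'   own RNG stream seeded from (cohort seed, donor index).
#' @return An object of class `CohortParams`.
#' @export
cohort_params <- function(n_per_group = 7,
                          multipliers = c(islet = 1.9, alpha = 4.3, beta = 1.9,
                                          bihormonal = 5.4, marker_area = 2.39,
                                          marker_intensity = 1.33),
                          cv = 0.25, seed = 1) {
  stopifnot_scalar(n_per_group, "n_per_group", positive = TRUE)
  if (n_per_group < 2) stop("'n_per_group' must be at least 2")
  full <- c(islet = 1.9, alpha = 4.3, beta = 1.9, bihormonal = 5.4,
            marker_area = 2.39, marker_intensity = 1.33)
  if (!is.null(names(multipliers))) {
    unknown <- setdiff(names(multipliers), names(full))
    if (length(unknown))
      stop("unknown multiplier name(s): ", paste(unknown, collapse = ", "))
    full[names(multipliers)] <- multipliers
  } else if (length(multipliers) == length(full)) {
    full[] <- multipliers
  } else stop("'multipliers' must be named")
  if (any(!is.finite(full)) || any(full <= 0))
    stop("all effect multipliers must be positive")
  stopifnot_scalar(cv, "cv", nonneg = TRUE)
  structure(list(n_per_group = as.integer(n_per_group), multipliers = full,
                 cv = cv, seed = as.integer(seed)),
            class = "CohortParams")
}

# Derive the per-donor SectionParams for one group. Compartment multipliers
# act on territory fractions relative to the whole-islet multiplier; islet
# blob area absorbs the rest, so each compartment's expected area fold is
# exact. When the compartment multipliers differ, the realized whole-islet
# fold is the area-weighted mean of the compartment folds (the compartments
# tile the islet), slightly above the nominal islet multiplier.
donor_params <- function(base, mult, cv, seed) {
  m_i <- mult[["islet"]]
  f <- c(a = base$alpha_fraction * mult[["alpha"]] / m_i,
         b = base$beta_fraction * mult[["beta"]] / m_i,
         bi = base$bihormonal_fraction * mult[["bihormonal"]] / m_i)
  s <- sum(f)
  area_mult <- m_i * s

  sd_size <- sqrt(log(1 + cv^2))
  sd_frac <- sqrt(log(1 + (cv / 2)^2))
  size_jit <- stats::rlnorm(1L, -sd_size^2 / 2, sd_size)
  fj <- stats::rlnorm(2L, -sd_frac^2 / 2, sd_frac)
  mj <- stats::rlnorm(1L, -sd_frac^2 / 2, sd_frac)
  # donor anatomy: tissue size varies independently of group
  tj <- min(1.05, max(0.85, stats::rlnorm(1L, 0, 0.06)))

  g <- f / s
  g_a <- min(0.9, g[["a"]] * fj[1L])
  g_bi <- min(0.9 - g_a, g[["bi"]] * fj[2L])
  g_b <- 1 - g_a - g_bi

  p <- base
  p$islet_radius_range <- base$islet_radius_range * sqrt(area_mult * size_jit)
  p$alpha_fraction <- g_a
  p$bihormonal_fraction <- g_bi
  p$beta_fraction <- g_b
  p$marker_positive_fraction_of_alpha <-
    min(0.95, base$marker_positive_fraction_of_alpha *
          mult[["marker_area"]] * mj)
  p$marker_signal_level <- base$marker_signal_level * mult[["marker_intensity"]]
  p$tissue_scale <- min(1.08, base$tissue_scale * tj)
  p$seed <- seed
  do.call(section_params, unclass(p))
}

#' Generate a synthetic pregnant-vs-control cohort of sections
#'
#' Draws `n_per_group` control donors (all multipliers 1) and
#' `n_per_group` "pregnant" donors whose generating parameters are scaled
#' by the cohort effect multipliers, with independent lognormal
#' between-donor variation. With all multipliers equal to 1 the two groups
#' are exchangeable in distribution.
#'
#' @param cohort A [cohort_params()] object.
#' @param base A [section_params()] object describing a control donor.
#' @param gdm_fraction Fraction of pregnant donors labelled as gestational
#'   diabetes (label only; no additional effect is simulated).
#' @return A list with one element per donor:
#'   `list(section, truth, group, donor_id, gdm)`.
#' @export
generate_cohort <- function(cohort, base = section_params(), gdm_fraction = 2 / 7) {
  stopifnot(inherits(cohort, "CohortParams"), inherits(base, "SectionParams"))
  n <- cohort$n_per_group
  null_mult <- cohort$multipliers; null_mult[] <- 1
  out <- vector("list", 2L * n)
  k <- 0L
  for (g in c("control", "pregnant")) {
    mult <- if (g == "control") null_mult else cohort$multipliers
    for (i in seq_len(n)) {
      k <- k + 1L
      dseed <- child_seed(cohort$seed, k)
      dp <- with_rng(dseed, donor_params(base, mult, cohort$cv, dseed + 1L))
      gs <- generate_section(dp)
      gdm <- g == "pregnant" && i <= round(gdm_fraction * n)
      out[[k]] <- list(section = gs$section, truth = gs$truth, group = g,
                       donor_id = sprintf("%s_%02d", g, i), gdm = gdm)
    }
  }
  out
}
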