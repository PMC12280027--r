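# Orchestration: section -> compartments -> nuclei -> metrics; cohort ->
# metrics table -> group comparisons; JSON run report.

#' Analyse one section end to end
#'
#' Segmentation, nucleus counting and morphometry for a single section.
#'
#' @param section A `MultiChannelSection`.
#' @param config Pipeline configuration ([default_config()]).
#' @return List with `compartments` (`CompartmentSet`), `nuclei`
#'   (`NucleusSet`), `metrics` (one-row data.frame) and `thresholds`.
#' @export
analyze_section <- function(section, config = default_config()) {
  comp <- segment_section(section, config)
  nuc <- segment_nuclei(section$channels$nuclei, section$pixel_size,
                        mean_radius = config$nucleus_mean_radius_um,
                        h = config$watershed_h)
  nuc <- filter_nuclei(nuc, config$nucleus_max_diameter_um)
  nuc <- assign_nuclei(nuc, comp)
  metrics <- section_metrics(comp, nuc, marker = section$channels$marker,
                             fractional_mode = config$fractional_mode,
                             min_alpha_area = config$min_alpha_area_um2)
  list(compartments = comp, nuclei = nuc, metrics = metrics,
       thresholds = attr(comp, "thresholds"))
}

# Metrics compared between groups by default in cohort reports.
default_cohort_metrics <- function() {
  c("islet_fractional_area_pct", "alpha_fractional_area_pct",
    "beta_fractional_area_pct", "bihormonal_fractional_area_pct",
    "mean_islet_area_um2", "alpha_mean_area_per_islet_um2",
    "beta_mean_area_per_islet_um2", "bihormonal_mean_area_per_islet_um2",
    "islet_density_per_mm2", "mean_islet_diameter_um",
    "alpha_prop_of_islet_pct", "bihormonal_prop_of_islet_pct",
    "alpha_positive_islet_pct")
}

#' Run the full pipeline on a cohort of sections
#'
#' Analyses every donor section, assembles the per-donor metrics table,
#' and (when both groups have at least two donors) runs the two-group
#' comparisons. Optionally writes `metrics.csv`, `comparisons.csv` and a
#' JSON run report (all parameters and per-section thresholds) to
#' `out_dir`.
#'
#' @param sections Either a cohort list as returned by [generate_cohort()]
#'   (elements with `section`, `group`, `donor_id`, optional `gdm`) or a
#'   character vector of TIFF paths with sidecars, in which case `groups`
#'   must give one label per path.
#' @param config Pipeline configuration.
#' @param groups Group labels when `sections` are file paths.
#' @param metrics Metric columns to compare (default
#'   `default_cohort_metrics()` restricted to those computed).
#' @param out_dir Optional output directory.
#' @return List with `metrics` (data.frame, one row per donor),
#'   `comparisons` (data.frame or NULL), `report` (list).
#' @export
run_full_pipeline <- function(sections, config = default_config(),
                              groups = NULL, metrics = NULL, out_dir = NULL) {
  if (is.character(sections)) {
    if (is.null(groups) || length(groups) != length(sections))
      stop("'groups' must give one label per section path")
    sections <- lapply(seq_along(sections), function(i)
      list(section = read_section(sections[i]), group = groups[i],
           donor_id = sprintf("%s_%02d", groups[i], i), gdm = FALSE))
  }
  if (length(sections) < 1L) stop("at least one section is required")

  rows <- vector("list", length(sections))
  thresholds <- vector("list", length(sections))
  for (i in seq_along(sections)) {
    el <- sections[[i]]
    res <- tryCatch(analyze_section(el$section, config), error = function(e)
      stop(sprintf("pipeline failed at stage 'analyze_section' for section '%s': %s",
                   el$donor_id, conditionMessage(e)), call. = FALSE))
    row <- cbind(data.frame(donor_id = el$donor_id, group = el$group,
                            gdm = isTRUE(el$gdm)), res$metrics)
    rows[[i]] <- row
    thresholds[[i]] <- as.list(res$thresholds)
    names(thresholds)[i] <- el$donor_id
  }
  tab <- do.call(rbind, rows)

  comparisons <- NULL
  gtab <- table(tab$group)
  if (length(gtab) == 2L && all(gtab >= 2L)) {
    if (is.null(metrics))
      metrics <- intersect(default_cohort_metrics(), names(tab))
    comparisons <- cohort_report(tab, metrics, "pregnant_vs_control",
                                 policy = config$stats_policy)
  }

  report <- list(package_version = as.character(utils::packageVersion("isletmorph")),
                 config = config, n_sections = length(sections),
                 section_thresholds = thresholds,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    if (!is.null(comparisons))
      utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                       row.names = FALSE)
    rep_out <- report
    rep_out$config$fixed_thresholds <-
      lapply(rep_out$config$fixed_thresholds, function(v) if (is.null(v)) NA else v)
    jsonlite::write_json(rep_out, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(metrics = tab, comparisons = comparisons, report = report)
}
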