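# Pipeline entry points tying the modules together. These back the thin
# command-line wrapper in inst/cli/uteqmri.R; each run archives a log line
# with the package version, configuration hash and seeds.

#' Simulate a series from a run configuration
#'
#' Builds the phantom described by the configuration, simulates the chosen
#' protocol and writes the series (NIfTI + sidecar) and the phantom to
#' `out_dir`.
#'
#' @param config A `run_config` (see [read_run_config()]) or a path to one.
#' @param out_dir Output directory (created if needed).
#' @return Invisible list of written prefixes.
#' @export
run_simulate <- function(config, out_dir) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  depot <- cfg$spio_depot
  if (!is.null(depot) && length(depot) == 0) depot <- NULL
  pcfg <- phantom_config(grid_size = cfg$grid_size,
                         voxel_size_mm = cfg$voxel_size_mm,
                         joint_space_tissue = cfg$joint_space_tissue,
                         spio_depot = depot,
                         texture_sd = cfg$texture_sd %||% 0)
  ph <- generate_phantom(pcfg, seed = cfg$seed)
  series <- simulate_series(ph, protocol_preset(cfg$protocol),
                            noise_sigma = cfg$noise_sigma, seed = cfg$seed)
  ph_prefix <- file.path(out_dir, "phantom")
  se_prefix <- file.path(out_dir, paste0("series_", cfg$protocol))
  write_phantom(ph, ph_prefix)
  write_series(series, se_prefix)
  write_run_log(out_dir, "simulate", cfg, cfg$seed)
  invisible(list(phantom = ph_prefix, series = se_prefix))
}

#' Fit a relaxation map from a stored series
#'
#' @param series_prefix Prefix of a series written by [write_series()].
#' @param signal_floor Optional signal floor passed to [fit_loglinear()].
#' @param out_prefix Output prefix for the map files.
#' @return Invisible output prefix.
#' @export
run_fit <- function(series_prefix, signal_floor = NULL, out_prefix) {
  series <- read_series(series_prefix)
  fit <- fit_loglinear(series, signal_floor = signal_floor)
  write_map(fit, out_prefix)
  invisible(out_prefix)
}

#' Compute echo-ratio maps from a stored series
#'
#' @param series_prefix Prefix of a stored series.
#' @param kinds Ratio kinds to compute (subset of `"R12"`, `"R15"`, `"R25"`).
#' @param out_prefix Output prefix; each map goes to `<out_prefix>_<kind>`.
#' @return Invisible character vector of written prefixes.
#' @export
run_ratios <- function(series_prefix, kinds = c("R12", "R15", "R25"),
                       out_prefix) {
  series <- read_series(series_prefix)
  written <- vapply(kinds, function(k) {
    prefix <- paste0(out_prefix, "_", k)
    write_map(ratio_map(series, k), prefix)
    prefix
  }, character(1))
  invisible(written)
}

#' Summarize maps over ROIs and compare two groups
#'
#' Reads one fitted map per replicate for each of two groups, summarizes
#' the requested ROI, runs the group comparison and writes tidy CSVs.
#'
#' @param map_prefixes_a,map_prefixes_b Character vectors of map prefixes
#'   (one per replicate) for the two groups.
#' @param phantom_prefix Prefix of the phantom defining the ROI labels.
#' @param roi ROI name to summarize.
#' @param alpha Significance level.
#' @param out_dir Output directory for `roi_summary.csv` and
#'   `comparisons.csv`.
#' @return Invisible list with the two tibbles.
#' @export
run_report <- function(map_prefixes_a, map_prefixes_b, phantom_prefix,
                       roi = "joint_space", alpha = 0.15, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ph <- read_phantom(phantom_prefix)
  read_map_values <- function(prefixes, group) {
    vapply(prefixes, function(p) {
      value <- as.array(RNifti::readNifti(paste0(p, ".nii.gz")))
      mask <- as.array(RNifti::readNifti(paste0(p, "_mask.nii.gz"))) > 0
      value[!mask] <- NA_real_
      roi_value(matrix(value, nrow(ph$label_map)), ph, roi)
    }, numeric(1))
  }
  a <- read_map_values(map_prefixes_a, "a")
  b <- read_map_values(map_prefixes_b, "b")
  summary <- tibble::tibble(
    roi = roi, metric = "map", group = rep(c("a", "b"), c(length(a), length(b))),
    value = c(a, b))
  cmp <- compare_groups(a, b, alpha = alpha)
  comparisons <- tibble::tibble(roi = roi, metric = "map",
                                t = cmp$t_statistic, p = cmp$p_value,
                                significant = cmp$significant)
  utils::write.csv(summary, file.path(out_dir, "roi_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                   row.names = FALSE)
  invisible(list(summary = summary, comparisons = comparisons))
}

#' Run the full replicate study and export its report
#'
#' One-command reproduction: runs [replicate_study()], writes the tidy
#' summary and comparison CSVs, and a bar-plot figure mirroring the
#' six-panel group-summary layout.
#'
#' @param seed Master seed.
#' @param n_per_group Replicates per group.
#' @param out_dir Output directory.
#' @param ... Further arguments passed to [replicate_study()].
#' @return The `roi_report`, invisibly.
#' @export
run_reproduce <- function(seed = 1L, n_per_group = 7L, out_dir, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- replicate_study(n_per_group = n_per_group, seed = seed, ...)
  utils::write.csv(report$summary, file.path(out_dir, "roi_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(report$comparisons, file.path(out_dir, "comparisons.csv"),
                   row.names = FALSE)
  grDevices::pdf(file.path(out_dir, "group_summary.pdf"), width = 7, height = 5)
  print(plot_roi_report(report))
  grDevices::dev.off()
  write_run_log(out_dir, "reproduce",
                list(n_per_group = n_per_group, args = list(...)), seed)
  invisible(report)
}
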