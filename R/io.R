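# File formats: NIfTI volumes with JSON sidecars (the sidecar is
# authoritative for echo times and protocol metadata; NIfTI time-axis
# metadata is not trusted across tools), YAML run configurations and CSV
# reports. All rates are serialized in 1/s, all times in ms.

#' Write a multi-echo series to disk
#'
#' Writes `<prefix>.nii.gz` (4D, echo as the 4th axis) and `<prefix>.json`
#' (echo times in ms, protocol, noise level, seed).
#'
#' @param series A `multi_echo_series`.
#' @param prefix Output path prefix (no extension).
#' @return The prefix, invisibly.
#' @export
write_series <- function(series, prefix) {
  d <- dim(series$data)
  arr <- array(series$data, c(d[1], d[2], 1L, d[3]))  # x, y, z, echo
  img <- RNifti::asNifti(arr, pixdim = c(rep(1, 3), 1))
  RNifti::writeNifti(img, paste0(prefix, ".nii.gz"))
  sidecar <- list(
    echo_times_ms = series$echo_times_ms,
    protocol = list(name = series$protocol$name,
                    echo_times_ms = series$protocol$echo_times_ms,
                    tr_ms = series$protocol$tr_ms,
                    flip_angle_deg = series$protocol$flip_angle_deg,
                    mode = series$protocol$mode),
    noise_sigma = series$noise_sigma,
    seed = series$seed
  )
  jsonlite::write_json(sidecar, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(prefix)
}

#' Read a multi-echo series
#'
#' Validates that the sidecar's echo-time list matches the volume's echo
#' axis; a mismatch raises a `uteqmri_sidecar_mismatch` error.
#'
#' @param prefix Path prefix used by [write_series()].
#' @return A `multi_echo_series`.
#' @export
read_series <- function(prefix) {
  nii_path <- paste0(prefix, ".nii.gz")
  json_path <- paste0(prefix, ".json")
  if (!file.exists(nii_path) || !file.exists(json_path)) {
    abort_qmri(sprintf("missing series file(s) at prefix '%s'", prefix),
               "uteqmri_missing_file")
  }
  arr <- as.array(RNifti::readNifti(nii_path))
  sidecar <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  d <- dim(arr)
  if (length(d) == 4L) arr <- array(arr, c(d[1], d[2], d[4]))
  n_echo <- dim(arr)[3]
  te <- as.numeric(sidecar$echo_times_ms)
  if (length(te) != n_echo) {
    abort_qmri(sprintf("sidecar lists %d echo times but the volume has %d echoes",
                       length(te), n_echo),
               "uteqmri_sidecar_mismatch")
  }
  p <- sidecar$protocol
  structure(list(
    data = arr,
    echo_times_ms = te,
    protocol = protocol(p$name, p$echo_times_ms, p$tr_ms, p$flip_angle_deg,
                        p$mode),
    noise_sigma = sidecar$noise_sigma %||% 0,
    seed = sidecar$seed %||% NA_integer_
  ), class = "multi_echo_series")
}

#' Write a phantom to disk
#'
#' Writes the label map as `<prefix>.nii.gz` and the tissue table, ROI
#' codes, voxel size, depot configuration and seed as `<prefix>.json`.
#'
#' @param phantom A `qmri_phantom`.
#' @param prefix Output path prefix.
#' @return The prefix, invisibly.
#' @export
write_phantom <- function(phantom, prefix) {
  RNifti::writeNifti(RNifti::asNifti(phantom$label_map * 1.0),
                     paste0(prefix, ".nii.gz"))
  cfg <- phantom$config
  sidecar <- list(
    voxel_size_mm = phantom$voxel_size_mm,
    roi_codes = as.list(phantom$roi_codes),
    tissues = lapply(cfg$tissues, unclass),
    joint_space_tissue = cfg$joint_space_tissue,
    grid_size = cfg$grid_size,
    defect_radius_mm = cfg$defect_radius_mm,
    spio_depot = cfg$spio_depot,
    texture_sd = cfg$texture_sd,
    seed = phantom$seed
  )
  jsonlite::write_json(sidecar, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(prefix)
}

#' Read a phantom written by [write_phantom()]
#'
#' The phantom is regenerated from its archived configuration and seed and
#' cross-checked against the stored label map.
#'
#' @param prefix Path prefix.
#' @return A `qmri_phantom`.
#' @export
read_phantom <- function(prefix) {
  json_path <- paste0(prefix, ".json")
  if (!file.exists(json_path)) {
    abort_qmri(sprintf("missing phantom sidecar at prefix '%s'", prefix),
               "uteqmri_missing_file")
  }
  sc <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  opt <- function(v) if (is.null(v) || length(v) == 0 || all(is.na(v))) NULL else v
  tissues <- lapply(sc$tissues, function(t) {
    tissue_spec(t$name, t$proton_density, t$r2star, t$r2,
                r2star_fast = opt(t$r2star_fast),
                fast_fraction = opt(t$fast_fraction),
                spio_concentration = t$spio_concentration %||% 0,
                susceptibility = t$susceptibility %||% 0)
  })
  depot <- if (is.null(sc$spio_depot) || length(sc$spio_depot) == 0) NULL else sc$spio_depot
  cfg <- phantom_config(grid_size = sc$grid_size,
                        voxel_size_mm = sc$voxel_size_mm,
                        tissues = tissues,
                        joint_space_tissue = sc$joint_space_tissue,
                        defect_radius_mm = sc$defect_radius_mm,
                        spio_depot = depot,
                        texture_sd = sc$texture_sd %||% 0)
  ph <- generate_phantom(cfg, seed = sc$seed %||% 1L)
  stored <- as.array(RNifti::readNifti(paste0(prefix, ".nii.gz")))
  if (!isTRUE(all.equal(as.numeric(stored), as.numeric(ph$label_map)))) {
    abort_qmri("stored label map does not match the archived configuration",
               "uteqmri_sidecar_mismatch")
  }
  ph
}

#' Write a relaxation or ratio map
#'
#' @param map A `relaxation_map` or `ratio_map`.
#' @param prefix Output path prefix; writes `<prefix>.nii.gz` (values, NA as
#'   NaN) plus `<prefix>_mask.nii.gz` and `<prefix>.json`.
#' @return The prefix, invisibly.
#' @export
write_map <- function(map, prefix) {
  value <- if (inherits(map, "relaxation_map")) map$rate else map$value
  RNifti::writeNifti(RNifti::asNifti(value), paste0(prefix, ".nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(map$valid_mask * 1.0),
                     paste0(prefix, "_mask.nii.gz"))
  meta <- if (inherits(map, "relaxation_map")) {
    list(type = "relaxation_map", mode = map$mode,
         echo_times_used_ms = map$echo_times_used_ms,
         signal_floor = map$signal_floor, units = "1/s")
  } else {
    list(type = "ratio_map", kind = map$kind, echo_pair = map$echo_pair,
         echo_times_used_ms = map$echo_times_used_ms, units = "dimensionless")
  }
  jsonlite::write_json(meta, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(prefix)
}

#' Read a run configuration
#'
#' Reads a YAML (or JSON) run configuration and validates the fields the
#' pipeline needs, naming the offending field on failure. A run is
#' reproducible from its archived configuration alone.
#'
#' @param path Path to a YAML/JSON configuration.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort_qmri(sprintf("configuration file '%s' not found", path),
               "uteqmri_missing_file")
  }
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg$protocol <- cfg$protocol %||% "cones_ute"
  if (!cfg$protocol %in% c("cones_ute", "cartesian_mge", "fse_r2")) {
    abort_qmri(sprintf("field 'protocol': unknown protocol '%s'", cfg$protocol),
               "uteqmri_bad_config")
  }
  cfg$noise_sigma <- cfg$noise_sigma %||% 0
  if (!is_scalar_number(cfg$noise_sigma) || cfg$noise_sigma < 0) {
    abort_qmri("field 'noise_sigma': must be a non-negative number",
               "uteqmri_bad_config")
  }
  cfg$seed <- cfg$seed %||% 1L
  cfg$grid_size <- as.integer(cfg$grid_size %||% c(128L, 128L))
  if (any(cfg$grid_size < 32L)) {
    abort_qmri("field 'grid_size': each axis must be >= 32", "uteqmri_bad_config")
  }
  cfg$voxel_size_mm <- cfg$voxel_size_mm %||% 0.56
  cfg$joint_space_tissue <- cfg$joint_space_tissue %||% "joint_space_control"
  cfg$alpha <- cfg$alpha %||% 0.15
  cfg$ratios <- cfg$ratios %||% c("R12", "R15", "R25")
  structure(cfg, class = "run_config")
}

#' @keywords internal
config_hash <- function(cfg) rlang::hash(unclass(cfg))

# Append a reproducibility log entry next to pipeline outputs.
#' @keywords internal
write_run_log <- function(out_dir, step, cfg, seed) {
  line <- sprintf("%s\tuteqmri %s\tstep=%s\tconfig_hash=%s\tseed=%s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  as.character(utils::packageVersion("uteqmri")),
                  step, config_hash(cfg), paste(seed, collapse = ","))
  cat(line, "\n", file = file.path(out_dir, "run.log"), append = TRUE, sep = "")
}
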