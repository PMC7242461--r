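# Digital stifle-joint phantom: parametric 2D (optionally thin-3D) label map
# with the five standard regions of interest and an optional focal SPIO depot.

ROI_NAMES <- c("joint_space", "fat_pad", "tibial_bone", "dorsal_muscle",
               "defect_region")

#' Tissue parameter specification
#'
#' Per-compartment physical parameters used by the forward signal model.
#' `r2star` must be at least `r2` (R2* includes the reversible dephasing
#' component R2'). A second fast-decaying component may be given via
#' `r2star_fast` and `fast_fraction`, modelling tissues such as cartilage
#' whose transverse decay is multi-exponential.
#'
#' @param name Text label.
#' @param proton_density Signal amplitude at TE = 0, arbitrary units, >= 0.
#' @param r2star Effective transverse rate R2*, 1/s, >= 0.
#' @param r2 Irreversible transverse rate R2, 1/s, with `r2 <= r2star`.
#' @param r2star_fast Optional fast-component R2*, 1/s. Must be supplied
#'   together with `fast_fraction`.
#' @param fast_fraction Optional fraction of the fast component in `[0, 1]`.
#' @param spio_concentration Iron-oxide label concentration, arbitrary
#'   micrograms-equivalent per voxel, >= 0.
#' @param susceptibility Magnetic susceptibility offset, ppm.
#' @return An object of class `tissue_spec`.
#' @export
tissue_spec <- function(name, proton_density, r2star, r2,
                        r2star_fast = NULL, fast_fraction = NULL,
                        spio_concentration = 0, susceptibility = 0) {
  if (!is.character(name) || length(name) != 1L) {
    abort_qmri("tissue `name` must be a single string", "uteqmri_bad_tissue")
  }
  for (v in list(proton_density = proton_density, r2star = r2star, r2 = r2,
                 spio_concentration = spio_concentration)) {
    if (!is_scalar_number(v) || v < 0) {
      abort_qmri(sprintf("tissue '%s': rates, proton density and SPIO concentration must be finite and non-negative", name),
                 "uteqmri_bad_tissue")
    }
  }
  if (!is_scalar_number(susceptibility)) {
    abort_qmri(sprintf("tissue '%s': susceptibility must be a finite number", name),
               "uteqmri_bad_tissue")
  }
  if (r2 > r2star) {
    abort_qmri(sprintf("tissue '%s': r2 (%g) must not exceed r2star (%g)", name, r2, r2star),
               "uteqmri_bad_tissue")
  }
  if (is.null(r2star_fast) != is.null(fast_fraction)) {
    abort_qmri(sprintf("tissue '%s': r2star_fast and fast_fraction must be supplied together", name),
               "uteqmri_bad_tissue")
  }
  if (!is.null(r2star_fast)) {
    if (!is_scalar_number(r2star_fast) || r2star_fast < 0) {
      abort_qmri(sprintf("tissue '%s': r2star_fast must be finite and non-negative", name),
                 "uteqmri_bad_tissue")
    }
    if (!is_scalar_number(fast_fraction) || fast_fraction < 0 || fast_fraction > 1) {
      abort_qmri(sprintf("tissue '%s': fast_fraction must lie in [0, 1]", name),
                 "uteqmri_bad_tissue")
    }
  }
  structure(list(
    name = name,
    proton_density = proton_density,
    r2star = r2star,
    r2 = r2,
    r2star_fast = r2star_fast,
    fast_fraction = fast_fraction,
    spio_concentration = spio_concentration,
    susceptibility = susceptibility
  ), class = "tissue_spec")
}

#' Default tissue parameter table
#'
#' Reference tissue parameters for the joint phantom. The two joint-space
#' variants carry the group-mean R2* values measured in the SPIO-injected
#' (64 1/s) and non-injected (70 1/s) stifles; all other compartments are
#' plausible defaults exposed for the user to override. Bone decays at
#' 300 1/s so that it is effectively invisible at the first Cartesian echo
#' (TE 7 ms) yet bright at the first UTE echo (TE 0.03 ms).
#'
#' @return Named list of [tissue_spec()] objects, including entries
#'   `joint_space_spio`, `joint_space_control`, `fat_pad`, `tibial_bone`,
#'   `dorsal_muscle`, `defect_region` and `background`.
#' @export
default_tissue_table <- function() {
  list(
    background = tissue_spec("background", proton_density = 0, r2star = 0, r2 = 0),
    joint_space_spio = tissue_spec("joint_space_spio", proton_density = 90,
                                   r2star = 64, r2 = 40),
    joint_space_control = tissue_spec("joint_space_control", proton_density = 90,
                                      r2star = 70, r2 = 44),
    fat_pad = tissue_spec("fat_pad", proton_density = 100, r2star = 50, r2 = 33),
    tibial_bone = tissue_spec("tibial_bone", proton_density = 30, r2star = 300,
                              r2 = 150),
    dorsal_muscle = tissue_spec("dorsal_muscle", proton_density = 80, r2star = 40,
                                r2 = 29),
    defect_region = tissue_spec("defect_region", proton_density = 70, r2star = 55,
                                r2 = 36)
  )
}

#' Phantom configuration
#'
#' Describes the geometry and tissue content of a synthetic sagittal
#' stifle-joint slice. Geometry is parametric (slabs, an ellipse and discs),
#' not anatomical. Coordinates follow the package convention: axis order
#' (row, column\[, slice\]), R's 1-based indices, voxel centers on the
#' integer grid.
#'
#' @param grid_size Integer vector of length 2 (or 3 for thin-3D mode),
#'   voxels per axis; each axis must be >= 32.
#' @param voxel_size_mm Isotropic in-plane voxel size, mm.
#' @param tissues Named list of [tissue_spec()]s; must contain `background`
#'   and a tissue for each of the five regions of interest (the joint-space
#'   tissue is selected by `joint_space_tissue`).
#' @param joint_space_tissue Name of the tissue table entry used for the
#'   joint space (`"joint_space_control"` or `"joint_space_spio"` with the
#'   default table).
#' @param defect_radius_mm Radius of the osteochondral defect disc, mm
#'   (default 4, i.e. an 8 mm diameter defect).
#' @param spio_depot Optional focal depot: a list with elements
#'   `concentration` (micrograms-equivalent per voxel), `susceptibility_ppm`,
#'   `radius_mm` and optionally `center` (fractional row/column position;
#'   defaults to the fat-pad center, emulating a supra-patellar injection).
#'   `NULL` for no depot.
#' @param texture_sd Standard deviation of multiplicative proton-density
#'   texture (lognormal-like jitter); 0 disables texture. Texture is the
#'   only seed-dependent feature: geometry is deterministic.
#' @param n_slices Number of slices for thin-3D mode (1 = 2D default).
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(grid_size = c(128L, 128L),
                           voxel_size_mm = 0.56,
                           tissues = default_tissue_table(),
                           joint_space_tissue = "joint_space_control",
                           defect_radius_mm = 4,
                           spio_depot = NULL,
                           texture_sd = 0,
                           n_slices = 1L) {
  structure(list(
    grid_size = as.integer(grid_size),
    voxel_size_mm = voxel_size_mm,
    tissues = tissues,
    joint_space_tissue = joint_space_tissue,
    defect_radius_mm = defect_radius_mm,
    spio_depot = spio_depot,
    texture_sd = texture_sd,
    n_slices = as.integer(n_slices)
  ), class = "phantom_config")
}

# Relative placement of the parametric shapes (fractions of the grid).
.geometry <- list(
  muscle_rows = c(0.06, 0.28), muscle_cols = c(0.08, 0.92),
  fat_center = c(0.45, 0.30), fat_semi = c(0.10, 0.13),
  joint_rows = c(0.55, 0.60), joint_cols = c(0.12, 0.88),
  bone_rows = c(0.60, 0.92), bone_cols = c(0.12, 0.88),
  defect_center = c(0.70, 0.50)
)

#' Generate a digital joint phantom
#'
#' Builds the label map (background 0, joint space 1, fat pad 2, tibial bone
#' 3, dorsal muscle 4, defect region 5), the SPIO concentration and
#' susceptibility maps, and optional proton-density texture. Geometry is a
#' pure function of the configuration; the seed only drives texture, so the
#' labelled volume is identical across seeds.
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed for the texture jitter.
#' @return An object of class `qmri_phantom` with elements `label_map`,
#'   `tissues` (code -> [tissue_spec()]), `roi_codes`, `voxel_size_mm`,
#'   `spio_map`, `susceptibility_map`, `pd_texture`, `config`, `seed`.
#' @export
generate_phantom <- function(config, seed = 1L) {
  if (!inherits(config, "phantom_config")) {
    abort_qmri("`config` must be a phantom_config", "uteqmri_bad_config")
  }
  gs <- config$grid_size
  if (length(gs) < 2L || any(gs < 32L)) {
    abort_qmri("phantom grid must be at least 32 voxels per axis",
               "uteqmri_grid_too_small")
  }
  n1 <- gs[1]; n2 <- gs[2]
  vz <- config$voxel_size_mm

  roi_tissue <- c(joint_space = config$joint_space_tissue,
                  fat_pad = "fat_pad", tibial_bone = "tibial_bone",
                  dorsal_muscle = "dorsal_muscle", defect_region = "defect_region")
  missing <- setdiff(c("background", unname(roi_tissue)), names(config$tissues))
  if (length(missing) > 0L) {
    abort_qmri(sprintf("tissue table lacks entries for: %s",
                       paste(missing, collapse = ", ")),
               "uteqmri_missing_roi")
  }

  g <- .geometry
  rows <- matrix(seq_len(n1), n1, n2)
  cols <- matrix(seq_len(n2), n1, n2, byrow = TRUE)
  frac_r <- (rows - 1) / (n1 - 1)
  frac_c <- (cols - 1) / (n2 - 1)

  lab <- matrix(0L, n1, n2)
  # Large dorsal muscle slab.
  lab[frac_r >= g$muscle_rows[1] & frac_r <= g$muscle_rows[2] &
        frac_c >= g$muscle_cols[1] & frac_c <= g$muscle_cols[2]] <- 4L
  # Supra-patellar fat pad (ellipse).
  fat <- ((frac_r - g$fat_center[1]) / g$fat_semi[1])^2 +
    ((frac_c - g$fat_center[2]) / g$fat_semi[2])^2 <= 1
  lab[fat] <- 2L
  # Synovial joint space between the femoral and tibial surfaces (band).
  lab[frac_r >= g$joint_rows[1] & frac_r <= g$joint_rows[2] &
        frac_c >= g$joint_cols[1] & frac_c <= g$joint_cols[2]] <- 1L
  # Tibial bone slab below the joint line.
  lab[frac_r > g$bone_rows[1] & frac_r <= g$bone_rows[2] &
        frac_c >= g$bone_cols[1] & frac_c <= g$bone_cols[2]] <- 3L
  # Osteochondral defect: disc carved out of the bone.
  def_center <- c(1 + g$defect_center[1] * (n1 - 1), 1 + g$defect_center[2] * (n2 - 1))
  def_r_vox <- config$defect_radius_mm / vz
  def_mask <- (rows - def_center[1])^2 + (cols - def_center[2])^2 <= def_r_vox^2
  lab[def_mask & lab == 3L] <- 5L

  roi_codes <- c(joint_space = 1L, fat_pad = 2L, tibial_bone = 3L,
                 dorsal_muscle = 4L, defect_region = 5L)
  tissues <- list(
    "0" = config$tissues$background,
    "1" = config$tissues[[config$joint_space_tissue]],
    "2" = config$tissues$fat_pad,
    "3" = config$tissues$tibial_bone,
    "4" = config$tissues$dorsal_muscle,
    "5" = config$tissues$defect_region
  )

  # SPIO concentration / susceptibility maps: per-tissue baseline plus the
  # optional focal depot disc inside the fat pad.
  conc <- matrix(0, n1, n2)
  chi <- matrix(0, n1, n2)
  for (code in names(tissues)) {
    sel <- lab == as.integer(code)
    conc[sel] <- tissues[[code]]$spio_concentration
    chi[sel] <- tissues[[code]]$susceptibility
  }
  depot <- config$spio_depot
  if (!is.null(depot)) {
    ctr_frac <- depot$center %||% g$fat_center
    ctr <- c(1 + ctr_frac[1] * (n1 - 1), 1 + ctr_frac[2] * (n2 - 1))
    r_vox <- (depot$radius_mm %||% 2.8) / vz
    dmask <- (rows - ctr[1])^2 + (cols - ctr[2])^2 <= r_vox^2
    conc[dmask] <- depot$concentration %||% 1
    chi[dmask] <- depot$susceptibility_ppm %||% 10
  }

  pd_texture <- NULL
  if (config$texture_sd > 0) {
    pd_texture <- with_seed(seed, matrix(exp(stats::rnorm(n1 * n2, 0, config$texture_sd)), n1, n2))
  }

  structure(list(
    label_map = lab,
    tissues = tissues,
    roi_codes = roi_codes,
    voxel_size_mm = vz,
    spio_map = conc,
    susceptibility_map = chi,
    pd_texture = pd_texture,
    config = config,
    seed = as.integer(seed)
  ), class = "qmri_phantom")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Logical mask for one region of interest
#'
#' @param phantom A `qmri_phantom`.
#' @param roi One of `"joint_space"`, `"fat_pad"`, `"tibial_bone"`,
#'   `"dorsal_muscle"`, `"defect_region"`.
#' @return Logical matrix the size of the phantom grid.
#' @export
roi_mask <- function(phantom, roi) {
  if (!roi %in% names(phantom$roi_codes)) {
    abort_qmri(sprintf("unknown ROI '%s'", roi), "uteqmri_missing_roi")
  }
  phantom$label_map == phantom$roi_codes[[roi]]
}

#' @export
print.qmri_phantom <- function(x, ...) {
  cat(sprintf("<qmri_phantom> %d x %d voxels (%.2f mm), %d ROIs, SPIO depot: %s\n",
              nrow(x$label_map), ncol(x$label_map), x$voxel_size_mm,
              length(x$roi_codes),
              if (any(x$spio_map > 0)) "yes" else "no"))
  invisible(x)
}
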