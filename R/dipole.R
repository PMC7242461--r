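# Susceptibility-induced static field perturbation, computed spectrally with
# the unit dipole kernel. This drives the blooming artifact around a focal
# SPIO depot.

#' Dipole field of a susceptibility source distribution
#'
#' Convolves a susceptibility (SPIO concentration) map with the unit dipole
#' kernel, evaluated in k-space as `1/3 - kz^2/|k|^2` (zero at `k = 0`).
#' The computation runs on a zero-padded grid to suppress circular
#' wrap-around. In 2D the main-field axis is taken in-plane (`b0_axis`
#' selects which array axis plays the role of z); in 3D the kernel is the
#' standard three-dimensional one.
#'
#' @param spio_map 2D matrix or 3D array of source concentration.
#' @param susceptibility_scale Susceptibility per unit concentration, ppm;
#'   the output is linear in this scale.
#' @param voxel_size_mm Voxel size per axis, mm (isotropic scalar accepted).
#'   The kernel depends only on k-space direction, so this only matters for
#'   anisotropic voxels.
#' @param b0_axis Array axis aligned with the main field (default 1).
#' @param pad_factor Zero-padding factor per axis, >= 2.
#' @return Field perturbation map, ppm, same shape as `spio_map`.
#' @export
dipole_field <- function(spio_map, susceptibility_scale = 1,
                         voxel_size_mm = 1, b0_axis = 1L, pad_factor = 2L) {
  d <- dim(spio_map)
  if (is.null(d)) abort_qmri("`spio_map` must be a matrix or 3D array", "uteqmri_bad_input")
  nd <- length(d)
  if (!nd %in% c(2L, 3L)) abort_qmri("`spio_map` must be 2D or 3D", "uteqmri_bad_input")
  if (pad_factor < 2) abort_qmri("`pad_factor` must be >= 2", "uteqmri_bad_input")
  vz <- rep_len(voxel_size_mm, nd)

  np <- as.integer(ceiling(d * pad_factor))
  chi <- array(0, np)
  idx <- lapply(d, seq_len)
  if (nd == 2L) chi[idx[[1]], idx[[2]]] <- spio_map * susceptibility_scale
  else chi[idx[[1]], idx[[2]], idx[[3]]] <- spio_map * susceptibility_scale

  kaxes <- lapply(seq_len(nd), function(a) fft_freq(np[a], vz[a]))
  # |k|^2 and kz^2 built by outer sums (broadcast along each axis).
  k2 <- array(0, np)
  for (a in seq_len(nd)) {
    ka2 <- kaxes[[a]]^2
    perm <- rep(1L, nd); perm[a] <- np[a]
    k2 <- k2 + array(rep(ka2, each = prod(np[seq_len(a - 1L)])), np)
  }
  kz2 <- array(rep(kaxes[[b0_axis]]^2,
                   each = prod(np[seq_len(b0_axis - 1L)])), np)
  kernel <- 1 / 3 - kz2 / k2
  kernel[k2 == 0] <- 0

  field <- Re(stats::fft(stats::fft(chi) * kernel, inverse = TRUE)) / prod(np)
  if (nd == 2L) field[idx[[1]], idx[[2]]] else field[idx[[1]], idx[[2]], idx[[3]]]
}
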