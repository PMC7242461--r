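# Intravoxel dephasing: magnitude attenuation caused by field variation
# inside a voxel, evaluated by subvoxel phase integration. Together with
# dipole_field() this produces the apparent enlargement ("blooming") of a
# strong susceptibility source at long echo times.

# Separable linear interpolation of a matrix onto an m-fold finer grid.
# Voxel centers sit at integer coordinates 1..n; fine samples for voxel i
# sit at i - 0.5 + (s - 0.5)/m, s = 1..m; edge values are clamped.
#' @keywords internal
bilinear_refine <- function(mat, m) {
  interp_axis <- function(n) {
    pos <- rep(seq_len(n), each = m) - 0.5 + (rep(seq_len(m), n) - 0.5) / m
    i0 <- pmin(pmax(floor(pos), 1L), n - 1L)
    list(i0 = i0, w = pmin(pmax(pos - i0, 0), 1))
  }
  r <- interp_axis(nrow(mat))
  c_ <- interp_axis(ncol(mat))
  rows_lo <- mat[r$i0, , drop = FALSE]
  rows_hi <- mat[r$i0 + 1L, , drop = FALSE]
  fine_rows <- rows_lo * (1 - r$w) + rows_hi * r$w
  cols_lo <- fine_rows[, c_$i0, drop = FALSE]
  cols_hi <- fine_rows[, c_$i0 + 1L, drop = FALSE]
  cols_lo * (1 - rep(c_$w, each = nrow(cols_lo))) +
    cols_hi * rep(c_$w, each = nrow(cols_hi))
}

# Mean of m x m blocks, reducing an (n1*m) x (n2*m) matrix to n1 x n2.
#' @keywords internal
block_mean <- function(mat, m) {
  n1 <- nrow(mat) / m; n2 <- ncol(mat) / m
  # Average rows within blocks, then columns.
  dim(mat) <- c(m, n1 * n2 * m)
  row_avg <- matrix(colMeans(mat), n1, n2 * m)
  t_avg <- t(row_avg)
  dim(t_avg) <- c(m, n2 * n1)
  t(matrix(colMeans(t_avg), n2, n1))
}

#' Intravoxel dephasing attenuation
#'
#' For each voxel, the magnitude of the complex mean of
#' `exp(i * 2*pi * f0 * field_ppm * 1e-6 * te)` over an `m x m` grid of
#' subvoxel samples, with the field linearly interpolated between voxel
#' centers. Attenuation is 1 where the field is locally uniform and, for a
#' fixed linear intravoxel gradient, non-increasing in `te` over the main
#' sinc lobe.
#'
#' @param field_ppm Field perturbation map, ppm (2D matrix).
#' @param te_ms Echo time, ms.
#' @param subvoxel_oversample Subvoxel samples per axis, >= 2.
#' @param b0_tesla Main field strength, tesla (sets the Larmor frequency).
#' @return Attenuation factor per voxel, in `[0, 1]`.
#' @export
dephasing_rate <- function(field_ppm, te_ms, subvoxel_oversample = 4L,
                           b0_tesla = B0_TESLA_DEFAULT) {
  if (subvoxel_oversample < 2) {
    abort_qmri("`subvoxel_oversample` must be >= 2", "uteqmri_bad_input")
  }
  if (te_ms == 0) return(matrix(1, nrow(field_ppm), ncol(field_ppm)))
  m <- as.integer(subvoxel_oversample)
  fine <- bilinear_refine(field_ppm, m)
  phase <- 2 * pi * larmor_hz(b0_tesla) * fine * 1e-6 * ms_to_s(te_ms)
  re <- block_mean(cos(phase), m)
  im <- block_mean(sin(phase), m)
  pmin(sqrt(re^2 + im^2), 1)
}
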