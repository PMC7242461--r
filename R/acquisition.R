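# Optional k-space layer: center-out radial (UTE-like) versus Cartesian
# sampling of a decaying object, with adjoint (Kaiser-Bessel) gridding
# reconstruction. A 2D center-out radial trajectory stands in for the 3D
# cones family: the property it demonstrates -- the k-space center is
# sampled at TE ~ 0, preserving short-T2* signal -- is generic to
# center-out trajectories.

#' Cartesian trajectory
#'
#' Full Cartesian k-space encoding of one echo: every sample shares the
#' same effective time offset from excitation (the echo time).
#'
#' @param grid_size Image matrix size (square).
#' @param fov_mm Field of view, mm.
#' @param te_ms Echo time shared by all samples, ms.
#' @return A `kspace_trajectory` with per-sample coordinates `kx`, `ky`
#'   (cycles/mm), times `t_ms`, density-compensation area elements `dcf`
#'   and grid bookkeeping.
#' @export
trajectory_cartesian <- function(grid_size, fov_mm, te_ms) {
  n <- as.integer(grid_size)
  kline <- (seq_len(n) - 1 - n / 2) / fov_mm
  kx <- matrix(kline, n, n)
  ky <- matrix(kline, n, n, byrow = TRUE)
  structure(list(
    kind = "cartesian",
    kx = as.numeric(kx), ky = as.numeric(ky),
    t_ms = rep(te_ms, n * n),
    dcf = rep(1 / fov_mm^2, n * n),
    grid_size = n, fov_mm = fov_mm
  ), class = "kspace_trajectory")
}

#' Center-out radial trajectory
#'
#' Spokes start at the k-space center at the nominal first echo time
#' (0.03 ms by default) and move outward; the per-sample time grows
#' linearly with `|k|` over the readout duration. Density compensation is
#' the analytic annulus area element.
#'
#' @param grid_size Image matrix size (square).
#' @param fov_mm Field of view, mm.
#' @param te0_ms Time of the center-of-k-space sample, ms.
#' @param readout_ms Duration of one spoke readout, ms (default 0.5; short readouts limit decay blurring of short-T2* tissue during the spoke).
#' @param n_spokes Number of spokes over 2*pi (default `2 * grid_size`,
#'   comfortably above the azimuthal Nyquist requirement pi*n/2).
#' @param n_shells Samples per spoke (default `2 * grid_size`, i.e. a 4x
#'   oversampled readout; radial quadrature error falls quickly with
#'   readout oversampling).
#' @return A `kspace_trajectory`.
#' @export
trajectory_radial <- function(grid_size, fov_mm, te0_ms = 0.03,
                              readout_ms = 0.5, n_spokes = NULL,
                              n_shells = NULL) {
  n <- as.integer(grid_size)
  n_spokes <- as.integer(n_spokes %||% (2L * n))
  n_shells <- as.integer(n_shells %||% (2L * n))
  kmax <- (n / 2 - 1) / fov_mm
  radii <- seq(0, kmax, length.out = n_shells)
  dk <- radii[2] - radii[1]
  angles <- (seq_len(n_spokes) - 1) * 2 * pi / n_spokes
  kx <- as.numeric(outer(radii, angles, function(r, a) r * cos(a)))
  ky <- as.numeric(outer(radii, angles, function(r, a) r * sin(a)))
  t_ms <- rep(te0_ms + (radii / kmax) * readout_ms, times = n_spokes)
  # Annulus area element per sample; the DC sample takes the central disc.
  area <- ifelse(radii > 0, 2 * pi * radii * dk, pi * (dk / 2)^2) / n_spokes
  structure(list(
    kind = "center_out_radial",
    kx = kx, ky = ky, t_ms = t_ms,
    dcf = rep(area, times = n_spokes),
    grid_size = n, fov_mm = fov_mm,
    te0_ms = te0_ms, readout_ms = readout_ms
  ), class = "kspace_trajectory")
}

#' Time-resolved complex object model
#'
#' Wraps a phantom into a function of acquisition time: evaluating at time
#' `t` (ms after excitation) returns the complex image with the tissue
#' decay (and, optionally, SPIO dephasing attenuation) applied at that
#' instant. Used by [sample_kspace()] so that every k-space sample sees the
#' object as it was at the sample's own acquisition time.
#'
#' @param phantom A `qmri_phantom`.
#' @param spio_relaxivity Additional rate per unit SPIO concentration, 1/s.
#' @param with_dephasing Include dipole-field dephasing.
#' @param b0_tesla Main field, tesla.
#' @param dephasing_oversample Subvoxel samples per axis.
#' @return `function(t_ms)` returning a complex matrix.
#' @export
object_model <- function(phantom, spio_relaxivity = 2000,
                         with_dephasing = TRUE,
                         b0_tesla = B0_TESLA_DEFAULT,
                         dephasing_oversample = 4L) {
  lab <- phantom$label_map
  n1 <- nrow(lab); n2 <- ncol(lab)
  pd <- matrix(0, n1, n2); r2s <- matrix(0, n1, n2)
  for (code in names(phantom$tissues)) {
    sel <- lab == as.integer(code)
    pd[sel] <- phantom$tissues[[code]]$proton_density
    r2s[sel] <- phantom$tissues[[code]]$r2star
  }
  if (!is.null(phantom$pd_texture)) pd <- pd * phantom$pd_texture
  r2s <- r2s + spio_relaxivity * phantom$spio_map
  use_deph <- with_dephasing && any(phantom$susceptibility_map != 0)
  field <- if (use_deph) {
    dipole_field(phantom$susceptibility_map, 1, phantom$voxel_size_mm)
  } else NULL
  function(t_ms) {
    s <- pd * exp(-r2s * ms_to_s(t_ms))
    if (use_deph && t_ms > 0) {
      s <- s * dephasing_rate(field, t_ms, dephasing_oversample, b0_tesla)
    }
    s + 0i
  }
}

#' Sample k-space along a trajectory
#'
#' Each sample is the discrete Fourier transform of the object evaluated at
#' that sample's acquisition time. Cartesian samples (all sharing one time)
#' are taken with an FFT; non-Cartesian samples are evaluated exactly with
#' a non-uniform DFT, grouped by unique sample time.
#'
#' @param object A `function(t_ms) -> complex matrix`, e.g. from
#'   [object_model()]. The matrix must be square of size
#'   `trajectory$grid_size`.
#' @param trajectory A `kspace_trajectory`.
#' @return Complex vector of k-space samples, in trajectory order.
#' @export
sample_kspace <- function(object, trajectory) {
  n <- trajectory$grid_size
  fov <- trajectory$fov_mm
  dx <- fov / n
  pos <- (seq_len(n) - 1 - n / 2) * dx
  samples <- complex(length(trajectory$kx))
  for (t in unique(trajectory$t_ms)) {
    idx <- which(trajectory$t_ms == t)
    img <- object(t)
    if (trajectory$kind == "cartesian" && length(idx) == n * n) {
      f <- fftshift2(stats::fft(ifftshift2(img)))
      samples[idx] <- f[cbind(
        round(trajectory$kx[idx] * fov + n / 2 + 1),
        round(trajectory$ky[idx] * fov + n / 2 + 1))]
    } else {
      xv <- matrix(pos, n, n); yv <- matrix(pos, n, n, byrow = TRUE)
      phase <- outer(trajectory$kx[idx], as.numeric(xv)) +
        outer(trajectory$ky[idx], as.numeric(yv))
      samples[idx] <- exp(-2i * pi * phase) %*% as.numeric(img)
    }
  }
  samples
}

# Kaiser-Bessel gridding kernel (Beatty parameterization), argument in
# oversampled-grid sample units, support |u| <= width/2.
#' @keywords internal
kb_kernel <- function(u, width, beta) {
  x <- 1 - (2 * u / width)^2
  out <- numeric(length(u))
  ok <- x > 0
  out[ok] <- besselI(beta * sqrt(x[ok]), 0) / besselI(beta, 0)
  out
}

# Fourier transform of the (normalized) KB kernel at image position p
# (original-image pixels from center), for deapodization.
#' @keywords internal
kb_deapod <- function(p, width, beta, os, n) {
  xi <- p / (os * n)
  arg <- beta^2 - (pi * width * xi)^2
  y <- ifelse(arg > 0, sinh(sqrt(arg)) / sqrt(arg), sinc_safe(sqrt(-arg)))
  width * y / besselI(beta, 0)
}

#' @keywords internal
sinc_safe <- function(x) ifelse(x == 0, 1, sin(x) / x)

#' Reconstruct an image from k-space samples
#'
#' Cartesian trajectories are reconstructed with an inverse FFT. For
#' non-Cartesian trajectories the adjoint gridding reconstruction is used:
#' density-compensated samples are spread onto a 2x oversampled grid with a
#' Kaiser-Bessel kernel, inverse-FFT'd, cropped and deapodized. The result
#' is deterministic.
#'
#' @param samples Complex sample vector from [sample_kspace()].
#' @param trajectory The matching `kspace_trajectory`.
#' @param grid_size Output image size (defaults to the trajectory's).
#' @return Magnitude image matrix.
#' @export
reconstruct <- function(samples, trajectory, grid_size = NULL) {
  if (length(samples) == 0L) {
    abort_qmri("empty sample set", "uteqmri_empty_samples")
  }
  n <- as.integer(grid_size %||% trajectory$grid_size)
  fov <- trajectory$fov_mm
  dx <- fov / n

  if (trajectory$kind == "cartesian") {
    f <- matrix(0i, n, n)
    f[cbind(round(trajectory$kx * fov + n / 2 + 1),
            round(trajectory$ky * fov + n / 2 + 1))] <- samples
    img <- fftshift2(stats::fft(ifftshift2(f), inverse = TRUE)) / (n * n)
    return(Mod(img))
  }

  os <- 2L; width <- 4L
  beta <- pi * sqrt((width / os)^2 * (os - 0.5)^2 - 0.8)
  g <- os * n
  # Sample positions on the oversampled grid (k = 0 at index g/2 + 1).
  gx <- trajectory$kx * os * fov + g / 2 + 1
  gy <- trajectory$ky * os * fov + g / 2 + 1
  w_samp <- trajectory$dcf * samples
  acc_re <- numeric(g * g); acc_im <- numeric(g * g)
  offs <- seq_len(width) - width / 2  # integer offsets around floor(g)
  fx <- floor(gx); fy <- floor(gy)
  for (ox in offs) {
    jx <- fx + ox
    wx <- kb_kernel(jx - gx, width, beta)
    jxm <- ((jx - 1) %% g) + 1
    for (oy in offs) {
      jy <- fy + oy
      wy <- kb_kernel(jy - gy, width, beta)
      jym <- ((jy - 1) %% g) + 1
      w <- wx * wy
      lin <- jxm + (jym - 1) * g
      re <- rowsum(Re(w_samp) * w, lin)
      im <- rowsum(Im(w_samp) * w, lin)
      ii <- as.integer(rownames(re))
      acc_re[ii] <- acc_re[ii] + re
      acc_im[ii] <- acc_im[ii] + im
    }
  }
  a <- matrix(complex(real = acc_re, imaginary = acc_im), g, g)
  img_os <- fftshift2(stats::fft(ifftshift2(a), inverse = TRUE))
  crop <- (g / 2 - n / 2 + 1):(g / 2 + n / 2)
  img <- img_os[crop, crop]
  p <- seq_len(n) - 1 - n / 2
  deap <- outer(kb_deapod(p, width, beta, os, n),
                kb_deapod(p, width, beta, os, n))
  Mod(img / deap) * dx^2
}
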