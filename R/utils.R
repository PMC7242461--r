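# Internal helpers shared across modules.

# Gyromagnetic ratio of 1H divided by 2*pi, Hz per tesla.
GAMMA_BAR_HZ_PER_T <- 42.577478518e6

# Default main field strength, tesla (3 T system).
B0_TESLA_DEFAULT <- 3

#' @keywords internal
larmor_hz <- function(b0_tesla = B0_TESLA_DEFAULT) GAMMA_BAR_HZ_PER_T * b0_tesla

#' @keywords internal
ms_to_s <- function(t_ms) t_ms / 1000

# Raise a classed condition so callers (and the CLI) can name the failure.
#' @keywords internal
abort_qmri <- function(message, class) {
  stop(structure(
    class = c(class, "uteqmri_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so simulation functions are pure in
# (inputs, seed) without clobbering the session RNG.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort_qmri("`seed` must be a single integer", "uteqmri_bad_seed")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' @keywords internal
is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# fftshift/ifftshift for 2D matrices (k = 0 moved to/from the center).
#' @keywords internal
fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c((floor(n1 / 2) + 1L):n1, 1L:floor(n1 / 2)),
    c((floor(n2 / 2) + 1L):n2, 1L:floor(n2 / 2)), drop = FALSE]
}

#' @keywords internal
ifftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c((n1 - floor(n1 / 2) + 1L):n1, 1L:(n1 - floor(n1 / 2))),
    c((n2 - floor(n2 / 2) + 1L):n2, 1L:(n2 - floor(n2 / 2))), drop = FALSE]
}

# DFT sample frequencies in cycles per unit, matching fft() ordering.
#' @keywords internal
fft_freq <- function(n, spacing = 1) {
  k <- c(0L:(ceiling(n / 2) - 1L), -floor(n / 2):-1L)
  k / (n * spacing)
}
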