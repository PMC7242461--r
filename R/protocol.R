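# Acquisition protocol descriptions: echo times, TR, flip angle and the
# relaxation mode they probe.

#' Acquisition protocol
#'
#' @param name Protocol label; the three study presets are `"cones_ute"`,
#'   `"cartesian_mge"` and `"fse_r2"`.
#' @param echo_times_ms Strictly increasing echo times, ms. For gradient-echo
#'   modes every TE must be below TR.
#' @param tr_ms Repetition time, ms.
#' @param flip_angle_deg Excitation flip angle, degrees.
#' @param mode `"r2star"` for gradient-echo protocols or `"r2"` for the
#'   spin-echo protocol.
#' @return An object of class `qmri_protocol`.
#' @export
protocol <- function(name, echo_times_ms, tr_ms, flip_angle_deg,
                     mode = c("r2star", "r2")) {
  mode <- match.arg(mode)
  te <- as.numeric(echo_times_ms)
  if (length(te) < 1L || any(!is.finite(te)) || any(diff(te) <= 0)) {
    abort_qmri("echo times must be finite and strictly increasing",
               "uteqmri_bad_protocol")
  }
  if (mode == "r2star" && any(te >= tr_ms)) {
    abort_qmri("gradient-echo echo times must all be below TR",
               "uteqmri_bad_protocol")
  }
  structure(list(name = name, echo_times_ms = te, tr_ms = tr_ms,
                 flip_angle_deg = flip_angle_deg, mode = mode),
            class = "qmri_protocol")
}

#' Study protocol presets
#'
#' The three acquisition protocols of the study: a five-echo 3D-cones UTE
#' multi-echo gradient echo (first TE 0.03 ms), a six-echo Cartesian
#' multi-echo gradient echo (SWAN, first TE 7.0 ms), and a four-echo
#' MLEV-prepared fast spin echo for R2 mapping.
#'
#' @param name One of `"cones_ute"`, `"cartesian_mge"`, `"fse_r2"`.
#' @return A [protocol()] object.
#' @export
protocol_preset <- function(name = c("cones_ute", "cartesian_mge", "fse_r2")) {
  name <- match.arg(name)
  switch(name,
    cones_ute = protocol("cones_ute", c(0.03, 4.0, 8.1, 12.1, 16.1),
                         tr_ms = 23, flip_angle_deg = 15, mode = "r2star"),
    cartesian_mge = protocol("cartesian_mge", c(7.0, 12.8, 18.5, 24.3, 30.1, 35.8),
                             tr_ms = 40.7, flip_angle_deg = 20, mode = "r2star"),
    fse_r2 = protocol("fse_r2", c(2.8, 31.7, 63.8, 112),
                      tr_ms = 1920, flip_angle_deg = 20, mode = "r2")
  )
}

#' @export
print.qmri_protocol <- function(x, ...) {
  cat(sprintf("<qmri_protocol> %s (%s): TEs [%s] ms, TR %g ms, flip %g deg\n",
              x$name, x$mode, paste(x$echo_times_ms, collapse = ", "),
              x$tr_ms, x$flip_angle_deg))
  invisible(x)
}
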