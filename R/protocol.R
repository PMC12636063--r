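#' Multi-echo acquisition protocol
#'
#' Describes the gradient-echo acquisition the signal model is sampled on.
#' The default instance is the 1.5 T abdominal protocol used throughout the
#' package: ten echoes from 2.38 to 23.82 ms, TR 27 ms, flip angle 20 degrees,
#' water referenced at 4.7 ppm.
#'
#' @param field_strength Main magnetic field in Tesla.
#' @param echo_times Strictly increasing echo times in milliseconds.
#' @param repetition_time Repetition time in ms (informational only).
#' @param flip_angle Excitation flip angle in degrees (informational only).
#' @param water_ppm Chemical shift of the water resonance in ppm.
#' @return An object of class `acq_protocol`.
#' @examples
#' p <- acq_protocol()
#' p$echo_times
#' @export
acq_protocol <- function(field_strength = 1.5,
                         echo_times = c(2.38, 4.76, 7.15, 9.53, 11.91,
                                        14.29, 16.67, 19.06, 21.44, 23.82),
                         repetition_time = 27,
                         flip_angle = 20,
                         water_ppm = 4.7) {
  if (!is.numeric(field_strength) || length(field_strength) != 1L ||
      field_strength <= 0)
    stop("field_strength must be a single positive number (Tesla)")
  if (!is.numeric(echo_times) || length(echo_times) < 1L ||
      any(echo_times <= 0) || any(diff(echo_times) <= 0))
    stop("echo_times must be strictly increasing and positive (ms)")
  structure(
    list(field_strength = field_strength,
         echo_times = as.numeric(echo_times),
         repetition_time = repetition_time,
         flip_angle = flip_angle,
         water_ppm = water_ppm),
    class = "acq_protocol")
}

#' @export
print.acq_protocol <- function(x, ...) {
  cat(sprintf("<acq_protocol> %.2g T, %d echoes (%.2f-%.2f ms), water %.1f ppm\n",
              x$field_strength, length(x$echo_times), min(x$echo_times),
              max(x$echo_times), x$water_ppm))
  invisible(x)
}
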