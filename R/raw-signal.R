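#' Construct a raw triaxial acceleration record
#'
#' Container for hip- or wrist-worn accelerometer output: time-stamped x/y/z
#' acceleration in g at a fixed sampling rate (nominally 100 Hz, dynamic range
#' +/- 16 g).
#'
#' @param time numeric vector of sample times in seconds, strictly increasing.
#' @param x,y,z numeric vectors of acceleration in g, same length as `time`.
#' @param sampling_rate_hz sampling rate in Hz (default 100).
#' @param wear_site `"hip"` or `"wrist"`.
#' @param dynamic_range_g symmetric dynamic range in g (default 16).
#' @return An object of class `raw_triaxial`: a data frame with columns
#'   `time`, `x`, `y`, `z` and attributes `sampling_rate_hz`, `wear_site`,
#'   `dynamic_range_g`.
#' @export
raw_triaxial <- function(time, x, y, z, sampling_rate_hz = 100,
                         wear_site = c("hip", "wrist"),
                         dynamic_range_g = 16) {
  wear_site <- match.arg(wear_site)
  n <- length(time)
  if (n == 0L) stop_input("empty signal")
  if (length(x) != n || length(y) != n || length(z) != n) {
    stop_input("x, y, z must have the same length as time")
  }
  if (n > 1L && any(diff(time) <= 0)) {
    stop_input("timestamps must be strictly increasing")
  }
  check_number(sampling_rate_hz, "sampling_rate_hz", lower = 1e-9)
  check_number(dynamic_range_g, "dynamic_range_g", lower = 1e-9)
  if (max(abs(c(x, y, z))) > dynamic_range_g) {
    stop_input("acceleration exceeds the stated dynamic range of %.1f g",
               dynamic_range_g)
  }
  out <- data.frame(time = time, x = x, y = y, z = z)
  attr(out, "sampling_rate_hz") <- sampling_rate_hz
  attr(out, "wear_site") <- wear_site
  attr(out, "dynamic_range_g") <- dynamic_range_g
  class(out) <- c("raw_triaxial", "data.frame")
  out
}

#' @export
print.raw_triaxial <- function(x, ...) {
  cat(sprintf("<raw_triaxial> %d samples @ %g Hz (%s), %.1f s\n",
              nrow(x), attr(x, "sampling_rate_hz"), attr(x, "wear_site"),
              nrow(x) / attr(x, "sampling_rate_hz")))
  invisible(x)
}

# split sample indices into complete epochs of `epoch_len_s`; trailing partial
# epoch dropped
epoch_index <- function(n_samples, sampling_rate_hz, epoch_len_s) {
  per <- round(epoch_len_s * sampling_rate_hz)
  n_epochs <- n_samples %/% per
  if (n_epochs < 1L) stop_input("signal spans less than one epoch")
  list(per = per, n_epochs = n_epochs)
}
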