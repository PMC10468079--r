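#' Mean amplitude deviation (MAD) per epoch
#'
#' MAD is the mean absolute deviation of the acceleration resultant
#' r = sqrt(x^2 + y^2 + z^2) from its epoch mean, computed in fixed
#' six-second epochs: MAD = mean(|r_i - mean(r)|). It is a movement-intensity
#' metric robust to static gravity and device orientation.
#'
#' @param signal a [raw_triaxial()] record spanning at least one epoch.
#' @param epoch_len_s epoch length in seconds (default 6).
#' @return Numeric vector, one MAD value in g per complete epoch; a trailing
#'   partial epoch is dropped.
#' @export
compute_mad <- function(signal, epoch_len_s = 6) {
  stopifnot(inherits(signal, "raw_triaxial"))
  check_number(epoch_len_s, "epoch_len_s", lower = 1e-9)
  r <- sqrt(signal$x^2 + signal$y^2 + signal$z^2)
  idx <- epoch_index(length(r), attr(signal, "sampling_rate_hz"), epoch_len_s)
  m <- matrix(r[seq_len(idx$per * idx$n_epochs)], nrow = idx$per)
  mu <- colMeans(m)
  colMeans(abs(m - rep(mu, each = idx$per)))
}

#' Angle for posture estimation (APE) per epoch
#'
#' Angle in degrees between each epoch's mean acceleration vector and a
#' reference (gravity) vector, in [0, 180]. A zero epoch-mean vector yields
#' `NA` (posture unknown) rather than an error.
#'
#' @param signal a [raw_triaxial()] record.
#' @param reference non-zero numeric length-3 reference vector (the gravity
#'   direction estimated during still wear; see
#'   [estimate_reference_vector()]).
#' @param epoch_len_s epoch length in seconds (default 6).
#' @return Numeric vector of angles in degrees, one per complete epoch.
#' @export
compute_ape <- function(signal, reference, epoch_len_s = 6) {
  stopifnot(inherits(signal, "raw_triaxial"))
  if (length(reference) != 3L || !is.numeric(reference)) {
    stop_input("reference must be a numeric length-3 vector")
  }
  rn <- sqrt(sum(reference^2))
  if (rn == 0) stop_input("reference vector must be non-zero")
  ref <- reference / rn
  idx <- epoch_index(nrow(signal), attr(signal, "sampling_rate_hz"),
                     epoch_len_s)
  keep <- seq_len(idx$per * idx$n_epochs)
  g <- rep(seq_len(idx$n_epochs), each = idx$per)
  mx <- tapply(signal$x[keep], g, mean)
  my <- tapply(signal$y[keep], g, mean)
  mz <- tapply(signal$z[keep], g, mean)
  nrm <- sqrt(mx^2 + my^2 + mz^2)
  ct <- (mx * ref[1] + my * ref[2] + mz * ref[3]) / nrm
  ang <- acos(pmin(1, pmax(-1, ct))) * 180 / pi
  ang[nrm == 0] <- NA_real_
  as.numeric(ang)
}

#' Estimate the gravity reference vector from still wear
#'
#' The orientation of the accelerometer with respect to gravity serves as the
#' posture reference. It is estimated as the normalised mean of the epoch-mean
#' acceleration vectors over the `k` lowest-MAD (stillest) epochs.
#'
#' @param signal a [raw_triaxial()] record.
#' @param epoch_len_s epoch length in seconds (default 6).
#' @param k number of stillest epochs to average (default 10, capped at the
#'   number of available epochs).
#' @return Unit numeric length-3 vector. If every candidate epoch mean is
#'   zero, falls back to the global mean direction with a warning.
#' @export
estimate_reference_vector <- function(signal, epoch_len_s = 6, k = 10) {
  stopifnot(inherits(signal, "raw_triaxial"))
  idx <- epoch_index(nrow(signal), attr(signal, "sampling_rate_hz"),
                     epoch_len_s)
  keep <- seq_len(idx$per * idx$n_epochs)
  g <- rep(seq_len(idx$n_epochs), each = idx$per)
  mad <- compute_mad(signal, epoch_len_s)
  mx <- tapply(signal$x[keep], g, mean)
  my <- tapply(signal$y[keep], g, mean)
  mz <- tapply(signal$z[keep], g, mean)
  k <- min(as.integer(k), idx$n_epochs)
  still <- order(mad)[seq_len(k)]
  v <- c(mean(mx[still]), mean(my[still]), mean(mz[still]))
  nv <- sqrt(sum(v^2))
  if (nv == 0) {
    warning("no stable still window found; falling back to global mean direction")
    v <- c(mean(signal$x), mean(signal$y), mean(signal$z))
    nv <- sqrt(sum(v^2))
    if (nv == 0) stop_input("signal has zero mean acceleration; cannot orient")
  }
  v / nv
}

#' Exponential moving-average smoothing
#'
#' First-order recursive smoother y_t = alpha * x_t + (1 - alpha) * y_(t-1)
#' with y_1 = x_1. `alpha` may be given directly or derived from the epoch
#' length and a time constant as alpha = 1 - exp(-epoch_len_s /
#' time_constant_s). Constant input is a fixed point and the output stays
#' within the input's range.
#'
#' @param series numeric vector (per-epoch values).
#' @param time_constant_s smoothing time constant in seconds (> 0).
#' @param epoch_len_s epoch length in seconds (default 6).
#' @param alpha optional smoothing weight in (0, 1]; overrides
#'   `time_constant_s`.
#' @return Numeric vector, same length as `series`.
#' @export
smooth_ema <- function(series, time_constant_s = NULL, epoch_len_s = 6,
                       alpha = NULL) {
  if (length(series) == 0L) stop_input("empty series")
  if (is.null(alpha)) {
    check_number(time_constant_s, "time_constant_s", lower = 1e-9)
    alpha <- 1 - exp(-epoch_len_s / time_constant_s)
  }
  check_number(alpha, "alpha", lower = 1e-12, upper = 1)
  # recursive filter with y_0 = x_1 makes y_1 = x_1 exactly
  y <- stats::filter(alpha * series, 1 - alpha, method = "recursive",
                     init = series[1])
  as.numeric(y)
}
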