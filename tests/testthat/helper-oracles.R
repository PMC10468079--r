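# independent brute-force oracles and small fixture builders used across tests

# signal whose per-sample resultant equals `r` (all on the x axis)
signal_from_resultants <- function(r, rate = 1) {
  raw_triaxial(time = seq_along(r) / rate, x = r, y = rep(0, length(r)),
               z = rep(0, length(r)), sampling_rate_hz = rate)
}

# naive per-epoch MAD: explicit loop over samples
oracle_mad <- function(signal, epoch_len_s = 6) {
  r <- sqrt(signal$x^2 + signal$y^2 + signal$z^2)
  per <- round(epoch_len_s * attr(signal, "sampling_rate_hz"))
  n_ep <- length(r) %/% per
  out <- numeric(n_ep)
  for (e in seq_len(n_ep)) {
    seg <- r[((e - 1) * per + 1):(e * per)]
    out[e] <- mean(abs(seg - mean(seg)))
  }
  out
}

# EMA by explicit recurrence
oracle_ema <- function(x, alpha) {
  y <- numeric(length(x))
  y[1] <- x[1]
  for (t in seq_along(x)[-1]) y[t] <- alpha * x[t] + (1 - alpha) * y[t - 1]
  y
}

# Spearman rho as Pearson on average-tie ranks
oracle_spearman <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
}

# Kruskal-Wallis H with tie correction, from the rank-sum formula
oracle_kw_h <- function(values, groups) {
  n <- length(values)
  r <- rank(values, ties.method = "average")
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(ri) sum(ri)^2 / length(ri))) - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# one-day epoch table builder: `classes` is a character vector (one entry
# per 6-s epoch) in {sb, light, mpa, vpa}; met values sit mid-band so
# smoothing with a short time constant cannot cross a cut-point mid-block
epochs_from_classes <- function(classes, date = as.Date("2024-06-08"),
                                id = "T01", awake = TRUE) {
  met <- c(sb = 1.2, light = 2.0, mpa = 4.0, vpa = 7.0)[classes]
  posture <- c(sb = "sitting", light = "standing", mpa = "active",
               vpa = "active")[classes]
  data.frame(
    participant_id = id,
    epoch_start = as.POSIXct(paste(date, "08:00:00"), tz = "UTC") +
      6 * (seq_along(classes) - 1),
    met = unname(met),
    posture = unname(posture),
    wear = TRUE,
    awake = awake,
    stringsAsFactors = FALSE
  )
}

# classified day summary without smoothing side effects: feed constant-class
# epochs through summarise_day directly
day_of <- function(n_sb = 0, n_light = 0, n_mpa = 0, n_vpa = 0,
                   date = as.Date("2024-06-03"), valid_day_min = 600) {
  cls <- c(rep("SB", n_sb), rep("light", n_light), rep("MPA", n_mpa),
           rep("VPA", n_vpa))
  epochs <- data.frame(
    epoch_start = as.POSIXct(paste(date, "07:00:00"), tz = "UTC") +
      6 * (seq_along(cls) - 1),
    intensity = factor(cls, levels = c("SB", "light", "MPA", "VPA")),
    wear = TRUE, awake = TRUE
  )
  summarise_day(epochs, valid_day_min = valid_day_min)
}
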