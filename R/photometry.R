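#' Photometry trace container checks
#' @keywords internal
.check_trace <- function(trace) {
  stopifnot(is.list(trace), all(c("time", "iso405", "act488") %in% names(trace)))
  n <- length(trace$time)
  if (length(trace$iso405) != n || length(trace$act488) != n) {
    .invalid_input("photometry channels must have equal lengths")
  }
  if (n < 3 || any(diff(trace$time) <= 0)) {
    .invalid_input("time must be strictly increasing")
  }
  fs <- if (!is.null(trace$fs)) trace$fs else 1 / stats::median(diff(trace$time))
  if (fs <= 0) .invalid_input("sampling rate must be > 0")
  fs
}

# zero-phase second-order Butterworth low-pass, then integer-factor
# downsampling to `fs_out`. The signal is mirror-padded before filtering:
# filtfilt starts from zero initial conditions, and without padding its edge
# transients would leak non-linear artifacts into the channel comparison.
.lowpass_downsample <- function(x, fs, corner, fs_out = 100) {
  bf <- signal::butter(2, corner / (fs / 2), type = "low")
  n <- length(x)
  pad <- min(n - 1L, as.integer(ceiling(5 * fs / corner)))
  xp <- c(rev(x[2:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
  y <- signal::filtfilt(bf, xp)[(pad + 1L):(pad + n)]
  fac <- as.integer(round(fs / fs_out))
  if (fac > 1L) y <- y[seq(1L, length(y), by = fac)]
  y
}

#' Debleach a GCaMP photometry recording
#'
#' Both channels are low-pass filtered at 2 Hz (zero-phase second-order
#' Butterworth) and downsampled to 100 Hz; a least-squares linear map of
#' the isosbestic 405-nm signal onto the activity-dependent 488-nm signal
#' is fitted over the whole recording, and the fitted isosbestic signal is
#' subtracted from the 488-nm signal. Bleaching and motion shared by the
#' two channels cancel; the output is the debleached activity signal.
#'
#' @param trace list with `time`, `iso405`, `act488` (and optionally `fs`);
#'   raw sampling rate must be >= 100 Hz.
#' @return list with `time`, `value`, `fs` (100 Hz), and the fit
#'   coefficients `fit` (intercept, slope).
#' @export
preprocess_gcamp <- function(trace) {
  fs <- .check_trace(trace)
  if (fs < 100) .invalid_input("raw sampling rate must be >= 100 Hz")
  iso <- .lowpass_downsample(trace$iso405, fs, 2, 100)
  act <- .lowpass_downsample(trace$act488, fs, 2, 100)
  if (stats::sd(iso) < 1e-8 * (abs(mean(iso)) + 1)) {
    .invalid_input("isosbestic channel is constant; debleaching fit degenerate")
  }
  fit <- stats::lm.fit(cbind(1, iso), act)
  value <- act - as.numeric(cbind(1, iso) %*% fit$coefficients)
  fac <- as.integer(round(fs / 100))
  list(time = trace$time[seq(1L, length(trace$time), by = max(fac, 1L))][seq_along(value)],
       value = value, fs = 100,
       fit = stats::setNames(fit$coefficients, c("intercept", "slope")))
}

#' Ratiometric AKAR2 PKA signal
#'
#' Both channels are low-pass filtered at 1 Hz and downsampled to 100 Hz;
#' the PKA signal is the 488/405 ratio, so any common multiplicative
#' bleach cancels exactly.
#'
#' @param trace list with `time`, `iso405`, `act488` (and optionally `fs`).
#' @param min_denominator error threshold on the filtered 405-nm signal.
#' @return list with `time`, `value`, `fs` (100 Hz).
#' @export
preprocess_akar2 <- function(trace, min_denominator = 1e-6) {
  fs <- .check_trace(trace)
  if (fs < 100) .invalid_input("raw sampling rate must be >= 100 Hz")
  iso <- .lowpass_downsample(trace$iso405, fs, 1, 100)
  act <- .lowpass_downsample(trace$act488, fs, 1, 100)
  if (any(abs(iso) < min_denominator)) {
    .invalid_input("isosbestic channel too close to 0 for a ratiometric signal")
  }
  fac <- as.integer(round(fs / 100))
  list(time = trace$time[seq(1L, length(trace$time), by = max(fac, 1L))][seq_along(iso)],
       value = act / iso, fs = 100)
}

#' Injection-locked minute-scale PETH of a photometry signal
#'
#' Takes the 10 min before to 30 min after an injection, z-scores the whole
#' window by the mean and sd of the full 10-min pre-injection segment,
#' downsamples to 1 Hz (block means) and applies a 1-min centred moving
#' average. A constant signal (zero pre-injection sd) yields an all-zero
#' PETH with a warning.
#'
#' @param signal list with `time`, `value`, `fs` (from preprocessing).
#' @param t_inj injection time in seconds.
#' @param pre_min,post_min window in minutes.
#' @return list with `t` (seconds relative to injection, 1 Hz) and `value`.
#' @export
injection_peth <- function(signal, t_inj, pre_min = 10, post_min = 30) {
  t0 <- t_inj - pre_min * 60
  if (min(signal$time) > t0 + 1e-9) {
    .invalid_input(sprintf("need >= %d min of pre-injection data", pre_min))
  }
  sel <- signal$time >= t0 & signal$time < t_inj + post_min * 60
  v <- signal$value[sel]
  tt <- signal$time[sel]
  pre <- v[tt < t_inj]
  m <- mean(pre); s <- stats::sd(pre)
  if (!is.finite(s) || s == 0) {
    warning("zero pre-injection s.d.; PETH set to zeros")
    z <- numeric(length(v))
  } else {
    z <- (v - m) / s
  }
  fac <- as.integer(round(signal$fs))
  z1 <- downsample_mean(z, fac)
  # 1-min centred moving average at 1 Hz (61-point window, partial at edges)
  n <- length(z1)
  sm <- vapply(seq_len(n), function(i) {
    mean(z1[max(1, i - 30):min(n, i + 30)])
  }, numeric(1))
  list(t = seq(-pre_min * 60, by = 1, length.out = n), value = sm)
}

#' Reward-locked AKAR2 PETHs and PKA response scalar
#'
#' Builds per-event PETHs of the PKA signal over (-10, +30) s around reward
#' deliveries, centres each event's PETH by its own (-5, -1) s baseline
#' mean, divides all PETHs by the sd of the concatenated baseline epochs
#' pooled across both ports (one scale per recording), and averages per
#' port. The PKA response scalar is the mean over (+5, +15] s of the
#' averaged PETH.
#'
#' @param signal list with `time`, `value`, `fs`.
#' @param event_times reward delivery times (s).
#' @param event_ports port label per event.
#' @param window c(pre, post) seconds.
#' @return list with `lags`, per-port `peth` (named list of vectors),
#'   `scalar` (named numeric), `n_events` (per port), `n_dropped`.
#' @export
reward_peth_pka <- function(signal, event_times, event_ports,
                            window = c(-10, 30)) {
  if (length(event_times) == 0L) .invalid_input("no events")
  fs <- signal$fs
  n_lag <- as.integer(round((window[2] - window[1]) * fs))
  lags <- window[1] + (seq_len(n_lag) - 0.5) / fs
  t_start <- signal$time[1]
  keep <- event_times + window[1] >= t_start &
    event_times + window[2] <= signal$time[length(signal$time)] + 1 / fs
  n_dropped <- sum(!keep)
  event_times <- event_times[keep]; event_ports <- event_ports[keep]
  if (length(event_times) == 0L) .invalid_input("no events with full windows")
  base_sel <- lags >= -5 & lags < -1
  peths <- matrix(NA_real_, length(event_times), n_lag)
  for (i in seq_along(event_times)) {
    i0 <- as.integer(round((event_times[i] + window[1] - t_start) * fs))
    peths[i, ] <- signal$value[i0 + seq_len(n_lag)]
    peths[i, ] <- peths[i, ] - mean(peths[i, base_sel])
  }
  pooled_sd <- stats::sd(as.numeric(t(peths[, base_sel, drop = FALSE])))
  if (!is.finite(pooled_sd) || pooled_sd == 0) pooled_sd <- 1
  peths <- peths / pooled_sd
  ports <- unique(event_ports)
  avg <- lapply(ports, function(p) colMeans(peths[event_ports == p, , drop = FALSE]))
  names(avg) <- ports
  resp_sel <- lags > 5 & lags <= 15
  scalar <- vapply(avg, function(v) mean(v[resp_sel]), numeric(1))
  list(lags = lags, peth = avg, scalar = scalar,
       n_events = table(event_ports), n_dropped = n_dropped)
}
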