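#' Per-neuron epoch statistics computed from spike times
#'
#' Mean and population sd of `bin_width` counts across an epoch, computed
#' without materializing the count matrix; identical to [epoch_stats()] on
#' [bin_spikes()] output over the same span.
#'
#' @param spikes named list of spike-time vectors.
#' @param ep an [epoch()].
#' @param bin_width bin width in seconds.
#' @return a [norm_stats()].
#' @export
epoch_stats_from_spikes <- function(spikes, ep, bin_width = 0.010) {
  stopifnot(inherits(ep, "epoch"))
  n_bins <- floor((ep$end - ep$start) / bin_width + 1e-9)
  if (n_bins < 2) .invalid_input("epoch must span at least 2 bins")
  end_t <- ep$start + n_bins * bin_width
  m <- sdv <- numeric(length(spikes))
  for (u in seq_along(spikes)) {
    st <- spikes[[u]]
    st <- st[st >= ep$start & st < end_t]
    idx <- floor((st - ep$start) / bin_width)
    cnt_sq <- if (length(idx)) sum(rle(sort(idx))$lengths^2) else 0
    m[u] <- length(st) / n_bins
    sdv[u] <- sqrt(max(cnt_sq / n_bins - m[u]^2, 0))
  }
  suppressWarnings(
    norm_stats(mean = m, sd = sdv, epoch_label = ep$label,
               bin_width = bin_width, granularity = "bin",
               unit_ids = names(spikes)))
}

#' Final-20-min delay statistics
#'
#' The normalization reference for delay/stimulation traces: mean and sd of
#' 10-ms counts over the last `last_min` minutes of the delay period.
#'
#' @param spikes named list of spike-time vectors.
#' @param events an [event_log()].
#' @param last_min minutes of delay to use, counted back from delay end
#'   (`Inf` for the full delay).
#' @param bin_width bin width in seconds.
#' @return a [norm_stats()].
#' @export
delay_stats <- function(spikes, events, last_min = 20, bin_width = 0.010) {
  dl <- events$epochs$delay
  start <- max(dl$start, dl$end - last_min * 60)
  epoch_stats_from_spikes(spikes,
                          epoch(sprintf("delay_final_%smin", last_min),
                                start, dl$end),
                          bin_width)
}

# summed per-lag spike counts over aligned event windows for one neuron;
# st must be sorted
.event_lag_counts <- function(st, event_times, window, bin_width, n_lags) {
  acc <- numeric(n_lags)
  for (te in event_times) {
    lo <- te + window[1]
    i0 <- findInterval(lo - 1e-12, st)
    i1 <- findInterval(lo + n_lags * bin_width - 1e-12, st)
    if (i1 > i0) {
      rel <- st[(i0 + 1):i1] - lo
      idx <- pmin(floor(rel / bin_width) + 1, n_lags)
      acc <- acc + tabulate(idx, nbins = n_lags)
    }
  }
  acc
}

.peth_matrix <- function(values, window, bin_width, baseline, normalization,
                         smoothed, n_events, n_dropped, unit_ids) {
  structure(list(values = values, window = window, bin_width = bin_width,
                 baseline = baseline, normalization = normalization,
                 smoothed = smoothed, n_events = n_events,
                 n_dropped = n_dropped, unit_ids = unit_ids,
                 lags = window[1] + (seq_len(ncol(values)) - 0.5) * bin_width),
            class = "peth_matrix")
}

#' @export
print.peth_matrix <- function(x, ...) {
  cat(sprintf("<peth_matrix> %d units x %d lags, window [%g, %g] s, %d events (%d dropped), baseline '%s', norm '%s'%s\n",
              nrow(x$values), ncol(x$values), x$window[1], x$window[2],
              x$n_events, x$n_dropped, x$baseline,
              x$normalization$epoch_label,
              if (isTRUE(x$smoothed)) ", smoothed" else ""))
  invisible(x)
}

#' Reward-delivery PETH
#'
#' Event-aligned average of z-scored 10-ms activity around reward
#' deliveries of one port (default window -5 s to +10 s). Normalization
#' statistics must come from the consumption period; for day-2 sessions of
#' a multiday recording, pass the day-1 statistics so units are comparable
#' across days. Events whose window extends past the recorded range are
#' dropped from the average (count recorded in `n_dropped`).
#'
#' @param spikes named list of sorted spike-time vectors.
#' @param events an [event_log()].
#' @param port `"flavour"` or `"water"`.
#' @param stats consumption-period [norm_stats()] (possibly day 1's).
#' @param window c(pre, post) in seconds.
#' @param bin_width bin width in seconds.
#' @param smooth_sd if non-`NULL`, causal half-Gaussian sd in seconds for
#'   display variants (0.100 standard).
#' @param t_range recorded data range used for the drop rule; defaults to
#'   `[0, last epoch end]`.
#' @param day provenance tag for the normalization (e.g. `"day1"`).
#' @return a `peth_matrix`.
#' @export
reward_peth <- function(spikes, events, port, stats, window = c(-5, 10),
                        bin_width = 0.010, smooth_sd = NULL, t_range = NULL,
                        day = "day1") {
  tt <- events$rewards$time[events$rewards$port == port]
  if (length(tt) == 0L) .invalid_input(sprintf("no '%s' rewards", port))
  if (is.null(t_range)) {
    t_range <- c(0, max(vapply(events$epochs, function(e) e$end, numeric(1))))
  }
  keep <- tt + window[1] >= t_range[1] & tt + window[2] <= t_range[2]
  n_dropped <- sum(!keep)
  tt <- tt[keep]
  if (length(tt) == 0L) .invalid_input("all events fall outside recorded range")
  n_lags <- as.integer(round((window[2] - window[1]) / bin_width))
  sdv <- ifelse(stats$zero_sd, 1, stats$sd)
  vals <- matrix(0, length(spikes), n_lags)
  for (u in seq_along(spikes)) {
    acc <- .event_lag_counts(spikes[[u]], tt, window, bin_width, n_lags)
    vals[u, ] <- (acc / length(tt) - stats$mean[u]) / sdv[u]
  }
  vals[stats$zero_sd, ] <- 0
  if (!is.null(smooth_sd)) {
    vals <- causal_half_gaussian_smooth(vals, smooth_sd, bin_width)
  }
  .peth_matrix(vals, window, bin_width, baseline = "none",
               normalization = list(epoch_label = stats$epoch_label, day = day),
               smoothed = !is.null(smooth_sd), n_events = length(tt),
               n_dropped = n_dropped, unit_ids = names(spikes))
}

#' Stimulation-bout PETH
#'
#' Bout-onset-aligned average of z-scored activity, minus each neuron's own
#' pre-bout baseline mean over (-1, 0) s. Window is (-1, +4) s for chronic
#' stimulation analyses and (-1, +2) s for the acute/GMM analysis.
#' Normalization must use that day's consumption-period statistics.
#'
#' @param spikes named list of sorted spike-time vectors.
#' @param events an [event_log()] with stim bouts (or a data.frame of bouts).
#' @param stats [norm_stats()] for z-scoring.
#' @param window c(pre, post) seconds; `pre <= -1` so the baseline exists.
#' @param bin_width bin width (s).
#' @param smooth_sd optional causal half-Gaussian sd (s).
#' @return a `peth_matrix` with `baseline = "pre_bout_-1_0"`.
#' @export
stim_bout_peth <- function(spikes, events, stats, window = c(-1, 4),
                           bin_width = 0.010, smooth_sd = NULL) {
  bouts <- if (inherits(events, "event_log")) events$bouts else events
  if (nrow(bouts) == 0L) .invalid_input("no stimulation bouts")
  tt <- bouts$onset
  n_lags <- as.integer(round((window[2] - window[1]) / bin_width))
  sdv <- ifelse(stats$zero_sd, 1, stats$sd)
  vals <- matrix(0, length(spikes), n_lags)
  for (u in seq_along(spikes)) {
    acc <- .event_lag_counts(spikes[[u]], tt, window, bin_width, n_lags)
    vals[u, ] <- (acc / length(tt) - stats$mean[u]) / sdv[u]
  }
  vals[stats$zero_sd, ] <- 0
  if (!is.null(smooth_sd)) {
    vals <- causal_half_gaussian_smooth(vals, smooth_sd, bin_width)
  }
  lag_centers <- window[1] + (seq_len(n_lags) - 0.5) * bin_width
  base_cols <- lag_centers >= -1 & lag_centers < 0
  vals <- vals - rowMeans(vals[, base_cols, drop = FALSE])
  .peth_matrix(vals, window, bin_width, baseline = "pre_bout_-1_0",
               normalization = list(epoch_label = stats$epoch_label,
                                    day = "same_day"),
               smoothed = !is.null(smooth_sd), n_events = length(tt),
               n_dropped = 0L, unit_ids = names(spikes))
}

# per-neuron minute-mean 10-ms-equivalent counts over [start, start + n_min
# minutes), z-scored with `stats`; minute means of z equal
# (minute mean count - mean) / sd
.minute_z <- function(spikes, start, n_min, stats, bin_width = 0.010) {
  sdv <- ifelse(stats$zero_sd, 1, stats$sd)
  edges <- start + seq(0, n_min) * 60
  bins_per_min <- 60 / bin_width
  out <- matrix(0, length(spikes), n_min)
  for (u in seq_along(spikes)) {
    st <- spikes[[u]]
    cnt <- diff(findInterval(edges - 1e-12, st))
    out[u, ] <- (cnt / bins_per_min - stats$mean[u]) / sdv[u]
  }
  out[stats$zero_sd, ] <- 0
  out
}

#' Whole-experiment minute-resolution trace
#'
#' Concatenates the final 15 min of consumption, the first 30 min of delay
#' and the first 45 min of the stimulation/malaise period, z-scored with
#' delay-derived statistics (final 20 min of delay by default) and
#' downsampled to 1 sample per minute, giving 90 samples per neuron.
#' Epochs shorter than the requested span are truncated with a warning.
#'
#' @param spikes named list of sorted spike-time vectors.
#' @param events an [event_log()].
#' @param stats_source `"delay20"` (final-20-min delay statistics, default)
#'   or `"delay_full"`.
#' @param bin_width underlying bin width (s).
#' @return a `minute_trace` object: `values` (neurons x minutes),
#'   `t_minutes` (minutes relative to stimulation/malaise onset), `segments`.
#' @export
whole_experiment_trace <- function(spikes, events,
                                   stats_source = c("delay20", "delay_full"),
                                   bin_width = 0.010) {
  stats_source <- match.arg(stats_source)
  eps <- events$epochs
  post_name <- intersect(c("stim", "malaise"), names(eps))
  if (length(post_name) == 0L) .invalid_input("no stim/malaise epoch present")
  post <- eps[[post_name[1]]]
  stats <- delay_stats(spikes, events,
                       last_min = if (stats_source == "delay20") 20 else Inf,
                       bin_width = bin_width)
  seg_min <- function(ep, want, from_end = FALSE) {
    avail <- floor((ep$end - ep$start) / 60)
    if (avail < want) {
      warning(sprintf("epoch '%s' shorter than %d min; truncated to %d",
                      ep$label, want, avail))
      want <- avail
    }
    start <- if (from_end) ep$end - want * 60 else ep$start
    list(start = start, n = want)
  }
  s1 <- seg_min(eps$consumption, 15, from_end = TRUE)
  s2 <- seg_min(eps$delay, 30)
  s3 <- seg_min(post, 45)
  vals <- cbind(.minute_z(spikes, s1$start, s1$n, stats, bin_width),
                .minute_z(spikes, s2$start, s2$n, stats, bin_width),
                .minute_z(spikes, s3$start, s3$n, stats, bin_width))
  t_minutes <- c(seq_len(s1$n) - s1$n - 30 - 1, seq_len(s2$n) - 30 - 1,
                 seq_len(s3$n) - 1)
  structure(list(values = vals, t_minutes = t_minutes,
                 segments = c(consumption = s1$n, delay = s2$n, post = s3$n),
                 origin = post_name[1], stats = stats,
                 unit_ids = names(spikes)),
            class = "minute_trace")
}

#' Event-locked minute-resolution trace
#'
#' Minute trace around a single event (stimulation onset or LiCl injection),
#' default 30 min before to 45 min after, z-scored with the statistics of
#' the final 20 min of the delay period preceding the event.
#'
#' @param spikes named list of sorted spike-time vectors.
#' @param events an [event_log()].
#' @param t_event event time in seconds; defaults to the stimulation-period
#'   start or the injection time.
#' @param window_min c(pre, post) in minutes.
#' @param bin_width underlying bin width (s).
#' @return a `minute_trace`; `t_minutes` gives each sample's start minute
#'   relative to the event (so 0 is the first post-event minute).
#' @export
delay_event_trace <- function(spikes, events, t_event = NULL,
                              window_min = c(-30, 45), bin_width = 0.010) {
  if (is.null(t_event)) {
    t_event <- if (is.finite(events$injection_time)) events$injection_time
               else if ("stim" %in% names(events$epochs)) events$epochs$stim$start
               else .invalid_input("no event time available")
  }
  dl <- events$epochs$delay
  if (t_event - dl$start < 20 * 60) {
    .invalid_input("need >= 20 min of delay before the event")
  }
  stats <- epoch_stats_from_spikes(
    spikes, epoch("delay_final_20min", t_event - 20 * 60, t_event), bin_width)
  n_min <- window_min[2] - window_min[1]
  vals <- .minute_z(spikes, t_event + window_min[1] * 60, n_min, stats,
                    bin_width)
  structure(list(values = vals,
                 t_minutes = window_min[1] + seq_len(n_min) - 1,
                 segments = c(pre = -window_min[1], post = window_min[2]),
                 origin = "event", stats = stats, unit_ids = names(spikes)),
            class = "minute_trace")
}

#' @export
print.minute_trace <- function(x, ...) {
  cat(sprintf("<minute_trace> %d units x %d min (origin: %s)\n",
              nrow(x$values), ncol(x$values), x$origin))
  invisible(x)
}

#' Scalar response summaries
#'
#' Collapses a minute trace or PETH to one number per neuron:
#' `cgrp_45min` is the mean over minutes 0-45 of the stimulation period,
#' `licl_5_15min` the mean over minutes +5 to +15 after injection, and
#' `post10s_reward` the mean z over 0-10 s after delivery in a reward PETH,
#' optionally minus the (-10, -5) s pre-delivery baseline.
#'
#' @param x a `minute_trace` (for the minute rules) or `peth_matrix` with a
#'   window covering the needed spans (for `post10s_reward`).
#' @param rule one of `"cgrp_45min"`, `"licl_5_15min"`, `"post10s_reward"`.
#' @param baseline_subtract for `post10s_reward`: subtract the (-10, -5) s
#'   baseline mean (used for cross-day comparisons).
#' @return named numeric vector, one scalar per neuron.
#' @export
scalar_response <- function(x, rule = c("cgrp_45min", "licl_5_15min",
                                        "post10s_reward"),
                            baseline_subtract = FALSE) {
  rule <- match.arg(rule)
  if (rule %in% c("cgrp_45min", "licl_5_15min")) {
    stopifnot(inherits(x, "minute_trace"))
    span <- if (rule == "cgrp_45min") c(0, 45) else c(5, 15)
    cols <- x$t_minutes >= span[1] & x$t_minutes < span[2]
    if (sum(cols) < span[2] - span[1]) .invalid_input("required span missing")
    out <- rowMeans(x$values[, cols, drop = FALSE])
  } else {
    stopifnot(inherits(x, "peth_matrix"))
    resp_cols <- x$lags > 0 & x$lags <= 10
    if (!any(resp_cols)) .invalid_input("PETH lacks the 0-10 s response span")
    out <- rowMeans(x$values[, resp_cols, drop = FALSE])
    if (baseline_subtract) {
      base_cols <- x$lags >= -10 & x$lags < -5
      if (!any(base_cols)) .invalid_input("PETH lacks the -10 to -5 s baseline")
      out <- out - rowMeans(x$values[, base_cols, drop = FALSE])
    }
  }
  names(out) <- x$unit_ids
  out
}

#' Write / read a PETH with its provenance sidecar
#'
#' Values go to CSV (neurons x lags); window, bin width, baseline rule,
#' normalization provenance, smoothing flag and event counts go to a JSON
#' sidecar so a PETH round-trips losslessly.
#'
#' @param peth a `peth_matrix`.
#' @param csv_path,json_path output paths.
#' @export
write_peth <- function(peth, csv_path, json_path) {
  df <- as.data.frame(peth$values)
  names(df) <- sprintf("lag_%g", peth$lags)
  df <- cbind(unit_id = peth$unit_ids, df)
  utils::write.csv(df, csv_path, row.names = FALSE)
  meta <- peth[c("window", "bin_width", "baseline", "normalization",
                 "smoothed", "n_events", "n_dropped", "unit_ids")]
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' @rdname write_peth
#' @export
read_peth <- function(csv_path, json_path) {
  df <- utils::read.csv(csv_path, check.names = FALSE)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  dimnames(vals) <- NULL
  .peth_matrix(vals, meta$window, meta$bin_width, meta$baseline,
               as.list(meta$normalization), meta$smoothed,
               meta$n_events, meta$n_dropped, meta$unit_ids)
}
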