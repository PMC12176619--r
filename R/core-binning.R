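#' Binned spike-count matrix
#'
#' Container for a neurons x bins matrix of spike counts. Bin `k` (1-based
#' column `k`) covers the half-open interval
#' `[t0 + (k-1) * bin_width, t0 + k * bin_width)` in session-clock seconds.
#'
#' @param counts non-negative integer matrix, neurons in rows.
#' @param bin_width bin width in seconds (default 0.010, the standard 10-ms
#'   analysis bin).
#' @param t0 session-clock time of the left edge of the first bin.
#' @param unit_ids ordered unit identifiers, one per row.
#' @return an object of class `binned_spikes`.
#' @export
binned_spikes <- function(counts, bin_width = 0.010, t0 = 0,
                          unit_ids = rownames(counts)) {
  counts <- as.matrix(counts)
  .assert_scalar_num(bin_width, "bin_width", positive = TRUE)
  .assert_scalar_num(t0, "t0")
  if (any(counts < 0) || any(!is.finite(counts))) {
    .invalid_input("counts must be finite and non-negative")
  }
  if (is.null(unit_ids)) unit_ids <- as.character(seq_len(nrow(counts)))
  if (length(unit_ids) != nrow(counts)) {
    .invalid_input("unit_ids length must match number of rows")
  }
  structure(list(counts = counts, bin_width = bin_width, t0 = t0,
                 unit_ids = as.character(unit_ids)),
            class = "binned_spikes")
}

#' @export
print.binned_spikes <- function(x, ...) {
  cat(sprintf("<binned_spikes> %d units x %d bins, %.0f-ms bins, t0 = %.3f s (%.1f s covered)\n",
              nrow(x$counts), ncol(x$counts), x$bin_width * 1000, x$t0,
              ncol(x$counts) * x$bin_width))
  invisible(x)
}

#' @export
dim.binned_spikes <- function(x) dim(x$counts)

#' Bin times of a binned_spikes object
#' @param x a `binned_spikes`.
#' @param edge `"left"`, `"center"` or `"right"` bin reference point.
#' @return numeric vector of times, one per column.
#' @export
bin_times <- function(x, edge = c("left", "center", "right")) {
  edge <- match.arg(edge)
  off <- switch(edge, left = 0, center = 0.5, right = 1)
  x$t0 + (seq_len(ncol(x$counts)) - 1 + off) * x$bin_width
}

#' Bin spike times into a count matrix
#'
#' Spikes are assigned to left-closed right-open bins; a spike exactly at the
#' end of `t_range` is dropped, so total counts always equal the number of
#' in-range spikes.
#'
#' @param spike_times list of numeric vectors (seconds), one per unit; names
#'   are used as unit ids when present.
#' @param bin_width bin width in seconds.
#' @param t_range length-2 numeric, `[start, end)` of the binned range.
#' @return a [binned_spikes()] object with `(end - start) / bin_width` bins
#'   (rounded up when the range is not a whole number of bins).
#' @export
bin_spikes <- function(spike_times, bin_width = 0.010, t_range) {
  if (!is.list(spike_times) || length(spike_times) == 0L) {
    .invalid_input("spike_times must be a non-empty list of numeric vectors")
  }
  .assert_scalar_num(bin_width, "bin_width", positive = TRUE)
  if (length(t_range) != 2L || !all(is.finite(t_range)) ||
      t_range[1] >= t_range[2]) {
    .invalid_input("t_range must be [start, end) with start < end")
  }
  n_bins <- as.integer(ceiling((t_range[2] - t_range[1]) / bin_width - 1e-9))
  counts <- matrix(0L, nrow = length(spike_times), ncol = n_bins)
  for (u in seq_along(spike_times)) {
    st <- spike_times[[u]]
    if (length(st) == 0L) next
    if (any(!is.finite(st))) .invalid_input("spike times must be finite")
    st <- st[st >= t_range[1] & st < t_range[2]]
    if (length(st) == 0L) next
    idx <- floor((st - t_range[1]) / bin_width) + 1
    idx[idx > n_bins] <- n_bins  # guard against floating-point edge overflow
    counts[u, ] <- tabulate(idx, nbins = n_bins)
  }
  ids <- names(spike_times)
  if (is.null(ids)) ids <- as.character(seq_along(spike_times))
  binned_spikes(counts, bin_width = bin_width, t0 = t_range[1],
                unit_ids = ids)
}

#' Named time interval
#'
#' @param label epoch name (e.g. `"consumption"`, `"delay"`, `"stim"`).
#' @param start,end interval bounds in seconds, `start < end`.
#' @return an `epoch` object.
#' @export
epoch <- function(label, start, end) {
  .assert_scalar_num(start, "start"); .assert_scalar_num(end, "end")
  if (start >= end) .invalid_input("epoch start must be < end")
  structure(list(label = as.character(label), start = start, end = end),
            class = "epoch")
}

#' @export
print.epoch <- function(x, ...) {
  cat(sprintf("<epoch> %s: [%.1f, %.1f) s (%.1f min)\n", x$label, x$start,
              x$end, (x$end - x$start) / 60))
  invisible(x)
}

#' Per-neuron normalization statistics from an epoch
#'
#' Computes, for each neuron, the mean and population (divide-by-N) standard
#' deviation of the bin counts whose bins lie wholly inside the epoch. These
#' are the statistics later used for z-scoring, with provenance (epoch label,
#' bin width) recorded so cross-day reuse is auditable.
#'
#' @param binned a [binned_spikes()].
#' @param ep an [epoch()]; must overlap the binned range by at least 2 bins.
#' @return a `norm_stats` object: `mean`, `sd` (numeric per neuron),
#'   `zero_sd` flag vector, and provenance fields.
#' @export
epoch_stats <- function(binned, ep) {
  stopifnot(inherits(binned, "binned_spikes"), inherits(ep, "epoch"))
  left <- bin_times(binned, "left")
  right <- left + binned$bin_width
  inside <- left >= ep$start - 1e-9 & right <= ep$end + 1e-9
  if (sum(inside) < 2L) {
    .invalid_input("epoch must overlap the binned range by at least 2 bins")
  }
  sub <- binned$counts[, inside, drop = FALSE]
  m <- rowMeans(sub)
  sd_pop <- sqrt(rowMeans(sub^2) - m^2)
  sd_pop[sd_pop < 0] <- 0  # numerical guard
  zero <- sd_pop == 0
  if (any(zero)) {
    warning(sprintf("%d unit(s) have zero s.d. in epoch '%s'",
                    sum(zero), ep$label))
  }
  norm_stats(mean = m, sd = sd_pop, epoch_label = ep$label,
             bin_width = binned$bin_width, granularity = "bin",
             unit_ids = binned$unit_ids)
}

#' Construct normalization statistics
#'
#' @param mean,sd per-neuron mean and standard deviation (sd >= 0).
#' @param epoch_label,bin_width,granularity provenance: which epoch the
#'   statistics came from, the bin width, and the counting granularity
#'   (`"bin"` for 10-ms bins, `"window"` for 1-s windows, ...).
#' @param unit_ids unit identifiers in order.
#' @return a `norm_stats` object.
#' @export
norm_stats <- function(mean, sd, epoch_label = NA_character_,
                       bin_width = NA_real_, granularity = "bin",
                       unit_ids = NULL) {
  if (length(mean) != length(sd)) .invalid_input("mean/sd length mismatch")
  if (any(sd < 0)) .invalid_input("sd must be >= 0")
  if (is.null(unit_ids)) unit_ids <- as.character(seq_along(mean))
  structure(list(mean = as.numeric(mean), sd = as.numeric(sd),
                 zero_sd = sd == 0, epoch_label = epoch_label,
                 bin_width = bin_width, granularity = granularity,
                 unit_ids = as.character(unit_ids), sd_convention = "population"),
            class = "norm_stats")
}

#' @export
print.norm_stats <- function(x, ...) {
  cat(sprintf("<norm_stats> %d units, epoch '%s', %s granularity (%d zero-sd)\n",
              length(x$mean), x$epoch_label, x$granularity, sum(x$zero_sd)))
  invisible(x)
}

#' Z-score binned counts with given statistics
#'
#' Applies `(count - mean) / sd` per neuron. Neurons with zero sd produce
#' all-zero rows (with a warning) rather than NaN, so downstream averages
#' remain defined.
#'
#' @param binned a [binned_spikes()] (or plain numeric matrix, neurons x bins).
#' @param stats a [norm_stats()] whose unit order matches `binned`.
#' @return numeric matrix of z-scores, same shape as the counts.
#' @export
zscore_with_stats <- function(binned, stats) {
  counts <- if (inherits(binned, "binned_spikes")) binned$counts else as.matrix(binned)
  if (nrow(counts) != length(stats$mean)) {
    .invalid_input("unit count mismatch between data and stats")
  }
  sd <- stats$sd
  if (any(stats$zero_sd)) {
    warning(sprintf("%d unit(s) with zero s.d. set to all-zero z-scores",
                    sum(stats$zero_sd)))
    sd[stats$zero_sd] <- 1
  }
  z <- (counts - stats$mean) / sd
  z[stats$zero_sd, ] <- 0
  z
}

#' Causal half-Gaussian smoothing
#'
#' Convolves a series with the right half (current and past samples only) of
#' a Gaussian kernel of the given standard deviation, truncated at 4 sd and
#' renormalized to unit sum. Output sample `k` therefore depends only on
#' samples `<= k` (causal). The first samples, where part of the kernel
#' falls before the data, are renormalized by the kernel mass inside the
#' data, so constant inputs are preserved exactly everywhere.
#'
#' @param trace numeric vector, or matrix smoothed row-wise.
#' @param sd kernel standard deviation in seconds (e.g. 0.100 for display
#'   PETHs, 0.025 for decoder rasters).
#' @param bin_width sample spacing in seconds.
#' @return smoothed series, same length/shape as input.
#' @export
causal_half_gaussian_smooth <- function(trace, sd, bin_width) {
  .assert_scalar_num(sd, "sd", positive = TRUE)
  .assert_scalar_num(bin_width, "bin_width", positive = TRUE)
  n_k <- max(1L, as.integer(floor(4 * sd / bin_width)) + 1L)
  lags <- (seq_len(n_k) - 1) * bin_width
  kern <- exp(-lags^2 / (2 * sd^2))
  kern <- kern / sum(kern)
  part <- cumsum(kern)  # partial kernel mass available near the start
  smooth1 <- function(x) {
    n <- length(x)
    if (n == 0L) return(x)
    # zero-pad the past; each output uses current and past samples only
    out <- stats::filter(c(rep(0, n_k - 1L), x), kern, method = "convolution",
                         sides = 1)
    out <- as.numeric(out[n_k:(n_k + n - 1L)])
    # renormalize the head by the kernel mass actually inside the data, so
    # constant inputs are preserved from the first sample on
    head_n <- min(n_k - 1L, n)
    if (head_n > 0L) out[seq_len(head_n)] <- out[seq_len(head_n)] / part[seq_len(head_n)]
    out
  }
  if (is.matrix(trace)) t(apply(trace, 1L, smooth1)) else smooth1(trace)
}

#' Downsample by non-overlapping block means
#'
#' A trailing partial block is averaged over its actual length (no padding).
#'
#' @param trace numeric vector, or matrix downsampled row-wise.
#' @param factor integer >= 1, samples per block.
#' @return block-mean series.
#' @export
downsample_mean <- function(trace, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor)) {
    .invalid_input("factor must be an integer >= 1")
  }
  ds1 <- function(x) {
    n <- length(x)
    g <- (seq_len(n) - 1L) %/% factor
    as.numeric(tapply(x, g, mean))
  }
  if (is.matrix(trace)) t(apply(trace, 1L, ds1)) else ds1(trace)
}
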