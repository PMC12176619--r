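#' Per-trial reward responses from a z-scored matrix
#'
#' For every reward delivery, the mean z-scored activity over the `window`
#' seconds following delivery (bins whose span lies inside
#' `(delivery, delivery + window]`), grouped by port. The window is fixed at
#' 10 s regardless of any overlap with the next trial.
#'
#' @param z numeric matrix (neurons x bins), z-scored over the consumption
#'   period.
#' @param events an [event_log()].
#' @param window response window in seconds after delivery.
#' @param bin_width,t0 bin geometry of `z` (seconds).
#' @return a `trial_responses` object: matrices `flavour` and `water`
#'   (neurons x trials), plus `unit_ids` and the window used.
#' @export
trial_response_matrix <- function(z, events, window = 10,
                                  bin_width = 0.010, t0 = 0) {
  stopifnot(is.matrix(z), inherits(events, "event_log"))
  nb <- as.integer(round(window / bin_width))
  resp_for <- function(port) {
    tt <- events$rewards$time[events$rewards$port == port]
    if (length(tt) == 0L) {
      return(matrix(numeric(0), nrow = nrow(z), ncol = 0))
    }
    out <- matrix(NA_real_, nrow(z), length(tt))
    for (i in seq_along(tt)) {
      k0 <- as.integer(ceiling((tt[i] - t0) / bin_width - 1e-9))
      hi <- k0 + nb
      if (hi > ncol(z)) {
        warning("response window truncated at end of data")
        hi <- ncol(z)
      }
      if (k0 + 1 > hi) next
      out[, i] <- rowMeans(z[, (k0 + 1):hi, drop = FALSE])
    }
    out
  }
  structure(list(flavour = resp_for("flavour"), water = resp_for("water"),
                 unit_ids = if (!is.null(rownames(z))) rownames(z)
                            else as.character(seq_len(nrow(z))),
                 window = window),
            class = "trial_responses")
}

#' Per-trial reward responses computed directly from spike times
#'
#' Exactly equivalent to z-scoring the 10-ms binned consumption trace and
#' calling [trial_response_matrix()], but without materializing the dense
#' matrix: the mean z over a window of bins equals
#' `(mean count in the window - mean) / sd`. Used for large populations.
#'
#' @param spikes named list of spike-time vectors.
#' @param events an [event_log()].
#' @param stats consumption-period [norm_stats()] (10-ms granularity).
#' @param window response window in seconds.
#' @param bin_width bin width in seconds.
#' @param t_max end of the recorded data; windows reaching past it are
#'   truncated with a warning (mean over the covered bins). Defaults to the
#'   last epoch end.
#' @return a `trial_responses` object, as [trial_response_matrix()].
#' @export
trial_responses_from_spikes <- function(spikes, events, stats, window = 10,
                                        bin_width = 0.010, t_max = NULL) {
  nb <- as.integer(round(window / bin_width))
  if (is.null(t_max)) {
    t_max <- max(vapply(events$epochs, function(e) e$end, numeric(1)))
  }
  sdv <- ifelse(stats$zero_sd, 1, stats$sd)
  resp_for <- function(port) {
    tt <- events$rewards$time[events$rewards$port == port]
    if (length(tt) == 0L) {
      return(matrix(numeric(0), nrow = length(spikes), ncol = 0))
    }
    # window edges aligned to the 10-ms bin grid (t0 = 0 session clock)
    lo <- ceiling(tt / bin_width - 1e-9) * bin_width
    eff <- pmin(nb, floor((t_max - lo) / bin_width + 1e-9))
    if (any(eff < nb)) warning("response window truncated at end of data")
    if (any(eff < 1)) .invalid_input("event window entirely outside the data")
    hi <- lo + eff * bin_width
    out <- matrix(NA_real_, length(spikes), length(tt))
    for (u in seq_along(spikes)) {
      st <- spikes[[u]]
      cnt <- findInterval(hi - 1e-12, st) - findInterval(lo - 1e-12, st)
      out[u, ] <- (cnt / eff - stats$mean[u]) / sdv[u]
    }
    out[stats$zero_sd, ] <- 0
    out
  }
  structure(list(flavour = resp_for("flavour"), water = resp_for("water"),
                 unit_ids = names(spikes), window = window),
            class = "trial_responses")
}

#' Wilcoxon rank-sum test (normal approximation)
#'
#' Midranks for ties; two-sided p from the normal approximation with
#' tie-corrected variance and a 0.5 continuity correction. The statistic
#' returned is the centered Mann-Whitney U of `x`
#' (`U - nx * ny / 2`), so swapping samples negates it.
#'
#' @param x,y numeric samples (each non-empty).
#' @return list with `statistic` (centered U) and `p` (two-sided).
#' @export
rank_sum_test <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 1L || ny < 1L) .invalid_input("both samples must be non-empty")
  n <- nx + ny
  r <- rank(c(x, y))  # midranks
  u_centered <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2 - nx * ny / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties)
  v <- nx * ny / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (v <= 0) return(list(statistic = u_centered, p = 1))
  z <- (abs(u_centered) - 0.5) / sqrt(v)
  z <- max(z, 0)
  list(statistic = u_centered, p = min(1, 2 * stats::pnorm(-z)))
}

# linear (Benjamini-Hochberg) step-up at level alpha; returns logical mask
.bh_stepup <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- ps <= alpha * seq_len(m) / m
  k <- if (any(ok)) max(which(ok)) else 0L
  mask <- logical(m)
  if (k > 0L) mask[o[seq_len(k)]] <- TRUE
  mask
}

#' Two-stage Benjamini-Krieger-Yekutieli FDR procedure
#'
#' Adaptive two-stage step-up: stage 1 runs the linear step-up at
#' `q' = q / (1 + q)` to estimate the number of true nulls
#' `m0 = m - r1`; if stage 1 rejects none or all, that is the answer;
#' otherwise stage 2 re-runs the linear step-up at level `q' * m / m0`.
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @param q target false discovery rate (default 0.05).
#' @return logical rejection mask, same length as `pvals`.
#' @export
bky_fdr <- function(pvals, q = 0.05) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    .invalid_input("p-values must lie in [0, 1]")
  }
  m <- length(pvals)
  if (m == 0L) return(logical(0))
  q1 <- q / (1 + q)
  stage1 <- .bh_stepup(pvals, q1)
  r1 <- sum(stage1)
  if (r1 == 0L || r1 == m) return(stage1)
  .bh_stepup(pvals, q1 * m / (m - r1))
}

#' Classify neurons as flavour-preferring, water-preferring or nonselective
#'
#' Runs the rank-sum test on per-trial 10-s responses (flavour vs water
#' trials) for every neuron, controls the FDR across all neurons in the call
#' with the two-stage BKY procedure, and labels rejected neurons by the sign
#' of (mean flavour - mean water): strictly greater means flavour-preferring,
#' otherwise water-preferring. Neurons with fewer than 2 trials in either
#' port are flagged unclassifiable and excluded from the FDR pool.
#'
#' @param responses a `trial_responses` object (from
#'   [trial_response_matrix()] or [trial_responses_from_spikes()]).
#' @param q FDR level (default 0.05, across all neurons provided; pool
#'   per-animal by calling once per animal).
#' @return a `selectivity_labels` data.frame: `unit_id`, `label`, `stat`,
#'   `p`, `mean_flavour`, `mean_water`, `rejected`, `unclassifiable`.
#' @export
classify_selectivity <- function(responses, q = 0.05) {
  stopifnot(inherits(responses, "trial_responses"))
  f <- responses$flavour; w <- responses$water
  n <- nrow(f)
  stat <- p <- mf <- mw <- rep(NA_real_, n)
  unclass <- rep(FALSE, n)
  for (u in seq_len(n)) {
    xf <- f[u, ]; xw <- w[u, ]
    xf <- xf[is.finite(xf)]; xw <- xw[is.finite(xw)]
    if (length(xf) < 2L || length(xw) < 2L) {
      unclass[u] <- TRUE
      next
    }
    ts <- rank_sum_test(xf, xw)
    stat[u] <- ts$statistic; p[u] <- ts$p
    mf[u] <- mean(xf); mw[u] <- mean(xw)
  }
  rejected <- rep(FALSE, n)
  pool <- which(!unclass)
  if (length(pool) > 0L) rejected[pool] <- bky_fdr(p[pool], q)
  label <- rep("nonselective", n)
  label[rejected & mf > mw] <- "flavour"
  label[rejected & mf <= mw] <- "water"  # exact ties fall to water
  label[unclass] <- NA_character_
  out <- data.frame(unit_id = responses$unit_ids, label = label, stat = stat,
                    p = p, mean_flavour = mf, mean_water = mw,
                    rejected = rejected, unclassifiable = unclass,
                    stringsAsFactors = FALSE)
  class(out) <- c("selectivity_labels", "data.frame")
  out
}

#' Classify a simulated or recorded session end to end
#'
#' Convenience wrapper: consumption-period normalization statistics from the
#' 10-ms binned trace, per-trial responses via the windowed spike-count path,
#' then [classify_selectivity()].
#'
#' @param spikes named list of spike-time vectors.
#' @param events an [event_log()].
#' @param q FDR level.
#' @param window response window (s).
#' @param bin_width bin width (s).
#' @return a `selectivity_labels` data.frame.
#' @export
classify_session <- function(spikes, events, q = 0.05, window = 10,
                             bin_width = 0.010) {
  cons <- events$epochs$consumption
  stats <- consumption_stats(spikes, events, bin_width = bin_width)
  resp <- trial_responses_from_spikes(spikes, events, stats, window = window,
                                      bin_width = bin_width)
  classify_selectivity(resp, q = q)
}

#' Consumption-period 10-ms-count statistics from spike times
#'
#' Per-neuron mean and population sd of 10-ms bin counts across the
#' consumption epoch, computed from spike times without materializing the
#' count matrix (sum of squared counts from run lengths of occupied bins).
#' Identical to [epoch_stats()] on the binned consumption trace.
#'
#' @param spikes named list of spike-time vectors.
#' @param events an [event_log()] (its consumption epoch is used).
#' @param bin_width bin width in seconds.
#' @return a [norm_stats()].
#' @export
consumption_stats <- function(spikes, events, bin_width = 0.010) {
  epoch_stats_from_spikes(spikes, events$epochs$consumption, bin_width)
}
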