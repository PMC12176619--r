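#' Per-trial window means relative to reward deliveries
#'
#' Mean z-scored activity over `(delivery + lo, delivery + hi]` for every
#' delivery of a port, computed from spike times and normalization
#' statistics (window edges aligned to the bin grid).
#' @keywords internal
.port_window_means <- function(spikes, events, stats, port, lo, hi,
                               bin_width = 0.010) {
  tt <- events$rewards$time[events$rewards$port == port]
  nb <- as.integer(round((hi - lo) / bin_width))
  sdv <- ifelse(stats$zero_sd, 1, stats$sd)
  lo_t <- ceiling((tt + lo) / bin_width - 1e-9) * bin_width
  hi_t <- lo_t + nb * bin_width
  out <- matrix(NA_real_, length(spikes), length(tt))
  for (u in seq_along(spikes)) {
    st <- spikes[[u]]
    cnt <- findInterval(hi_t - 1e-12, st) - findInterval(lo_t - 1e-12, st)
    out[u, ] <- (cnt / nb - stats$mean[u]) / sdv[u]
  }
  out[stats$zero_sd, ] <- 0
  out
}

#' Cross-day change in flavour response and selectivity
#'
#' For units matched across a conditioning (day 1) and retrieval (day 2)
#' session: per-trial 10-s reward responses with the (-10, -5) s pre-trial
#' baseline subtracted (so baseline-rate drift between days cancels),
#' averaged per day; the flavour response is the mean response to flavour
#' deliveries and selectivity is flavour minus water. Both days are
#' z-scored with day-1 consumption statistics so units are comparable.
#' Units missing from either day are excluded (count reported via the
#' `n_unmatched` attribute).
#'
#' @param day1,day2 lists with `events` and `spikes` (named by unit).
#' @param labels day-1 `selectivity_labels` (classification on day 1 only).
#' @param window response window (s).
#' @param baseline_window pre-delivery baseline window (s, negative lags).
#' @return data.frame: `unit_id`, `label`, `delta_response`,
#'   `delta_selectivity`, day-wise responses.
#' @export
paired_day_responses <- function(day1, day2, labels, window = 10,
                                 baseline_window = c(-10, -5)) {
  ids <- intersect(names(day1$spikes), names(day2$spikes))
  n_unmatched <- length(union(names(day1$spikes), names(day2$spikes))) -
    length(ids)
  if (length(ids) == 0L) .invalid_input("no matched units across days")
  s1 <- day1$spikes[ids]; s2 <- day2$spikes[ids]
  stats1 <- consumption_stats(s1, day1$events)
  day_resp <- function(spk, events) {
    resp <- function(port) {
      r <- .port_window_means(spk, events, stats1, port, 0, window)
      b <- .port_window_means(spk, events, stats1, port,
                              baseline_window[1], baseline_window[2])
      rowMeans(r - b)
    }
    list(flavour = resp("flavour"), water = resp("water"))
  }
  r1 <- day_resp(s1, day1$events)
  r2 <- day_resp(s2, day2$events)
  lab <- labels$label[match(ids, labels$unit_id)]
  out <- data.frame(unit_id = ids, label = lab,
                    flavour_day1 = r1$flavour, flavour_day2 = r2$flavour,
                    water_day1 = r1$water, water_day2 = r2$water,
                    delta_response = r2$flavour - r1$flavour,
                    delta_selectivity = (r2$flavour - r2$water) -
                      (r1$flavour - r1$water),
                    stringsAsFactors = FALSE)
  attr(out, "n_unmatched") <- n_unmatched
  out
}

#' Regress cross-day response change on stimulation-period response
#'
#' Ordinary least squares of the change in flavour response (or
#' selectivity) on the stimulation-period ("CGRP") response, fitted
#' separately per neuron class, with Pearson r, its t-based two-sided p,
#' and 95% confidence intervals for the slope and the mean fit.
#'
#' @param delta per-neuron change values.
#' @param cgrp per-neuron stimulation-period scalar responses.
#' @param class_labels per-neuron class labels (fit runs per class);
#'   `NULL` fits a single pooled regression.
#' @return a named list of `regression_summary` objects (slope, intercept,
#'   r, p, slope_ci, sigma, n, and `band(x)` parameters for the mean-fit
#'   CI), one per class.
#' @export
delta_vs_cgrp_regression <- function(delta, cgrp, class_labels = NULL) {
  if (is.null(class_labels)) class_labels <- rep("all", length(delta))
  out <- list()
  for (cl in unique(class_labels[!is.na(class_labels)])) {
    i <- which(class_labels == cl)
    if (length(i) < 3L) {
      warning(sprintf("class '%s' has < 3 neurons; skipped", cl))
      next
    }
    x <- cgrp[i]; yv <- delta[i]
    if (stats::sd(x) == 0) .invalid_input("zero-variance predictor")
    fit <- stats::lm(yv ~ x)
    ct <- stats::cor.test(x, yv)
    ci <- stats::confint(fit)["x", ]
    s <- summary(fit)
    out[[cl]] <- structure(
      list(slope = unname(stats::coef(fit)[2]),
           intercept = unname(stats::coef(fit)[1]),
           r = unname(ct$estimate), p = ct$p.value,
           slope_ci = unname(ci), sigma = s$sigma,
           x_mean = mean(x), sxx = sum((x - mean(x))^2),
           n = length(i)),
      class = "regression_summary")
  }
  out
}

#' @export
print.regression_summary <- function(x, ...) {
  cat(sprintf("slope %.3f [%.3f, %.3f], r = %.3f, p = %.3g, n = %d\n",
              x$slope, x$slope_ci[1], x$slope_ci[2], x$r, x$p, x$n))
  invisible(x)
}

#' Class proportions per day with paired comparison
#'
#' Fraction of neurons in each selectivity class when classification is run
#' independently on each day, plus the day-2 minus day-1 difference (the
#' familiarization analysis tracks the drop in the flavour-preferring
#' fraction).
#'
#' @param labels_day1,labels_day2 `selectivity_labels` data.frames.
#' @return data.frame with `class`, `day1`, `day2`, `difference`.
#' @export
selectivity_proportions_by_day <- function(labels_day1, labels_day2) {
  frac <- function(lab) {
    lab <- lab$label[!is.na(lab$label)]
    vapply(c("flavour", "water", "nonselective"),
           function(cl) mean(lab == cl), numeric(1))
  }
  f1 <- frac(labels_day1); f2 <- frac(labels_day2)
  data.frame(class = names(f1), day1 = unname(f1), day2 = unname(f2),
             difference = unname(f2 - f1))
}
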