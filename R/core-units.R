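#' Unit quality filtering
#'
#' Applies the standard curation thresholds for chronically recorded units:
#' clusters with median template-scaling amplitude < 20 uV, estimated
#' false-positive rate > 100%, or firing rate < 0.05 sp/s are excluded as
#' noise. Among included clusters, those curated as `good` with
#' false-positive rate < 10% are single units; the rest are multiunits.
#' Both single units and multiunits are retained for analysis.
#'
#' @param meta data.frame with columns `unit_id`, `median_amplitude_uv`,
#'   `fp_rate` (fraction), `firing_rate` (sp/s), `label` (`"good"`/`"mua"`).
#' @param amplitude_min,fp_max,rate_min,fp_single exclusion/classification
#'   thresholds (uV, fraction, sp/s, fraction).
#' @return data.frame with logical columns `included` and `single_unit`
#'   alongside `unit_id`.
#' @export
unit_quality_filter <- function(meta, amplitude_min = 20, fp_max = 1.0,
                                rate_min = 0.05, fp_single = 0.10) {
  req <- c("unit_id", "median_amplitude_uv", "fp_rate", "firing_rate", "label")
  if (!all(req %in% names(meta))) {
    .invalid_input(paste("meta must have columns:", paste(req, collapse = ", ")))
  }
  if (any(meta$fp_rate < 0) || any(meta$firing_rate < 0) ||
      any(meta$median_amplitude_uv < 0)) {
    .invalid_input("quality metrics must be non-negative")
  }
  included <- meta$median_amplitude_uv >= amplitude_min &
    meta$fp_rate <= fp_max & meta$firing_rate >= rate_min
  single <- included & meta$label == "good" & meta$fp_rate < fp_single
  data.frame(unit_id = meta$unit_id, included = included,
             single_unit = single, stringsAsFactors = FALSE)
}

#' Estimated false-positive rate from refractory-period violations
#'
#' Reference computation of the contamination estimate used as the `fp_rate`
#' quality metric. Uses the standard violation-rate estimator (Hill et al.,
#' J Neurosci 2011): with N spikes over duration T and V inter-spike
#' violations of the refractory period `t_ref` (beyond a censored period
#' `t_cens` that the sorter cannot resolve), the contaminant fraction f
#' solves V = 2 (t_ref - t_cens) N^2 f (1 - f) / T; the smaller root is
#' returned, or 1 when no real root exists (violation rate beyond what any
#' contaminant fraction can produce).
#'
#' @param n_spikes total spike count of the cluster.
#' @param n_violations number of inter-spike intervals < `t_ref`.
#' @param duration recording duration in seconds.
#' @param t_ref refractory period in seconds (default 0.002).
#' @param t_cens censored period in seconds (default 0).
#' @return estimated false-positive fraction in `[0, 1]`.
#' @export
refractory_fp_rate <- function(n_spikes, n_violations, duration,
                               t_ref = 0.002, t_cens = 0) {
  .assert_scalar_num(duration, "duration", positive = TRUE)
  if (n_spikes < 2 || n_violations < 0) {
    .invalid_input("need n_spikes >= 2 and n_violations >= 0")
  }
  if (n_violations == 0) return(0)
  k <- 2 * (t_ref - t_cens) * n_spikes^2 / duration
  disc <- 1 - 4 * n_violations / k
  if (disc < 0) return(1)
  (1 - sqrt(disc)) / 2
}

#' Two-bottle flavour preference
#'
#' Retrieval-test preference: weight of flavour consumed over total weight
#' consumed, `flavour / (flavour + water)`.
#'
#' @param flavour_g,water_g grams consumed from each bottle (>= 0).
#' @return preference fraction in `[0, 1]`.
#' @export
two_bottle_preference <- function(flavour_g, water_g) {
  if (any(flavour_g < 0) || any(water_g < 0)) {
    .invalid_input("consumed weights must be non-negative")
  }
  tot <- flavour_g + water_g
  if (any(tot == 0)) {
    .invalid_input("preference undefined when nothing was consumed")
  }
  flavour_g / tot
}
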