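#' Simulation configuration
#'
#' Parameters of the synthetic two-reward conditioning experiment. Defaults
#' describe a single session of the task: 5-min acclimation; a consumption
#' period of 60 cued 20-ul rewards (blocks of ten split 5/5 across the
#' flavour and water ports, integer-second inter-trial intervals uniform on
#' 10-20 s); a 30-min delay in a second context; then either a 45-min
#' stimulation period of 3-s bouts at truncated-exponential intervals or a
#' LiCl injection. Neurons are Poisson with lognormal baseline rates and
#' fall into flavour-preferring, water-preferring and nonselective classes
#' (default split 30%/10%/60%, qualitatively mirroring the observed
#' proportions of flavour- and water-activated CEA neurons).
#'
#' @param n_neurons number of simulated neurons.
#' @param frac_flavour,frac_water class fractions (remainder nonselective).
#' @param baseline_log_mean,baseline_log_sd lognormal parameters of baseline
#'   rates in sp/s (default median 2 sp/s).
#' @param reward_gain peak multiplicative rate gain of the alpha-function
#'   response to the preferred reward.
#' @param kernel_tau alpha-kernel timescale in seconds (peak at `tau`).
#' @param delay_suppression multiplicative rate factor applied to all
#'   neurons from the end of consumption onward (activity drop after the
#'   meal ends; magnitude is a free parameter of the generator).
#' @param react_gain_mean,react_gain_sd mean/sd of the per-neuron bout-locked
#'   reactivation gain of flavour-preferring neurons (normal, truncated at
#'   0); water-preferring and nonselective neurons have no bout gain. The
#'   default produces bout-locked reactivation of roughly 1 z-unit in
#'   minute-resolution delay-to-stimulation traces under Poisson
#'   variability, the scale at which reactivation is measured.
#' @param plasticity_beta slope linking a flavour neuron's bout reactivation
#'   gain to its day-2 gain change (`gain2 = gain1 + beta * react_gain + noise`).
#' @param plasticity_noise_sd sd of the cross-day plasticity noise.
#' @param familiarization_decay multiplicative factor applied to day-1
#'   flavour gains in the familiarization variant.
#' @param n_rewards total rewards in the consumption period (1.2 ml at 20 ul).
#' @param block_size rewards per balanced block.
#' @param malaise `"stim"` (bout stimulation period) or `"licl"` (injection).
#' @param rate_max per-neuron instantaneous rate ceiling in sp/s; exceeding
#'   it is an error rather than silent saturation.
#' @param seed default master seed used when a stage is called without one.
#' @return a validated `sim_config` object.
#' @export
sim_config <- function(n_neurons = 300,
                       frac_flavour = 0.30, frac_water = 0.10,
                       baseline_log_mean = log(2), baseline_log_sd = 0.5,
                       reward_gain = 2.0, kernel_tau = 2.0,
                       delay_suppression = 0.6,
                       react_gain_mean = 8, react_gain_sd = 3,
                       plasticity_beta = 0, plasticity_noise_sd = 0,
                       familiarization_decay = 1.0,
                       n_rewards = 60, block_size = 10,
                       malaise = c("stim", "licl"),
                       rate_max = 500, seed = 1) {
  malaise <- match.arg(malaise)
  cfg <- list(n_neurons = as.integer(n_neurons), frac_flavour = frac_flavour,
              frac_water = frac_water, baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd, reward_gain = reward_gain,
              kernel_tau = kernel_tau, delay_suppression = delay_suppression,
              react_gain_mean = react_gain_mean, react_gain_sd = react_gain_sd,
              plasticity_beta = plasticity_beta,
              plasticity_noise_sd = plasticity_noise_sd,
              familiarization_decay = familiarization_decay,
              n_rewards = as.integer(n_rewards),
              block_size = as.integer(block_size), malaise = malaise,
              rate_max = rate_max, seed = seed)
  if (cfg$n_neurons < 1) .invalid_input("n_neurons must be >= 1")
  if (cfg$frac_flavour < 0 || cfg$frac_water < 0 ||
      cfg$frac_flavour + cfg$frac_water > 1) {
    .invalid_input("class fractions must be non-negative and sum to <= 1")
  }
  if (cfg$reward_gain < 0 || cfg$react_gain_mean < 0 ||
      cfg$delay_suppression < 0 || cfg$familiarization_decay < 0) {
    .invalid_input("gains and factors must be non-negative")
  }
  if (cfg$n_rewards %% cfg$block_size != 0 || cfg$block_size %% 2 != 0) {
    .invalid_input("n_rewards must be a whole number of even-sized blocks")
  }
  structure(cfg, class = "sim_config")
}

# one gap between 3-s stimulation bouts: exponential with mean 2 s shifted
# to a minimum of 1 s (untruncated mean 3 s), resampled above 7.8 s
.sample_bout_gap <- function() {
  repeat {
    g <- 1 + stats::rexp(1, rate = 1 / 2)
    if (g <= 7.8) return(g)
  }
}

#' Simulate the task event timeline
#'
#' Generates one session: acclimation, cued consumption trials with balanced
#' port blocks, delay, then a stimulation period with 3-s bouts (or a LiCl
#' injection). Trial ITIs are drawn uniformly from the integers 10-20 s;
#' port-entry (= reward-delivery) latency after cue onset is uniform on
#' 0.5-3 s. All trials are successful, matching well-trained animals.
#'
#' @param config a [sim_config()].
#' @param seed master seed; the event stream uses the `"events"` substream.
#' @return an [event_log()] with epochs `acclimation`, `consumption`,
#'   `delay`, and `stim` (with bouts) or `malaise` (with `injection_time`).
#' @export
simulate_task_events <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  with_substream(seed, "events", {
    n_blocks <- config$n_rewards %/% config$block_size
    ports <- unlist(lapply(seq_len(n_blocks), function(b) {
      sample(rep(c("flavour", "water"), config$block_size / 2))
    }))
    t <- 300  # consumption starts after 5-min acclimation
    cue_t <- reward_t <- numeric(config$n_rewards)
    for (i in seq_len(config$n_rewards)) {
      cue_t[i] <- t
      latency <- stats::runif(1, 0.5, 3)
      reward_t[i] <- t + latency
      iti <- sample(10:20, 1)
      t <- reward_t[i] + iti
    }
    cons_end <- reward_t[config$n_rewards] + 1
    delay_end <- cons_end + 30 * 60
    epochs <- list(acclimation = epoch("acclimation", 0, 300),
                   consumption = epoch("consumption", 300, cons_end),
                   delay = epoch("delay", cons_end, delay_end))
    bouts <- data.frame(onset = numeric(0), offset = numeric(0))
    injection <- NA_real_
    if (config$malaise == "stim") {
      stim_end <- delay_end + 45 * 60
      epochs$stim <- epoch("stim", delay_end, stim_end)
      on <- numeric(0); tt <- delay_end
      while (tt + 3 <= stim_end) {
        on <- c(on, tt)
        tt <- tt + 3 + .sample_bout_gap()
      }
      bouts <- data.frame(onset = on, offset = on + 3)
    } else {
      epochs$malaise <- epoch("malaise", delay_end, delay_end + 45 * 60)
      injection <- delay_end
    }
    event_log(
      cues = data.frame(time = cue_t, port = ports, stringsAsFactors = FALSE),
      rewards = data.frame(time = reward_t, port = ports,
                           stringsAsFactors = FALSE),
      entries = data.frame(time = reward_t, port = ports,
                           stringsAsFactors = FALSE),
      bouts = bouts, injection_time = injection, epochs = epochs)
  })
}

# unit-peak alpha kernel: a(t) = (t/tau) exp(1 - t/tau), t > 0
.alpha_kernel <- function(t, tau) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- (t[pos] / tau) * exp(1 - t[pos] / tau)
  out
}

# summed unit-peak kernel over a set of event times, evaluated at `at`
# (kernel support truncated at 10 tau)
.kernel_sum <- function(at, event_times, tau) {
  out <- numeric(length(at))
  if (length(event_times) == 0L) return(out)
  horizon <- 10 * tau
  idx_hi <- findInterval(at, event_times)
  # up to 3 preceding events can contribute within the horizon given >= 10-s ITIs
  for (back in 0:2) {
    j <- idx_hi - back
    ok <- j >= 1
    if (!any(ok)) break
    dt <- at[ok] - event_times[j[ok]]
    use <- dt > 0 & dt <= horizon
    if (any(use)) {
      val <- numeric(sum(ok)); val[use] <- .alpha_kernel(dt[use], tau)
      out[ok] <- out[ok] + val
    }
  }
  out
}

# indicator of lying inside any [onset, offset) bout
.in_bout <- function(at, bouts) {
  if (nrow(bouts) == 0L) return(numeric(length(at)))
  j <- findInterval(at, bouts$onset)
  inb <- j >= 1 & at < bouts$offset[pmax(j, 1)]
  as.numeric(inb)
}

#' Draw per-neuron ground-truth parameters
#' @keywords internal
.draw_ground_truth <- function(config, seed) {
  with_substream(seed, "ground_truth", {
    n <- config$n_neurons
    n_f <- round(config$frac_flavour * n)
    n_w <- round(config$frac_water * n)
    labels <- sample(c(rep("flavour", n_f), rep("water", n_w),
                       rep("nonselective", n - n_f - n_w)))
    baseline <- stats::rlnorm(n, config$baseline_log_mean,
                              config$baseline_log_sd)
    react <- numeric(n)
    react[labels == "flavour"] <-
      pmax(0, stats::rnorm(sum(labels == "flavour"),
                           config$react_gain_mean, config$react_gain_sd))
    gain <- numeric(n)
    gain[labels == "flavour"] <- config$reward_gain
    gain[labels == "water"] <- config$reward_gain
    data.frame(unit_id = sprintf("u%03d", seq_len(n)), label = labels,
               baseline = baseline, reward_gain = gain, react_gain = react,
               stringsAsFactors = FALSE)
  })
}

#' Simulate population spiking for a session
#'
#' Inhomogeneous Poisson spike trains by thinning. Each neuron's rate is
#' `baseline * suppression(t) * (1 + reward_gain * K_class(t) +
#' react_gain * bout(t))`, where `K_class` is a sum of unit-peak alpha
#' kernels over that class's preferred-reward deliveries, `bout(t)` is the
#' stimulation-bout indicator (flavour-preferring neurons only), and
#' `suppression(t)` drops every neuron's baseline by `delay_suppression`
#' from the end of consumption onward.
#'
#' @param config a [sim_config()].
#' @param events an [event_log()] from [simulate_task_events()].
#' @param seed master seed; spikes use the `"spikes"` substream.
#' @param truth optional pre-drawn ground truth (from a multiday parent);
#'   drawn from the `"ground_truth"` substream when `NULL`.
#' @param t_range optional `[start, end)` restriction of simulated time
#'   (e.g. consumption only), used to keep small studies fast.
#' @return list with `spikes` (named list of sorted spike times) and
#'   `truth` (data.frame: unit_id, label, baseline, reward_gain, react_gain).
#' @export
simulate_population <- function(config = sim_config(), events,
                                seed = config$seed, truth = NULL,
                                t_range = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(events, "event_log"))
  if (is.null(truth)) truth <- .draw_ground_truth(config, seed)
  eps <- events$epochs
  if (is.null(t_range)) {
    ends <- vapply(eps, function(e) e$end, numeric(1))
    t_range <- c(0, max(ends))
  }
  supp_from <- eps$consumption$end
  flav_rew <- events$rewards$time[events$rewards$port == "flavour"]
  wat_rew <- events$rewards$time[events$rewards$port == "water"]
  with_substream(seed, "spikes", {
    n <- nrow(truth)
    # margin 1.15 covers worst-case alpha-kernel overlap at >= 10-s ITIs
    ceilings <- truth$baseline *
      (1 + truth$reward_gain * 1.15 + truth$react_gain)
    if (any(ceilings > config$rate_max)) {
      stop(sprintf("instantaneous rate ceiling %.1f sp/s exceeds rate_max",
                   max(ceilings)))
    }
    dur <- t_range[2] - t_range[1]
    n_cand <- stats::rpois(n, ceilings * dur)
    neuron <- rep(seq_len(n), n_cand)
    tt <- t_range[1] + stats::runif(sum(n_cand)) * dur
    lab <- truth$label[neuron]
    mod <- rep(1, length(tt))
    horizon <- 10 * config$kernel_tau
    # reward kernels are non-zero only near that class's own reward times
    for (cls in c("flavour", "water")) {
      rew <- if (cls == "flavour") flav_rew else wat_rew
      if (length(rew) == 0L) next
      sel <- which(lab == cls & tt > rew[1] & tt < rew[length(rew)] + horizon)
      if (length(sel)) {
        mod[sel] <- mod[sel] + truth$reward_gain[neuron[sel]] *
          .kernel_sum(tt[sel], rew, config$kernel_tau)
      }
    }
    if (nrow(events$bouts) > 0L) {
      selb <- which(lab == "flavour" & tt >= events$bouts$onset[1] &
                      tt < events$bouts$offset[nrow(events$bouts)])
      if (length(selb)) {
        mod[selb] <- mod[selb] + truth$react_gain[neuron[selb]] *
          .in_bout(tt[selb], events$bouts)
      }
    }
    supp <- 1 + (tt >= supp_from) * (config$delay_suppression - 1)
    rate <- truth$baseline[neuron] * supp * mod
    keep <- stats::runif(length(tt)) < rate / ceilings[neuron]
    spk <- split(tt[keep], factor(neuron[keep], levels = seq_len(n)))
    spk <- lapply(spk, sort)
    names(spk) <- truth$unit_id
    list(spikes = spk, truth = truth)
  })
}

#' Simulate a complete single-day session
#'
#' Convenience wrapper: events plus population spiking under one master seed.
#' @inheritParams simulate_population
#' @return list with `events`, `spikes`, `truth`, and the `config`.
#' @export
simulate_session <- function(config = sim_config(), seed = config$seed,
                             t_range = NULL) {
  events <- simulate_task_events(config, seed)
  pop <- simulate_population(config, events, seed, t_range = t_range)
  list(events = events, spikes = pop$spikes, truth = pop$truth,
       config = config, seed = seed)
}

#' Simulate a paired conditioning/retrieval (or novel/familiar) experiment
#'
#' Day 1 is a full conditioning session. On day 2 each flavour-preferring
#' neuron's reward gain is `gain1 + beta * react_gain + N(0, noise_sd)`
#' (plasticity proportional to its stimulation-bout response); in the
#' `familiarization` variant day-2 flavour gains are instead
#' `familiarization_decay * gain1` and water responses are unchanged. Day 2
#' is a consumption + delay session (no stimulation).
#'
#' @param config a [sim_config()]; `plasticity_beta`, `plasticity_noise_sd`
#'   and `familiarization_decay` set the cross-day rule.
#' @param seed master seed.
#' @param variant `"conditioning"` (reactivation-proportional plasticity) or
#'   `"familiarization"` (uniform decay of flavour gains).
#' @param spikes if `FALSE`, return only events and ground truth (fast path
#'   for parameter-recovery studies that work on true quantities).
#' @return list with `day1`, `day2` (each `events` + `spikes`), and `truth`
#'   including `gain_day1`, `gain_day2`, `react_gain`, `beta`, `decay`.
#' @export
simulate_multiday <- function(config = sim_config(), seed = config$seed,
                              variant = c("conditioning", "familiarization"),
                              spikes = TRUE) {
  variant <- match.arg(variant)
  truth <- .draw_ground_truth(config, seed)
  flav <- truth$label == "flavour"
  truth$gain_day1 <- truth$reward_gain
  noise <- with_substream(seed, "plasticity",
                          stats::rnorm(nrow(truth), 0, config$plasticity_noise_sd))
  truth$gain_day2 <- truth$gain_day1
  if (variant == "conditioning") {
    truth$gain_day2[flav] <- truth$gain_day1[flav] +
      config$plasticity_beta * truth$react_gain[flav] + noise[flav]
  } else {
    truth$gain_day2[flav] <- config$familiarization_decay * truth$gain_day1[flav]
  }
  truth$gain_day2 <- pmax(truth$gain_day2, 0)
  truth$beta <- config$plasticity_beta
  truth$decay <- config$familiarization_decay
  truth$variant <- variant
  out <- list(truth = truth, config = config, seed = seed)
  if (spikes) {
    ev1 <- simulate_task_events(config, seed)
    out$day1 <- list(events = ev1,
                     spikes = simulate_population(config, ev1, seed,
                                                  truth = truth)$spikes)
    cfg2 <- config
    cfg2$malaise <- "licl"  # placeholder; day-2 run stops before malaise
    ev2 <- simulate_task_events(cfg2, seed + 101)
    truth2 <- truth
    truth2$reward_gain <- truth$gain_day2
    out$day2 <- list(events = ev2,
                     spikes = simulate_population(config, ev2, seed + 101,
                                                  truth = truth2,
                                                  t_range = c(0, ev2$epochs$delay$end))$spikes)
  }
  out
}

#' Simulate fibre-photometry traces
#'
#' Two channels sharing a slow exponential bleach, with activity transients
#' on the 488-nm channel only and Gaussian sensor noise on both. In
#' `"gcamp"` mode the bleach is additive on both channels (the 405-nm
#' isosbestic channel tracks it); in `"akar2"` mode the bleach is a common
#' multiplicative factor and transients scale the 488/405 ratio, matching a
#' ratiometric sensor.
#'
#' @param config a [sim_config()] (only its seed default is used).
#' @param seed master seed; the `"photometry"` substream is used.
#' @param mode `"gcamp"` or `"akar2"`.
#' @param duration recording length in seconds.
#' @param fs sampling rate in Hz (must be >= 100).
#' @param event_times transient onset times; default 8 events spaced through
#'   the recording.
#' @param event_ports port labels for `event_times` (recycled), used by the
#'   reward-locked PKA analysis.
#' @param transient_amp transient amplitude (additive for gcamp, fractional
#'   ratio change for akar2), recycled over events so ports can differ;
#'   0 simulates a null recording.
#' @param transient_tau transient decay timescale in seconds.
#' @param bleach_tau bleach timescale in seconds.
#' @param noise_sd sensor noise sd.
#' @return list with `time`, `iso405`, `act488`, `fs`, `event_times`,
#'   `event_ports`.
#' @export
simulate_photometry <- function(config = sim_config(), seed = config$seed,
                                mode = c("gcamp", "akar2"),
                                duration = 600, fs = 200,
                                event_times = NULL, event_ports = "flavour",
                                transient_amp = 1.0, transient_tau = 3,
                                bleach_tau = 900, noise_sd = 0.02) {
  mode <- match.arg(mode)
  if (fs < 100) .invalid_input("fs must be >= 100 Hz")
  with_substream(seed, "photometry", {
    time <- seq(0, duration - 1 / fs, by = 1 / fs)
    if (is.null(event_times)) {
      event_times <- seq(duration * 0.1, duration * 0.9, length.out = 8)
    }
    event_ports <- rep_len(event_ports, length(event_times))
    amp <- rep_len(transient_amp, length(event_times))
    trans <- numeric(length(time))
    for (i in seq_along(event_times)) {
      dt <- time - event_times[i]
      pos <- dt > 0 & dt < 10 * transient_tau
      trans[pos] <- trans[pos] +
        amp[i] * (dt[pos] / transient_tau) * exp(1 - dt[pos] / transient_tau)
    }
    bleach <- exp(-time / bleach_tau)
    n1 <- stats::rnorm(length(time), 0, noise_sd)
    n2 <- stats::rnorm(length(time), 0, noise_sd)
    if (mode == "gcamp") {
      iso405 <- 2 * bleach + 1 + n1
      act488 <- 3 * bleach + 1.5 + trans + n2
    } else {
      iso405 <- (2 + n1 * 0.1) * bleach + 0.5
      act488 <- iso405 * (1.5 + trans) + n2 * 0.05
    }
    list(time = time, iso405 = iso405, act488 = act488, fs = fs,
         event_times = event_times, event_ports = event_ports)
  })
}
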