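test_that("task events have the two-reward structure with balanced blocks", {
  for (s in 1:10) {
    ev <- simulate_task_events(sim_config(), seed = s)
    expect_s3_class(validate_event_log(ev), "event_log")
    expect_equal(nrow(ev$rewards), 60L)
    blocks <- split(ev$rewards$port, rep(1:6, each = 10))
    for (b in blocks) expect_equal(sum(b == "flavour"), 5L)
    itis <- diff(ev$cues$time)
    expect_true(all(itis >= 10 & itis <= 23.1))  # 10-20 s ITI + <=3 s latency
    expect_equal(ev$epochs$delay$end - ev$epochs$delay$start, 1800)
    expect_equal(ev$epochs$stim$end - ev$epochs$stim$start, 2700)
    expect_true(all(abs(ev$bouts$offset - ev$bouts$onset - 3) < 1e-9))
  }
  # LiCl variant has an injection and no bouts
  ev <- simulate_task_events(sim_config(malaise = "licl"), seed = 1)
  expect_true(is.finite(ev$injection_time))
  expect_equal(nrow(ev$bouts), 0L)
  expect_equal(ev$injection_time, ev$epochs$malaise$start)
})

test_that("bout gaps follow the truncated shifted exponential", {
  set.seed(7)
  gaps <- replicate(10000, cfareact:::.sample_bout_gap())
  expect_true(all(gaps >= 1 & gaps <= 7.8))
  # mean of the truncated distribution by numeric integration:
  # density of 1 + Exp(rate 1/2) restricted to [1, 7.8], renormalized
  dens <- function(g) 0.5 * exp(-(g - 1) / 2)
  z <- integrate(dens, 1, 7.8)$value
  mu <- integrate(function(g) g * dens(g), 1, 7.8)$value / z
  v <- integrate(function(g) (g - mu)^2 * dens(g), 1, 7.8)$value / z
  expect_lt(abs(mean(gaps) - mu), 3 * sqrt(v / 10000))
  expect_lt(mu, 3)  # truncation pulls the realized mean below 3 s
})

test_that("same seed gives byte-identical simulated sessions", {
  cfg <- small_config()
  a <- simulate_session(cfg, seed = 9)
  b <- simulate_session(cfg, seed = 9)
  td <- withr::local_tempdir()
  f1 <- file.path(td, "a.csv"); f2 <- file.path(td, "b.csv")
  write_spikes_csv(a$spikes, f1); write_spikes_csv(b$spikes, f2)
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_identical(a$events, b$events)
  expect_identical(a$truth, b$truth)
  c <- simulate_session(cfg, seed = 10)
  expect_false(identical(a$spikes, c$spikes))
})

test_that("zero-gain population spiking is Poisson at the configured rate", {
  cfg <- sim_config(n_neurons = 10, frac_flavour = 0, frac_water = 0,
                    baseline_log_mean = log(4), baseline_log_sd = 0,
                    reward_gain = 0, react_gain_mean = 0, react_gain_sd = 0)
  ev <- simulate_task_events(cfg, 1)
  cons <- ev$epochs$consumption
  pop <- simulate_population(cfg, ev, 1, t_range = c(cons$start, cons$end))
  # counts in 200 disjoint 1-s windows, pooled over 10 neurons ~ Pois(4)
  starts <- cons$start + 0:19
  counts <- unlist(lapply(pop$spikes, function(st) {
    findInterval(starts + 1 - 1e-12, st) - findInterval(starts - 1e-12, st)
  }))
  expect_length(counts, 200L)
  lambda <- 4
  kmax <- 12
  probs <- c(dpois(0:(kmax - 1), lambda), 1 - ppois(kmax - 1, lambda))
  obs <- tabulate(pmin(counts, kmax) + 1, nbins = kmax + 1)
  keep <- probs * length(counts) >= 5
  chi2 <- sum((obs[keep] - length(counts) * probs[keep])^2 /
                (length(counts) * probs[keep]))
  expect_lt(chi2, qchisq(0.99, sum(keep) - 1))
})

test_that("thinning recovers the target inhomogeneous rate within 5%", {
  # 500 identical flavour neurons at 20 sp/s with a gain-1 alpha response;
  # class-mean counts per 1-s bin are compared to the analytic rate
  cfg <- sim_config(n_neurons = 500, frac_flavour = 1, frac_water = 0,
                    baseline_log_mean = log(20), baseline_log_sd = 0,
                    reward_gain = 1, react_gain_mean = 0, react_gain_sd = 0)
  ev <- simulate_task_events(cfg, 2)
  cons <- ev$epochs$consumption
  t0 <- cons$start; t1 <- min(cons$start + 120, cons$end)
  pop <- simulate_population(cfg, ev, 2, t_range = c(t0, t1))
  starts <- seq(t0, t1 - 1, by = 1)
  counts <- sapply(pop$spikes, function(st) {
    findInterval(starts + 1 - 1e-12, st) - findInterval(starts - 1e-12, st)
  })
  emp_rate <- rowMeans(counts)
  # independent analytic target: unit-peak alpha kernel integrated per bin
  flav_t <- ev$rewards$time[ev$rewards$port == "flavour"]
  target <- vapply(starts, function(s) {
    f <- function(t) {
      k <- 0
      for (te in flav_t) {
        dt <- t - te
        k <- k + ifelse(dt > 0, (dt / 2) * exp(1 - dt / 2), 0)
      }
      20 * (1 + k)
    }
    integrate(f, s, s + 1, rel.tol = 1e-8)$value
  }, numeric(1))
  expect_true(all(abs(emp_rate - target) / target < 0.05))
})

test_that("flavour-class neurons respond to flavour but not water rewards", {
  s <- small_session()
  stats <- consumption_stats(s$spikes, s$events)
  resp <- trial_responses_from_spikes(s$spikes, s$events, stats)
  flav <- s$truth$label == "flavour"
  nonsel <- s$truth$label == "nonselective"
  # paired across > 500 neuron-trials of the flavour class
  expect_gt(sum(flav) * ncol(resp$flavour), 500)
  expect_gt(mean(resp$flavour[flav, ]), mean(resp$water[flav, ]))
  expect_gt(mean(resp$flavour[flav, ]) - mean(resp$water[flav, ]), 0.05)
  expect_lt(abs(mean(resp$flavour[nonsel, ]) - mean(resp$water[nonsel, ])),
            0.02)
})

test_that("multiday plasticity rule links day-2 gains to reactivation gains", {
  # null plasticity: day-2 gains equal day-1 gains exactly
  cfg0 <- small_config(plasticity_beta = 0, plasticity_noise_sd = 0)
  md0 <- simulate_multiday(cfg0, seed = 1, spikes = FALSE)
  expect_equal(md0$truth$gain_day2, md0$truth$gain_day1)
  # beta = 1, no noise: regression of true gain change on true bout gain
  # has slope exactly 1
  cfg1 <- small_config(plasticity_beta = 1, plasticity_noise_sd = 0)
  md1 <- simulate_multiday(cfg1, seed = 1, spikes = FALSE)
  fl <- md1$truth$label == "flavour"
  fit <- lm((gain_day2 - gain_day1) ~ react_gain, data = md1$truth[fl, ])
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 1e-10)
  # familiarization with decay 0.5 halves flavour gains, leaves water alone
  cfgf <- small_config(familiarization_decay = 0.5)
  mdf <- simulate_multiday(cfgf, seed = 1, variant = "familiarization",
                           spikes = FALSE)
  expect_equal(mdf$truth$gain_day2[fl], 0.5 * mdf$truth$gain_day1[fl])
  wat <- mdf$truth$label == "water"
  expect_equal(mdf$truth$gain_day2[wat], mdf$truth$gain_day1[wat])
})

test_that("full decay makes familiar-day flavour responses indistinguishable from water", {
  hits <- 0
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(n_neurons = 40, familiarization_decay = 0)
    md <- simulate_multiday(cfg, seed = s, variant = "familiarization",
                            spikes = FALSE)
    truth2 <- md$truth
    truth2$reward_gain <- truth2$gain_day2
    ev2 <- simulate_task_events(cfg, s + 500)
    cons <- ev2$epochs$consumption
    pop2 <- simulate_population(cfg, ev2, s + 500, truth = truth2,
                                t_range = c(cons$start, cons$end))
    stats <- consumption_stats(pop2$spikes, ev2)
    resp <- suppressWarnings(
      trial_responses_from_spikes(pop2$spikes, ev2, stats,
                                  t_max = cons$end))
    fl <- truth2$label == "flavour"
    p <- rank_sum_test(rowMeans(resp$flavour[fl, ]),
                       rowMeans(resp$water[fl, ]))$p
    if (p > 0.05) hits <- hits + 1
  }
  expect_gte(hits, round(0.85 * n_seeds))
})

test_that("multiday with spikes returns paired sessions with matched units", {
  cfg <- sim_config(n_neurons = 30, plasticity_beta = 0.5,
                    plasticity_noise_sd = 0.1)
  md <- simulate_multiday(cfg, seed = 3)
  expect_named(md$day1, c("events", "spikes"))
  expect_identical(names(md$day1$spikes), names(md$day2$spikes))
  expect_equal(nrow(md$day2$events$rewards), 60L)
})

test_that("rate ceiling violations are an error", {
  cfg <- sim_config(n_neurons = 5, baseline_log_mean = log(300),
                    baseline_log_sd = 0, rate_max = 400)
  ev <- simulate_task_events(cfg, 1)
  expect_error(simulate_population(cfg, ev, 1), "rate_max")
})
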