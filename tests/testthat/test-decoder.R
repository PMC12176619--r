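test_that("training set has one vector per event with exact hand-computed features", {
  s <- small_session()
  tr <- build_training_set(s$spikes, s$events)
  expect_equal(nrow(tr$features), 120L)  # 30 + 30 rewards, 60 cue baselines
  expect_equal(as.integer(table(tr$labels)), c(30L, 30L, 60L))
  # hand-built 2-neuron fixture
  ev <- tiny_events(n_per_port = 1, bouts = FALSE)
  t_f <- ev$rewards$time[ev$rewards$port == "flavour"]
  t_w <- ev$rewards$time[ev$rewards$port == "water"]
  cues <- ev$cues$time
  # neuron 1 fires 3 spikes after the flavour reward, 1 before each cue;
  # neuron 2 fires regularly at 2 Hz through consumption
  spk1 <- sort(c(t_f + c(0.1, 0.3, 0.7), cues - 0.5))
  cons <- ev$epochs$consumption
  spk2 <- seq(cons$start + 0.25, cons$end, by = 0.5)
  expect_warning(tr2 <- build_training_set(list(a = spk1, b = spk2), ev),
                 "zero")
  # neuron 1: pre-cue mean = 1; tiled-window counts over the consumption
  # epoch give its sd; feature for the flavour event = (3 - 1) / sd
  tiles <- seq(cons$start, cons$end - 1, by = 1)
  cnt1 <- findInterval(tiles + 1 - 1e-12, spk1) - findInterval(tiles - 1e-12, spk1)
  expect_equal(tr2$features[1, 1], (3 - 1) / sd(cnt1))
  # neuron 2 is perfectly regular: 2 per window everywhere -> zero sd,
  # features zeroed with a warning
  expect_true(tr2$train_stats$zero_sd[2])
  expect_true(all(tr2$features[, 2] == 0))
})

test_that("constant-rate populations give null features", {
  ev <- tiny_events(n_per_port = 3, bouts = FALSE)
  set.seed(41)
  spikes <- lapply(1:6, function(i) sort(runif(4000, 0, ev$epochs$delay$end)))
  names(spikes) <- paste0("u", 1:6)
  tr <- build_training_set(spikes, ev)
  cm <- tapply(rowMeans(tr$features), tr$labels, mean)
  expect_true(all(abs(cm) < 0.5))
  expect_lt(abs(mean(tr$features)), 0.2)
})

test_that("decoder fit handles the separable and penalty-dominated limits", {
  set.seed(42)
  X <- rbind(matrix(rnorm(60, 0, 0.2), 20, 3),
             sweep(matrix(rnorm(60, 0, 0.2), 20, 3), 2, c(3, 0, 0), "+"),
             sweep(matrix(rnorm(60, 0, 0.2), 20, 3), 2, c(0, 3, 0), "+"))
  y <- factor(rep(c("a", "b", "c"), each = 20))
  # with a vanishing penalty the separable problem has no finite optimum;
  # the capped fit still classifies the training set perfectly
  fit <- suppressWarnings(fit_multinomial_l1(X, y, lambda = 1e-6,
                                             max_iter = 5000))
  expect_equal(mean(predict(fit, X, type = "class") == y), 1)
  # huge penalty: all weights zero, posteriors equal class frequencies
  y2 <- factor(rep(c("a", "b", "c"), times = c(10, 20, 30)))
  X2 <- matrix(rnorm(60 * 4), 60, 4)
  fit2 <- fit_multinomial_l1(X2, y2, lambda = 1e6)
  expect_true(all(fit2$weights == 0))
  P <- predict(fit2, X2)
  expect_equal(unname(P[1, ]), c(10, 20, 30) / 60, tolerance = 1e-4)
  # posteriors always sum to 1
  expect_true(all(abs(rowSums(P) - 1) < 1e-12))
  expect_error(fit_multinomial_l1(X2, factor(rep("a", 60)), 1), "2 classes")
})

test_that("analytic NLL gradient matches central differences to 1e-6", {
  set.seed(43)
  for (rep_i in 1:3) {
    n <- 25; p <- 6; k <- 3
    X <- matrix(rnorm(n * p), n, p)
    y <- factor(sample(letters[1:k], n, replace = TRUE))
    W <- matrix(rnorm(k * p, 0, 0.5), k, p)
    b <- rnorm(k, 0, 0.5)
    g <- multinomial_nll_grad(W, b, X, y)
    h <- 1e-5
    num_W <- W
    for (i in seq_len(k)) for (j in seq_len(p)) {
      Wp <- W; Wm <- W
      Wp[i, j] <- W[i, j] + h; Wm[i, j] <- W[i, j] - h
      num_W[i, j] <- (multinomial_nll_grad(Wp, b, X, y)$nll -
                        multinomial_nll_grad(Wm, b, X, y)$nll) / (2 * h)
    }
    num_b <- vapply(seq_len(k), function(i) {
      bp <- b; bm <- b
      bp[i] <- b[i] + h; bm[i] <- b[i] - h
      (multinomial_nll_grad(W, bp, X, y)$nll -
         multinomial_nll_grad(W, bm, X, y)$nll) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(g$grad_W - num_W)), 1e-6)
    expect_lt(max(abs(g$grad_b - num_b)), 1e-6)
  }
})

test_that("objective is monotone, lambda shrinks weights, and glmnet agrees", {
  set.seed(44)
  n <- 90; p <- 12
  X <- matrix(rnorm(n * p), n, p)
  beta <- matrix(0, 3, p); beta[1, 1:3] <- 2; beta[2, 4:6] <- -2
  pr <- exp(X %*% t(beta)); pr <- pr / rowSums(pr)
  y <- factor(apply(pr, 1, function(q) sample(c("a", "b", "c"), 1, prob = q)),
              levels = c("a", "b", "c"))
  grid <- 10^seq(-4, 4, length.out = 9)
  tot <- vapply(grid, function(lam) {
    fit <- fit_multinomial_l1(X, y, lambda = lam)
    expect_true(all(diff(fit$objective) <= 1e-9))
    sum(abs(fit$weights))
  }, numeric(1))
  expect_true(all(diff(tot) <= 1e-6))
  skip_if_not_installed("glmnet")
  # glmnet minimizes (1/n) NLL + (lambda/n) |W|; posteriors must agree
  fit <- fit_multinomial_l1(X, y, lambda = 2)
  g <- glmnet::glmnet(X, y, family = "multinomial", lambda = 2 / n,
                      standardize = FALSE, thresh = 1e-12)
  Pg <- predict(g, X, type = "response")[, , 1]
  Pm <- predict(fit, X)
  expect_lt(max(abs(Pm[, colnames(Pg)] - Pg)), 1e-4)
})

test_that("cross-validation uses the standard grid and finds chance on noise", {
  grid <- 10^seq(-4, 4, length.out = 9)
  expect_equal(grid, c(1e-4, 1e-3, 1e-2, 1e-1, 1, 10, 100, 1000, 10000))
  set.seed(45)
  X <- matrix(rnorm(120 * 8), 120, 8)
  y <- factor(rep(c("a", "b", "c"), 40))
  cv <- cross_validate_lambda(X, y, folds = 5, lambda_grid = c(0.1, 1, 10),
                              seed = 7)
  expect_equal(names(cv), c("lambda", "heldout_ll", "misclass"))
  # chance misclassification for 3 balanced classes is 2/3
  expect_lt(abs(min(cv$misclass) - 2 / 3), 0.15)
  expect_error(cross_validate_lambda(X, factor(rep("a", 120)), seed = 1),
               "single-class")
  expect_warning(
    cross_validate_lambda(X[1:12, ], y[1:12], folds = 10,
                          lambda_grid = 1, seed = 1),
    "reducing folds")
})

test_that("held-out decoding of the default session is nearly perfect at lambda = 1", {
  s <- simulate_session(sim_config(), seed = 42)
  tr <- build_training_set(s$spikes, s$events, min_neurons = 75)
  cv <- cross_validate_lambda(tr$features, tr$labels, folds = 5,
                              lambda_grid = 1, seed = 11)
  expect_lte(cv$misclass, 0.05)
  # population gate refuses small ensembles
  expect_error(build_training_set(s$spikes[1:50], s$events, min_neurons = 75),
               "gate")
})

test_that("sliding posteriors cover the span and rise during bouts", {
  s <- small_session()
  tr <- build_training_set(s$spikes, s$events)
  model <- fit_multinomial_l1(tr$features, tr$labels, lambda = 1)
  dstats <- delay_window_stats(s$spikes, s$events)
  stim <- s$events$epochs$stim
  ser <- sliding_posteriors(model, s$spikes, dstats,
                            c(stim$start, stim$end))
  span <- stim$end - stim$start
  expect_equal(length(ser$times), floor((span - 1) / 0.15) + 1)
  expect_true(all(abs(rowSums(ser$posteriors) - 1) < 1e-12))
  inb <- vapply(ser$times, function(t) {
    any(t >= s$events$bouts$onset & t < s$events$bouts$offset)
  }, logical(1))
  expect_gt(mean(ser$posteriors[inb, "flavour"]),
            mean(ser$posteriors[!inb, "flavour"]))
  expect_error(sliding_posteriors(model, s$spikes, dstats,
                                  c(stim$start, stim$start + 0.5)),
               "window larger")
})

test_that("peak detection matches its definition and a brute-force scan", {
  expect_equal(detect_reactivations(c(0.1, 0.6, 0.4, 0.7, 0.9, 0.2))$indices,
               c(2L, 5L))
  expect_equal(detect_reactivations(c(0.4, 0.5, 0.3))$indices, integer(0))
  # plateau contributes its first index; eligible endpoints count
  expect_equal(detect_reactivations(c(0.4, 0.7, 0.7, 0.3))$indices, 2L)
  expect_equal(detect_reactivations(c(0.9, 0.2, 0.6))$indices, c(1L, 3L))
  expect_equal(detect_reactivations(rep(0.8, 5))$indices, 1L)
  # brute-force reference on random series with plateaus
  set.seed(46)
  for (rep_i in 1:20) {
    v <- round(runif(200), sample(c(1, 2), 1))  # rounding creates plateaus
    expect_equal(detect_reactivations(v)$indices, brute_peaks(v))
  }
})

test_that("reactivation rates count events per minute in sliding windows", {
  r <- reactivation_rate(c(10, 20, 30), span = c(0, 60))
  expect_equal(r$rate, 3)
  r0 <- reactivation_rate(numeric(0), span = c(0, 300))
  expect_true(all(r0$rate == 0))
  expect_equal(r0$t_center, seq(30, 270, by = 30))
  # Poisson events at rate r: time-averaged rate is close to r
  set.seed(47)
  rates <- vapply(1:50, function(i) {
    ev <- cumsum(rexp(2000, rate = 2 / 60))  # 2 events/min
    ev <- ev[ev < 3600]
    mean(reactivation_rate(ev, span = c(0, 3600))$rate)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 2), 3 * sd(rates) / sqrt(50))
})
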