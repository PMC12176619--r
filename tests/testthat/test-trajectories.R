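# build a peth_matrix directly from a value matrix for fixture tests
mk_peth <- function(values, window = c(-5, 10), bw = 0.01,
                    ids = paste0("u", seq_len(nrow(values)))) {
  cfareact:::.peth_matrix(values, window, bw, baseline = "none",
                          normalization = list(epoch_label = "consumption",
                                               day = "day1"),
                          smoothed = TRUE, n_events = 1L, n_dropped = 0L,
                          unit_ids = ids)
}

test_that("PCA input is baseline-subtracted, peak-normalized, 1000 bins wide", {
  lags <- seq(-5 + 0.005, 10 - 0.005, by = 0.01)
  # hand fixture: neuron 1 responds 2 z to flavour, neuron 2 responds -1 to
  # water; both have baseline offset 0.5
  f <- rbind(0.5 + 2 * (lags > 0 & lags <= 5), rep(0.5, length(lags)))
  w <- rbind(rep(0.5, length(lags)), 0.5 - 1 * (lags > 0 & lags <= 5))
  inp <- build_pca_input(mk_peth(f), mk_peth(w), c(TRUE, TRUE))
  expect_equal(ncol(inp$matrix), 1000L)
  expect_equal(inp$baseline, c(0.5, 0.5))
  expect_equal(inp$peak, c(2, 1))
  # flavour half of neuron 1 is 2/2 = 1; water half of neuron 2 is -1/1
  expect_true(all(inp$matrix[1, 1:500] == 1))
  expect_true(all(inp$matrix[1, 501:1000] == 0))
  expect_true(all(inp$matrix[2, 501:1000] == -1))
  # rows attain |max| = 1 after normalization
  expect_equal(unname(apply(abs(inp$matrix), 1, max)), c(1, 1))
  # zero-peak neurons are dropped with a warning
  f2 <- rbind(f, 0.5); w2 <- rbind(w, 0.5)
  expect_warning(inp2 <- build_pca_input(mk_peth(f2), mk_peth(w2),
                                         rep(TRUE, 3)), "dropped")
  expect_equal(nrow(inp2$matrix), 2L)
})

test_that("fit_pca matches an SVD oracle and recovers planted structure", {
  set.seed(51)
  # rank-1: a single population pattern explains everything
  u <- rnorm(20); v <- rnorm(300)
  M <- outer(u, v)
  pc <- fit_pca(M)
  expect_lt(abs(pc$var_explained[1] - 1), 1e-10)
  expect_equal(sum(pc$all_var_explained), 1, tolerance = 1e-10)
  # two orthogonal planted patterns of equal power
  u1 <- rnorm(40); u1 <- u1 / sqrt(sum(u1^2))
  u2 <- rnorm(40); u2 <- u2 - sum(u2 * u1) * u1; u2 <- u2 / sqrt(sum(u2^2))
  # distinct pattern powers so the eigenvalues are non-degenerate and the
  # principal directions are identifiable
  t1 <- sin(seq(0, 4 * pi, length.out = 600))
  t2 <- 0.6 * cos(seq(0, 6 * pi, length.out = 600))
  M2 <- outer(u1, t1) + outer(u2, t2) + matrix(rnorm(40 * 600, 0, 0.02), 40)
  pc2 <- fit_pca(M2, n_pcs = 5)
  expect_gt(sum(pc2$var_explained[1:2]), 0.95)
  cors <- abs(cor(pc2$loadings[, 1:2], cbind(u1, u2)))
  expect_true(all(apply(cors, 2, max) > 0.95))
  # SVD oracle: loadings and variance fractions from first principles
  Mc <- sweep(M2, 2, colMeans(M2))
  sv <- svd(Mc)
  expect_equal(pc2$all_var_explained, sv$d^2 / sum(sv$d^2), tolerance = 1e-8)
  for (j in 1:2) {
    expect_lt(min(sum((pc2$loadings[, j] - sv$u[, j])^2),
                  sum((pc2$loadings[, j] + sv$u[, j])^2)), 1e-8)
  }
  # orthonormal loadings
  expect_equal(crossprod(pc2$loadings), diag(5), tolerance = 1e-10)
  expect_error(fit_pca(M2[1:2, ]), "3 neurons")
})

test_that("fit_pca is invariant to neuron permutation", {
  set.seed(52)
  M <- matrix(rnorm(30 * 100), 30)
  pc <- fit_pca(M, n_pcs = 3)
  perm <- sample(30)
  pc_p <- fit_pca(M[perm, ], n_pcs = 3)
  expect_equal(pc_p$loadings, pc$loadings[perm, ], tolerance = 1e-8)
  expect_equal(pc_p$var_explained, pc$var_explained, tolerance = 1e-10)
})

test_that("trajectory projection is linear and separates the reward types", {
  s <- small_session()
  stats <- consumption_stats(s$spikes, s$events)
  pf <- reward_peth(s$spikes, s$events, "flavour", stats, smooth_sd = 0.1)
  pw <- reward_peth(s$spikes, s$events, "water", stats, smooth_sd = 0.1)
  lab <- classify_session(s$spikes, s$events)
  sel <- !is.na(lab$label) & lab$label != "nonselective"
  inp <- build_pca_input(pf, pw, sel)
  pc <- fit_pca(inp, n_pcs = 2)
  tf <- project_trajectory(pf, pc)
  tw <- project_trajectory(pw, pc)
  # the two reward trajectories separate along the PCs after delivery
  d <- sqrt(rowSums((tf$values - tw$values)^2))
  post <- tf$lags > 0 & tf$lags <= 5
  pre <- tf$lags < 0
  expect_gt(max(d[post]), 5 * mean(d[pre]))
  # flavour-positive sign convention
  expect_gte(max(tf$values[post, 1]), 0)
  # linearity: traj(aX + bY) = a traj(X) + b traj(Y)
  mix <- pf
  mix$values <- 0.3 * pf$values + 0.7 * pw$values
  tmix <- project_trajectory(mix, pc, normalize = FALSE)
  tf0 <- project_trajectory(pf, pc, normalize = FALSE)
  tw0 <- project_trajectory(pw, pc, normalize = FALSE)
  expect_equal(tmix$values, 0.3 * tf0$values + 0.7 * tw0$values,
               tolerance = 1e-10)
  # all-zero PETH projects to the zero trajectory
  z <- pf; z$values[] <- 0
  expect_true(all(project_trajectory(z, pc, normalize = FALSE)$values == 0))
  expect_error(project_trajectory(mk_peth(matrix(0, 2, 1500)), pc), "missing")
})

test_that("stimulation trajectory mirrors the flavour trajectory when reactivation is planted", {
  s <- small_session()
  stats <- consumption_stats(s$spikes, s$events)
  pf <- reward_peth(s$spikes, s$events, "flavour", stats, smooth_sd = 0.1)
  pw <- reward_peth(s$spikes, s$events, "water", stats, smooth_sd = 0.1)
  lab <- classify_session(s$spikes, s$events)
  sel <- !is.na(lab$label) & lab$label != "nonselective"
  pc <- fit_pca(build_pca_input(pf, pw, sel), n_pcs = 2)
  ps <- stim_bout_peth(s$spikes, s$events, stats, smooth_sd = 0.1)
  ts <- project_stim_trajectory(ps, pc)
  tf <- project_trajectory(pf, pc)
  tw <- project_trajectory(pw, pc)
  cf <- trajectory_cosine(ts, tf, lags_a = ts$lags > 0,
                          lags_b = tf$lags > 0 & tf$lags <= 5)
  cw <- trajectory_cosine(ts, tw, lags_a = ts$lags > 0,
                          lags_b = tw$lags > 0 & tw$lags <= 5)
  expect_gt(cf, 0.8)
  expect_gt(cf, cw)
  # zero stim PETH gives the zero trajectory
  z <- ps; z$values[] <- 0
  expect_true(all(project_stim_trajectory(z, pc)$values == 0))
})

test_that("without planted reactivation the stimulation trajectory is small", {
  cfg <- sim_config(n_neurons = 250, react_gain_mean = 0, react_gain_sd = 0)
  s <- simulate_session(cfg, seed = 43)
  stats <- consumption_stats(s$spikes, s$events)
  pf <- reward_peth(s$spikes, s$events, "flavour", stats, smooth_sd = 0.1)
  pw <- reward_peth(s$spikes, s$events, "water", stats, smooth_sd = 0.1)
  lab <- classify_session(s$spikes, s$events)
  sel <- !is.na(lab$label) & lab$label != "nonselective"
  pc <- fit_pca(build_pca_input(pf, pw, sel), n_pcs = 2)
  ps <- stim_bout_peth(s$spikes, s$events, stats, smooth_sd = 0.1)
  ts <- project_stim_trajectory(ps, pc)
  tf <- project_trajectory(pf, pc)
  norm_stim <- sqrt(mean(rowSums(ts$values[ts$lags > 0, ]^2)))
  norm_flav <- sqrt(mean(rowSums(tf$values[tf$lags > 0 & tf$lags <= 5, ]^2)))
  expect_lt(norm_stim, 0.2 * norm_flav)
})

test_that("frozen day-1 loadings reproduce same-day projections on copied data", {
  s <- small_session()
  stats <- consumption_stats(s$spikes, s$events)
  pf <- reward_peth(s$spikes, s$events, "flavour", stats, smooth_sd = 0.1)
  pw <- reward_peth(s$spikes, s$events, "water", stats, smooth_sd = 0.1)
  lab <- classify_session(s$spikes, s$events)
  sel <- !is.na(lab$label) & lab$label != "nonselective"
  pc <- fit_pca(build_pca_input(pf, pw, sel), n_pcs = 2)
  t1 <- project_trajectory(pf, pc)
  # "day-2" PETH that is a copy of day 1, normalized with day-1 constants
  pf2 <- pf
  pf2$normalization$day <- "day1"
  t2 <- project_trajectory(pf2, pc)
  expect_equal(t2$values, t1$values, tolerance = 1e-12)
})
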