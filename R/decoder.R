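#' Build the decoder training set from consumption-period activity
#'
#' One feature vector per event, three classes: normalized spike counts in
#' the 1 s after each flavour delivery, the 1 s after each water delivery,
#' and the 1 s before each cue onset (baseline). Normalization is per
#' neuron: subtract the mean pre-cue 1-s count, divide by the sd of 1-s
#' counts over non-overlapping windows tiling the consumption period.
#' Neurons with zero sd contribute all-zero features (with a warning).
#'
#' @param spikes named list of sorted spike-time vectors.
#' @param events an [event_log()].
#' @param count_window counting window in seconds (1 s standard).
#' @param min_neurons population-size gate; populations at or below it are
#'   rejected (the recorded-data analyses required > 75 simultaneously
#'   recorded neurons; disable with `min_neurons = 0`).
#' @return list with `features` (events x neurons), `labels` (factor with
#'   levels flavour/water/baseline), and `train_stats` ([norm_stats()],
#'   1-s-window granularity: mean = pre-cue mean, sd = consumption sd).
#' @export
build_training_set <- function(spikes, events, count_window = 1,
                               min_neurons = 0) {
  stopifnot(inherits(events, "event_log"))
  if (length(spikes) <= min_neurons) {
    .invalid_input(sprintf("population gate: need > %d neurons", min_neurons))
  }
  cons <- events$epochs$consumption
  count_in <- function(st, starts, width) {
    findInterval(starts + width - 1e-12, st) - findInterval(starts - 1e-12, st)
  }
  cue_t <- events$cues$time
  flav_t <- events$rewards$time[events$rewards$port == "flavour"]
  wat_t <- events$rewards$time[events$rewards$port == "water"]
  if (length(flav_t) == 0L || length(wat_t) == 0L || length(cue_t) == 0L) {
    .invalid_input("need at least one event per class")
  }
  tile_starts <- seq(cons$start, cons$end - count_window, by = count_window)
  n <- length(spikes)
  mu <- sdv <- numeric(n)
  feats <- matrix(0, length(flav_t) + length(wat_t) + length(cue_t), n)
  starts_all <- c(flav_t, wat_t, cue_t - count_window)
  for (u in seq_len(n)) {
    st <- spikes[[u]]
    pre_cue <- count_in(st, cue_t - count_window, count_window)
    tiles <- count_in(st, tile_starts, count_window)
    mu[u] <- mean(pre_cue)
    sdv[u] <- stats::sd(tiles)
    feats[, u] <- count_in(st, starts_all, count_window)
  }
  zero <- sdv == 0 | !is.finite(sdv)
  if (any(zero)) {
    warning(sprintf("%d neuron(s) with zero consumption s.d.; features zeroed",
                    sum(zero)))
    sdv[zero] <- 1
  }
  feats <- sweep(sweep(feats, 2, mu), 2, sdv, "/")
  feats[, zero] <- 0
  labels <- factor(c(rep("flavour", length(flav_t)),
                     rep("water", length(wat_t)),
                     rep("baseline", length(cue_t))),
                   levels = c("flavour", "water", "baseline"))
  stats <- norm_stats(mean = mu, sd = ifelse(zero, 0, sdv),
                      epoch_label = "consumption", bin_width = count_window,
                      granularity = "window", unit_ids = names(spikes))
  list(features = feats, labels = labels, train_stats = stats)
}

#' Multinomial negative log-likelihood and analytic gradient
#'
#' Smooth part of the decoder objective: total (unaveraged) multinomial
#' negative log-likelihood of labels given softmax(X W' + b). Exposed so the
#' analytic gradient can be verified against numerical differentiation.
#'
#' @param W weight matrix (classes x features).
#' @param b intercept vector (classes).
#' @param X feature matrix (samples x features).
#' @param y factor of labels; its levels index the rows of `W`.
#' @return list: `nll`, `grad_W` (classes x features), `grad_b` (classes).
#' @export
multinomial_nll_grad <- function(W, b, X, y) {
  eta <- X %*% t(W)
  eta <- sweep(eta, 2, b, "+")
  eta <- eta - apply(eta, 1, max)      # log-sum-exp stabilization
  P <- exp(eta)
  P <- P / rowSums(P)
  Y <- stats::model.matrix(~ y - 1)
  nll <- -sum(log(pmax(P[cbind(seq_along(y), as.integer(y))], 1e-300)))
  D <- P - Y
  list(nll = nll, grad_W = t(D) %*% X, grad_b = colSums(D))
}

#' Fit an L1-penalized multinomial logistic decoder
#'
#' Minimizes `total NLL + lambda * sum(|W|)` (intercepts unpenalized; the
#' penalty multiplies the unaveraged negative log-likelihood) by monotone
#' accelerated proximal gradient descent (MFISTA) from a zero
#' initialization, so the fit is deterministic and the objective decreases
#' monotonically: the accelerated step is taken when it improves the
#' objective, otherwise the plain proximal step from the current iterate is
#' used. Convergence is declared when the largest parameter change in a
#' step falls below `tol`; otherwise the partial model is returned flagged
#' as unconverged.
#'
#' @param features samples x neurons matrix.
#' @param labels factor of class labels (>= 2 classes present).
#' @param lambda L1 penalty weight (>= 0); 1 is the standard operating point.
#' @param tol convergence tolerance on the parameter step (default 1e-6).
#' @param max_iter iteration cap.
#' @param train_stats,eval_stats optional [norm_stats()] carried for
#'   provenance (training and evaluation normalizations).
#' @return a `cfa_decoder` object: `weights` (classes x neurons),
#'   `intercepts`, `lambda`, `classes`, `converged`, `n_iter`, `objective`
#'   (per-iteration trace), plus any stats supplied.
#' @export
fit_multinomial_l1 <- function(features, labels, lambda = 1, tol = 1e-6,
                               max_iter = 20000L, train_stats = NULL,
                               eval_stats = NULL) {
  X <- as.matrix(features)
  y <- droplevels(as.factor(labels))
  if (nlevels(y) < 2L) .invalid_input("need >= 2 classes present")
  if (lambda < 0) .invalid_input("lambda must be >= 0")
  k <- nlevels(y); p <- ncol(X)
  W <- matrix(0, k, p); b <- numeric(k)
  # Lipschitz bound for the multinomial NLL gradient: 0.5 * smax(X~)^2
  Xa <- cbind(X, 1)
  smax <- svd(Xa, nu = 0, nv = 0)$d[1]
  L <- 0.5 * smax^2
  soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)
  step <- 1 / L
  prox_from <- function(Wp, bp) {
    g <- multinomial_nll_grad(Wp, bp, X, y)
    list(W = soft(Wp - step * g$grad_W, step * lambda),
         b = bp - step * g$grad_b)
  }
  objective <- function(Wp, bp) {
    multinomial_nll_grad(Wp, bp, X, y)$nll + lambda * sum(abs(Wp))
  }
  obj <- objective(W, b)
  obj_trace <- obj
  # extrapolation state for the accelerated (FISTA) candidate
  Wy <- W; by <- b; tk <- 1
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    cand <- prox_from(Wy, by)
    obj_cand <- objective(cand$W, cand$b)
    if (obj_cand > obj) {
      # accelerated candidate not monotone; fall back to plain prox step
      cand <- prox_from(W, b)
      obj_cand <- objective(cand$W, cand$b)
      tk <- 1  # restart momentum
    }
    delta <- max(max(abs(cand$W - W)), max(abs(cand$b - b)))
    t_next <- (1 + sqrt(1 + 4 * tk^2)) / 2
    mom <- (tk - 1) / t_next
    Wy <- cand$W + mom * (cand$W - W)
    by <- cand$b + mom * (cand$b - b)
    tk <- t_next
    W <- cand$W; b <- cand$b; obj <- obj_cand
    obj_trace <- c(obj_trace, obj)
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning(sprintf("decoder did not converge in %d iterations (last step %.2e)",
                    max_iter, delta))
  }
  dimnames(W) <- list(levels(y), colnames(X))
  structure(list(weights = W, intercepts = stats::setNames(b, levels(y)),
                 lambda = lambda, classes = levels(y), converged = converged,
                 n_iter = it, objective = obj_trace,
                 train_stats = train_stats, eval_stats = eval_stats),
            class = "cfa_decoder")
}

#' @export
print.cfa_decoder <- function(x, ...) {
  cat(sprintf("<cfa_decoder> %d classes x %d neurons, lambda = %g, %d non-zero weights, %s in %d iterations\n",
              nrow(x$weights), ncol(x$weights), x$lambda,
              sum(x$weights != 0),
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' @export
coef.cfa_decoder <- function(object, ...) {
  cbind(intercept = object$intercepts, object$weights)
}

#' Class posteriors for new feature vectors
#'
#' @param object a `cfa_decoder`.
#' @param newdata samples x neurons matrix of normalized features.
#' @param type `"posterior"` (matrix of class probabilities, rows sum to 1)
#'   or `"class"` (argmax labels).
#' @param ... unused.
#' @export
predict.cfa_decoder <- function(object, newdata,
                                type = c("posterior", "class"), ...) {
  type <- match.arg(type)
  eta <- as.matrix(newdata) %*% t(object$weights)
  eta <- sweep(eta, 2, object$intercepts, "+")
  eta <- eta - apply(eta, 1, max)
  P <- exp(eta)
  P <- P / rowSums(P)
  colnames(P) <- object$classes
  if (type == "class") factor(object$classes[max.col(P)],
                              levels = object$classes) else P
}

#' Cross-validate the L1 penalty
#'
#' Stratified k-fold cross-validation over a log-spaced lambda grid
#' (default the nine values 1e-4 ... 1e4), reporting the mean held-out
#' log-likelihood per sample and the misclassification rate per lambda.
#' If some class has fewer members than `folds`, the fold count is reduced
#' with a warning. Fold assignment is drawn from the `"cv_folds"` substream
#' of `seed` and recorded in the output.
#'
#' @param features,labels as in [fit_multinomial_l1()].
#' @param folds number of folds (default 10).
#' @param lambda_grid penalty grid.
#' @param seed master seed for fold assignment.
#' @return data.frame: `lambda`, `heldout_ll` (mean per held-out sample),
#'   `misclass`; attribute `fold_seed` records the substream seed.
#' @export
cross_validate_lambda <- function(features, labels, folds = 10,
                                  lambda_grid = 10^seq(-4, 4, length.out = 9),
                                  seed = 1) {
  X <- as.matrix(features)
  y <- droplevels(as.factor(labels))
  if (nlevels(y) < 2L) .invalid_input("single-class data")
  min_class <- min(table(y))
  if (min_class < folds) {
    warning(sprintf("reducing folds from %d to %d (smallest class)",
                    folds, min_class))
    folds <- min_class
  }
  fold <- integer(length(y))
  with_substream(seed, "cv_folds", {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  res <- lapply(lambda_grid, function(lam) {
    ll <- 0; err <- 0; n_test <- 0
    for (f in seq_len(folds)) {
      tr <- fold != f; te <- !tr
      fit <- fit_multinomial_l1(X[tr, , drop = FALSE], y[tr], lambda = lam)
      P <- predict(fit, X[te, , drop = FALSE])
      yi <- as.integer(factor(y[te], levels = fit$classes))
      ll <- ll + sum(log(pmax(P[cbind(seq_len(nrow(P)), yi)], 1e-300)))
      err <- err + sum(fit$classes[max.col(P)] != as.character(y[te]))
      n_test <- n_test + sum(te)
    }
    c(heldout_ll = ll / n_test, misclass = err / n_test)
  })
  out <- data.frame(lambda = lambda_grid, do.call(rbind, res))
  attr(out, "fold_seed") <- substream_seed(seed, "cv_folds")
  out
}

#' Per-neuron 1-s-count statistics over the delay period
#'
#' Evaluation-time normalization for the decoder: mean and sd of spike
#' counts in non-overlapping `width`-second windows tiling the delay epoch.
#'
#' @param spikes named list of sorted spike-time vectors.
#' @param events an [event_log()].
#' @param width window width in seconds.
#' @return a [norm_stats()] with `"window"` granularity.
#' @export
delay_window_stats <- function(spikes, events, width = 1) {
  dl <- events$epochs$delay
  starts <- seq(dl$start, dl$end - width, by = width)
  m <- sdv <- numeric(length(spikes))
  for (u in seq_along(spikes)) {
    st <- spikes[[u]]
    cnt <- findInterval(starts + width - 1e-12, st) -
      findInterval(starts - 1e-12, st)
    m[u] <- mean(cnt)
    sdv[u] <- sqrt(mean(cnt^2) - m[u]^2)  # population sd
  }
  sdv[sdv < 0] <- 0
  suppressWarnings(
    norm_stats(mean = m, sd = sdv, epoch_label = "delay", bin_width = width,
               granularity = "window", unit_ids = names(spikes)))
}

#' Sliding-window decoder posteriors
#'
#' Bins spikes in a 1-s window sliding in 150-ms steps over `t_range`,
#' z-scores each neuron's window counts with delay-period statistics, and
#' scores every window with the decoder. Window `k` covers
#' `[start + (k-1) step, start + (k-1) step + window)`; its reported time is
#' the window centre.
#'
#' @param model a `cfa_decoder`.
#' @param spikes named list of sorted spike-time vectors.
#' @param eval_stats delay-period [norm_stats()] from [delay_window_stats()].
#' @param t_range evaluated span `[start, end]` in seconds (session start to
#'   end in the full analysis; delay + stimulation for reactivation counts).
#' @param window,step window width and step in seconds.
#' @return a `posterior_series`: `times`, `posteriors` (windows x classes,
#'   rows summing to 1), `window`, `step`.
#' @export
sliding_posteriors <- function(model, spikes, eval_stats, t_range,
                               window = 1, step = 0.15) {
  span <- t_range[2] - t_range[1]
  if (span < window) .invalid_input("window larger than evaluated span")
  n_win <- floor((span - window) / step) + 1
  starts <- t_range[1] + (seq_len(n_win) - 1) * step
  Z <- matrix(0, n_win, length(spikes))
  sdv <- ifelse(eval_stats$zero_sd, 1, eval_stats$sd)
  for (u in seq_along(spikes)) {
    st <- spikes[[u]]
    cnt <- findInterval(starts + window - 1e-12, st) -
      findInterval(starts - 1e-12, st)
    Z[, u] <- (cnt - eval_stats$mean[u]) / sdv[u]
  }
  Z[, eval_stats$zero_sd] <- 0
  P <- predict(model, Z)
  structure(list(times = starts + window / 2, posteriors = P,
                 window = window, step = step),
            class = "posterior_series")
}

#' @export
print.posterior_series <- function(x, ...) {
  cat(sprintf("<posterior_series> %d windows (%.2f-s window, %.0f-ms step), classes: %s\n",
              length(x$times), x$window, x$step * 1000,
              paste(colnames(x$posteriors), collapse = ", ")))
  invisible(x)
}

#' Detect reactivation events in a posterior series
#'
#' Reactivation events are strict local maxima of the class posterior with
#' value above the threshold. A plateau (run of equal values above both
#' neighbours) contributes its first index; an endpoint is eligible when it
#' exceeds its single neighbour.
#'
#' @param series a `posterior_series` (or plain numeric vector).
#' @param class class name, e.g. `"flavour"` (ignored for plain vectors).
#' @param threshold posterior threshold (default 0.5).
#' @return list with `indices` (1-based window indices) and `times`
#'   (window-centre seconds; `NULL` for plain vectors).
#' @export
detect_reactivations <- function(series, class = "flavour", threshold = 0.5) {
  v <- if (inherits(series, "posterior_series")) {
    series$posteriors[, class]
  } else as.numeric(series)
  r <- rle(v)
  n_runs <- length(r$values)
  first_idx <- cumsum(c(1, r$lengths[-n_runs]))
  left <- c(-Inf, r$values[-n_runs])   # -Inf: endpoint run has no neighbour
  right <- c(r$values[-1], -Inf)
  is_peak <- r$values > left & r$values > right & r$values > threshold
  idx <- first_idx[is_peak]
  list(indices = idx,
       times = if (inherits(series, "posterior_series"))
         series$times[idx] else NULL)
}

#' Reactivation rate in sliding windows
#'
#' Counts events in 1-min windows advanced in 30-s steps across `span`,
#' expressed in events per minute.
#'
#' @param event_times event times in seconds.
#' @param span `[start, end]` of the evaluated period.
#' @param window,step window width and step in seconds.
#' @return data.frame with `t_center` (s) and `rate` (events/min).
#' @export
reactivation_rate <- function(event_times, span, window = 60, step = 30) {
  starts <- seq(span[1], span[2] - window, by = step)
  counts <- vapply(starts, function(s) {
    sum(event_times >= s & event_times < s + window)
  }, numeric(1))
  data.frame(t_center = starts + window / 2, rate = counts / (window / 60))
}
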