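# log density of x under a diagonal Gaussian, vectorized over rows
.diag_gauss_logdens <- function(X, mu, var) {
  -0.5 * (rowSums(sweep(sweep(X, 2, mu)^2, 2, var, "/")) +
            sum(log(2 * pi * var)))
}

# one EM run from given responsibilities; returns NULL on degeneracy
.em_run <- function(X, resp, k, var_floor, max_iter = 500, tol = 1e-8) {
  n <- nrow(X); d <- ncol(X)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    # M step
    nk <- colSums(resp)
    if (any(nk < 1e-10)) return(NULL)
    pi_k <- nk / n
    mu <- t(resp) %*% X / nk
    var <- matrix(0, k, d)
    for (j in seq_len(k)) {
      var[j, ] <- colSums(resp[, j] * sweep(X, 2, mu[j, ])^2) / nk[j]
    }
    var <- pmax(var, var_floor)
    # E step
    logd <- vapply(seq_len(k), function(j) {
      log(pi_k[j]) + .diag_gauss_logdens(X, mu[j, ], var[j, ])
    }, numeric(n))
    m <- apply(logd, 1, max)
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    if (!is.finite(ll)) return(NULL)
    resp <- exp(logd - lse)
    ll_trace <- c(ll_trace, ll)
    if (iter > 1 && ll - ll_old < tol * abs(ll_old)) break
    ll_old <- ll
  }
  list(pi = pi_k, mu = mu, var = var, resp = resp, loglik = ll,
       ll_trace = ll_trace)
}

#' Gaussian-mixture response typing of stimulation PETHs
#'
#' Fits a 4-component Gaussian mixture with diagonal covariances (variance
#' floor 1e-5) to the 0 to +1 s bins of baseline-subtracted stimulation
#' PETHs, using EM with random-responsibility initialization and multiple
#' restarts, keeping the restart with the highest log-likelihood.
#' Components are then labelled semantically from their mean response over
#' the feature window: the most negative mean is `inhibited`, the mean
#' closest to zero among the rest is `unmodulated`, and the remaining two
#' are `strongly_activated` and `weakly_activated` by magnitude. If the
#' fitted means do not show this two-activated / one-inhibited /
#' one-unmodulated structure a warning is raised (labels are still
#' assigned by the rule).
#'
#' @param peths a `peth_matrix` over (-1, +2) s (the 0-1 s bins are used)
#'   or a plain neurons x bins feature matrix used as is.
#' @param n_components number of response types (default 4).
#' @param replicates number of EM restarts (default 100).
#' @param var_floor variance regularization floor.
#' @param seed master seed; restarts draw from the `"gmm"` substream.
#' @return a `cfa_gmm` object: `means`, `variances`, `weights`,
#'   `assignment` (hard component per neuron), `type` (semantic label per
#'   neuron), `component_type`, `loglik`, `ll_trace` (best restart),
#'   `all_monotone` (log-likelihood monotone on every restart),
#'   `n_degenerate`.
#' @export
gmm_response_types <- function(peths, n_components = 4, replicates = 100,
                               var_floor = 1e-5, seed = 1) {
  X <- if (inherits(peths, "peth_matrix")) {
    cols <- peths$lags > 0 & peths$lags <= 1
    peths$values[, cols, drop = FALSE]
  } else as.matrix(peths)
  n <- nrow(X); k <- n_components
  if (n < 4 * k) .invalid_input("need >= 4x more neurons than components")
  best <- NULL; n_degenerate <- 0L; all_monotone <- TRUE
  with_substream(seed, "gmm", {
    for (rep_i in seq_len(replicates)) {
      resp <- matrix(stats::rexp(n * k), n, k)
      resp <- resp / rowSums(resp)
      run <- .em_run(X, resp, k, var_floor)
      if (is.null(run)) { n_degenerate <- n_degenerate + 1L; next }
      if (any(diff(run$ll_trace) < -1e-6 * (abs(run$loglik) + 1))) {
        all_monotone <- FALSE
      }
      if (is.null(best) || run$loglik > best$loglik) best <- run
    }
  })
  if (is.null(best)) stop("all EM restarts degenerate")
  comp_mean <- rowMeans(best$mu)
  type <- rep(NA_character_, k)
  inhibited <- which.min(comp_mean)
  type[inhibited] <- "inhibited"
  rest <- setdiff(seq_len(k), inhibited)
  unmod <- rest[which.min(abs(comp_mean[rest]))]
  type[unmod] <- "unmodulated"
  act <- setdiff(rest, unmod)
  act <- act[order(comp_mean[act], decreasing = TRUE)]
  type[act] <- c("strongly_activated", "weakly_activated")[seq_along(act)]
  if (comp_mean[inhibited] >= 0 || any(comp_mean[act] <= 0)) {
    warning("component means do not show the expected activated/inhibited/unmodulated structure")
  }
  assignment <- max.col(best$resp)
  structure(list(means = best$mu, variances = best$var, weights = best$pi,
                 assignment = assignment, type = type[assignment],
                 component_type = type, loglik = best$loglik,
                 ll_trace = best$ll_trace, all_monotone = all_monotone,
                 n_degenerate = n_degenerate, var_floor = var_floor),
            class = "cfa_gmm")
}

#' @export
print.cfa_gmm <- function(x, ...) {
  tab <- table(factor(x$type, levels = c("strongly_activated",
                                         "weakly_activated", "inhibited",
                                         "unmodulated")))
  cat(sprintf("<cfa_gmm> %d components over %d neurons, loglik %.1f\n",
              length(x$weights), length(x$assignment), x$loglik))
  print(tab)
  invisible(x)
}

#' Assign new PETHs to fitted response types
#'
#' @param object a `cfa_gmm`.
#' @param newdata a `peth_matrix` (0-1 s bins used) or feature matrix.
#' @param ... unused.
#' @return factor of semantic type labels, one per row.
#' @export
predict.cfa_gmm <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "peth_matrix")) {
    cols <- newdata$lags > 0 & newdata$lags <= 1
    newdata$values[, cols, drop = FALSE]
  } else as.matrix(newdata)
  k <- length(object$weights)
  logd <- vapply(seq_len(k), function(j) {
    log(object$weights[j]) +
      .diag_gauss_logdens(X, object$means[j, ], object$variances[j, ])
  }, numeric(nrow(X)))
  if (nrow(X) == 1L) logd <- matrix(logd, nrow = 1)
  factor(object$component_type[max.col(logd)],
         levels = c("strongly_activated", "weakly_activated", "inhibited",
                    "unmodulated"))
}
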