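#' Build the PCA input matrix from reward PETHs
#'
#' For each reward-selective neuron: subtract the mean baseline activity
#' over (-5, -4) s before delivery, averaged across both reward types;
#' peak-normalize by the maximum absolute value across both reward types;
#' then concatenate the 0 to +5 s segments of the flavour and water PETHs.
#' With 10-ms bins this yields neurons x 1,000 time bins. PETHs should be
#' smoothed with the causal half-Gaussian (sd 100 ms). Neurons whose peak
#' value is zero are dropped with a warning. The normalization constants
#' are recorded so day-2 data can be normalized with day-1 values.
#'
#' @param flavour_peth,water_peth `peth_matrix` objects over (-5, +10) s
#'   (or any window covering (-5, +5) s), same neurons in the same order.
#' @param selective logical mask (or unit-id character vector) of
#'   reward-selective neurons to include.
#' @return a `pca_input` object: `matrix` (neurons x 1,000), `baseline`,
#'   `peak`, `unit_ids`, `n_seg` (bins per reward segment).
#' @export
build_pca_input <- function(flavour_peth, water_peth, selective) {
  stopifnot(inherits(flavour_peth, "peth_matrix"),
            inherits(water_peth, "peth_matrix"))
  if (!identical(flavour_peth$unit_ids, water_peth$unit_ids)) {
    .invalid_input("PETHs must cover the same neurons in the same order")
  }
  if (is.character(selective)) {
    selective <- flavour_peth$unit_ids %in% selective
  }
  f <- flavour_peth$values[selective, , drop = FALSE]
  w <- water_peth$values[selective, , drop = FALSE]
  ids <- flavour_peth$unit_ids[selective]
  lags <- flavour_peth$lags
  base_cols <- lags >= -5 & lags < -4
  seg_cols <- lags > 0 & lags <= 5
  if (!any(base_cols) || !any(seg_cols)) {
    .invalid_input("PETH window must cover (-5, -4) s and (0, 5] s")
  }
  baseline <- (rowMeans(f[, base_cols, drop = FALSE]) +
               rowMeans(w[, base_cols, drop = FALSE])) / 2
  f <- f - baseline; w <- w - baseline
  peak <- pmax(apply(abs(f), 1, max), apply(abs(w), 1, max))
  keep <- peak > 0
  if (any(!keep)) {
    warning(sprintf("%d neuron(s) with zero peak dropped", sum(!keep)))
  }
  f <- f[keep, , drop = FALSE] / peak[keep]
  w <- w[keep, , drop = FALSE] / peak[keep]
  structure(list(matrix = cbind(f[, seg_cols, drop = FALSE],
                                w[, seg_cols, drop = FALSE]),
                 baseline = baseline[keep], peak = peak[keep],
                 unit_ids = ids[keep], n_seg = sum(seg_cols),
                 bin_width = flavour_peth$bin_width),
            class = "pca_input")
}

#' PCA on trial-averaged population activity
#'
#' Centres every column (time bin) of the input across neurons, then
#' computes principal directions in neuron space (time bins are the
#' observations, neurons the variables), giving per-neuron loading vectors
#' and variance-explained fractions. PCA signs are arbitrary, so each PC is
#' oriented so that the flavour trajectory's peak projection is
#' non-negative (recorded in `sign_flip`).
#'
#' @param x a `pca_input` (preferred; carries normalization constants) or a
#'   plain neurons x bins matrix.
#' @param n_pcs number of components to retain (default all).
#' @return a `cfa_pca` object: `loadings` (neurons x PCs, orthonormal),
#'   `var_explained`, `sign_flip`, `unit_ids`, `normalization` (baseline /
#'   peak constants when available), and the training trajectories
#'   `flavour_traj` / `water_traj` when `x` is a `pca_input`.
#' @export
fit_pca <- function(x, n_pcs = NULL) {
  inp <- if (inherits(x, "pca_input")) x else NULL
  M <- if (is.null(inp)) as.matrix(x) else inp$matrix
  n <- nrow(M)
  if (n < 3) .invalid_input("need >= 3 neurons")
  k_max <- min(n, ncol(M))
  if (is.null(n_pcs)) n_pcs <- k_max
  if (n_pcs > k_max) n_pcs <- k_max
  Mc <- sweep(M, 2, colMeans(M))  # centre each time bin across neurons
  sv <- svd(Mc)
  d2 <- sv$d^2
  var_explained <- d2 / sum(d2)
  loadings <- sv$u[, seq_len(n_pcs), drop = FALSE]
  # projection of the training data on PC j at time bin t is d_j * v[t, j]
  proj <- sweep(sv$v[, seq_len(n_pcs), drop = FALSE], 2,
                sv$d[seq_len(n_pcs)], "*")
  sign_flip <- rep(1, n_pcs)
  n_seg <- if (is.null(inp)) floor(ncol(M) / 2) else inp$n_seg
  for (j in seq_len(n_pcs)) {
    fl <- proj[seq_len(n_seg), j]
    if (fl[which.max(abs(fl))] < 0) sign_flip[j] <- -1
  }
  loadings <- sweep(loadings, 2, sign_flip, "*")
  proj <- sweep(proj, 2, sign_flip, "*")
  structure(list(loadings = loadings,
                 var_explained = var_explained[seq_len(n_pcs)],
                 all_var_explained = var_explained,
                 sign_flip = sign_flip,
                 unit_ids = if (is.null(inp)) rownames(M) else inp$unit_ids,
                 normalization = if (is.null(inp)) NULL else
                   list(baseline = inp$baseline, peak = inp$peak),
                 flavour_traj = proj[seq_len(n_seg), , drop = FALSE],
                 water_traj = if (ncol(M) >= 2 * n_seg)
                   proj[(n_seg + 1):(2 * n_seg), , drop = FALSE] else NULL),
            class = "cfa_pca")
}

#' @export
print.cfa_pca <- function(x, ...) {
  cat(sprintf("<cfa_pca> %d neurons, %d PCs; variance explained: %s\n",
              nrow(x$loadings), ncol(x$loadings),
              paste(sprintf("%.1f%%", 100 * x$var_explained[seq_len(min(3, length(x$var_explained)))]),
                    collapse = ", ")))
  invisible(x)
}

#' Project a population PETH onto PC axes
#'
#' Normalizes a reward PETH with the constants recorded at fit time
#' (baseline subtraction and peak normalization -- for day-2 data these are
#' day-1 constants), then at every lag bin centres the population vector
#' across neurons and projects it onto each loading vector.
#'
#' @param peth a `peth_matrix` covering the neurons in the fit (same order).
#' @param pca a `cfa_pca`.
#' @param normalize apply the recorded baseline/peak normalization (set
#'   `FALSE` if `peth` is already normalized).
#' @return a `pc_trajectory`: `values` (lags x PCs), `lags`.
#' @export
project_trajectory <- function(peth, pca, normalize = TRUE) {
  stopifnot(inherits(peth, "peth_matrix"), inherits(pca, "cfa_pca"))
  V <- peth$values
  if (!is.null(pca$unit_ids) && !is.null(peth$unit_ids)) {
    if (!all(pca$unit_ids %in% peth$unit_ids)) {
      .invalid_input("PETH is missing neurons present in the PCA fit")
    }
    V <- V[match(pca$unit_ids, peth$unit_ids), , drop = FALSE]
  }
  if (nrow(V) != nrow(pca$loadings)) {
    .invalid_input("neuron set mismatch with the PCA fit")
  }
  if (normalize) {
    if (is.null(pca$normalization)) {
      .invalid_input("no normalization constants recorded in the fit")
    }
    V <- (V - pca$normalization$baseline) / pca$normalization$peak
  }
  Vc <- sweep(V, 2, colMeans(V))  # centre each time bin across neurons
  structure(list(values = t(Vc) %*% pca$loadings, lags = peth$lags),
            class = "pc_trajectory")
}

#' Project a stimulation PETH onto PC axes
#'
#' The stimulation-bout PETH is baseline-subtracted over (-1, 0) s and
#' peak-normalized by its own maximum absolute value per neuron (not the
#' reward constants), then projected like a reward PETH.
#'
#' @param stim_peth a `peth_matrix` from [stim_bout_peth()].
#' @param pca a `cfa_pca`.
#' @return a `pc_trajectory`.
#' @export
project_stim_trajectory <- function(stim_peth, pca) {
  stopifnot(inherits(stim_peth, "peth_matrix"))
  V <- stim_peth$values
  if (!is.null(pca$unit_ids) && !is.null(stim_peth$unit_ids)) {
    if (!all(pca$unit_ids %in% stim_peth$unit_ids)) {
      .invalid_input("stim PETH is missing neurons present in the PCA fit")
    }
    V <- V[match(pca$unit_ids, stim_peth$unit_ids), , drop = FALSE]
  }
  base_cols <- stim_peth$lags >= -1 & stim_peth$lags < 0
  V <- V - rowMeans(V[, base_cols, drop = FALSE])
  peak <- apply(abs(V), 1, max)
  peak[peak == 0] <- 1  # flat neurons stay zero
  V <- V / peak
  p2 <- stim_peth
  p2$values <- V
  p2$unit_ids <- if (is.null(pca$unit_ids)) NULL else pca$unit_ids
  project_trajectory(p2, pca, normalize = FALSE)
}

#' Cosine similarity between two trajectories over a lag range
#'
#' Compares the flattened PC coordinates of two trajectories (e.g. the
#' stimulation-period trajectory vs the flavour consumption trajectory)
#' over post-event lags.
#'
#' @param a,b `pc_trajectory` objects or plain matrices (bins x PCs).
#' @param lags_a,lags_b optional logical/index selections of rows.
#' @param pcs which PCs to include (default first two).
#' @return cosine similarity in `[-1, 1]`.
#' @export
trajectory_cosine <- function(a, b, lags_a = NULL, lags_b = NULL, pcs = 1:2) {
  get <- function(x, sel) {
    v <- if (inherits(x, "pc_trajectory")) x$values else as.matrix(x)
    v <- v[, pcs, drop = FALSE]
    if (!is.null(sel)) v <- v[sel, , drop = FALSE]
    v
  }
  va <- get(a, lags_a); vb <- get(b, lags_b)
  if (nrow(va) != nrow(vb)) {
    # compare mean PC coordinates when sampled at different resolutions
    va <- colMeans(va); vb <- colMeans(vb)
  }
  sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
}
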