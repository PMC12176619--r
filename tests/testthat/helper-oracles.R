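# Independent reference implementations used as oracles. These are kept
# deliberately naive and separate from the package code paths they check.

# exact two-sided rank-sum p by full enumeration of group assignments,
# using the centered U statistic with midranks (valid with ties)
exact_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  r <- rank(pooled)
  obs <- abs(sum(r[seq_len(nx)]) - nx * (nx + 1) / 2 - nx * length(y) / 2)
  combs <- utils::combn(n, nx)
  stats <- apply(combs, 2, function(idx) {
    abs(sum(r[idx]) - nx * (nx + 1) / 2 - nx * (n - nx) / 2)
  })
  mean(stats >= obs - 1e-9)
}

# textbook two-stage adaptive step-up procedure, straight from its
# published definition
bky_reference <- function(p, q = 0.05) {
  m <- length(p)
  q1 <- q / (1 + q)
  lsu <- function(pv, alpha) {
    srt <- sort(pv, index.return = TRUE)
    pass <- which(srt$x <= (seq_len(m) / m) * alpha)
    rej <- rep(FALSE, m)
    if (length(pass)) rej[srt$ix[seq_len(max(pass))]] <- TRUE
    rej
  }
  r1 <- lsu(p, q1)
  if (sum(r1) == 0 || sum(r1) == m) return(r1)
  lsu(p, q1 * m / (m - sum(r1)))
}

# exhaustive scan for strict local maxima above a threshold, plateaus
# contributing their first index, endpoints eligible against their single
# neighbour
brute_peaks <- function(v, thr = 0.5) {
  out <- integer(0)
  for (i in seq_along(v)) {
    if (v[i] <= thr) next
    if (i > 1 && v[i - 1] == v[i]) next  # not the first of its plateau
    jl <- i - 1
    while (jl >= 1 && v[jl] == v[i]) jl <- jl - 1
    left_ok <- jl < 1 || v[jl] < v[i]
    jr <- i + 1
    while (jr <= length(v) && v[jr] == v[i]) jr <- jr + 1
    right_ok <- jr > length(v) || v[jr] < v[i]
    if (left_ok && right_ok) out <- c(out, i)
  }
  out
}

# adjusted Rand index between two hard partitions
ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab)); si <- sum(ch2(rowSums(tab))); sj <- sum(ch2(colSums(tab)))
  exp_idx <- si * sj / ch2(length(a))
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# balanced accuracy: mean per-class recall over the classes present in truth
balanced_accuracy <- function(truth, est) {
  classes <- unique(truth)
  mean(vapply(classes, function(cl) {
    mean(est[truth == cl] == cl, na.rm = TRUE)
  }, numeric(1)))
}
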