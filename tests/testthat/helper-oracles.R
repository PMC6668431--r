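# Independent brute-force references used as oracles. Deliberately written
# as naive O(n^2) loops, with no code shared with the package internals.

brute_bh_threshold <- function(pvals, alpha, n_total = length(pvals)) {
  ps <- sort(pvals)
  best <- 0
  for (k in seq_along(ps)) {
    if (ps[k] <= k * alpha / n_total) best <- k * alpha / n_total
  }
  best
}

brute_storey_reject <- function(pvals, alpha, n_total = length(pvals),
                                lambda = 0.5) {
  n_large <- 0
  for (p in pvals) if (p > lambda) n_large <- n_large + 1
  pi0 <- min(1, n_large / ((1 - lambda) * n_total))
  thr <- brute_bh_threshold(pvals, min(alpha / pi0, 1 - 1e-12), n_total)
  list(reject = pvals <= thr, pi0_hat = pi0)
}

brute_count <- function(pvals, thresholds) {
  d <- 0L
  for (i in seq_along(pvals)) if (pvals[i] <= thresholds[i]) d <- d + 1L
  d
}

brute_mirror <- function(pvals, thresholds) {
  fd <- 0L
  for (i in seq_along(pvals)) if (pvals[i] >= 1 - thresholds[i]) fd <- fd + 1L
  fd
}

# brute-force rescale search over an explicit candidate set; boundary hits
# count with a small absolute tolerance, matching exact decimal arithmetic
brute_gamma <- function(pvals, thresholds, alpha, c0, n_total, candidates) {
  best <- 0
  d_min <- max(1, ceiling(c0 * n_total))
  for (g in sort(candidates)) {
    tt <- pmin(g * thresholds, 0.5)
    D <- 0L; FD <- 0L
    for (i in seq_along(pvals)) {
      if (pvals[i] <= tt[i] + 1e-9) D <- D + 1L
      if (pvals[i] >= 1 - tt[i] - 1e-9) FD <- FD + 1L
    }
    if (D >= d_min && FD / max(D, 1) <= alpha && g > best) best <- g
  }
  best
}
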