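#' Count discoveries at a per-hypothesis threshold
#'
#' A hypothesis is rejected when its p-value is less than or equal to its
#' threshold, so `count_discoveries` returns `sum(pvals <= thresholds)`.
#'
#' @param pvals Numeric vector of p-values.
#' @param thresholds Numeric vector of per-hypothesis thresholds, same length.
#' @return Integer count of rejections.
#' @export
count_discoveries <- function(pvals, thresholds) {
  if (length(pvals) != length(thresholds)) {
    stop("pvals and thresholds must have equal length")
  }
  sum(pvals <= thresholds)
}

#' Mirror estimate of the number of false discoveries
#'
#' Counts p-values in the mirrored region `p >= 1 - t(x)`. Under the standard
#' assumption that null p-values are uniform given the covariates, this count
#' has expectation at least that of the true number of false discoveries at
#' threshold `t(x)`, making it a conservative plug-in estimate.
#'
#' @inheritParams count_discoveries
#' @return Integer mirror count.
#' @export
mirror_fd <- function(pvals, thresholds) {
  if (length(pvals) != length(thresholds)) {
    stop("pvals and thresholds must have equal length")
  }
  sum(pvals >= 1 - thresholds)
}

#' Estimated (and, with labels, true) false discovery proportion
#'
#' Combines the discovery count and the mirror estimate into
#' `FDP_hat = FD_hat / max(D, 1)`. When ground-truth labels are supplied the
#' true false-discovery count and proportion are reported alongside.
#'
#' @inheritParams count_discoveries
#' @param labels Optional 0/1 vector of ground truth (1 = true alternative).
#' @return An object of class `count_summary` with elements `D`, `FD_hat`,
#'   `FDP_hat` and, when labels are given, `FD_true`, `FDP_true`.
#' @export
fdp_hat <- function(pvals, thresholds, labels = NULL) {
  D <- count_discoveries(pvals, thresholds)
  FDh <- mirror_fd(pvals, thresholds)
  out <- list(D = D, FD_hat = FDh, FDP_hat = FDh / max(D, 1))
  if (!is.null(labels)) {
    out$FD_true <- sum(pvals <= thresholds & labels == 0L)
    out$FDP_true <- out$FD_true / max(D, 1)
  }
  structure(out, class = "count_summary")
}

#' @export
print.count_summary <- function(x, ...) {
  cat(sprintf("D = %d, FD_hat = %d, FDP_hat = %.4f", x$D, x$FD_hat, x$FDP_hat))
  if (!is.null(x$FD_true)) {
    cat(sprintf(" | FD_true = %d, FDP_true = %.4f", x$FD_true, x$FDP_true))
  }
  cat("\n")
  invisible(x)
}

#' Benjamini-Hochberg p-value threshold
#'
#' Step-up threshold `t_BH = k* alpha / n_total` where `k*` is the largest `k`
#' with `p_(k) <= k alpha / n_total` among the sorted retained p-values.
#' In filtered mode `n_total` exceeds `length(pvals)` and plays the role of the
#' original hypothesis count.
#'
#' @param pvals Numeric vector of (retained) p-values.
#' @param alpha Nominal FDR level in (0, 1).
#' @param n_total Total number of hypotheses; defaults to `length(pvals)`.
#' @return The threshold, or 0 when no rejection is possible.
#' @export
bh_threshold <- function(pvals, alpha, n_total = length(pvals)) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)")
  }
  if (n_total < length(pvals)) stop("n_total must be >= length(pvals)")
  ps <- sort(pvals)
  k <- seq_along(ps)
  ok <- which(ps <= k * alpha / n_total)
  if (!length(ok)) return(0)
  max(ok) * alpha / n_total
}

#' Storey-BH adaptive procedure
#'
#' Estimates the null proportion `pi0_hat = min(1, #\{p > lambda\} /
#' ((1 - lambda) n_total))` from the large p-values and runs BH at the
#' inflated level `alpha / pi0_hat`.
#'
#' @inheritParams bh_threshold
#' @param lambda Tuning point for the null-proportion estimate, in (0, 1).
#' @param filter_range Optional `c(lower, upper)` filtering bounds of the
#'   retained p-values. Storey's estimate needs every `p > lambda` present, so
#'   filtered input with `upper > lambda` is rejected.
#' @return A list with `reject` (logical vector over `pvals`), `pi0_hat`,
#'   and `t_bh` (the applied threshold).
#' @export
storey_bh <- function(pvals, alpha, n_total = length(pvals), lambda = 0.5,
                      filter_range = NULL) {
  if (lambda <= 0 || lambda >= 1) stop("lambda must lie in (0, 1)")
  if (!is.null(filter_range) && n_total > length(pvals) &&
      filter_range[2] > lambda) {
    stop("filtered input incompatible with lambda = ", lambda,
         ": p-values in (", lambda, ", ", filter_range[2], "] were removed")
  }
  pi0 <- min(1, sum(pvals > lambda) / ((1 - lambda) * n_total))
  level <- min(alpha / max(pi0, .Machine$double.eps), 1 - 1e-12)
  thr <- bh_threshold(pvals, level, n_total)
  list(reject = pvals <= thr, pi0_hat = pi0, t_bh = thr)
}

#' Split hypotheses into approximate null and alternative ensembles
#'
#' Hypotheses with `p >= 0.75` form a proxy for the nulls; hypotheses with
#' `p <= t_BH` (the BH threshold at level `alpha`) form a proxy for the
#' alternatives. These ensembles seed the threshold initialization and the
#' covariate diagnostics.
#'
#' @inheritParams bh_threshold
#' @return An object of class `ensemble_split` with `null_idx`, `alt_idx`,
#'   `t_bh`.
#' @export
build_ensembles <- function(pvals, alpha, n_total = length(pvals)) {
  t_bh <- bh_threshold(pvals, alpha, n_total)
  structure(
    list(null_idx = which(pvals >= 0.75),
         alt_idx = if (t_bh > 0) which(pvals <= t_bh) else integer(0),
         t_bh = t_bh),
    class = "ensemble_split"
  )
}

#' Best rescale factor for a learned threshold on a held-out fold
#'
#' Finds the largest factor `gamma` such that the rescaled threshold
#' `gamma * t(x)` (re-capped at 0.5) keeps the mirror-estimated FDP at or
#' below `alpha` while making at least `max(1, ceiling(c0 * n_total))`
#' discoveries; returns 0 when no factor qualifies, in which case the fold
#' contributes no rejections.
#'
#' The estimated FDP is not monotone in `gamma`, so the search enumerates a
#' fixed logarithmic grid augmented with the exact breakpoints `p_i / t_i`
#' where the discovery count jumps; counting at each candidate is done by
#' rank arithmetic on the sorted ratios, which is exact.
#'
#' @param pvals Numeric p-values on the fold.
#' @param thresholds Evaluated threshold `t(x_i)` on the fold (capped at 0.5).
#' @param alpha Nominal FDP level.
#' @param c0 Minimum discovery proportion; the fold must make at least
#'   `ceiling(c0 * n_total)` (and at least one) discoveries.
#' @param n_total Total hypothesis count backing the fold (original count in
#'   filtered mode).
#' @param grid Optional vector of candidate factors; default is 1000
#'   log-spaced points on \[0.01, 10\].
#' @return An object of class `gamma_result` with `gamma_star`, `c0`, `grid`,
#'   and `counts_at_star` (a [fdp_hat()] summary at the chosen factor).
#' @export
rescale_gamma <- function(pvals, thresholds, alpha, c0 = 1e-4,
                          n_total = length(pvals), grid = NULL) {
  if (length(pvals) != length(thresholds)) {
    stop("pvals and thresholds must have equal length")
  }
  if (c0 < 0 || c0 >= 1) stop("c0 must lie in [0, 1)")
  if (!length(pvals)) {
    warning("empty fold: gamma_star = 0")
    return(structure(list(gamma_star = 0, c0 = c0, grid = numeric(0),
                          counts_at_star = fdp_hat(numeric(0), numeric(0))),
                     class = "gamma_result"))
  }
  if (is.null(grid)) {
    grid <- exp(seq(log(0.01), log(10), length.out = 1000))
  }
  gmax <- max(grid)
  if (any(thresholds <= 0)) stop("thresholds must be strictly positive")

  # Rejection with cap: p <= min(g*t, 0.5)  <=>  p <= 0.5 and p/t <= g.
  # Mirror with cap:    p >= 1 - min(g*t, 0.5)  <=>  p >= 0.5 and (1-p)/t <= g.
  r <- pvals / thresholds
  s <- (1 - pvals) / thresholds
  r_rej <- sort(r[pvals <= 0.5])
  s_mir <- sort(s[pvals >= 0.5])

  cand <- sort(unique(c(grid, r[r > 0 & r <= gmax])))
  # boundary hits (p == gamma * t, p == 1 - gamma * t) must count despite
  # floating-point representation noise in the ratios
  cand_eff <- cand * (1 + 1e-9)
  D <- findInterval(cand_eff, r_rej)
  FDh <- findInterval(cand_eff, s_mir)
  D_min <- max(1L, ceiling(c0 * n_total))
  valid <- (FDh <= alpha * pmax(D, 1)) & (D >= D_min)

  if (any(valid)) {
    i_star <- max(which(valid))
    gamma_star <- cand[i_star]
    counts <- structure(
      list(D = D[i_star], FD_hat = FDh[i_star],
           FDP_hat = FDh[i_star] / max(D[i_star], 1)),
      class = "count_summary")
  } else {
    gamma_star <- 0
    counts <- fdp_hat(pvals, rep(0, length(pvals)))
  }
  structure(
    list(gamma_star = gamma_star, c0 = c0, grid = grid,
         counts_at_star = counts),
    class = "gamma_result"
  )
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("gamma* = %.4g (c0 = %g): ", x$gamma_star, x$c0))
  print(x$counts_at_star)
  invisible(x)
}
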