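# Mixture density over the normalized covariate cube [0,1]^d:
# one exponential-tilt component (density prod_j a_j exp(a_j x_j)/(e^{a_j}-1),
# the analogue of the threshold's GLM term) plus K diagonal Gaussians
# truncated to [0,1]^d and renormalized. Fitted by weighted EM.

# mean of the tilt density on [0,1] and its derivative (the variance),
# stable near a = 0
tilt_mean <- function(a) {
  ifelse(abs(a) < 1e-5, 0.5 + a / 12,
         1 / (1 - exp(-a)) - 1 / a)
}

tilt_mean_deriv <- function(a) {
  ifelse(abs(a) < 1e-5, 1 / 12,
         -exp(-a) / (1 - exp(-a))^2 + 1 / a^2)
}

# log prod_j a_j exp(a_j x_j) / (e^{a_j} - 1), rows of X
tilt_logdensity <- function(X, coef) {
  logc <- ifelse(abs(coef) < 1e-8, -coef / 2 + coef^2 / 24,
                 log(abs(coef)) - log(abs(expm1(coef))))
  drop(X %*% coef) + sum(logc)
}

# log of truncated-normal density on [0,1] per coordinate, summed
gauss_logdensity <- function(X, mean_k, var_k) {
  sd_k <- sqrt(var_k)
  z <- pmax(stats::pnorm((1 - mean_k) / sd_k) - stats::pnorm(-mean_k / sd_k),
            1e-12)
  out <- numeric(nrow(X))
  for (j in seq_along(mean_k)) {
    out <- out + stats::dnorm(X[, j], mean_k[j], sd_k[j], log = TRUE) - log(z[j])
  }
  out
}

component_logdensities <- function(cd, X) {
  K <- nrow(cd$means)
  L <- matrix(0, nrow(X), K + 1L)
  L[, 1] <- tilt_logdensity(X, cd$tilt_coef)
  for (k in seq_len(K)) {
    L[, k + 1L] <- gauss_logdensity(X, cd$means[k, ], cd$vars[k, ])
  }
  L
}

#' Evaluate a fitted covariate mixture density
#'
#' @param cd A `covariate_density` from [fit_density_em()].
#' @param X Numeric matrix of points in \[0, 1\]^d.
#' @return Vector of density values (integrating to 1 over the unit cube).
#' @export
density_eval <- function(cd, X) {
  X <- as.matrix(X)
  L <- component_logdensities(cd, X)
  lw <- sweep(L, 2, log(pmax(cd$weights, 1e-300)), "+")
  m <- apply(lw, 1, max)
  exp(m) * rowSums(exp(lw - m))
}

weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  xo <- x[ord]
  cw <- cumsum(w[ord]) / sum(w)
  xo[pmin(length(xo), findInterval(probs, cw) + 1L)]
}

uniform_density <- function(d, K) {
  structure(
    list(weights = c(1, rep(0, K)), tilt_coef = rep(0, d),
         means = matrix(0.5, K, d), vars = matrix(0.04, K, d),
         loglik_trace = numeric(0), converged = TRUE, uniform = TRUE),
    class = "covariate_density"
  )
}

#' Fit the covariate mixture density by weighted EM
#'
#' Fits a mixture of one exponential-tilt component and `K` truncated diagonal
#' Gaussians to weighted samples in the unit cube. Responsibilities are exact;
#' the Gaussian M-step uses weighted moments and the tilt coefficients are
#' updated by moment matching with 5 Newton steps per coordinate, so the
#' weighted log-likelihood is tracked every iteration and the fit stops (and
#' reverts) on any decrease beyond `tol`.
#'
#' Component means start at the weighted `(k - 0.5)/K` quantiles per
#' coordinate, variances at `0.2^2`, all mixture weights uniform.
#'
#' @param X Numeric m x d matrix with entries in \[0, 1\].
#' @param sample_weights Nonnegative weights, one per row; default uniform.
#' @param K Number of Gaussian components.
#' @param max_iter,tol EM stopping rule on the weighted log-likelihood.
#' @param seed Seed used only when `restarts > 0` to jitter the extra starts.
#' @param restarts Extra randomized starts; the best likelihood wins.
#' @return An object of class `covariate_density` with mixture `weights`
#'   (tilt first), `tilt_coef`, `means`, `vars`, and a `loglik_trace`.
#' @export
fit_density_em <- function(X, sample_weights = NULL, K = 5, max_iter = 100,
                           tol = 1e-4, seed = 0, restarts = 0) {
  X <- as.matrix(X)
  m <- nrow(X)
  d <- ncol(X)
  if (is.null(sample_weights)) sample_weights <- rep(1, m)
  if (length(sample_weights) != m || any(sample_weights < 0)) {
    stop("sample_weights must be nonnegative, one per row")
  }
  if (m < K + 1 || sum(sample_weights) <= 0 || d == 0L) {
    if (d > 0L) warning("too few points for EM: falling back to uniform density")
    return(uniform_density(d, K))
  }

  base_means <- matrix(0, K, d)
  for (j in seq_len(d)) {
    base_means[, j] <- weighted_quantile(X[, j], sample_weights,
                                         (seq_len(K) - 0.5) / K)
  }

  fits <- list(run_em(X, sample_weights, K, base_means, max_iter, tol))
  if (restarts > 0) {
    jitters <- with_seed(seed, replicate(restarts,
      matrix(stats::runif(K * d, -0.1, 0.1), K, d), simplify = FALSE))
    for (jt in jitters) {
      mns <- pmin(pmax(base_means + jt, 0), 1)
      fits <- c(fits, list(run_em(X, sample_weights, K, mns, max_iter, tol)))
    }
  }
  lls <- vapply(fits, function(f) {
    tr <- f$loglik_trace
    if (length(tr)) tr[length(tr)] else -Inf
  }, numeric(1))
  fits[[which.max(lls)]]
}

run_em <- function(X, w, K, means, max_iter, tol) {
  d <- ncol(X)
  cd <- structure(
    list(weights = rep(1 / (K + 1), K + 1), tilt_coef = rep(0, d),
         means = means, vars = matrix(0.04, K, d),
         loglik_trace = numeric(0), converged = FALSE, uniform = FALSE),
    class = "covariate_density"
  )
  wsum <- sum(w)
  prev <- cd
  ll_prev <- -Inf
  for (iter in seq_len(max_iter)) {
    L <- component_logdensities(cd, X)
    lw <- sweep(L, 2, log(pmax(cd$weights, 1e-300)), "+")
    mx <- apply(lw, 1, max)
    lse <- mx + log(rowSums(exp(lw - mx)))
    ll <- sum(w * lse)
    if (ll < ll_prev - tol) {         # safeguard: approximate M-step overshot
      cd <- prev
      break
    }
    cd$loglik_trace <- c(prev$loglik_trace, ll)
    if (is.finite(ll_prev) && ll - ll_prev < tol) {
      cd$converged <- TRUE
      break
    }
    prev <- cd
    ll_prev <- ll

    resp <- exp(lw - lse)             # m x (K+1)
    wr <- resp * w
    nk <- colSums(wr)
    cd$weights <- pmax(nk, 1e-10) / sum(pmax(nk, 1e-10))

    # tilt component: weighted moment matching, 5 Newton steps per coordinate
    if (nk[1] > 1e-8) {
      target <- drop(crossprod(wr[, 1], X)) / nk[1]
      target <- pmin(pmax(target, 0.001), 0.999)
      for (j in seq_len(d)) {
        a <- cd$tilt_coef[j]
        for (s in 1:5) {
          a <- a - (tilt_mean(a) - target[j]) / tilt_mean_deriv(a)
          a <- min(max(a, -50), 50)
        }
        cd$tilt_coef[j] <- a
      }
    }

    for (k in seq_len(K)) {
      if (nk[k + 1] <= 1e-8) next
      mu_k <- drop(crossprod(wr[, k + 1], X)) / nk[k + 1]
      dx2 <- sweep(X, 2, mu_k, "-")^2
      var_k <- drop(crossprod(wr[, k + 1], dx2)) / nk[k + 1]
      cd$means[k, ] <- pmin(pmax(mu_k, 0), 1)
      cd$vars[k, ] <- pmin(pmax(var_k, 1e-4), 10)
    }
  }
  cd
}

#' Initialize the decision threshold from the p-value ensembles
#'
#' Implements the initialization heuristic `t(x) proportional to
#' pi1(x)/pi0(x)`: (1) fit the covariate density of the proxy null ensemble
#' (`p >= 0.75`); (2) weight each proxy alternative (`p <= t_BH`) by
#' `1 / pi0_hat(x)`; (3) fit the weighted density; (4) map the fitted mixture
#' onto [threshold_params()] (Gaussian components become bumps with
#' `sigma = 1/(2 var)`, the tilt component becomes the GLM term), keeping only
#' relative amplitudes; (5) set the absolute scale by a rescale search
#' ([rescale_gamma()]) on the training fold so the estimated FDP there is at
#' most `alpha`.
#'
#' When the alternative ensemble is empty or has fewer than `10 * K` points,
#' the constant threshold `t = t_BH` is returned instead (degenerate
#' initialization; attribute `degenerate` is set).
#'
#' @param pvals Training-fold p-values.
#' @param Xnorm Training-fold normalized covariates (n x d in \[0, 1\]).
#' @param alpha Nominal FDP level.
#' @param K Number of Gaussian bumps.
#' @param seed Seed forwarded to the EM fits.
#' @param n_total Total hypothesis count backing the fold.
#' @param c0 Minimum discovery proportion for the scale search.
#' @return A [threshold_params()] object; attribute `degenerate` is TRUE for
#'   the constant-threshold fallback, and attribute `density` carries the
#'   fitted null/alternative densities otherwise.
#' @export
initialize_threshold <- function(pvals, Xnorm, alpha, K = 5, seed = 0,
                                 n_total = length(pvals), c0 = 1e-4) {
  Xnorm <- as.matrix(Xnorm)
  d <- ncol(Xnorm)
  ens <- build_ensembles(pvals, alpha, n_total)
  fallback <- function() {
    tp <- threshold_params(a = rep(0, d), b = log(max(ens$t_bh, 1e-10)))
    attr(tp, "degenerate") <- TRUE
    tp
  }
  if (length(ens$alt_idx) < 10 * K || d == 0L) return(fallback())

  pi0 <- fit_density_em(Xnorm[ens$null_idx, , drop = FALSE], K = K, seed = seed)
  Xalt <- Xnorm[ens$alt_idx, , drop = FALSE]
  w_alt <- 1 / pmax(density_eval(pi0, Xalt), 1e-10)
  pi1 <- fit_density_em(Xalt, sample_weights = w_alt, K = K, seed = seed)

  # mixture -> threshold: match the density's functional form term by term
  amp_tilt <- pi1$weights[1] * exp(tilt_logdensity(matrix(0, 1, d),
                                                   pi1$tilt_coef))
  a <- pi1$tilt_coef
  b <- log(max(amp_tilt, 1e-300))
  Kn <- nrow(pi1$means)
  w <- numeric(Kn); mu <- pi1$means; sg <- matrix(0, Kn, d)
  for (k in seq_len(Kn)) {
    amp_k <- pi1$weights[k + 1] *
      exp(gauss_logdensity(matrix(pi1$means[k, ], 1, d),
                           pi1$means[k, ], pi1$vars[k, ]))
    w[k] <- log(max(amp_k, 1e-300))
    sg[k, ] <- 1 / (2 * pi1$vars[k, ])
  }
  tp <- threshold_params(a = a, b = b, w = w, mu = mu, sigma = sg)

  # absolute scale: bring the raw density down to p-value scale, then search
  t_raw <- evaluate_threshold(tp, Xnorm, cap = Inf)
  shift <- log(max(ens$t_bh, 1e-10) / max(mean(t_raw), 1e-300))
  tp <- scale_threshold(tp, exp(shift))
  gr <- rescale_gamma(pvals, evaluate_threshold(tp, Xnorm, cap = 0.5),
                      alpha, c0 = c0, n_total = n_total)
  if (gr$gamma_star <= 0) return(fallback())
  tp <- scale_threshold(tp, gr$gamma_star)
  attr(tp, "degenerate") <- FALSE
  attr(tp, "density") <- list(pi0 = pi0, pi1 = pi1, t_bh = ens$t_bh)
  tp
}
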