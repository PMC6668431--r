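#' Numerically stable sigmoid
#'
#' @param z Numeric vector.
#' @return `1 / (1 + exp(-z))`, computed without overflow for large `|z|`.
#' @export
sigmoid <- function(z) {
  out <- numeric(length(z))
  pos <- z >= 0
  out[pos] <- 1 / (1 + exp(-z[pos]))
  ez <- exp(z[!pos])
  out[!pos] <- ez / (1 + ez)
  out
}

#' Sigmoid-smoothed discovery and mirror counts
#'
#' Replaces the indicator counts by their sigmoid relaxations
#' `D_smooth = sum S(lambda0 (t_i - p_i))` and
#' `FD_smooth = sum S(lambda0 (p_i - 1 + t_i))`, which converge to the exact
#' counts as `lambda0` grows.
#'
#' @param pvals,thresholds Equal-length numeric vectors.
#' @param lambda0 Positive smoothing sharpness.
#' @return List with `D` and `FD` (both real).
#' @export
smoothed_counts <- function(pvals, thresholds, lambda0) {
  if (lambda0 <= 0) stop("lambda0 must be > 0")
  list(D = sum(sigmoid(lambda0 * (thresholds - pvals))),
       FD = sum(sigmoid(lambda0 * (pvals - 1 + thresholds))))
}

#' Automatic smoothing sharpness
#'
#' Chooses `lambda0 = 10 / median(init_thresholds)` so the sigmoid transition
#' width (about `4 / lambda0` in p-value units) is at most 40% of the typical
#' threshold, then clamps to \[10, 1e6\].
#'
#' @param pvals Unused except for interface symmetry; the choice depends only
#'   on the initial thresholds.
#' @param init_thresholds Positive initial thresholds on the training fold.
#' @return The smoothing sharpness `lambda0`.
#' @export
select_lambda0 <- function(pvals, init_thresholds) {
  med <- stats::median(init_thresholds)
  if (!is.finite(med) || med <= 0) return(1e6)
  min(max(10 / med, 10), 1e6)
}

#' Configuration of the smoothed Lagrangian objective
#'
#' @param alpha Nominal FDP level.
#' @param lambda1 Constraint multiplier; default `10 / alpha`.
#' @param lambda0 Smoothing sharpness; `NULL` selects it automatically from
#'   the initial thresholds via [select_lambda0()].
#' @param n_iter Number of gradient steps (default 1500).
#' @param learning_rate Step size of the adaptive-moment updates.
#' @param seed Seed (kept for interface stability; the optimizer itself is
#'   deterministic).
#' @return An `objective_config` list.
#' @export
objective_config <- function(alpha, lambda1 = 10 / alpha, lambda0 = NULL,
                             n_iter = 1500, learning_rate = 0.01, seed = 0) {
  stopifnot(alpha > 0, alpha < 1, lambda1 > 0, n_iter >= 0, learning_rate > 0)
  if (!is.null(lambda0)) stopifnot(lambda0 > 0)
  structure(list(alpha = alpha, lambda1 = lambda1, lambda0 = lambda0,
                 n_iter = n_iter, learning_rate = learning_rate, seed = seed),
            class = "objective_config")
}

lagrangian_value <- function(D, FD, alpha, lambda1) {
  -D + lambda1 * max(FD - alpha * D, 0)
}

#' Smoothed Lagrangian objective for the threshold parameters
#'
#' Evaluates `-D_smooth + lambda1 * max(FD_smooth - alpha * D_smooth, 0)` at
#' the (capped) threshold induced by `params`. Minimizing this trades more
#' discoveries against the mirror-estimated FDP constraint.
#'
#' @param params A [threshold_params()] object.
#' @param pvals Training-fold p-values.
#' @param Xnorm Normalized training covariates.
#' @param cfg An [objective_config()]; `lambda0` must be set.
#' @return Scalar objective value.
#' @export
lagrangian_objective <- function(params, pvals, Xnorm, cfg) {
  if (is.null(cfg$lambda0)) stop("cfg$lambda0 must be set (see select_lambda0)")
  t <- evaluate_threshold(params, Xnorm, cap = 0.5)
  sc <- smoothed_counts(pvals, t, cfg$lambda0)
  lagrangian_value(sc$D, sc$FD, cfg$alpha, cfg$lambda1)
}

# pack/unpack the unconstrained parameter vector
# theta = (a, b, w, mu, rho) with sigma = exp(rho)
pack_params <- function(params) {
  c(params$a, params$b, params$w, as.numeric(params$mu),
    log(as.numeric(params$sigma)))
}

unpack_params <- function(theta, d, K) {
  i <- 0L
  a <- theta[seq_len(d)]; i <- d
  b <- theta[i + 1L]; i <- i + 1L
  w <- theta[i + seq_len(K)]; i <- i + K
  mu <- matrix(theta[i + seq_len(K * d)], K, d); i <- i + K * d
  sigma <- matrix(exp(theta[i + seq_len(K * d)]), K, d)
  threshold_params(a = a, b = b, w = w,
                   mu = if (K) mu else NULL,
                   sigma = if (K) sigma else NULL)
}

# objective and analytic gradient in one pass; the threshold cap contributes
# zero gradient (clip subgradient), as does the hinge exactly at its kink
objective_and_grad <- function(theta, pvals, X, d, K, cfg) {
  n <- length(pvals)
  a <- theta[seq_len(d)]
  b <- theta[d + 1L]
  w <- theta[d + 1L + seq_len(K)]
  mu <- matrix(theta[d + 1L + K + seq_len(K * d)], K, d)
  rho <- matrix(theta[d + 1L + K + K * d + seq_len(K * d)], K, d)
  sg <- exp(rho)

  eta <- if (d > 0L) drop(X %*% a) + b else rep(b, n)
  g <- exp(eta)
  t_raw <- g
  B <- matrix(0, n, K)
  for (k in seq_len(K)) {
    dx <- sweep(X, 2, mu[k, ], "-")
    q <- drop(dx^2 %*% sg[k, ])
    B[, k] <- exp(w[k] - q)
    t_raw <- t_raw + B[, k]
  }
  capped <- t_raw >= 0.5
  t <- pmin(pmax(t_raw, 1e-300), 0.5)

  l0 <- cfg$lambda0
  sD <- sigmoid(l0 * (t - pvals))
  sF <- sigmoid(l0 * (pvals - 1 + t))
  Ds <- sum(sD); Fs <- sum(sF)
  hinge <- Fs - cfg$alpha * Ds
  obj <- -Ds + cfg$lambda1 * max(hinge, 0)

  mult <- if (hinge > 0) cfg$lambda1 else 0
  # dL/dt_i, zeroed where the cap is active
  dD_dt <- l0 * sD * (1 - sD)
  dF_dt <- l0 * sF * (1 - sF)
  dL_dt <- -dD_dt + mult * (dF_dt - cfg$alpha * dD_dt)
  dL_dt[capped] <- 0

  gb <- sum(dL_dt * g)
  ga <- if (d > 0L) drop(crossprod(X, dL_dt * g)) else numeric(0)
  gw <- numeric(K)
  gmu <- matrix(0, K, d)
  grho <- matrix(0, K, d)
  for (k in seq_len(K)) {
    vb <- dL_dt * B[, k]
    gw[k] <- sum(vb)
    dx <- sweep(X, 2, mu[k, ], "-")
    gmu[k, ] <- drop(crossprod(dx, vb)) * 2 * sg[k, ]
    grho[k, ] <- -drop(crossprod(dx^2, vb)) * sg[k, ]
  }
  list(obj = obj,
       grad = c(ga, gb, gw, as.numeric(gmu), as.numeric(grho)))
}

#' Refine the threshold by adaptive-moment gradient descent
#'
#' Minimizes the sigmoid-smoothed Lagrangian over the unconstrained
#' parameterization (scales stored as `log(sigma)` so positivity is
#' preserved), using adaptive-moment updates (decay 0.9/0.999, epsilon 1e-8)
#' for `cfg$n_iter` steps, and returns the iterate with the best objective
#' seen. A non-finite objective reverts to the initialization with a warning.
#'
#' @param init Initial [threshold_params()] (from [initialize_threshold()]).
#' @param pvals Training-fold p-values.
#' @param Xnorm Normalized training covariates.
#' @param cfg An [objective_config()]. A `NULL` `lambda0` is selected
#'   automatically from the initial thresholds.
#' @return The refined [threshold_params()], with attribute `objective_trace`.
#' @export
optimize_threshold <- function(init, pvals, Xnorm, cfg) {
  X <- as.matrix(Xnorm)
  d <- init$d
  K <- init$K
  if (is.null(cfg$lambda0)) {
    cfg$lambda0 <- select_lambda0(pvals, evaluate_threshold(init, X, cap = 0.5))
  }
  if (cfg$n_iter == 0L) return(init)

  theta <- pack_params(init)
  mth <- numeric(length(theta))
  vth <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best_theta <- theta
  best_obj <- objective_and_grad(theta, pvals, X, d, K, cfg)$obj
  trace <- numeric(cfg$n_iter)

  for (it in seq_len(cfg$n_iter)) {
    og <- objective_and_grad(theta, pvals, X, d, K, cfg)
    trace[it] <- og$obj
    if (!is.finite(og$obj) || any(!is.finite(og$grad))) {
      warning("non-finite objective during optimization: reverting to init")
      return(init)
    }
    if (og$obj < best_obj) {
      best_obj <- og$obj
      best_theta <- theta
    }
    mth <- b1 * mth + (1 - b1) * og$grad
    vth <- b2 * vth + (1 - b2) * og$grad^2
    mhat <- mth / (1 - b1^it)
    vhat <- vth / (1 - b2^it)
    theta <- theta - cfg$learning_rate * mhat / (sqrt(vhat) + eps)
  }
  out <- unpack_params(best_theta, d, K)
  attr(out, "objective_trace") <- trace
  attr(out, "lambda0") <- cfg$lambda0
  out
}
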