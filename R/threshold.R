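#' Parameters of the covariate-dependent rejection threshold
#'
#' The decision threshold combines a log-linear (GLM) term with `K` Gaussian
#' bumps with diagonal scales:
#' \deqn{t(x) = \exp(a^T x + b) + \sum_{k=1}^K \exp[w_k - (x-\mu_k)^T
#'   \mathrm{diag}(\sigma_k) (x-\mu_k)]}
#' The GLM term captures global monotone ("slope") structure, the bumps local
#' enrichment. Both terms are positive, so `t(x) > 0` everywhere; evaluation
#' caps the threshold at 0.5 to keep the rejection region disjoint from the
#' mirrored region used for false-discovery estimation.
#'
#' @param a Numeric d-vector of GLM slopes.
#' @param b Scalar GLM offset (log scale).
#' @param w Numeric K-vector of log bump amplitudes (may be length 0).
#' @param mu K x d matrix of bump centers.
#' @param sigma K x d matrix of strictly positive inverse squared scales.
#' @return An object of class `threshold_params`.
#' @export
#' @examples
#' tp <- threshold_params(a = 0, b = log(0.1))
#' evaluate_threshold(tp, matrix(runif(5)))
threshold_params <- function(a, b, w = numeric(0), mu = NULL, sigma = NULL) {
  a <- as.numeric(a)
  d <- length(a)
  K <- length(w)
  if (K == 0L) {
    mu <- matrix(0, 0, d)
    sigma <- matrix(0, 0, d)
  } else {
    mu <- matrix(as.numeric(mu), K, d)
    sigma <- matrix(as.numeric(sigma), K, d)
    if (any(sigma <= 0)) stop("all sigma entries must be > 0")
  }
  structure(list(a = a, b = as.numeric(b)[1], K = K, w = as.numeric(w),
                 mu = mu, sigma = sigma, d = d),
            class = "threshold_params")
}

#' Evaluate the decision threshold at covariate positions
#'
#' @param params A [threshold_params()] object.
#' @param X Numeric n x d matrix of (normalized) covariates.
#' @param cap Upper cap applied to the threshold; default 0.5. Use `Inf` for
#'   the raw, uncapped value.
#' @return Numeric vector of strictly positive thresholds `t(x_i)`.
#' @export
evaluate_threshold <- function(params, X, cap = 0.5) {
  X <- as.matrix(X)
  if (ncol(X) != params$d) {
    stop("X has ", ncol(X), " columns but params expect d = ", params$d)
  }
  eta <- if (params$d > 0L) drop(X %*% params$a) + params$b else
    rep(params$b, nrow(X))
  t <- exp(eta)
  for (k in seq_len(params$K)) {
    dx <- sweep(X, 2, params$mu[k, ], "-")
    q <- drop(dx^2 %*% params$sigma[k, ])
    t <- t + exp(params$w[k] - q)
  }
  pmin(pmax(t, 1e-300), cap)
}

#' Multiply a threshold by a positive factor
#'
#' Rescaling by `gamma` is absorbed into the parameters: `b' = b + log(gamma)`
#' and `w' = w + log(gamma)`, so `evaluate_threshold(scale_threshold(p, g), X)`
#' equals `g * evaluate_threshold(p, X)` (before capping).
#'
#' @param params A [threshold_params()] object.
#' @param gamma Positive scale factor.
#' @return A rescaled `threshold_params` object.
#' @export
scale_threshold <- function(params, gamma) {
  if (gamma <= 0) stop("gamma must be > 0")
  params$b <- params$b + log(gamma)
  params$w <- params$w + log(gamma)
  params
}

#' Serialize threshold parameters to JSON
#'
#' @param params A [threshold_params()] object.
#' @return A JSON string; invert with [threshold_from_json()].
#' @export
threshold_to_json <- function(params) {
  jsonlite::toJSON(
    list(a = params$a, b = params$b, w = params$w,
         mu = params$mu, sigma = params$sigma),
    digits = NA, matrix = "rowmajor"
  )
}

#' @rdname threshold_to_json
#' @param json A JSON string produced by [threshold_to_json()].
#' @export
threshold_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  K <- length(x$w)
  d <- length(x$a)
  threshold_params(
    a = x$a, b = x$b, w = x$w,
    mu = if (K) matrix(x$mu, K, d, byrow = FALSE) else NULL,
    sigma = if (K) matrix(x$sigma, K, d, byrow = FALSE) else NULL
  )
}

#' @export
print.threshold_params <- function(x, ...) {
  cat(sprintf("threshold_params: d = %d, K = %d, b = %.3f\n", x$d, x$K, x$b))
  invisible(x)
}
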