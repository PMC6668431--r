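#' Configuration for the synthetic testing-data generator
#'
#' The generator emulates covariate-dependent enrichment of alternatives: a
#' global monotone "slope" and/or local Gaussian "bumps" in the probability
#' `pi1(x)` that a hypothesis with covariate `x` is a true alternative.
#' Null p-values are uniform (marginally, also under the dependence modes);
#' alternative p-values follow a Beta law concentrated near zero.
#'
#' @param n Number of hypotheses.
#' @param d Covariate dimension; covariates are drawn uniformly on \[0,1\]^d.
#' @param pi1_fun Function mapping an n x d covariate matrix to alternative
#'   probabilities in \[0, 1\]. Default: slope-free single bump
#'   `0.02 + 0.15 exp(-(x1 - 0.8)^2 / 0.02)`.
#' @param alt_shape1,alt_shape2 Shape parameters of the Beta alternative
#'   p-value law (default Beta(0.3, 4), stochastically smaller than uniform).
#' @param dependence `"none"` for independent nulls, `"weak"` for
#'   block-equicorrelated null z-scores (block size 10, rho = 0.3), `"strong"`
#'   (block size 100, rho = 0.8). Marginals stay uniform.
#' @param uninformative If `TRUE`, labels are drawn with the mean of
#'   `pi1_fun` regardless of the covariate, making the covariate useless.
#' @param seed Integer seed; identical configurations give identical data.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n = 5000, d = 1,
                              pi1_fun = function(X)
                                0.02 + 0.15 * exp(-(X[, 1] - 0.8)^2 / 0.02),
                              alt_shape1 = 0.3, alt_shape2 = 4,
                              dependence = c("none", "weak", "strong"),
                              uninformative = FALSE, seed = 0) {
  dependence <- match.arg(dependence)
  stopifnot(n >= 1, d >= 1, alt_shape1 > 0, alt_shape2 > 0)
  structure(list(n = n, d = d, pi1_fun = pi1_fun,
                 alt_shape1 = alt_shape1, alt_shape2 = alt_shape2,
                 dependence = dependence, uninformative = uninformative,
                 seed = seed),
            class = "simulation_config")
}

#' Named simulation scenarios
#'
#' Presets covering the study conditions of the simulation suite:
#' \describe{
#'   \item{informative}{d = 1, `pi1(x) = 0.02 + 0.15 exp(-(x-0.8)^2/0.02)` —
#'     small-p enrichment at high covariate values.}
#'   \item{uninformative}{same marginal alternative rate, labels independent
#'     of the covariate.}
#'   \item{all_null}{`pi1 = 0`: every hypothesis null, uniform p-values.}
#'   \item{weak_dep}{informative signal with weakly dependent nulls
#'     (block 10, rho 0.3).}
#'   \item{strong_dep}{informative signal with strongly dependent nulls
#'     (block 100, rho 0.8).}
#'   \item{multi_d}{d = 2 with a bump at (0.8, 0.8) over a small slope.}
#' }
#'
#' @param name Scenario name.
#' @param n Number of hypotheses.
#' @param seed Integer seed.
#' @return A [simulation_config()].
#' @export
simulation_scenario <- function(name = c("informative", "uninformative",
                                         "all_null", "weak_dep", "strong_dep",
                                         "multi_d"),
                                n = 5000, seed = 0) {
  name <- match.arg(name)
  bump1 <- function(X) 0.02 + 0.15 * exp(-(X[, 1] - 0.8)^2 / 0.02)
  switch(name,
    informative = simulation_config(n = n, d = 1, pi1_fun = bump1, seed = seed),
    uninformative = simulation_config(n = n, d = 1, pi1_fun = bump1,
                                      uninformative = TRUE, seed = seed),
    all_null = simulation_config(n = n, d = 1,
                                 pi1_fun = function(X) rep(0, nrow(X)),
                                 seed = seed),
    weak_dep = simulation_config(n = n, d = 1, pi1_fun = bump1,
                                 dependence = "weak", seed = seed),
    strong_dep = simulation_config(n = n, d = 1, pi1_fun = bump1,
                                   dependence = "strong", seed = seed),
    multi_d = simulation_config(n = n, d = 2, pi1_fun = function(X)
      0.02 + 0.15 * exp(-((X[, 1] - 0.8)^2 + (X[, 2] - 0.8)^2) / 0.02),
      seed = seed)
  )
}

dependence_params <- function(dependence) {
  switch(dependence,
         none = NULL,
         weak = list(block = 10L, rho = 0.3),
         strong = list(block = 100L, rho = 0.8))
}

#' Generate a synthetic hypothesis set with known ground truth
#'
#' Draws covariates uniformly on the unit cube, labels from
#' `Bernoulli(pi1(x))` (or the covariate-free mean rate when uninformative),
#' null p-values uniform — under dependence, as `Phi(z)` of
#' block-equicorrelated Gaussians, which preserves uniform marginals — and
#' alternative p-values from the configured Beta law.
#'
#' @param cfg A [simulation_config()].
#' @return A [hypothesis_set()] with labels.
#' @export
simulate_testing_data <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$seed, {
    n <- cfg$n
    X <- matrix(stats::runif(n * cfg$d), n, cfg$d)
    pi1 <- pmin(pmax(cfg$pi1_fun(X), 0), 1)
    h <- if (cfg$uninformative) {
      stats::rbinom(n, 1L, mean(pi1))
    } else {
      stats::rbinom(n, 1L, pi1)
    }
    dp <- dependence_params(cfg$dependence)
    p <- if (is.null(dp)) {
      stats::runif(n)
    } else {
      n_block <- ceiling(n / dp$block)
      shared <- rep(stats::rnorm(n_block), each = dp$block)[seq_len(n)]
      z <- sqrt(dp$rho) * shared + sqrt(1 - dp$rho) * stats::rnorm(n)
      stats::pnorm(z)
    }
    alt <- h == 1L
    p[alt] <- stats::rbeta(sum(alt), cfg$alt_shape1, cfg$alt_shape2)
    covs <- as.data.frame(X)
    names(covs) <- paste0("x", seq_len(cfg$d))
    hypothesis_set(pvals = p, covariates = covs,
                   kinds = rep("numeric", cfg$d), labels = h)
  })
}

#' Realized FDP and power of a discovery result
#'
#' @param result A `discovery_result` from [cov_fdr()], or a logical/0-1
#'   rejection vector.
#' @param labels 0/1 ground-truth labels (1 = true alternative).
#' @return List with `fdp` (rejected nulls over rejections, 0 when nothing is
#'   rejected) and `power` (rejected alternatives over total alternatives).
#' @export
evaluate_fdp_power <- function(result, labels) {
  if (is.null(labels)) stop("ground-truth labels are required")
  rejected <- if (inherits(result, "discovery_result")) result$rejected
              else as.logical(result)
  if (length(rejected) != length(labels)) {
    stop("rejections and labels must have equal length")
  }
  D <- sum(rejected)
  list(fdp = sum(rejected & labels == 0L) / max(D, 1),
       power = sum(rejected & labels == 1L) / max(sum(labels == 1L), 1))
}
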