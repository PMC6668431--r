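#' Randomly split hypotheses into two balanced folds
#'
#' @param n Number of hypotheses (at least 2).
#' @param seed Integer seed; the assignment is reproducible given the seed.
#' @return An object of class `fold_assignment` with `fold_of` (n-vector in
#'   \{1, 2\}, sizes differing by at most one) and `seed`.
#' @export
split_folds <- function(n, seed = 0) {
  if (n < 2) stop("need at least 2 hypotheses to split")
  fold_of <- integer(n)
  perm <- with_seed(seed, sample.int(n))
  fold_of[perm] <- rep(c(1L, 2L), length.out = n)
  structure(list(fold_of = fold_of, seed = seed), class = "fold_assignment")
}

#' Covariate-adaptive multiple testing with FDP control
#'
#' Learns a covariate-dependent p-value threshold and reports discoveries
#' while controlling the false discovery proportion at level `alpha` via
#' two-fold cross-fitting. For each ordered fold pair, the procedure:
#' normalizes covariates on the training fold (transforms frozen and applied
#' to the test fold), initializes the threshold from the p-value ensembles by
#' weighted EM ([initialize_threshold()]), optionally refines it by gradient
#' descent on the smoothed objective ([optimize_threshold()]; skipped when
#' `fast = TRUE`), evaluates the learned threshold on the test fold, rescales
#' it by the largest factor keeping the mirror-estimated FDP at or below
#' `alpha` with at least `c0 * N` discoveries ([rescale_gamma()]), and rejects
#' test-fold hypotheses below the rescaled threshold. Discoveries are the
#' union over both folds.
#'
#' At least 100 hypotheses are required; below 10,000 the mirror estimate is
#' noisy and the fast variant is recommended (a warning says so). For
#' pre-filtered input (`n_original > n` with `filter_range` set), the applied
#' thresholds are checked post hoc against the filtering bounds.
#'
#' @param hs A [hypothesis_set()].
#' @param alpha Nominal FDP level in (0, 1).
#' @param K Number of Gaussian bumps in the threshold model.
#' @param n_iter Gradient steps for the refinement stage.
#' @param c0 Minimum discovery proportion per fold.
#' @param seed Integer seed controlling the fold split (and any EM restarts).
#' @param fast If `TRUE`, skip the gradient refinement (EM-only variant).
#' @param lambda0 Optional smoothing sharpness override.
#' @return An object of class `discovery_result`: `rejected` (logical
#'   n-vector), `applied_threshold` (the rescaled threshold each hypothesis
#'   was tested against; 0 on folds with no admissible rescale factor),
#'   `fold_of`, `folds` (per-fold parameters, rescale result and counts),
#'   `alpha`, `mode`, `seed`, `n_discoveries`, and the overall `fdp_hat`.
#' @export
#' @examples
#' hs <- simulate_testing_data(simulation_scenario("informative", n = 2000))
#' res <- cov_fdr(hs, alpha = 0.1, fast = TRUE)
#' res$n_discoveries
cov_fdr <- function(hs, alpha = 0.1, K = 5, n_iter = 1500, c0 = 1e-4,
                    seed = 0, fast = FALSE, lambda0 = NULL) {
  stopifnot(inherits(hs, "hypothesis_set"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  n <- hs$n
  if (n < 100) {
    stop("only ", n, " hypotheses: the mirror-based FDP estimate needs many ",
         "hypotheses (>= 10,000 recommended; 100 is the hard floor)")
  }
  if (n < 1e4 && !fast) {
    warning("fewer than 10,000 hypotheses: the fast (EM-only) variant is ",
            "the recommended, more robust choice at this size")
  }

  fa <- split_folds(n, seed)
  rejected <- logical(n)
  applied <- numeric(n)
  folds <- list()

  for (train_fold in 1:2) {
    test_fold <- 3L - train_fold
    tr <- which(fa$fold_of == train_fold)
    te <- which(fa$fold_of == test_fold)
    n_total_tr <- max(length(tr), round(hs$n_original * length(tr) / n))
    n_total_te <- max(length(te), round(hs$n_original * length(te) / n))

    hs_tr <- subset_hypotheses(hs, tr, n_original = n_total_tr)
    norm <- normalize_covariates(hs_tr, alpha = alpha)
    X_tr <- norm$values
    X_te <- apply_normalization(norm$transforms,
                                hs$covariates[te, , drop = FALSE])

    init <- initialize_threshold(hs$pvals[tr], X_tr, alpha, K = K,
                                 seed = seed, n_total = n_total_tr, c0 = c0)
    params <- init
    if (!fast && n_iter > 0 && !isTRUE(attr(init, "degenerate"))) {
      cfg <- objective_config(alpha, lambda0 = lambda0, n_iter = n_iter,
                              seed = seed)
      params <- optimize_threshold(init, hs$pvals[tr], X_tr, cfg)
    }

    t_star <- evaluate_threshold(params, X_te, cap = 0.5)
    gr <- rescale_gamma(hs$pvals[te], t_star, alpha, c0 = c0,
                        n_total = n_total_te)
    if (gr$gamma_star > 0) {
      applied[te] <- pmin(gr$gamma_star * t_star, 0.5)
      rejected[te] <- hs$pvals[te] <= applied[te]
    } else {
      applied[te] <- 0
      rejected[te] <- FALSE
    }

    folds[[test_fold]] <- list(
      params = params, gamma = gr,
      counts = fdp_hat(hs$pvals[te], applied[te],
                       labels = if (!is.null(hs$labels)) hs$labels[te]),
      train_idx = tr, test_idx = te, degenerate_init = attr(init, "degenerate")
    )
  }

  if (hs$n_original > n && !is.null(hs$filter_range)) {
    lo <- hs$filter_range[1]; hi <- hs$filter_range[2]
    if (any(applied > 0) &&
        (max(applied) >= lo || max(applied) >= 1 - hi)) {
      stop("filtered-input violation: an applied threshold reaches into the ",
           "removed p-value band (", lo, ", ", hi, "); rerun on unfiltered data")
    }
  }

  structure(
    list(rejected = rejected, applied_threshold = applied,
         fold_of = fa$fold_of, folds = folds, alpha = alpha,
         mode = if (fast) "fast" else "full", seed = seed,
         n_discoveries = sum(rejected),
         fdp_hat = fdp_hat(hs$pvals, applied,
                           labels = hs$labels)),
    class = "discovery_result"
  )
}

#' EM-only fast variant of the covariate-adaptive procedure
#'
#' Identical to [cov_fdr()] with the gradient refinement skipped: the
#' EM-derived initialization goes straight to the rescale search. Recommended
#' for fewer than 10,000 hypotheses, few expected discoveries, or p-value
#' inflation at 1.
#'
#' @inheritParams cov_fdr
#' @return A `discovery_result`, see [cov_fdr()].
#' @export
cov_fdr_fast <- function(hs, alpha = 0.1, K = 5, c0 = 1e-4, seed = 0) {
  cov_fdr(hs, alpha = alpha, K = K, c0 = c0, seed = seed, fast = TRUE)
}

#' @export
print.discovery_result <- function(x, ...) {
  cat(sprintf("covariate-adaptive testing (%s mode, alpha = %g, seed = %d)\n",
              x$mode, x$alpha, x$seed))
  cat(sprintf("discoveries: %d of %d hypotheses\n",
              x$n_discoveries, length(x$rejected)))
  for (f in seq_along(x$folds)) {
    fd <- x$folds[[f]]
    cat(sprintf("  fold %d: gamma* = %.3g, D = %d, FDP_hat = %.4f%s\n",
                f, fd$gamma$gamma_star, fd$counts$D, fd$counts$FDP_hat,
                if (isTRUE(fd$degenerate_init)) " (constant-threshold init)" else ""))
  }
  invisible(x)
}

#' Summarize a discovery result as JSON
#'
#' @param result A `discovery_result` from [cov_fdr()].
#' @param n,d Optional problem dimensions to include.
#' @return A JSON string with n, alpha, mode, seed, per-fold gamma*,
#'   discovery counts, estimated FDP, and the serialized threshold
#'   parameters.
#' @export
discovery_summary_json <- function(result, n = length(result$rejected),
                                   d = NULL) {
  per_fold <- lapply(result$folds, function(f) {
    list(gamma_star = f$gamma$gamma_star, D = f$counts$D,
         FD_hat = f$counts$FD_hat, FDP_hat = f$counts$FDP_hat,
         params = jsonlite::fromJSON(threshold_to_json(f$params),
                                     simplifyMatrix = FALSE))
  })
  jsonlite::toJSON(
    list(n = n, d = d, alpha = result$alpha, mode = result$mode,
         seed = result$seed, n_discoveries = result$n_discoveries,
         FDP_hat = result$fdp_hat$FDP_hat, folds = per_fold),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
}
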