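#' Normalize covariates to the unit cube
#'
#' The threshold model works on a common numeric domain, so every covariate is
#' mapped to \[0, 1\]. Numeric columns are mapped by empirical rank (average
#' rank for ties, scaled by `1/(n - 1)`), which is robust to heavy tails and
#' invariant to monotone transforms. Categorical columns are embedded at
#' equally spaced points ordered by the category's alternative/null enrichment
#' ratio, estimated from the p-value ensembles of [build_ensembles()] with
#' add-one smoothing, so categories enriched for small p-values land higher on
#' \[0, 1\]. A constant column maps to 0.5 everywhere.
#'
#' The fitted transforms can be re-applied to new data (e.g. the held-out fold
#' of the cross-fitting procedure) with [apply_normalization()]; numeric
#' values between training knots are interpolated, values outside the training
#' range are clamped, and unseen categories map to 0.5.
#'
#' @param hs A [hypothesis_set()].
#' @param alpha Level used for the BH threshold defining the alternative
#'   ensemble for categorical ordering.
#' @return An object of class `normalized_covariates` with `values` (n x d
#'   matrix in \[0, 1\]) and `transforms` (per-column recipes).
#' @export
normalize_covariates <- function(hs, alpha = 0.1) {
  d <- hs$d
  transforms <- vector("list", d)
  names(transforms) <- names(hs$covariates)
  for (j in seq_len(d)) {
    col <- hs$covariates[[j]]
    transforms[[j]] <- if (hs$kinds[j] == "numeric") {
      fit_rank_transform(col)
    } else {
      fit_category_transform(col, hs$pvals, alpha, hs$n_original)
    }
  }
  transforms <- structure(transforms, class = "covariate_transforms")
  structure(
    list(values = apply_normalization(transforms, hs$covariates),
         transforms = transforms),
    class = "normalized_covariates"
  )
}

fit_rank_transform <- function(x) {
  ux <- sort(unique(x))
  if (length(ux) == 1L) {
    return(list(type = "constant"))
  }
  n <- length(x)
  r <- rank(x, ties.method = "average")
  y <- (r - 1) / (n - 1)
  # one normalized value per unique raw value (ties share an average rank)
  uy <- y[match(ux, x)]
  list(type = "rank", knots_x = ux, knots_y = uy)
}

fit_category_transform <- function(x, pvals, alpha, n_total) {
  x <- as.character(x)
  cats <- sort(unique(x))
  L <- length(cats)
  if (L == 1L) return(list(type = "constant"))
  ens <- build_ensembles(pvals, alpha, n_total)
  n0 <- table(factor(x[ens$null_idx], levels = cats))
  n1 <- table(factor(x[ens$alt_idx], levels = cats))
  pi0 <- (as.numeric(n0) + 1) / (sum(n0) + L)
  pi1 <- (as.numeric(n1) + 1) / (sum(n1) + L)
  ratio <- pi1 / pi0
  ord <- order(ratio, cats)           # ties broken by name for determinism
  pos <- numeric(L)
  pos[ord] <- seq(0, 1, length.out = L)
  names(pos) <- cats
  list(type = "category", positions = pos, ratio = stats::setNames(ratio, cats))
}

#' Apply fitted covariate transforms to new data
#'
#' @param transforms The `transforms` element of a [normalize_covariates()]
#'   result (or the result itself).
#' @param covariates Data frame with the same columns as the training data.
#' @return Numeric matrix with entries in \[0, 1\].
#' @export
apply_normalization <- function(transforms, covariates) {
  if (inherits(transforms, "normalized_covariates")) {
    transforms <- transforms$transforms
  }
  n <- nrow(covariates)
  d <- length(transforms)
  out <- matrix(0.5, nrow = n, ncol = d,
                dimnames = list(NULL, names(transforms)))
  for (j in seq_len(d)) {
    tr <- transforms[[j]]
    col <- covariates[[names(transforms)[j]]]
    out[, j] <- switch(tr$type,
      constant = rep(0.5, n),
      rank = stats::approx(tr$knots_x, tr$knots_y, xout = as.numeric(col),
                           rule = 2, ties = "ordered")$y,
      category = {
        v <- tr$positions[as.character(col)]
        v[is.na(v)] <- 0.5
        unname(v)
      },
      stop("unknown transform type")
    )
  }
  out
}
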