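#' Covariate diagnostics: null versus alternative covariate distributions
#'
#' Estimates, for each covariate, the covariate distribution of the proxy
#' null ensemble (`p >= 0.75`) and the proxy alternative ensemble
#' (`p <= t_BH`), the same ensembles used to initialize the threshold. For
#' numeric covariates a Gaussian kernel density with Scott's-rule bandwidth is
#' evaluated on a 256-point grid spanning the observed range; for categorical
#' covariates category frequencies with add-one smoothing are reported, with
#' categories ordered by decreasing alternative/null ratio. A covariate with
#' an empty ensemble is flagged unavailable.
#'
#' The ratio of the two curves is, up to a constant, the odds that a
#' hypothesis at that covariate value is a true alternative — covariate
#' values where the alternative curve exceeds the null curve are where an
#' adaptive threshold gains power.
#'
#' @param hs A [hypothesis_set()].
#' @param alpha Level for the BH threshold defining the alternative ensemble.
#' @return An object of class `explore_result`: `t_bh`, ensemble sizes, and
#'   one entry per covariate — numeric: `grid`, `pi0_curve`, `pi1_curve`;
#'   categorical: `categories` (ordered by decreasing ratio), `pi0`, `pi1`,
#'   `ratio`.
#' @export
explore_covariates <- function(hs, alpha = 0.1) {
  ens <- build_ensembles(hs$pvals, alpha, hs$n_original)
  n0 <- length(ens$null_idx)
  n1 <- length(ens$alt_idx)
  out <- list(t_bh = ens$t_bh, n_null = n0, n_alt = n1,
              covariates = vector("list", hs$d))
  names(out$covariates) <- names(hs$covariates)
  for (j in seq_len(hs$d)) {
    col <- hs$covariates[[j]]
    if (n0 == 0L || n1 == 0L) {
      out$covariates[[j]] <- list(kind = hs$kinds[j], available = FALSE)
      next
    }
    out$covariates[[j]] <- if (hs$kinds[j] == "numeric") {
      explore_numeric(col, ens)
    } else {
      explore_categorical(col, ens)
    }
  }
  structure(out, class = "explore_result")
}

explore_numeric <- function(x, ens) {
  rng <- range(x)
  grid <- seq(rng[1], rng[2], length.out = 256)
  kde <- function(v) {
    if (length(unique(v)) < 2L) return(rep(NA_real_, 256))
    y <- stats::density(v, bw = stats::bw.nrd(v), from = rng[1], to = rng[2],
                        n = 256)$y
    # renormalize: kernel mass smeared beyond the observed range is folded
    # back so the curve is a proper density over the grid
    dx <- (rng[2] - rng[1]) / 255
    y / (sum((y[-1] + y[-256]) / 2) * dx)
  }
  list(kind = "numeric", available = TRUE, grid = grid,
       pi0_curve = kde(x[ens$null_idx]),
       pi1_curve = kde(x[ens$alt_idx]))
}

explore_categorical <- function(x, ens) {
  x <- as.character(x)
  cats <- sort(unique(x))
  L <- length(cats)
  n0 <- table(factor(x[ens$null_idx], levels = cats))
  n1 <- table(factor(x[ens$alt_idx], levels = cats))
  pi0 <- (as.numeric(n0) + 1) / (sum(n0) + L)
  pi1 <- (as.numeric(n1) + 1) / (sum(n1) + L)
  ratio <- pi1 / pi0
  ord <- order(-ratio, cats)
  list(kind = "categorical", available = TRUE,
       categories = cats[ord],
       pi0 = stats::setNames(pi0[ord], cats[ord]),
       pi1 = stats::setNames(pi1[ord], cats[ord]),
       ratio = stats::setNames(ratio[ord], cats[ord]))
}

#' Write exploration results to CSV files
#'
#' One file per covariate (`<prefix>_<name>.csv`: grid and density curves for
#' numeric covariates, per-category probabilities and ratio for categorical
#' ones) plus `<prefix>_summary.csv` with the ensemble sizes and category
#' orderings.
#'
#' @param ex An [explore_covariates()] result.
#' @param prefix Output path prefix.
#' @return Character vector of written paths, invisibly.
#' @export
write_explore_csv <- function(ex, prefix) {
  paths <- character(0)
  for (nm in names(ex$covariates)) {
    cv <- ex$covariates[[nm]]
    if (!isTRUE(cv$available)) next
    path <- paste0(prefix, "_", nm, ".csv")
    if (cv$kind == "numeric") {
      utils::write.csv(data.frame(grid = cv$grid, pi0 = cv$pi0_curve,
                                  pi1 = cv$pi1_curve),
                       path, row.names = FALSE)
    } else {
      utils::write.csv(data.frame(category = cv$categories, pi0 = cv$pi0,
                                  pi1 = cv$pi1, ratio = cv$ratio),
                       path, row.names = FALSE)
    }
    paths <- c(paths, path)
  }
  spath <- paste0(prefix, "_summary.csv")
  utils::write.csv(
    data.frame(t_bh = ex$t_bh, n_null = ex$n_null, n_alt = ex$n_alt),
    spath, row.names = FALSE)
  invisible(c(paths, spath))
}

#' Stratified p-value histogram diagnostic
#'
#' Bins a numeric covariate into equal-count strata and tabulates the p-value
#' histogram within each stratum. A flat histogram away from zero in every
#' stratum is consistent with the assumption that the covariate carries no
#' information under the null.
#'
#' @param hs A [hypothesis_set()].
#' @param covariate Name of a numeric covariate column.
#' @param n_strata Number of equal-count covariate bins.
#' @param breaks P-value histogram breaks.
#' @return Data frame with `stratum`, `p_lo`, `p_hi`, `count`; counts within
#'   each stratum sum to the stratum size.
#' @export
stratified_pvalue_histogram <- function(hs, covariate, n_strata = 5,
                                        breaks = seq(0, 1, by = 0.05)) {
  x <- hs$covariates[[covariate]]
  if (is.null(x) || !is.numeric(x)) stop("'", covariate, "' must be numeric")
  qs <- stats::quantile(x, probs = seq(0, 1, length.out = n_strata + 1))
  stratum <- cut(x, breaks = unique(qs), include.lowest = TRUE,
                 labels = FALSE)
  out <- do.call(rbind, lapply(sort(unique(stratum)), function(s) {
    counts <- hist(hs$pvals[stratum == s], breaks = breaks, plot = FALSE)$counts
    data.frame(stratum = s, p_lo = breaks[-length(breaks)], p_hi = breaks[-1],
               count = counts)
  }))
  rownames(out) <- NULL
  out
}
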