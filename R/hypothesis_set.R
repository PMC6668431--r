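#' Construct a set of hypotheses with p-values and covariates
#'
#' A `hypothesis_set` bundles everything the testing procedures need: one
#' p-value per hypothesis, an optional table of per-hypothesis covariates
#' (numeric or categorical), optional ground-truth labels (simulation only),
#' and the original number of hypotheses for pre-filtered inputs.
#'
#' @param pvals Numeric vector of p-values, all in \[0, 1\], no missing values.
#' @param covariates Optional data frame with one row per hypothesis. Columns
#'   may be numeric or categorical (factor/character).
#' @param kinds Optional character vector, one of `"numeric"` or
#'   `"categorical"` per covariate column. When omitted, numeric columns with
#'   more than 20 distinct values are treated as numeric and everything else
#'   as categorical (a notice is emitted for numeric columns downgraded this
#'   way).
#' @param labels Optional 0/1 vector; 1 marks a true alternative. Only
#'   available in simulations.
#' @param n_original Original number of hypotheses before any p-value
#'   filtering; defaults to `length(pvals)`.
#' @param filter_range Optional numeric length-2 vector `c(lower, upper)`
#'   recording that only rows with `p < lower` or `p > upper` were retained.
#'   Required for the post-hoc validity checks in filtered mode.
#'
#' @return An object of class `hypothesis_set` with elements `pvals`,
#'   `covariates`, `kinds`, `labels`, `n`, `d`, `n_original`, `filter_range`.
#' @export
#' @examples
#' hs <- hypothesis_set(c(0.01, 0.2, 0.96), data.frame(x = c(1, 2, 3)))
#' hs$n
hypothesis_set <- function(pvals, covariates = NULL, kinds = NULL,
                           labels = NULL, n_original = length(pvals),
                           filter_range = NULL) {
  pvals <- as.numeric(pvals)
  if (anyNA(pvals)) stop("p-values must not contain missing values")
  if (any(pvals < 0 | pvals > 1)) stop("all p-values must lie in [0, 1]")
  n <- length(pvals)
  if (n < 1L) stop("empty input: no hypotheses")

  if (is.null(covariates)) {
    covariates <- data.frame(row.names = seq_len(n))
  }
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != n) {
    stop("covariates must have exactly one row per hypothesis")
  }
  d <- ncol(covariates)

  if (is.null(kinds)) {
    kinds <- vapply(covariates, detect_kind, character(1))
  } else {
    kinds <- match.arg(kinds, c("numeric", "categorical"), several.ok = TRUE)
    if (length(kinds) == 1L && d > 1L) kinds <- rep(kinds, d)
    if (length(kinds) != d) stop("kinds must name one kind per covariate column")
  }
  for (j in seq_len(d)) {
    if (kinds[j] == "numeric" && !is.numeric(covariates[[j]])) {
      stop("column '", names(covariates)[j], "' declared numeric but is not")
    }
  }

  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != n || anyNA(labels) || !all(labels %in% c(0L, 1L))) {
      stop("labels must be a 0/1 vector of length n")
    }
  }

  n_original <- as.integer(n_original)
  if (is.na(n_original) || n_original < n) {
    stop("n_original must be an integer >= n (", n, ")")
  }
  if (!is.null(filter_range)) {
    filter_range <- as.numeric(filter_range)
    if (length(filter_range) != 2L || filter_range[1] >= filter_range[2]) {
      stop("filter_range must be c(lower, upper) with lower < upper")
    }
  }

  structure(
    list(pvals = pvals, covariates = covariates, kinds = kinds,
         labels = labels, n = n, d = d, n_original = n_original,
         filter_range = filter_range),
    class = "hypothesis_set"
  )
}

detect_kind <- function(col) {
  if (!is.numeric(col)) return("categorical")
  if (length(unique(col)) <= 20L) {
    message("numeric column with <= 20 distinct values treated as categorical")
    return("categorical")
  }
  "numeric"
}

#' @export
print.hypothesis_set <- function(x, ...) {
  cat("hypothesis_set:", x$n, "hypotheses,", x$d, "covariate(s)")
  if (x$n_original > x$n) cat(" [filtered from", x$n_original, "]")
  if (!is.null(x$labels)) {
    cat(sprintf(", %d labelled alternatives", sum(x$labels)))
  }
  cat("\n")
  if (x$d > 0L) {
    cat("covariates:",
        paste(sprintf("%s (%s)", names(x$covariates), x$kinds), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Subset a hypothesis set by index
#'
#' @param hs A `hypothesis_set`.
#' @param idx Integer or logical index vector.
#' @return A `hypothesis_set` restricted to `idx`, keeping `n_original` scaled
#'   proportionally (used internally for fold splitting).
#' @keywords internal
subset_hypotheses <- function(hs, idx, n_original = NULL) {
  n_sub <- length(hs$pvals[idx])
  if (is.null(n_original)) {
    n_original <- max(n_sub, round(hs$n_original * n_sub / hs$n))
  }
  hypothesis_set(
    pvals = hs$pvals[idx],
    covariates = hs$covariates[idx, , drop = FALSE],
    kinds = hs$kinds,
    labels = if (!is.null(hs$labels)) hs$labels[idx],
    n_original = n_original,
    filter_range = hs$filter_range
  )
}

#' Read a hypothesis table from a delimited text file
#'
#' Loads a CSV/TSV file with a header row, extracts the p-value column and the
#' declared covariate columns, validates every row, and drops (with a warning)
#' rows whose p-value falls outside \[0, 1\] or whose covariates are missing.
#'
#' @param path Path to a delimited text file with a header. Files ending in
#'   `.tsv`/`.txt` are read tab-separated, everything else comma-separated.
#' @param pval_column Name of the p-value column.
#' @param covariate_columns Character vector of covariate column names. An
#'   optional `:num` or `:cat` suffix declares the kind (e.g.
#'   `"dist:num"`, `"state:cat"`); undeclared kinds are auto-detected.
#' @param n_original Original number of hypotheses for pre-filtered input;
#'   defaults to the number of retained rows.
#' @param filter_range Optional `c(lower, upper)` filtering bounds, see
#'   [hypothesis_set()].
#' @return A validated [hypothesis_set()].
#' @export
read_hypotheses <- function(path, pval_column = "pval",
                            covariate_columns = NULL, n_original = NULL,
                            filter_range = NULL) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!pval_column %in% names(tab)) {
    stop("p-value column '", pval_column, "' not found in ", path)
  }

  cov_names <- character(0)
  cov_kinds <- character(0)
  if (!is.null(covariate_columns)) {
    for (spec in covariate_columns) {
      parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
      nm <- parts[1]
      if (!nm %in% names(tab)) stop("covariate column '", nm, "' not found")
      kd <- if (length(parts) > 1L) {
        switch(parts[2], num = "numeric", cat = "categorical",
               stop("unknown kind suffix ':", parts[2], "'"))
      } else NA_character_
      cov_names <- c(cov_names, nm)
      cov_kinds <- c(cov_kinds, kd)
    }
  }

  p <- suppressWarnings(as.numeric(tab[[pval_column]]))
  keep <- !is.na(p) & p >= 0 & p <= 1
  covs <- tab[, cov_names, drop = FALSE]
  for (j in seq_along(cov_names)) {
    if (identical(cov_kinds[j], "numeric")) {
      covs[[j]] <- suppressWarnings(as.numeric(covs[[j]]))
    }
    keep <- keep & !is.na(covs[[j]])
  }
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    warning(n_drop, " row(s) dropped: p-value outside [0,1] or missing covariate")
  }
  if (!any(keep)) stop("all rows were dropped during validation")

  kinds <- cov_kinds
  for (j in seq_along(cov_names)) {
    if (is.na(kinds[j])) kinds[j] <- detect_kind(covs[[j]][keep])
    if (kinds[j] == "numeric") covs[[j]] <- as.numeric(covs[[j]])
  }

  hypothesis_set(
    pvals = p[keep],
    covariates = covs[keep, , drop = FALSE],
    kinds = if (length(kinds)) kinds else NULL,
    n_original = if (is.null(n_original)) sum(keep) else n_original,
    filter_range = filter_range
  )
}

#' Write a hypothesis table to a delimited text file
#'
#' Numeric columns are written with 17 significant digits so that a
#' write/read round trip reproduces p-values and numeric covariates exactly.
#'
#' @param hs A [hypothesis_set()].
#' @param path Output path (`.tsv`/`.txt` written tab-separated, else CSV).
#' @param pval_column Column name used for the p-values.
#' @return `path`, invisibly.
#' @export
write_hypotheses <- function(hs, path, pval_column = "pval") {
  fmt <- function(x) {
    if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)
  }
  out <- data.frame(p = fmt(hs$pvals), stringsAsFactors = FALSE)
  names(out) <- pval_column
  for (nm in names(hs$covariates)) out[[nm]] <- fmt(hs$covariates[[nm]])
  if (!is.null(hs$labels)) out$label <- hs$labels
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
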