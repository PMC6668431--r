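test_that("fold splitting is balanced, seeded and covers all indices", {
  fa <- split_folds(10, seed = 4)
  expect_setequal(unique(fa$fold_of), 1:2)
  expect_equal(sum(fa$fold_of == 1), 5)
  expect_identical(split_folds(10, seed = 4)$fold_of, fa$fold_of)
  fa1 <- split_folds(100, seed = 1)
  fa2 <- split_folds(100, seed = 2)
  expect_true(any(fa1$fold_of != fa2$fold_of))
  # odd n: sizes differ by one
  fo <- split_folds(11, seed = 0)$fold_of
  expect_equal(abs(sum(fo == 1) - sum(fo == 2)), 1)
  expect_error(split_folds(1), "at least 2")
})

test_that("the procedure refuses tiny inputs and warns below 10k", {
  hs <- simulate_testing_data(simulation_config(n = 50, seed = 1))
  expect_error(cov_fdr(hs), "100")
  hs2 <- simulate_testing_data(simulation_config(n = 500, seed = 1))
  expect_warning(cov_fdr(hs2, fast = FALSE), "fast")
})

test_that("results are deterministic given the seed", {
  hs <- simulate_testing_data(simulation_scenario("informative",
                                                  n = 4000, seed = 2))
  a <- suppressWarnings(cov_fdr(hs, alpha = 0.1, seed = 7, fast = TRUE))
  b <- suppressWarnings(cov_fdr(hs, alpha = 0.1, seed = 7, fast = TRUE))
  expect_identical(a$rejected, b$rejected)
  expect_identical(a$applied_threshold, b$applied_threshold)
})

test_that("the fast variant equals the full run with zero iterations", {
  hs <- simulate_testing_data(simulation_scenario("informative",
                                                  n = 4000, seed = 3))
  fast <- suppressWarnings(cov_fdr_fast(hs, alpha = 0.1, seed = 1))
  zero <- suppressWarnings(cov_fdr(hs, alpha = 0.1, seed = 1, n_iter = 0))
  expect_identical(fast$rejected, zero$rejected)
  expect_equal(fast$applied_threshold, zero$applied_threshold)
  expect_equal(fast$mode, "fast")
})

test_that("rejections match the applied thresholds and stored counts", {
  hs <- simulate_testing_data(simulation_scenario("informative",
                                                  n = 5000, seed = 4))
  res <- suppressWarnings(cov_fdr(hs, alpha = 0.1, seed = 0, fast = TRUE))
  expect_identical(res$rejected,
                   hs$pvals <= res$applied_threshold & res$applied_threshold > 0)
  for (f in 1:2) {
    te <- res$folds[[f]]$test_idx
    expect_equal(res$folds[[f]]$counts$D,
                 count_discoveries(hs$pvals[te], res$applied_threshold[te]))
    # cross-fit integrity: the threshold for fold f was trained on the others
    expect_length(intersect(res$folds[[f]]$train_idx, te), 0)
    expect_setequal(c(res$folds[[f]]$train_idx, te), seq_len(hs$n))
  }
  expect_equal(res$n_discoveries, sum(res$rejected))
})

test_that("a fold with no admissible rescale factor contributes nothing", {
  # global null: most runs find no admissible factor on at least one fold
  hs <- simulate_testing_data(simulation_scenario("all_null",
                                                  n = 2000, seed = 5))
  res <- suppressWarnings(cov_fdr(hs, alpha = 0.1, seed = 0, fast = TRUE))
  for (f in 1:2) {
    if (res$folds[[f]]$gamma$gamma_star == 0) {
      te <- res$folds[[f]]$test_idx
      expect_false(any(res$rejected[te]))
      expect_true(all(res$applied_threshold[te] == 0))
    }
  }
})

test_that("filtered input uses the original count and validates thresholds", {
  hs_full <- simulate_testing_data(simulation_scenario("informative",
                                                       n = 20000, seed = 6))
  keep <- hs_full$pvals < 0.01 | hs_full$pvals > 0.99
  hs_filt <- hypothesis_set(hs_full$pvals[keep],
                            hs_full$covariates[keep, , drop = FALSE],
                            kinds = hs_full$kinds,
                            labels = hs_full$labels[keep],
                            n_original = hs_full$n,
                            filter_range = c(0.01, 0.99))
  res <- suppressWarnings(cov_fdr(hs_filt, alpha = 0.1, seed = 0, fast = TRUE))
  # every applied threshold stays below the lower filter bound
  expect_lt(max(res$applied_threshold), 0.01)
  # discoveries comparable to running BH on the full data with original N
  t_full <- bh_threshold(hs_full$pvals, 0.1)
  t_filt <- bh_threshold(hs_filt$pvals, 0.1, n_total = hs_filt$n_original)
  expect_equal(t_filt, t_full)
})

test_that("summary JSON carries the per-fold diagnostics", {
  hs <- simulate_testing_data(simulation_scenario("informative",
                                                  n = 2000, seed = 7))
  res <- suppressWarnings(cov_fdr(hs, alpha = 0.1, seed = 0, fast = TRUE))
  js <- jsonlite::fromJSON(discovery_summary_json(res, d = 1),
                           simplifyDataFrame = FALSE)
  expect_equal(js$n, 2000)
  expect_equal(js$alpha, 0.1)
  expect_equal(js$n_discoveries, res$n_discoveries)
  expect_length(js$folds, 2)
})

test_that("the command-line interface runs end to end", {
  skip_if_not_installed("optparse")
  simf <- tempfile(fileext = ".csv")
  outf <- tempfile(fileext = ".csv")
  covfdr_main(c("simulate", "--scenario", "informative", "--n", "3000",
                "--seed", "1", "--output", simf))
  expect_true(file.exists(simf))
  suppressWarnings(covfdr_main(c(
    "--input", simf, "--pval-col", "pval", "--covariates", "x1:num",
    "--alpha", "0.1", "--fast", "--seed", "0", "--output", outf,
    "--log-level", "quiet")))
  out <- utils::read.csv(outf)
  expect_true(all(c("rejected", "fold", "threshold") %in% names(out)))
  expect_equal(nrow(out), 3000)
  js <- jsonlite::fromJSON(paste0(outf, ".json"))
  expect_equal(js$n_discoveries, sum(out$rejected))
})
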