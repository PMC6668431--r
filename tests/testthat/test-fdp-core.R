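test_that("discovery and mirror counts follow the boundary conventions", {
  p <- c(0.01, 0.2, 0.96, 0.995)
  expect_equal(count_discoveries(p, rep(0.05, 4)), 1L)
  expect_equal(mirror_fd(p, rep(0.05, 4)), 2L)     # counts p >= 0.95
  expect_equal(count_discoveries(p, rep(0, 4)), 0L)
  expect_equal(count_discoveries(p, rep(1, 4)), 4L)
  expect_equal(mirror_fd(p, rep(0, 4)), 0L)
  expect_equal(mirror_fd(c(p, 1), rep(0, 5)), 1L)  # p = 1 hits the boundary
  # boundary p = t counts as rejected
  expect_equal(count_discoveries(0.05, 0.05), 1L)
  expect_error(count_discoveries(p, 0.1), "length")
})

test_that("the mirror count is an unbiased proxy for uniform-null FD", {
  set.seed(101)
  n <- 200; cc <- 0.05; reps <- 10000
  P <- matrix(runif(n * reps), reps, n)
  fd_hat <- rowSums(P >= 1 - cc)
  fd_true <- rowSums(P <= cc)
  expect_equal(mean(fd_hat), n * cc, tolerance = 0.02)
  expect_equal(mean(fd_hat), mean(fd_true), tolerance = 0.02)
})

test_that("fdp_hat applies the D-or-1 convention and uses labels", {
  s <- fdp_hat(c(0.01, 0.96, 0.97), rep(0.05, 3))
  expect_equal(s$D, 1L)
  expect_equal(s$FD_hat, 2L)
  expect_equal(s$FDP_hat, 2.0)        # > 1 is legal and flags a bad threshold
  s0 <- fdp_hat(c(0.4, 0.6), rep(0.01, 2))
  expect_equal(s0$D, 0L)
  expect_equal(s0$FDP_hat, s0$FD_hat / 1)
  # with all-null labels every rejection is false
  sl <- fdp_hat(c(0.001, 0.002, 0.9), rep(0.01, 3), labels = c(0L, 0L, 0L))
  expect_equal(sl$FD_true, sl$D)
})

test_that("BH threshold matches hand-worked examples", {
  expect_equal(bh_threshold(c(0.001, 0.008, 0.039, 0.041, 0.27), 0.05), 0.02)
  expect_equal(bh_threshold(rep(0.9, 5), 0.05), 0)
  expect_equal(bh_threshold(0.04, 0.05), 0.05)
  expect_error(bh_threshold(runif(5), 1.5), "alpha")
})

test_that("Storey-BH matches hand-worked examples", {
  r1 <- storey_bh(c(0.01, 0.02, 0.6, 0.8), 0.05)
  expect_equal(r1$pi0_hat, 1.0)       # 2 / (0.5 * 4)
  expect_equal(r1$reject,
               c(0.01, 0.02, 0.6, 0.8) <= bh_threshold(c(0.01, 0.02, 0.6, 0.8),
                                                       0.05))
  r2 <- storey_bh(c(0.6, 0.7, 0.8, 0.9), 0.05)
  expect_equal(r2$pi0_hat, 1.0)       # capped
  r3 <- storey_bh(c(0.001, 0.002, 0.003, 0.9), 0.05)
  expect_equal(r3$pi0_hat, 0.5)
  expect_equal(r3$reject, brute_storey_reject(c(0.001, 0.002, 0.003, 0.9),
                                              0.05)$reject)
  expect_error(storey_bh(runif(4), 0.05, n_total = 100, lambda = 0.5,
                         filter_range = c(0.01, 0.99)), "incompatible")
})

test_that("BH, Storey, D and mirror FD match brute-force references", {
  set.seed(77)
  for (i in 1:1000) {
    n <- sample(1:50, 1)
    p <- round(runif(n), 3)
    alpha <- runif(1, 0.01, 0.3)
    expect_identical(bh_threshold(p, alpha), brute_bh_threshold(p, alpha))
    s <- storey_bh(p, alpha)
    b <- brute_storey_reject(p, alpha)
    expect_identical(s$reject, b$reject)
    expect_identical(s$pi0_hat, b$pi0_hat)
    t <- runif(n, 0, 0.5)
    expect_identical(count_discoveries(p, t), brute_count(p, t))
    expect_identical(mirror_fd(p, t), brute_mirror(p, t))
  }
  # independent cross-check of BH rejections against stats::p.adjust
  set.seed(42)
  for (i in 1:50) {
    p <- runif(sample(5:50, 1))
    thr <- bh_threshold(p, 0.1)
    expect_identical(p <= thr, p.adjust(p, "BH") <= 0.1)
  }
})

test_that("ensembles split at 0.75 and the BH threshold", {
  p <- c(0.001, 0.3, 0.8, 0.99)
  ens <- build_ensembles(p, 0.1)
  expect_equal(ens$t_bh, 0.025)
  expect_equal(ens$null_idx, c(3L, 4L))
  expect_equal(ens$alt_idx, 1L)
  ens2 <- build_ensembles(rep(0.9, 10), 0.1)
  expect_length(ens2$alt_idx, 0)
  expect_equal(ens2$t_bh, 0)
})

test_that("the rescale search matches the worked example and brute force", {
  p <- c(0.004, 0.006, 0.30, 0.70, 0.96, 0.97, 0.98, 0.99)
  t <- rep(0.01, 8)
  grid <- seq(0.1, 2.0, by = 0.1)
  gr <- rescale_gamma(p, t, alpha = 0.2, c0 = 0, grid = grid)
  expect_equal(gr$gamma_star, 0.9)    # gamma = 1.0 trips the mirror count
  expect_equal(gr$counts_at_star$D, 2L)
  expect_equal(gr$counts_at_star$FD_hat, 0L)

  # randomized agreement with an exhaustive search over the same candidates
  set.seed(13)
  for (i in 1:25) {
    n <- sample(20:60, 1)
    p <- runif(n)
    t <- runif(n, 1e-4, 0.3)
    alpha <- runif(1, 0.05, 0.3)
    grid <- exp(seq(log(0.01), log(10), length.out = 200))
    cand <- c(grid, (p / t)[p / t <= 10])
    gr <- rescale_gamma(p, t, alpha, c0 = 0, grid = grid)
    expect_equal(gr$gamma_star, brute_gamma(p, t, alpha, 0, n, cand))
  }
})

test_that("no admissible factor yields gamma = 0 and zero rejections", {
  set.seed(3)
  p <- runif(50, 0.4, 0.6)
  gr <- rescale_gamma(p, rep(0.01, 50), alpha = 0.1)
  expect_equal(gr$gamma_star, 0)
  expect_equal(gr$counts_at_star$D, 0L)
})

test_that("the search is covariant under threshold/factor rescaling", {
  set.seed(23)
  p <- runif(200)
  t <- runif(200, 1e-3, 0.2)
  grid <- exp(seq(log(0.01), log(10), length.out = 500))
  g1 <- rescale_gamma(p, t, 0.1, c0 = 0, grid = grid)
  g2 <- rescale_gamma(p, 2 * t, 0.1, c0 = 0, grid = grid / 2)
  expect_equal(g1$gamma_star, 2 * g2$gamma_star)
  r1 <- p <= pmin(g1$gamma_star * t, 0.5)
  r2 <- p <= pmin(g2$gamma_star * 2 * t, 0.5)
  expect_identical(r1, r2)
})

test_that("counts are nondecreasing in the rescale factor", {
  set.seed(31)
  p <- runif(300)
  t <- runif(300, 1e-3, 0.3)
  gammas <- sort(runif(30, 0.01, 5))
  D <- sapply(gammas, function(g) count_discoveries(p, pmin(g * t, 0.5)))
  FD <- sapply(gammas, function(g) mirror_fd(p, pmin(g * t, 0.5)))
  expect_true(all(diff(D) >= 0))
  expect_true(all(diff(FD) >= 0))
})

test_that("the mirror estimate is conservative on uniform nulls", {
  # fixed non-constant threshold function, many null replicates
  set.seed(55)
  n <- 400; reps <- 400
  x <- runif(n)
  t <- pmin(0.002 + 0.05 * exp(-(x - 0.8)^2 / 0.02), 0.5)
  diffs <- replicate(reps, {
    p <- runif(n)
    mirror_fd(p, t) - count_discoveries(p, t)   # all hypotheses are null
  })
  se <- sd(diffs) / sqrt(reps)
  expect_gte(mean(diffs), -2 * se)
})
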