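test_that("pearson matches hand computations and rejects bad input", {
  expect_equal(pearson(1:5, 1:5), 1)
  expect_equal(pearson(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearson(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_error(pearson(1:2, 1:2), "at least 3")
  expect_error(pearson(rep(1, 5), 1:5), "constant")
  expect_error(pearson(1:4, 1:5), "equal length")
})

test_that("BCa endpoints match the brute-force oracle to 3 decimals", {
  x <- c(0.9, 1.7, 2.1, 2.8, 3.2, 3.9, 4.4, 5.1, 5.6, 6.4, 7.0, 8.2)
  y <- c(1.4, 1.2, 2.9, 2.1, 4.0, 3.1, 4.9, 4.6, 5.2, 7.1, 6.2, 7.9)
  got <- bca_ci(x, y, B = 2000, seed = 123)
  want <- oracle_bca(x, y, B = 2000, seed = 123)
  expect_equal(got$lo, want[1], tolerance = 5e-4)
  expect_equal(got$hi, want[2], tolerance = 5e-4)
  expect_equal(got$kind, "BCa")
  expect_true(got$lo <= got$statistic && got$statistic <= got$hi)
})

test_that("BCa agrees with an independent library implementation", {
  set.seed(5)
  x <- rnorm(40)
  y <- 0.6 * x + rnorm(40, 0, 0.8)
  ours <- bca_ci(x, y, B = 8000, seed = 17)
  bt <- boot::boot(cbind(x, y),
                   function(d, i) cor(d[i, 1], d[i, 2]), R = 8000)
  ref <- boot::boot.ci(bt, type = "bca")$bca[4:5]
  expect_equal(ours$lo, ref[1], tolerance = 0.03)
  expect_equal(ours$hi, ref[2], tolerance = 0.03)
})

test_that("BCa reduces to percentile under a symmetric unbiased bootstrap", {
  # mean of symmetric data: z0 ~ 0 and a = 0, so the adjusted levels are
  # alpha/2 and 1 - alpha/2 and BCa coincides with percentile endpoints
  # (values chosen so resample means rarely tie with the observed mean)
  x <- c(-3.6, -2.9, -1.7, -0.8, 0.8, 1.7, 2.9, 3.6)
  sym_stat <- function(x, y) mean(x)
  got <- bca_ci(x, x, stat = sym_stat, B = 4000, seed = 31)
  set.seed(31)
  n <- length(x)
  idx <- matrix(sample.int(n, n * 4000, replace = TRUE), nrow = 4000)
  th <- apply(idx, 1, function(i) mean(x[i]))
  perc <- quantile(th, c(0.025, 0.975), type = 6, names = FALSE)
  expect_lt(abs(got$lo - perc[1]), 0.1)
  expect_lt(abs(got$hi - perc[2]), 0.1)
})

test_that("degenerate bootstrap distributions fall back to percentile", {
  x <- 1:10
  expect_warning(ci <- bca_ci(x, x, B = 500, seed = 1), "degenerate")
  expect_equal(ci$kind, "percentile")
  expect_equal(ci$lo, 1)
  expect_equal(ci$hi, 1)
})

test_that("BCa intervals achieve near-nominal coverage", {
  set.seed(99)
  rho <- 0.4
  hits <- vapply(1:300, function(i) {
    x <- rnorm(46)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(46)
    ci <- bca_ci(x, y, B = 600)
    ci$lo <= rho && rho <= ci$hi
  }, logical(1))
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.98)
})

test_that("HDI is the shortest mass-covering interval", {
  set.seed(2)
  d <- rnorm(1e5)
  h <- hdi(d)
  expect_equal(h$lo, -1.96, tolerance = 0.05)
  expect_equal(h$hi, 1.96, tolerance = 0.05)
  expect_equal(hdi(rep(3.5, 200))[, c("lo", "hi")],
               tibble::tibble(lo = 3.5, hi = 3.5))
  # right-skewed draws: HDI narrower than the equal-tailed interval
  sk <- rexp(1e5)
  h2 <- hdi(sk)
  eq <- quantile(sk, c(0.025, 0.975))
  expect_lt(h2$hi - h2$lo, eq[2] - eq[1])
  # full mass spans the range
  h3 <- hdi(sk, 1.0)
  expect_equal(c(h3$lo, h3$hi), range(sk))
})

test_that("split R-hat separates mixed from unmixed chains", {
  set.seed(4)
  good <- matrix(rnorm(4000), ncol = 4)
  expect_lt(split_rhat(good), 1.01)
  # identical chains: only the half-chain split distinguishes the columns,
  # so the statistic sits within sampling error of 1
  one <- rnorm(500)
  expect_equal(split_rhat(cbind(one, one)), 1, tolerance = 5e-3)
  # disjoint ranges
  bad <- cbind(rnorm(500), rnorm(500) + 10)
  expect_gt(split_rhat(bad), 1.1)
  # within-chain collapse on distinct constants
  expect_true(is.infinite(split_rhat(cbind(rep(1, 100), rep(2, 100)),
                                     method = "classic")))
  expect_error(split_rhat(matrix(rnorm(10), ncol = 1)), "2 chains")
})

test_that("covariate correlations flag signal and respect missingness", {
  set.seed(12)
  n <- 200
  est <- tibble::tibble(subject = sprintf("S%03d", 1:n),
                        metric_a = rnorm(n))
  covs <- tibble::tibble(subject = est$subject,
                         same = est$metric_a,
                         indep = rnorm(n))
  suppressWarnings(
    out <- covariate_correlations(est, covs, B = 500, seed = 3))
  same_row <- out[out$covariate == "same", ]
  expect_equal(same_row$r, 1)
  indep_row <- out[out$covariate == "indep", ]
  expect_lt(abs(indep_row$r), 0.2)
  expect_false(indep_row$excludes_zero)
  # fewer than 8 complete pairs warns and returns NA
  small <- covs[1:5, c("subject", "same")]
  expect_warning(out2 <- covariate_correlations(est[1:5, ], small, B = 500),
                 "fewer than 8")
  expect_true(all(is.na(out2$r)))
})
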