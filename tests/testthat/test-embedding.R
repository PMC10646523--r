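test_that("standardization has zero mean, unit sd, and is idempotent", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  z <- standardize(rnorm(50, mean = 7, sd = 3))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(standardize(z), z, tolerance = 1e-12)
  expect_error(standardize(c(5, 5, 5)), "constant")
  expect_error(standardize(5), "length")
})

test_that("delay embedding builds the documented row structure", {
  m <- delay_embed(1:10, lag = 2, dim = 3)
  expect_equal(dim(m), c(6L, 3L))
  expect_equal(unname(m[1, ]), c(1, 3, 5))
  expect_equal(unname(m[6, ]), c(6, 8, 10))
  one <- delay_embed(1:7, lag = 3, dim = 1)
  expect_equal(dim(one), c(7L, 1L))
  expect_equal(as.numeric(one), 1:7)
  long <- delay_embed(rnorm(2100), lag = 100, dim = 5)
  expect_equal(nrow(long), 1700L)
  expect_error(delay_embed(1:5, lag = 2, dim = 4), "length >= 8")
  expect_equal(nrow(delay_embed(1:10, embedding_spec(2, 3))), 6L)
})

test_that("AMI of i.i.d. noise is near zero at positive lags", {
  set.seed(42)
  prof <- ami_profile(rnorm(10000), max_lag = 20)
  expect_true(all(prof$ami[prof$lag >= 1] < 0.05))
  # lag 0 is the marginal entropy estimate, far above the noise floor
  expect_gt(prof$ami[1], 1)
})

test_that("AMI matches a plain-table implementation", {
  set.seed(7)
  s <- sin(seq(0, 20, length.out = 300)) + rnorm(300, sd = 0.2)
  prof <- ami_profile(s, max_lag = 10, n_bins = 8)
  for (k in c(0, 3, 7, 10)) {
    expect_equal(prof$ami[prof$lag == k], bf_ami(s, k, 8), tolerance = 1e-12)
  }
})

test_that("AMI of a sinusoid bottoms out in the quarter-period valley", {
  # the profile declines steeply and then flattens into a broad valley
  # centred near P/4; the first strict minimum is a point of that valley
  period <- 40
  s <- sin(2 * pi * seq_len(2000) / period)
  prof <- ami_profile(s, max_lag = 60)
  lag <- first_minimum_lag(prof)
  expect_gte(lag, period / 8)
  expect_lte(lag, 3 * period / 8)
  valley_min <- min(prof$ami[prof$lag >= 1 & prof$lag <= period / 2])
  expect_lt(prof$ami[prof$lag == lag] - valley_min, 0.01)
  # and the quarter-period value itself sits at the valley floor
  expect_lt(prof$ami[prof$lag == period / 4] - valley_min, 0.01)
  # oracle: the profile must agree with an independent computation
  bf <- vapply(1:60, function(k) bf_ami(s, k, 32), numeric(1))
  expect_equal(prof$ami[prof$lag >= 1], bf, tolerance = 1e-12)
})

test_that("monotone AMI profiles fall back to the global minimum with a warning", {
  prof <- data.frame(lag = 0:5, ami = c(5, 4, 3, 2, 1, 0.5))
  expect_warning(lag <- first_minimum_lag(prof), "global minimum")
  expect_equal(lag, 5)
})

test_that("FNN separates a noiseless sinusoid from i.i.d. noise", {
  # incommensurate period: genuine near-recurrences, no exact duplicates
  s <- sin(2 * pi * seq_len(800) / 25.7)
  prof <- fnn_profile(s, lag = 6, max_dim = 4)
  expect_lt(prof$fnn_fraction[prof$dim == 2], 0.01)
  # a periodic orbit unfolds in at most two dimensions (with dense sampling
  # the dim-1 nearest neighbour is usually a same-phase recurrence, so the
  # classic criterion can already accept dim 1)
  expect_lte(select_dim(prof), 2L)
  set.seed(9)
  noise <- rnorm(400)
  nprof <- fnn_profile(noise, lag = 1, max_dim = 5)
  expect_true(all(nprof$fnn_fraction > 0.01))
  expect_warning(expect_true(is.na(select_dim(nprof))), "threshold")
})

test_that("FNN profile truncates with a warning when the series runs out", {
  expect_warning(prof <- fnn_profile(rnorm(30), lag = 8, max_dim = 6),
                 "truncated")
  expect_lt(max(prof$dim), 6)
})

test_that("select_dim returns a dimension whose fraction is already zero", {
  prof <- data.frame(dim = 1:3, fnn_fraction = c(0.4, 0, 0))
  expect_equal(select_dim(prof), 2L)
})

test_that("recurrence analysis is invariant to affine rescaling when standardized", {
  set.seed(3)
  x <- cumsum(rnorm(300))
  y <- cumsum(rnorm(300))
  a <- analyze_pair(x, y, lag = 5, dim = 3, rr_auto = .05, rr_cross = .04)
  b <- analyze_pair(7 * x - 2, y / 3 + 11, lag = 5, dim = 3,
                    rr_auto = .05, rr_cross = .04)
  expect_equal(a$c_xy, b$c_xy, tolerance = 1e-10)
  expect_equal(a$c_yx, b$c_yx, tolerance = 1e-10)
})
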