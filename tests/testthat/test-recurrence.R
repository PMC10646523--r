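test_that("distance matrices agree with hand-computed values", {
  a <- rbind(c(0, 0), c(3, 4))
  d <- distance_matrix(a)
  expect_equal(d[1, 2], 5)
  expect_equal(distance_matrix(a, norm = "chebyshev")[1, 2], 4)
  expect_equal(diag(d), c(0, 0))
  expect_true(isSymmetric(d))
  expect_error(distance_matrix(a, rbind(c(1, 2, 3))), "dimension")
})

test_that("threshold calibration matches a sort-and-count oracle", {
  # eligible population {1, 2, 3, 4, 5}; at target 0.40 exactly 2 of the 5
  # cells must recur, so epsilon lies between 2 and 3
  d <- matrix(1:5, nrow = 1)
  eps <- threshold_for_rr(d, 0.40, "cross")
  expect_gte(eps, 2); expect_lt(eps, 3)
  expect_equal(sum(d <= eps), 2)
  # near-1 target: epsilon approaches the maximum distance and the realized
  # count still agrees with the target to within one cell
  eps_hi <- threshold_for_rr(d, 0.999, "cross")
  expect_gt(eps_hi, 4.9)
  expect_lte(abs(mean(d <= eps_hi) - 0.999), 1 / length(d))
  # auto kind: one-cell agreement on a random cloud
  cloud <- distance_matrix(matrix(rnorm(40), ncol = 2))
  pop <- cloud[upper.tri(cloud)]
  eps_a <- threshold_for_rr(cloud, 0.25, "auto")
  expect_lte(abs(mean(pop <= eps_a) - 0.25), 1 / length(pop))
  expect_error(threshold_for_rr(matrix(1, 3, 3), 0.5, "cross"), "equal")
  expect_error(threshold_for_rr(d, 1.2, "cross"), "between 0 and 1")
})

test_that("calibration lands within one cell of the target rate", {
  set.seed(21)
  for (i in 1:20) {
    traj <- matrix(rnorm(80), ncol = 2)
    target <- runif(1, 0.02, 0.3)
    rp <- auto_recurrence(traj, target_rr = target)
    n_cells <- choose(nrow(traj), 2)
    expect_lte(abs(rp$realized_rr - target), 1 / n_cells)
    other <- matrix(rnorm(60), ncol = 2)
    cp <- cross_recurrence(traj, other, target_rr = target)
    expect_lte(abs(cp$realized_rr - target), 1 / (nrow(traj) * nrow(other)))
  }
})

test_that("realized recurrence rate is monotone in epsilon", {
  set.seed(5)
  traj <- matrix(rnorm(100), ncol = 2)
  eps_grid <- seq(0, 4, length.out = 25)
  rr <- vapply(eps_grid,
               function(e) auto_recurrence(traj, epsilon = e)$realized_rr,
               numeric(1))
  expect_true(all(diff(rr) >= 0))
  expect_equal(rr[1], 0)                      # distinct points at eps = 0
  expect_equal(auto_recurrence(traj, epsilon = 10)$realized_rr, 1)
})

test_that("recurrence matrices match a naive double loop exactly", {
  set.seed(11)
  a <- matrix(rnorm(120), ncol = 2)
  b <- matrix(rnorm(80), ncol = 2)
  for (norm in c("euclidean", "chebyshev")) {
    eps <- 0.7
    rp <- auto_recurrence(a, epsilon = eps, norm = norm)
    expect_identical(rp$matrix, bf_recurrence(a, a, eps, norm))
    cp <- cross_recurrence(a, b, epsilon = eps, norm = norm)
    expect_identical(cp$matrix, bf_recurrence(a, b, eps, norm))
  }
})

test_that("cross-recurrence obeys the transpose law", {
  set.seed(13)
  a <- matrix(rnorm(90), ncol = 3)
  b <- matrix(rnorm(60), ncol = 3)
  xy <- cross_recurrence(a, b, epsilon = 1.1)
  yx <- cross_recurrence(b, a, epsilon = 1.1)
  expect_identical(xy$matrix, t(yx$matrix))
})

test_that("cross-recurrence of a trajectory with itself is the auto matrix", {
  set.seed(17)
  traj <- matrix(rnorm(70), ncol = 2)
  eps <- threshold_for_rr(distance_matrix(traj), 0.1, "auto")
  a <- auto_recurrence(traj, epsilon = eps)
  cr <- cross_recurrence(traj, traj, epsilon = eps)
  expect_identical(cr$matrix, a$matrix)
  expect_true(all(diag(cr$matrix) == 1L))     # unit diagonal retained
})

test_that("mirrored inputs give a symmetric cross-recurrence matrix", {
  tr <- simulate_oscillators(
    oscillator_params(t_grid = seq(0, 49)))   # antiphase mirror pair, N = 50
  x <- cbind(standardize(tr$x), standardize(tr$dx))
  y <- cbind(standardize(tr$y), standardize(tr$dy))
  cr <- cross_recurrence(x, y, target_rr = 0.1)
  expect_identical(cr$matrix, t(cr$matrix))
})

test_that("simulation scenarios calibrate to the configured rates", {
  tr <- simulate_oscillators(scenario_params("x_drives_y"))
  x <- cbind(standardize(tr$x), standardize(tr$dx))
  y <- cbind(standardize(tr$y), standardize(tr$dy))
  rx <- auto_recurrence(x, target_rr = 0.05)
  cr <- cross_recurrence(x, y, target_rr = 0.03)
  expect_lte(abs(rx$realized_rr - 0.05), 1 / choose(201, 2))
  expect_lte(abs(cr$realized_rr - 0.03), 1 / 201^2)
})
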