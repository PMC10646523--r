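test_that("the six-vertex toy network reproduces its worked measures exactly", {
  b <- toy_irn_blocks()
  g <- build_irn(b$rx, b$ry, b$cr)
  a <- irn_adjacency(g)
  expect_identical(a, t(a))
  expect_true(all(diag(a) == 0L))
  expect_equal(cross_degree(g), c(2L, 1L, 0L, 2L, 1L, 0L))
  expect_equal(cross_edge_density(g), 1 / 3)
  expect_equal(local_cross_clustering(g, 1:3), c(1, 0, 0))
  expect_equal(local_cross_clustering(g, 4:6), c(0, 0, 0))
  expect_equal(global_cross_clustering(g, "x"), 1 / 3)
  expect_equal(global_cross_clustering(g, "y"), 0)
})

test_that("degenerate graphs behave as documented", {
  b <- toy_irn_blocks()
  empty <- build_irn(b$rx, b$ry, matrix(0L, 3, 3))
  expect_equal(cross_degree(empty), rep(0L, 6))
  expect_equal(cross_edge_density(empty), 0)
  full <- build_irn(b$rx, b$ry, matrix(1L, 3, 3))
  expect_equal(cross_edge_density(full), 1)
  expect_equal(cross_degree(full), rep(3L, 6))
  # two cross-neighbours that are not adjacent in the opposite block
  cr <- matrix(0L, 3, 3); cr[1, 1] <- cr[1, 3] <- 1L   # u1, u3 not adjacent
  g <- build_irn(b$rx, b$ry, cr)
  expect_equal(local_cross_clustering(g, 1), 0)
  expect_error(build_irn(b$rx, b$ry, matrix(0L, 2, 3)), "cross block")
  expect_error(cross_degree(build_irn(b$rx, b$ry, b$cr), 7), "unknown vertex")
})

test_that("cross-clustering matches exhaustive triangle enumeration", {
  set.seed(31)
  for (i in 1:150) {
    nx <- sample(3:30, 1); ny <- sample(3:30, 1)
    b <- random_irn_blocks(nx, ny, p_auto = runif(1, .1, .5),
                          p_cross = runif(1, .05, .4))
    g <- build_irn(b$rx, b$ry, b$cr)
    bf <- bf_local_cross_clustering(b$rx, b$ry, b$cr)
    expect_equal(local_cross_clustering(g, seq_len(nx)), bf$x, tolerance = 1e-12)
    expect_equal(local_cross_clustering(g, nx + seq_len(ny)), bf$y, tolerance = 1e-12)
    expect_equal(global_cross_clustering(g, "x"), mean(bf$x), tolerance = 1e-12)
  }
})

test_that("randomly placed cross-edges give C^XY near the opposite density", {
  # with uncorrelated edge placement the expected local coefficient equals
  # the edge probability of the closure block, discounted by the vertices
  # with cross-degree 0 or 1 (which contribute 0 by definition)
  set.seed(33)
  p_auto <- 0.15; p_cross <- 0.1; n <- 40
  p_low_degree <- dbinom(0, n, p_cross) + dbinom(1, n, p_cross)
  expected <- p_auto * (1 - p_low_degree)
  vals <- replicate(300, {
    b <- random_irn_blocks(n, n, p_auto = p_auto, p_cross = p_cross)
    global_cross_clustering(build_irn(b$rx, b$ry, b$cr), "x")
  })
  expect_lt(abs(mean(vals) - expected), 0.01)
})

test_that("persistent and anti-persistent connectivity move C across rho", {
  # anti-persistent: Y splits into two cliques and every X vertex connects
  # to both sides, so cross-neighbours are never adjacent: C = 0 << rho^Y
  n <- 6
  ry <- matrix(0L, n, n)
  ry[1:3, 1:3] <- 1L; ry[4:6, 4:6] <- 1L; diag(ry) <- 0L
  rx <- matrix(0L, n, n)
  cr <- matrix(0L, n, n)
  for (v in 1:n) { cr[v, 1] <- 1L; cr[v, 4] <- 1L }
  g <- build_irn(rx, ry, cr)
  rho_y <- mean(ry[upper.tri(ry)])
  expect_equal(global_cross_clustering(g, "x"), 0)
  expect_gt(rho_y, 0.3)
  # persistent: neighbours always adjacent: C = 1 >> rho^Y of a sparse block
  ry2 <- matrix(0L, n, n); ry2[1, 2] <- ry2[2, 1] <- 1L
  cr2 <- matrix(0L, n, n); cr2[, 1] <- 1L; cr2[, 2] <- 1L
  g2 <- build_irn(rx, ry2, cr2)
  expect_equal(global_cross_clustering(g2, "x"), 1)
  expect_lt(mean(ry2[upper.tri(ry2)]), 0.1)
})

test_that("the direction rule reproduces its reference decisions", {
  expect_equal(classify_direction(0.131, 0.388), "X_leads")
  expect_equal(classify_direction(0.393, 0.109), "Y_leads")
  expect_equal(classify_direction(0.384, 0.379), "bidirectional_or_uncoupled")
  expect_equal(classify_direction(0.2, 0.2), "bidirectional_or_uncoupled")
  # threshold boundary is inclusive
  expect_equal(classify_direction(0.21, 0.2), "bidirectional_or_uncoupled")
  expect_equal(classify_direction(0.2, 0.2105), "X_leads")
  expect_error(classify_direction(1.2, 0.1), "\\[0, 1\\]")
})

test_that("analyze_pair obeys the relabelling swap law", {
  set.seed(35)
  x <- as.numeric(arima.sim(list(ar = 0.8), 260))
  y <- as.numeric(arima.sim(list(ar = 0.8), 260))
  for (cl in c("scale_matched", "within")) {
    ab <- analyze_pair(x, y, lag = 3, dim = 3, rr_auto = .05, rr_cross = .04,
                       closure = cl)
    ba <- analyze_pair(y, x, lag = 3, dim = 3, rr_auto = .05, rr_cross = .04,
                       closure = cl)
    expect_equal(ab$c_xy, ba$c_yx, tolerance = 1e-12)
    expect_equal(ab$c_yx, ba$c_xy, tolerance = 1e-12)
    expect_equal(ab$rho_xy, ba$rho_xy, tolerance = 1e-12)
  }
})

test_that("coupling summaries stay in range and rho equals the realized rate", {
  set.seed(37)
  x <- cumsum(rnorm(300)); y <- cumsum(rnorm(300))
  cs <- analyze_pair(x, y, lag = 4, dim = 3, rr_auto = .07, rr_cross = .05)
  expect_true(all(c(cs$c_xy, cs$c_yx, cs$rho_xy) >= 0))
  expect_true(all(c(cs$c_xy, cs$c_yx, cs$rho_xy) <= 1))
  expect_true(all(cs$local_c_xy >= 0 & cs$local_c_xy <= 1))
  expect_identical(cs$rho_xy, unname(cs$realized_rr["xy"]))
  expect_equal(cs$delta_c, cs$c_xy - cs$c_yx)
})

test_that("closure conventions coincide for symmetric systems", {
  tr <- simulate_oscillators(scenario_params("uncoupled"))
  x <- cbind(tr$x, tr$dx); y <- cbind(tr$y, tr$dy)
  sm <- analyze_pair(x, y, rr_auto = .05, rr_cross = .03, closure = "scale_matched")
  wi <- analyze_pair(x, y, rr_auto = .05, rr_cross = .03, closure = "within")
  expect_equal(sm$c_xy, wi$c_xy, tolerance = 1e-12)
  expect_equal(sm$c_yx, wi$c_yx, tolerance = 1e-12)
})
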