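make_var_list <- function(series_x, series_y, vars) {
  out <- lapply(seq_along(vars), function(i) list(x = series_x[[i]], y = series_y[[i]]))
  names(out) <- vars
  out
}

test_that("five variables give the ten expected weighted labelled edges", {
  set.seed(51)
  vars <- c("ACC", "BVP", "EDA", "HR", "TEMP")
  sx <- replicate(5, cumsum(rnorm(220)), simplify = FALSE)
  sy <- replicate(5, cumsum(rnorm(220)), simplify = FALSE)
  g <- build_multiplex(make_var_list(sx, sy, vars), lag = 2, dim = 3,
                       rr_auto = .05, rr_cross = .04)
  expect_equal(igraph::vcount(g), 5)
  expect_equal(igraph::ecount(g), 10)
  e <- multiplex_edges(g)
  expect_true(all(c("weight", "direction", "c_xy", "c_yx") %in% names(e)))
  expect_true(all(e$weight >= 0))
  expect_equal(unname(multiplex_strength(g)),
               unname(igraph::strength(g, weights = igraph::E(g)$weight)))
})

test_that("identical series everywhere give zero differences and strengths", {
  s <- cumsum(rnorm(200))
  vars <- c("a", "b", "c")
  lst <- make_var_list(list(s, s, s), list(s, s, s), vars)
  g <- build_multiplex(lst, lag = 2, dim = 2, rr_auto = .05, rr_cross = .04)
  expect_true(all(abs(multiplex_edges(g)$delta_c) < 1e-12))
  expect_true(all(multiplex_strength(g) < 1e-12))
})

test_that("input validation rejects unusable variable sets", {
  s <- rnorm(100)
  expect_error(build_multiplex(list(a = list(x = s, y = s))), "at least 2")
  expect_error(build_multiplex(list(a = list(x = s, y = s),
                                    b = list(x = s, y = rnorm(50)))),
               "same length")
})

test_that("a variable that drives all others attains maximal vertex strength", {
  # EDA carries the clean driver signal on both sides; every other stream is
  # a noisy lagged copy. Pairs involving EDA are then strongly asymmetric
  # (clean driver vs noisy follower) while the remaining pairs compare two
  # equally noisy followers, so EDA accumulates the largest strength.
  vars <- c("ACC", "BVP", "EDA", "HR", "TEMP")
  hits <- vapply(1:12, function(s) {
    set.seed(600 + s)
    n <- 400; nl <- 10
    driver <- as.numeric(arima.sim(list(ar = 0.95), n + 2 * nl))
    noisy_copy <- function() {
      l <- sample(0:nl, 1)
      driver[(nl - l + 1):(nl - l + n)] +
        as.numeric(arima.sim(list(ar = 0.5), n))
    }
    lst <- lapply(vars, function(v) {
      if (v == "EDA") {
        list(x = driver[(nl + 1):(nl + n)],
             y = driver[(nl - 2):(nl - 3 + n)])
      } else {
        list(x = noisy_copy(), y = noisy_copy())
      }
    })
    names(lst) <- vars
    g <- build_multiplex(lst, lag = 3, dim = 3, rr_auto = .05, rr_cross = .04)
    names(which.max(multiplex_strength(g))) == "EDA"
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("graphml export round-trips the edge attributes", {
  set.seed(53)
  lst <- make_var_list(list(rnorm(150), cumsum(rnorm(150))),
                       list(rnorm(150), cumsum(rnorm(150))), c("a", "b"))
  g <- build_multiplex(lst, lag = 1, dim = 2, rr_auto = .06, rr_cross = .05)
  path <- tempfile(fileext = ".graphml")
  write_multiplex_graphml(g, path)
  back <- igraph::read_graph(path, format = "graphml")
  expect_equal(sort(igraph::V(back)$name), c("a", "b"))
  expect_equal(igraph::E(back)$weight, igraph::E(g)$weight, tolerance = 1e-9)
})
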