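# internal helpers shared across modules

# Pairwise distances between the rows of two matrices.
# Euclidean uses the crossproduct identity; chebyshev loops over the (few)
# state-space coordinates. `a` and `b` must have the same column count.
pairwise_distances <- function(a, b = NULL, norm = c("euclidean", "chebyshev")) {
  norm <- match.arg(norm)
  a <- as_state_matrix(a)
  auto <- is.null(b)
  b <- if (auto) a else as_state_matrix(b)
  if (ncol(a) != ncol(b)) {
    stop("trajectories have different state-space dimensions (",
         ncol(a), " vs ", ncol(b), ")", call. = FALSE)
  }
  if (norm == "euclidean") {
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
    d <- sqrt(pmax(d2, 0))
  } else {
    d <- abs(outer(a[, 1], b[, 1], "-"))
    for (k in seq_len(ncol(a))[-1]) {
      d <- pmax(d, abs(outer(a[, k], b[, k], "-")))
    }
  }
  if (auto) {
    d <- (d + t(d)) / 2
    diag(d) <- 0
  }
  d
}

as_state_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.numeric(x)) return(matrix(x, ncol = 1))
  if (is.data.frame(x)) return(as.matrix(x))
  stop("expected a numeric vector or matrix of state vectors", call. = FALSE)
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. A NULL seed runs expr unchanged.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# 0/1 integer matrix from a logical comparison
binarize <- function(x) {
  storage.mode(x) <- "integer"
  x
}

zero_diag <- function(m) {
  diag(m) <- 0L
  m
}

is_binary_matrix <- function(m) {
  is.matrix(m) && all(m %in% c(0L, 1L))
}
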