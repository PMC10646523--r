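# Independent brute-force oracles: plain loops, no shared code with the
# package internals they check.

# Fig-style six-vertex toy IRN: X vertices v1..v3 (intra edge v2-v3),
# Y vertices u1..u3 (intra edge u1-u2), cross edges v1-u1, v1-u2, v2-u1.
toy_irn_blocks <- function() {
  rx <- matrix(0L, 3, 3); rx[2, 3] <- rx[3, 2] <- 1L
  ry <- matrix(0L, 3, 3); ry[1, 2] <- ry[2, 1] <- 1L
  cr <- matrix(0L, 3, 3); cr[1, 1] <- cr[1, 2] <- cr[2, 1] <- 1L
  list(rx = rx, ry = ry, cr = cr)
}

# exhaustive triangle enumeration for the local cross-clustering of every
# vertex of a composite IRN given as blocks
bf_local_cross_clustering <- function(rx, ry, cr) {
  nx <- nrow(rx); ny <- nrow(ry)
  cx <- numeric(nx)
  for (v in seq_len(nx)) {
    nb <- which(cr[v, ] == 1)
    k <- length(nb)
    if (k <= 1) next
    s <- 0
    for (i in nb) for (j in nb) if (i != j && ry[i, j] == 1) s <- s + 1
    cx[v] <- s / (k * (k - 1))
  }
  cy <- numeric(ny)
  for (u in seq_len(ny)) {
    nb <- which(cr[, u] == 1)
    k <- length(nb)
    if (k <= 1) next
    s <- 0
    for (i in nb) for (j in nb) if (i != j && rx[i, j] == 1) s <- s + 1
    cy[u] <- s / (k * (k - 1))
  }
  list(x = cx, y = cy)
}

# naive double-loop recurrence matrix
bf_recurrence <- function(a, b, eps, norm = "euclidean") {
  a <- as.matrix(a); b <- as.matrix(b)
  m <- matrix(0L, nrow(a), nrow(b))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- if (norm == "euclidean") sqrt(sum((a[i, ] - b[j, ])^2))
           else max(abs(a[i, ] - b[j, ]))
      if (d <= eps) m[i, j] <- 1L
    }
  }
  m
}

# plain-table mutual information in nats at one lag
bf_ami <- function(series, k, n_bins) {
  n <- length(series)
  breaks <- seq(min(series), max(series), length.out = n_bins + 1)
  b <- findInterval(series, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  x <- b[1:(n - k)]
  y <- b[(1 + k):n]
  joint <- table(factor(x, levels = 1:n_bins), factor(y, levels = 1:n_bins))
  p <- joint / sum(joint)
  px <- rowSums(p); py <- colSums(p)
  s <- 0
  for (i in 1:n_bins) for (j in 1:n_bins) {
    if (p[i, j] > 0) s <- s + p[i, j] * log(p[i, j] / (px[i] * py[j]))
  }
  as.numeric(s)
}

# random IRN blocks for property tests
random_irn_blocks <- function(nx, ny, p_auto = 0.2, p_cross = 0.2) {
  sym <- function(n, p) {
    m <- matrix(0L, n, n)
    up <- which(upper.tri(m))
    m[up] <- rbinom(length(up), 1, p)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }
  list(rx = sym(nx, p_auto), ry = sym(ny, p_auto),
       cr = matrix(rbinom(nx * ny, 1, p_cross), nx, ny))
}
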