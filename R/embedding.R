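#' Standardize a series to zero mean and unit variance
#'
#' Uses the sample standard deviation (denominator N - 1). Constant series
#' have no meaningful scale and raise an error.
#'
#' @param x Numeric vector, length >= 2.
#' @return Standardized numeric vector.
#' @export
standardize <- function(x) {
  if (length(x) < 2) stop("series must have length >= 2")
  if (anyNA(x)) stop("series contains missing values")
  s <- stats::sd(x)
  if (s == 0) stop("cannot standardize a constant series (zero variance)")
  (x - mean(x)) / s
}

#' Embedding specification
#'
#' @param lag Embedding lag in samples (>= 1).
#' @param dim Embedding dimension (>= 1).
#' @return An `embedding_spec` object.
#' @export
embedding_spec <- function(lag = 1, dim = 1) {
  lag <- as.integer(lag); dim <- as.integer(dim)
  if (is.na(lag) || lag < 1) stop("lag must be a positive integer")
  if (is.na(dim) || dim < 1) stop("dim must be a positive integer")
  structure(list(lag = lag, dim = dim), class = "embedding_spec")
}

#' Time-delay embedding
#'
#' Reconstructs a state-space trajectory from a scalar series: row i of the
#' result is `(s[i], s[i + lag], ..., s[i + (dim - 1) * lag])`, for
#' `i = 1, ..., N - (dim - 1) * lag`.
#'
#' @param series Numeric vector.
#' @param lag Embedding lag (samples), or an [embedding_spec()].
#' @param dim Embedding dimension (ignored when `lag` is an `embedding_spec`).
#' @return Matrix with `length(series) - (dim - 1) * lag` rows and `dim`
#'   columns; attributes `embedding_lag`, `embedding_dim` and `source_length` record the
#'   construction.
#' @export
delay_embed <- function(series, lag = 1, dim = 1) {
  if (inherits(lag, "embedding_spec")) {
    dim <- lag$dim
    lag <- lag$lag
  }
  spec <- embedding_spec(lag, dim)
  n <- length(series)
  n_out <- n - (spec$dim - 1L) * spec$lag
  if (n_out < 2) {
    stop(sprintf("series too short for lag %d, dim %d: need length >= %d, got %d",
                 spec$lag, spec$dim, (spec$dim - 1L) * spec$lag + 2L, n))
  }
  m <- vapply(seq_len(spec$dim) - 1L,
              function(d) series[seq_len(n_out) + d * spec$lag],
              numeric(n_out))
  m <- matrix(m, nrow = n_out, ncol = spec$dim)
  attr(m, "embedding_lag") <- spec$lag
  attr(m, "embedding_dim") <- spec$dim
  attr(m, "source_length") <- n
  m
}

#' Average mutual information profile
#'
#' Mutual information (in nats) between the series and its lagged copy,
#' estimated from a 2-D equal-width histogram, for lags 0..`max_lag`. The
#' first minimum of this profile is the standard choice of embedding lag.
#'
#' @param series Numeric vector.
#' @param max_lag Largest lag; must be below half the series length.
#' @param n_bins Number of histogram bins per axis.
#' @return Data frame with columns `lag` and `ami`.
#' @export
ami_profile <- function(series, max_lag, n_bins = 32) {
  n <- length(series)
  if (max_lag >= n / 2) stop("max_lag must be smaller than half the series length")
  breaks <- seq(min(series), max(series), length.out = n_bins + 1L)
  b <- findInterval(series, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  mi_at <- function(k) {
    i1 <- b[seq_len(n - k)]
    i2 <- b[seq_len(n - k) + k]
    joint <- tabulate((i2 - 1L) * n_bins + i1, nbins = n_bins * n_bins)
    p <- joint / sum(joint)                       # column-major: [i1, i2]
    px <- tabulate(i1, nbins = n_bins) / (n - k)
    py <- tabulate(i2, nbins = n_bins) / (n - k)
    pp <- outer(px, py)
    pos <- p > 0
    sum(p[pos] * log(p[pos] / pp[pos]))
  }
  data.frame(lag = 0:max_lag, ami = vapply(0:max_lag, mi_at, numeric(1)))
}

#' First minimum of an AMI profile
#'
#' Returns the first strict local minimum of the profile over lags >= 1; when
#' the profile has none (e.g. it is monotone), falls back to the global
#' minimum with a warning.
#'
#' @param profile Data frame as returned by [ami_profile()].
#' @return Integer lag.
#' @export
first_minimum_lag <- function(profile) {
  stopifnot(is.data.frame(profile), all(c("lag", "ami") %in% names(profile)))
  a <- profile$ami
  n <- length(a)
  if (n >= 3) {
    for (k in 2:(n - 1)) {
      if (a[k] < a[k - 1] && a[k] < a[k + 1]) return(profile$lag[k])
    }
  }
  warning("AMI profile has no strict local minimum; returning the global minimum")
  cand <- which(profile$lag >= 1)
  profile$lag[cand[which.min(a[cand])]]
}

#' False-nearest-neighbour profile
#'
#' Classic false-nearest-neighbour criterion for selecting the embedding
#' dimension: for each point's nearest neighbour in dimension m, the
#' neighbour is "false" when the extra (m+1)-th coordinate distance is large
#' relative to the dimension-m distance (`r_tol`) or when the expanded
#' distance is large relative to the series' spread (`a_tol` times the
#' standard deviation).
#'
#' @param series Numeric vector.
#' @param lag Embedding lag.
#' @param max_dim Largest dimension to evaluate.
#' @param r_tol Ratio tolerance (default 10).
#' @param a_tol Attractor-size tolerance (default 2).
#' @return Data frame with columns `dim` and `fnn_fraction`; truncated with a
#'   warning when the series is too short for the larger dimensions.
#' @export
fnn_profile <- function(series, lag, max_dim, r_tol = 10, a_tol = 2) {
  n <- length(series)
  s_sd <- stats::sd(series)
  out <- data.frame(dim = integer(), fnn_fraction = numeric())
  for (m in seq_len(max_dim)) {
    n_pts <- n - m * lag  # rows for which the (m+1)-th coordinate also exists
    if (n_pts < 2) {
      warning(sprintf("series too short beyond dim %d; profile truncated", m - 1L))
      break
    }
    em <- delay_embed(series, lag, m)[seq_len(n_pts), , drop = FALSE]
    d <- pairwise_distances(em)
    diag(d) <- Inf
    nn <- max.col(-d, ties.method = "first")
    rd <- d[cbind(seq_len(n_pts), nn)]
    extra <- abs(series[seq_len(n_pts) + m * lag] - series[nn + m * lag])
    false <- (extra > r_tol * rd) | (sqrt(rd^2 + extra^2) > a_tol * s_sd)
    # exact duplicates (periodic data whose period divides the sampling)
    # make the distance ratio floating-point noise; such neighbours are
    # false only if the extra coordinate genuinely separates them
    dup <- rd < 1e-8 * s_sd
    false[dup] <- extra[dup] > 1e-8 * s_sd
    out <- rbind(out, data.frame(dim = m, fnn_fraction = mean(false)))
  }
  out
}

#' Select embedding dimension from an FNN profile
#'
#' @param profile Data frame from [fnn_profile()].
#' @param threshold Acceptable false-neighbour fraction (default 1%).
#' @return Smallest dimension whose fraction falls below the threshold, or
#'   `NA` (with a warning) when none does.
#' @export
select_dim <- function(profile, threshold = 0.01) {
  ok <- which(profile$fnn_fraction < threshold)
  if (length(ok) == 0) {
    warning("no dimension reaches the false-neighbour threshold; returning NA")
    return(NA_integer_)
  }
  as.integer(profile$dim[ok[1]])
}
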