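#' Assemble an inter-system recurrence network
#'
#' Combines the two auto-recurrence matrices and the cross-recurrence matrix
#' into the composite symmetric adjacency
#' `A = [[R^X, CR], [CR', R^Y]] - I`, i.e. the auto blocks sit on the
#' diagonal, the cross block and its transpose off the diagonal, and
#' self-loops are removed. Vertices `1..N_X` belong to system X,
#' `N_X+1..N_X+N_Y` to system Y, in temporal order within each block.
#'
#' @param r_x,r_y Auto `recurrence_plot` objects (or square symmetric 0/1
#'   matrices).
#' @param cr_xy Cross `recurrence_plot` (or `N_X x N_Y` 0/1 matrix) with rows
#'   indexing X states.
#' @return An `irn_graph` object with fields `r_x`, `r_y`, `cr` (0/1 blocks,
#'   auto diagonals zeroed), `n_x`, `n_y` and `thresholds`.
#' @export
build_irn <- function(r_x, r_y, cr_xy) {
  get_mat <- function(p) if (inherits(p, "recurrence_plot")) p$matrix else p
  get_eps <- function(p) if (inherits(p, "recurrence_plot")) p$epsilon else NA_real_
  mx <- get_mat(r_x); my <- get_mat(r_y); mc <- get_mat(cr_xy)
  storage.mode(mx) <- "integer"; storage.mode(my) <- "integer"
  storage.mode(mc) <- "integer"
  if (nrow(mx) != ncol(mx) || nrow(my) != ncol(my)) {
    stop("auto-recurrence blocks must be square")
  }
  if (!isSymmetric(unname(mx)) || !isSymmetric(unname(my))) {
    stop("auto-recurrence blocks must be symmetric")
  }
  if (nrow(mc) != nrow(mx) || ncol(mc) != nrow(my)) {
    stop(sprintf("cross block must be %d x %d, got %d x %d",
                 nrow(mx), nrow(my), nrow(mc), ncol(mc)))
  }
  structure(list(r_x = zero_diag(mx), r_y = zero_diag(my), cr = mc,
                 n_x = nrow(mx), n_y = nrow(my),
                 thresholds = c(x = get_eps(r_x), y = get_eps(r_y),
                                xy = get_eps(cr_xy))),
            class = "irn_graph")
}

#' @export
print.irn_graph <- function(x, ...) {
  cat(sprintf("Inter-system recurrence network: N_X = %d, N_Y = %d\n", x$n_x, x$n_y))
  cat(sprintf("  cross-edges: %d (density %.4f)\n", sum(x$cr), cross_edge_density(x)))
  if (!all(is.na(x$thresholds))) {
    cat(sprintf("  thresholds: eps_x %.4g, eps_y %.4g, eps_xy %.4g\n",
                x$thresholds["x"], x$thresholds["y"], x$thresholds["xy"]))
  }
  invisible(x)
}

#' Composite adjacency matrix of an IRN
#'
#' @param g An `irn_graph`.
#' @return `(N_X + N_Y)` square symmetric 0/1 matrix with zero diagonal.
#' @export
irn_adjacency <- function(g) {
  stopifnot(inherits(g, "irn_graph"))
  rbind(cbind(g$r_x, g$cr), cbind(t(g$cr), g$r_y))
}

check_vertices <- function(g, v) {
  n <- g$n_x + g$n_y
  if (is.null(v)) return(seq_len(n))
  v <- as.integer(v)
  if (any(is.na(v)) || any(v < 1L) || any(v > n)) {
    stop(sprintf("unknown vertex; the graph has vertices 1..%d", n))
  }
  v
}

#' Cross-degree of IRN vertices
#'
#' Number of edges connecting a vertex to the opposite subnetwork.
#'
#' @param g An `irn_graph`.
#' @param v Vertex indices in `1..(N_X + N_Y)`; `NULL` for all vertices.
#' @return Integer vector of cross-degrees.
#' @export
cross_degree <- function(g, v = NULL) {
  v <- check_vertices(g, v)
  kx <- rowSums(g$cr)
  ky <- colSums(g$cr)
  as.integer(ifelse(v <= g$n_x, kx[pmin(v, g$n_x)], ky[pmax(v - g$n_x, 1L)]))
}

#' Cross-edge density of an IRN
#'
#' Number of cross-edges over the maximum possible `N_X * N_Y`; identical to
#' the realized cross recurrence rate.
#'
#' @param g An `irn_graph`.
#' @return Fraction in \[0, 1\].
#' @export
cross_edge_density <- function(g) {
  stopifnot(inherits(g, "irn_graph"))
  sum(g$cr) / (g$n_x * g$n_y)
}

# Local cross-clustering for both sides at once.
#
# For v in X with cross-neighbour set U in Y of size k, the coefficient is
# (# ordered pairs (u_i, u_j), i != j, adjacent in the closure matrix) /
# (k (k - 1)), and 0 when k <= 1; mirrored for the Y side. `close_xy` is the
# adjacency among Y vertices used to close X-side triangles (by default the
# Y auto block); `close_yx` the mirror. Uses sparse algebra for large plots.
cross_clustering_locals <- function(cr, close_xy, close_yx) {
  kx <- rowSums(cr)
  ky <- colSums(cr)
  big <- length(cr) > 250000
  if (big) {
    crs <- Matrix::Matrix(cr, sparse = TRUE)
    num_x <- Matrix::rowSums((crs %*% Matrix::Matrix(close_xy, sparse = TRUE)) * crs)
    num_y <- Matrix::colSums((Matrix::Matrix(close_yx, sparse = TRUE) %*% crs) * crs)
  } else {
    num_x <- rowSums((cr %*% close_xy) * cr)
    num_y <- colSums((close_yx %*% cr) * cr)
  }
  list(x = ifelse(kx > 1, num_x / (kx * (kx - 1)), 0),
       y = ifelse(ky > 1, num_y / (ky * (ky - 1)), 0))
}

#' Local cross-clustering coefficients
#'
#' For a vertex v of system X with cross-neighbours U in system Y, the local
#' cross-clustering coefficient is the probability that two distinct
#' cross-neighbours of v are themselves adjacent within system Y; vertices
#' with cross-degree 0 or 1 have coefficient 0. For Y-side vertices the
#' definition mirrors, closing triangles within system X.
#'
#' @param g An `irn_graph`.
#' @param v Vertex indices (`NULL` for all).
#' @param closure Optional list with elements `xy` (adjacency among Y
#'   vertices closing X-side triangles) and `yx` (mirror); defaults to the
#'   graph's own auto blocks. [analyze_pair()] uses this to implement its
#'   scale-matched closure variant.
#' @return Numeric vector of local coefficients for `v`.
#' @export
local_cross_clustering <- function(g, v = NULL, closure = NULL) {
  v <- check_vertices(g, v)
  if (is.null(closure)) closure <- list(xy = g$r_y, yx = g$r_x)
  loc <- cross_clustering_locals(g$cr, closure$xy, closure$yx)
  ifelse(v <= g$n_x, loc$x[pmin(v, g$n_x)], loc$y[pmax(v - g$n_x, 1L)])
}

#' Global cross-clustering coefficient
#'
#' Arithmetic mean of the local cross-clustering coefficients over *all*
#' vertices of one side (zero-degree vertices included).
#'
#' @param g An `irn_graph`.
#' @param from `"x"` for the X-side average (the coefficient toward Y) or
#'   `"y"`.
#' @param closure See [local_cross_clustering()].
#' @return Fraction in \[0, 1\].
#' @export
global_cross_clustering <- function(g, from = c("x", "y"), closure = NULL) {
  from <- match.arg(from)
  n_side <- if (from == "x") g$n_x else g$n_y
  if (n_side == 0) stop("empty partition")
  if (is.null(closure)) closure <- list(xy = g$r_y, yx = g$r_x)
  loc <- cross_clustering_locals(g$cr, closure$xy, closure$yx)
  mean(if (from == "x") loc$x else loc$y)
}

#' Classify the implied coupling direction
#'
#' Applies the fixed-threshold rule to the two global cross-clustering
#' coefficients: differences within `threshold` are read as bidirectional or
#' uncoupled; `c_xy - c_yx < -threshold` implies X drives (the driven system
#' shows the larger coefficient toward the driver), and the mirror image
#' implies Y drives.
#'
#' @param c_xy,c_yx Global cross-clustering coefficients in \[0, 1\].
#' @param threshold Decision threshold (default 0.01).
#' @return One of `"X_leads"`, `"Y_leads"`, `"bidirectional_or_uncoupled"`.
#' @export
classify_direction <- function(c_xy, c_yx, threshold = 0.01) {
  if (!is.finite(c_xy) || !is.finite(c_yx) ||
      c_xy < 0 || c_xy > 1 || c_yx < 0 || c_yx > 1) {
    stop("clustering coefficients must lie in [0, 1]")
  }
  d <- c_xy - c_yx
  if (abs(d) <= threshold) "bidirectional_or_uncoupled"
  else if (d < 0) "X_leads"
  else "Y_leads"
}

#' Full IRN coupling analysis of a pair of series
#'
#' Runs the complete pipeline on two simultaneously observed series:
#' standardize, delay-embed (unless the inputs are already state-vector
#' matrices), calibrate the three thresholds to the target recurrence rates,
#' build the inter-system recurrence network, and compute the coupling
#' measures and implied direction.
#'
#' Two triangle-closure conventions are available for the cross-clustering
#' coefficients. `"within"` closes the triangles of a vertex with the
#' opposite system's own recurrence matrix (its threshold `eps` calibrated on
#' that system). `"scale_matched"` (the default) closes them at the
#' *perspective vertex's* own calibrated threshold, i.e. X-side triangles
#' use `theta(eps_x - ||y_i - y_j||)`. When one system is driven its
#' trajectory fills state space differently and its calibrated threshold can
#' be several times larger than the other system's; under `"within"` closure
#' this scale asymmetry dominates the coefficients and can invert the
#' direction reading. Scale-matched closure tests both coefficients at
#' comparable resolution, which keeps the fixed `+-threshold` direction rule
#' meaningful. The two conventions coincide whenever the two calibrated
#' thresholds agree (in particular for symmetric systems).
#'
#' @param series_x,series_y Numeric vectors (scalar series) or matrices
#'   (native state-space trajectories).
#' @param lag,dim Delay-embedding parameters applied to both scalar series;
#'   ignored for matrix input.
#' @param rr_auto Target auto recurrence rate (both systems).
#' @param rr_cross Target cross recurrence rate (at or below `rr_auto`).
#' @param norm Distance norm.
#' @param closure `"scale_matched"` (default) or `"within"`.
#' @param direction_threshold Threshold of the direction rule.
#' @param scale Standardize the series first (default TRUE).
#' @return A `coupling_summary`: global coefficients `c_xy`, `c_yx`, their
#'   difference `delta_c`, cross-edge density `rho_xy`, the `direction`
#'   label, per-vertex `local_c_xy` / `local_c_yx`, thresholds and realized
#'   recurrence rates.
#' @export
analyze_pair <- function(series_x, series_y, lag = 1, dim = 1,
                         rr_auto = 0.05, rr_cross = 0.03,
                         norm = c("euclidean", "chebyshev"),
                         closure = c("scale_matched", "within"),
                         direction_threshold = 0.01,
                         scale = TRUE) {
  norm <- match.arg(norm)
  closure <- match.arg(closure)
  prep <- function(s) {
    if (is.matrix(s) || is.data.frame(s)) {
      m <- as_state_matrix(s)
      if (scale) m <- apply(m, 2, standardize)
      m
    } else {
      if (scale) s <- standardize(s)
      delay_embed(s, lag, dim)
    }
  }
  tx <- prep(series_x)
  ty <- prep(series_y)
  dx <- pairwise_distances(tx, norm = norm)
  dy <- pairwise_distances(ty, norm = norm)
  dxy <- pairwise_distances(tx, ty, norm = norm)
  eps_x <- threshold_for_rr(dx, rr_auto, "auto")
  eps_y <- threshold_for_rr(dy, rr_auto, "auto")
  eps_xy <- threshold_for_rr(dxy, rr_cross, "cross")
  r_x <- zero_diag(binarize(dx <= eps_x))
  r_y <- zero_diag(binarize(dy <= eps_y))
  cr <- binarize(dxy <= eps_xy)
  g <- build_irn(r_x, r_y, cr)
  g$thresholds <- c(x = eps_x, y = eps_y, xy = eps_xy)
  cl <- if (closure == "within") {
    list(xy = r_y, yx = r_x)
  } else {
    list(xy = zero_diag(binarize(dy <= eps_x)),
         yx = zero_diag(binarize(dx <= eps_y)))
  }
  loc <- cross_clustering_locals(cr, cl$xy, cl$yx)
  c_xy <- mean(loc$x)
  c_yx <- mean(loc$y)
  structure(list(
    c_xy = c_xy, c_yx = c_yx, delta_c = c_xy - c_yx,
    rho_xy = cross_edge_density(g),
    direction = classify_direction(c_xy, c_yx, direction_threshold),
    local_c_xy = loc$x, local_c_yx = loc$y,
    thresholds = g$thresholds,
    realized_rr = c(x = mean(r_x[upper.tri(r_x)]),
                    y = mean(r_y[upper.tri(r_y)]),
                    xy = mean(cr)),
    closure = closure, norm = norm,
    config = list(lag = lag, dim = dim, rr_auto = rr_auto,
                  rr_cross = rr_cross,
                  direction_threshold = direction_threshold)
  ), class = "coupling_summary")
}

#' @export
print.coupling_summary <- function(x, ...) {
  cat("IRN coupling summary\n")
  cat(sprintf("  C^XY = %.4f   C^YX = %.4f   delta C = %+.4f\n",
              x$c_xy, x$c_yx, x$delta_c))
  cat(sprintf("  cross-edge density rho^XY = %.4f\n", x$rho_xy))
  cat(sprintf("  implied direction: %s (threshold %.3g, %s closure)\n",
              x$direction, x$config$direction_threshold, x$closure))
  invisible(x)
}
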