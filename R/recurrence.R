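#' State-space distance matrix
#'
#' Distances between the rows of two trajectories (or all pairs of rows of
#' one trajectory when `b` is absent). The auto case is returned exactly
#' symmetric with a zero diagonal.
#'
#' @param a,b Numeric matrices of state vectors (vectors are treated as
#'   one-dimensional trajectories); `b = NULL` gives the auto case.
#' @param norm `"euclidean"` (default) or `"chebyshev"` (maximum norm).
#' @return Numeric matrix of distances.
#' @export
distance_matrix <- function(a, b = NULL, norm = c("euclidean", "chebyshev")) {
  pairwise_distances(a, b, match.arg(norm))
}

#' Calibrate a recurrence threshold to a target recurrence rate
#'
#' Returns the empirical quantile of the eligible distance population such
#' that thresholding yields the target recurrence rate to within one cell.
#' For auto-recurrence the eligible population is the strict upper triangle
#' (the line of identity is excluded); for cross-recurrence it is all cells.
#' The quantile uses linear interpolation between order statistics
#' (`stats::quantile`, type 7).
#'
#' @param distances Distance matrix (square for `kind = "auto"`).
#' @param target_rr Target recurrence rate in (0, 1).
#' @param kind `"auto"` or `"cross"`.
#' @return Threshold epsilon (state-space distance units).
#' @export
threshold_for_rr <- function(distances, target_rr, kind = c("auto", "cross")) {
  kind <- match.arg(kind)
  if (!is.numeric(target_rr) || target_rr <= 0 || target_rr >= 1) {
    stop("target_rr must lie strictly between 0 and 1")
  }
  pop <- if (kind == "auto") {
    stopifnot(nrow(distances) == ncol(distances))
    distances[upper.tri(distances)]
  } else {
    as.vector(distances)
  }
  if (diff(range(pop)) == 0) {
    stop("all eligible distances are equal; the recurrence rate cannot be controlled")
  }
  stats::quantile(pop, probs = target_rr, names = FALSE, type = 7)
}

recurrence_plot <- function(matrix, kind, epsilon, realized_rr, norm, target_rr = NULL) {
  structure(list(matrix = matrix, kind = kind, epsilon = epsilon,
                 realized_rr = realized_rr, norm = norm, target_rr = target_rr),
            class = "recurrence_plot")
}

#' Auto-recurrence matrix of a trajectory
#'
#' Thresholds the auto-distance matrix: `R_ij = 1` when
#' `||y_i - y_j|| <= epsilon`. The matrix is symmetric; the line of identity
#' is retained in the matrix but excluded from the recurrence-rate
#' accounting (and removed when the matrix enters an IRN adjacency).
#'
#' @param traj Matrix of state vectors (or numeric vector).
#' @param epsilon Recurrence threshold; omit to calibrate from `target_rr`.
#' @param target_rr Target recurrence rate used when `epsilon` is missing.
#' @param norm Distance norm.
#' @return A `recurrence_plot` object: fields `matrix` (0/1 integer),
#'   `kind`, `epsilon`, `realized_rr`, `norm`, `target_rr`.
#' @export
auto_recurrence <- function(traj, epsilon = NULL, target_rr = NULL,
                            norm = c("euclidean", "chebyshev")) {
  norm <- match.arg(norm)
  d <- pairwise_distances(traj, norm = norm)
  if (is.null(epsilon)) {
    if (is.null(target_rr)) stop("supply either epsilon or target_rr")
    epsilon <- threshold_for_rr(d, target_rr, kind = "auto")
  }
  m <- binarize(d <= epsilon)
  recurrence_plot(m, "auto", epsilon, mean(m[upper.tri(m)]), norm, target_rr)
}

#' Cross-recurrence matrix of two trajectories
#'
#' `CR_ij = 1` when `||x_i - y_j|| <= epsilon`: rows index the states of X,
#' columns the states of Y. The matrix is generally asymmetric and is not
#' symmetrized; its transpose is the cross-recurrence of Y relative to X.
#' The recurrence rate is accounted over all cells.
#'
#' @param traj_x,traj_y State-vector matrices with equal column count.
#' @param epsilon Threshold; omit to calibrate from `target_rr` on the
#'   cross-distance population.
#' @param target_rr Target cross recurrence rate.
#' @param norm Distance norm.
#' @return A `recurrence_plot` object with `kind = "cross"`.
#' @export
cross_recurrence <- function(traj_x, traj_y, epsilon = NULL, target_rr = NULL,
                             norm = c("euclidean", "chebyshev")) {
  norm <- match.arg(norm)
  d <- pairwise_distances(traj_x, traj_y, norm = norm)
  if (is.null(epsilon)) {
    if (is.null(target_rr)) stop("supply either epsilon or target_rr")
    epsilon <- threshold_for_rr(d, target_rr, kind = "cross")
  }
  m <- binarize(d <= epsilon)
  recurrence_plot(m, "cross", epsilon, mean(m), norm, target_rr)
}

#' @export
print.recurrence_plot <- function(x, ...) {
  cat(sprintf("%s-recurrence plot: %d x %d, epsilon = %.4g (%s norm), RR = %.4f\n",
              x$kind, nrow(x$matrix), ncol(x$matrix), x$epsilon, x$norm,
              x$realized_rr))
  invisible(x)
}

#' @export
plot.recurrence_plot <- function(x, ...) {
  m <- x$matrix
  graphics::image(x = seq_len(nrow(m)), y = seq_len(ncol(m)), z = m,
                  col = c("white", "black"), useRaster = TRUE,
                  xlab = "i", ylab = "j",
                  main = sprintf("%s-recurrence plot (RR = %.3f)", x$kind, x$realized_rr),
                  ...)
  invisible(x)
}

#' Export a recurrence plot as a coordinate list
#'
#' Writes the (i, j) coordinates of recurrent cells as CSV.
#'
#' @param rp A `recurrence_plot`.
#' @param path Output file.
#' @export
write_recurrence_csv <- function(rp, path) {
  idx <- which(rp$matrix == 1L, arr.ind = TRUE)
  utils::write.csv(data.frame(i = idx[, 1], j = idx[, 2]), path, row.names = FALSE)
  invisible(path)
}

#' Export a recurrence plot in Matrix Market format
#'
#' @param rp A `recurrence_plot`.
#' @param path Output file (`.mtx`).
#' @export
write_recurrence_mm <- function(rp, path) {
  Matrix::writeMM(Matrix::Matrix(rp$matrix, sparse = TRUE), path)
  invisible(path)
}
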