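#' Multiplex inter-system recurrence network over several variables
#'
#' Builds the variable-level multiplex network: one vertex per observed
#' variable; for every unordered variable pair a full IRN coupling analysis
#' links the two variables, the edge weight being the absolute
#' cross-clustering difference `|delta_c|` and the edge label the implied
#' coupling direction. The vertex strength (weighted degree) summarises how
#' strongly a variable participates in the coupling structure.
#'
#' All series must share one sampling rate and one embedding, which is what
#' makes cross-variable cross-recurrence well-defined. How the two persons'
#' streams enter a variable pair is controlled by `pairing`: the default
#' `"cross_person"` analyses person X's variable `a` against person Y's
#' variable `b` (for the pair `a < b` in list order); `"within_x"` /
#' `"within_y"` analyse both variables within one person. The choice is
#' recorded in the graph's `pairing` attribute.
#'
#' @param series_by_variable Named list; each element a list with components
#'   `x` and `y` (the two persons' series for that variable, equal-length
#'   numeric vectors).
#' @param lag,dim Shared embedding parameters.
#' @param rr_auto,rr_cross Target recurrence rates.
#' @param norm Distance norm.
#' @param closure Triangle-closure convention, see [analyze_pair()].
#' @param direction_threshold Direction-rule threshold.
#' @param pairing `"cross_person"` (default), `"within_x"` or `"within_y"`.
#' @return An [igraph::igraph] object with edge attributes `weight`
#'   (`|delta_c|`), `direction`, `c_xy`, `c_yx`, `delta_c` and vertex
#'   attribute `strength`.
#' @export
build_multiplex <- function(series_by_variable, lag = 100, dim = 5,
                            rr_auto = 0.05, rr_cross = 0.04,
                            norm = "euclidean",
                            closure = "scale_matched",
                            direction_threshold = 0.01,
                            pairing = c("cross_person", "within_x", "within_y")) {
  pairing <- match.arg(pairing)
  vars <- names(series_by_variable)
  if (length(vars) < 2) stop("a multiplex network needs at least 2 variables")
  lens <- unlist(lapply(series_by_variable, function(v) c(length(v$x), length(v$y))))
  if (length(unique(lens)) != 1) stop("all series must have the same length")
  pairs <- utils::combn(vars, 2)
  edges <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    sides <- switch(pairing,
      cross_person = list(series_by_variable[[a]]$x, series_by_variable[[b]]$y),
      within_x     = list(series_by_variable[[a]]$x, series_by_variable[[b]]$x),
      within_y     = list(series_by_variable[[a]]$y, series_by_variable[[b]]$y)
    )
    cs <- analyze_pair(sides[[1]], sides[[2]], lag = lag, dim = dim,
                       rr_auto = rr_auto, rr_cross = rr_cross, norm = norm,
                       closure = closure,
                       direction_threshold = direction_threshold)
    data.frame(from = a, to = b, weight = abs(cs$delta_c),
               direction = cs$direction, c_xy = cs$c_xy, c_yx = cs$c_yx,
               delta_c = cs$delta_c)
  })
  g <- igraph::graph_from_data_frame(do.call(rbind, edges), directed = FALSE,
                                     vertices = data.frame(name = vars))
  igraph::V(g)$strength <- igraph::strength(g, weights = igraph::E(g)$weight)
  g <- igraph::set_graph_attr(g, "pairing", pairing)
  g <- igraph::set_graph_attr(g, "lag", lag)
  g <- igraph::set_graph_attr(g, "dim", dim)
  g
}

#' Vertex strengths of a multiplex IRN
#'
#' @param g Multiplex graph from [build_multiplex()].
#' @return Named numeric vector of vertex strengths.
#' @export
multiplex_strength <- function(g) {
  stats::setNames(igraph::V(g)$strength, igraph::V(g)$name)
}

#' Write a multiplex IRN as GraphML
#'
#' @param g Multiplex graph from [build_multiplex()].
#' @param path Output `.graphml` file.
#' @export
write_multiplex_graphml <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Edge list of a multiplex IRN as a data frame
#'
#' @param g Multiplex graph from [build_multiplex()].
#' @return Data frame with one row per variable pair.
#' @export
multiplex_edges <- function(g) {
  igraph::as_data_frame(g, what = "edges")
}
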