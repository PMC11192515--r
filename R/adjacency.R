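#' Build a sensor/vertex adjacency graph from coordinates
#'
#' Two nodes are neighbours iff their Euclidean distance is at most
#' `max_dist`. When a `sensor_layout` is supplied, adjacency is computed
#' within one sensor kind at a time (`kind = "mag"`, `"grad"`, or
#' `"grad_pairs"` for combined planar pairs located at their site).
#'
#' @param x A `sensor_layout`, or a numeric matrix of coordinates with
#'   rownames as node ids (columns = dimensions).
#' @param max_dist Neighbourhood distance threshold, meters (> 0).
#' @param kind Sensor kind when `x` is a layout.
#' @return An `adjacency_graph`: `nodes` (ids), `edges` (2-column character
#'   matrix, each row an unordered pair), `max_dist`.
#' @export
#' @examples
#' g <- build_adjacency(cbind(x = c(0, 0.004), y = 0, z = 0), max_dist = 0.006)
#' nrow(g$edges)  # 1
build_adjacency <- function(x, max_dist, kind = c("mag", "grad", "grad_pairs")) {
  stopifnot_scalar_number(max_dist, "max_dist", positive = TRUE)
  if (inherits(x, "sensor_layout")) {
    kind <- match.arg(kind)
    pos <- layout_positions(x, kind)
  } else {
    pos <- as.matrix(x)
    if (is.null(rownames(pos))) rownames(pos) <- paste0("v", seq_len(nrow(pos)))
  }
  if (!nrow(pos)) stop("empty node set", call. = FALSE)
  if (!all(is.finite(pos))) stop("non-finite coordinates", call. = FALSE)

  d <- as.matrix(stats::dist(pos))
  idx <- which(upper.tri(d) & d <= max_dist, arr.ind = TRUE)
  edges <- cbind(rownames(pos)[idx[, 1]], rownames(pos)[idx[, 2]])
  structure(list(
    nodes = rownames(pos),
    edges = edges,
    max_dist = max_dist
  ), class = "adjacency_graph")
}

#' Create an adjacency graph from explicit nodes and edges
#'
#' @param nodes Character vector of node ids.
#' @param edges Two-column matrix (or data frame) of node id pairs.
#' @return An `adjacency_graph`.
#' @export
adjacency_graph <- function(nodes, edges = matrix(character(), ncol = 2)) {
  nodes <- as.character(nodes)
  if (!length(nodes)) stop("empty node set", call. = FALSE)
  if (anyDuplicated(nodes)) stop("duplicate node ids", call. = FALSE)
  edges <- as.matrix(edges)
  if (length(edges) && ncol(edges) != 2L) stop("`edges` must have two columns", call. = FALSE)
  storage.mode(edges) <- "character"
  if (length(edges)) {
    if (!all(edges %in% nodes)) stop("edge endpoints must be listed nodes", call. = FALSE)
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed", call. = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, max_dist = NULL), class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat(sprintf("<adjacency_graph> %d nodes, %d edges%s\n",
              length(x$nodes), nrow(x$edges),
              if (!is.null(x$max_dist)) sprintf(" (max_dist = %g m)", x$max_dist) else ""))
  invisible(x)
}

# Adjacency list as integer indices into `nodes`, for the cluster kernels.
adjacency_index_list <- function(graph, nodes = graph$nodes) {
  adj <- vector("list", length(nodes))
  if (nrow(graph$edges)) {
    i <- match(graph$edges[, 1], nodes)
    j <- match(graph$edges[, 2], nodes)
    if (anyNA(i) || anyNA(j)) stop("graph does not cover all nodes", call. = FALSE)
    for (e in seq_along(i)) {
      adj[[i[e]]] <- c(adj[[i[e]]], j[e])
      adj[[j[e]]] <- c(adj[[j[e]]], i[e])
    }
  }
  adj
}
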