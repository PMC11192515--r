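#' Write response maps as tidy TSV
#'
#' Long format: `subject`, `condition`, `node`, `f_target`, `value`.
#'
#' @param maps List of `response_map`s.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_response_maps <- function(maps, path) {
  rows <- lapply(maps, function(r) {
    data.frame(
      subject = r$subject_id %||% "", condition = r$condition %||% "",
      node = names(r$values), f_target = r$f_target, value = unname(r$values),
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read response maps from tidy TSV
#'
#' @param path TSV written by [write_response_maps()].
#' @return List of `response_map`s, one per subject x condition.
#' @export
read_response_maps <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject", "condition", "node", "f_target", "value")
  if (!all(need %in% names(df))) {
    stop("response TSV must have columns: ", paste(need, collapse = ","), call. = FALSE)
  }
  key <- interaction(df$subject, df$condition, drop = TRUE)
  lapply(split(df, key), function(g) {
    structure(list(
      values = stats::setNames(g$value, g$node),
      f_target = g$f_target[1],
      subject_id = g$subject[1], condition = g$condition[1]
    ), class = "response_map")
  })
}

#' Write an adjacency graph as an edge-list TSV
#'
#' Nodes without edges are preserved via a header comment-free `nodes` column
#' convention: the file has columns `from`, `to`; isolated nodes appear with
#' an empty `to`.
#'
#' @param graph An `adjacency_graph`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(graph, path) {
  iso <- setdiff(graph$nodes, unique(as.character(graph$edges)))
  df <- rbind(
    if (nrow(graph$edges)) data.frame(from = graph$edges[, 1], to = graph$edges[, 2],
                                      stringsAsFactors = FALSE),
    if (length(iso)) data.frame(from = iso, to = "", stringsAsFactors = FALSE)
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an adjacency graph from an edge-list TSV
#'
#' @param path TSV written by [write_adjacency()].
#' @return An `adjacency_graph`.
#' @export
read_adjacency <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL,
                          colClasses = "character")
  has_edge <- nzchar(df$to)
  adjacency_graph(
    nodes = unique(c(df$from, df$to[has_edge])),
    edges = cbind(df$from[has_edge], df$to[has_edge])
  )
}

#' Save / load an epoch set
#'
#' Epoch sets are dense trial x sensor x time arrays; they are serialized with
#' R's native format. Sensor layouts, response maps and statistical outputs
#' use the plain-text formats documented in their writers.
#'
#' @param x An `epoch_set`.
#' @param path File path (`.rds`).
#' @return `path` invisibly; `read_epoch_set()` returns the `epoch_set`.
#' @export
write_epoch_set <- function(x, path) {
  if (!inherits(x, "epoch_set")) stop("`x` must be an epoch_set", call. = FALSE)
  saveRDS(x, path)
  invisible(path)
}

#' @rdname write_epoch_set
#' @export
read_epoch_set <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "epoch_set")) stop("file does not contain an epoch_set", call. = FALSE)
  x
}
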