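#' Cluster permutation test configuration
#'
#' @param n_permutations Monte Carlo draws for the null distribution
#'   (default 5000).
#' @param alpha Cluster-level significance level (default 0.05).
#' @param cluster_forming_alpha Per-node one-tailed threshold used to form
#'   clusters; nodes with `t` above the `qt(1 - alpha, df)` critical value
#'   enter clusters (default 0.05).
#' @param tail Only `"greater"` (one-tailed, experimental > baseline) is
#'   supported, matching the directional oddball design.
#' @param statistic Cluster statistic: `"mass"` (sum of member t values,
#'   default) or `"size"` (member count).
#' @param seed Integer seed for the permutation draws.
#' @return A `cluster_config`.
#' @export
cluster_config <- function(n_permutations = 5000L, alpha = 0.05,
                           cluster_forming_alpha = 0.05, tail = "greater",
                           statistic = c("mass", "size"), seed = 1L) {
  statistic <- match.arg(statistic)
  tail <- match.arg(tail, "greater")
  stopifnot_scalar_number(n_permutations, "n_permutations", positive = TRUE)
  stopifnot_scalar_number(alpha, "alpha", positive = TRUE)
  if (alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  stopifnot_scalar_number(cluster_forming_alpha, "cluster_forming_alpha", positive = TRUE)
  if (cluster_forming_alpha >= 1) stop("cluster_forming_alpha must be in (0, 1)", call. = FALSE)
  structure(list(
    n_permutations = as.integer(n_permutations), alpha = alpha,
    cluster_forming_alpha = cluster_forming_alpha, tail = tail,
    statistic = statistic, seed = as.integer(seed)
  ), class = "cluster_config")
}

# Coerce response input (subjects x nodes matrix, or list of response_maps)
# to a matrix.
as_response_matrix <- function(x, arg = "responses") {
  if (is.list(x) && !is.data.frame(x) && all(vapply(x, inherits, logical(1), "response_map"))) {
    return(response_matrix(x))
  }
  m <- as.matrix(x)
  if (is.null(colnames(m))) colnames(m) <- paste0("v", seq_len(ncol(m)))
  m
}

#' Node-wise paired t statistics
#'
#' Paired t test per node on experimental-minus-baseline differences;
#' `df = n - 1`. Nodes with zero difference variance have no defined t and are
#' returned as `NA` with a warning (they are excluded from clustering).
#'
#' @param resp_exp,resp_base Subjects x nodes matrices (same subjects, same
#'   node order), or lists of per-subject [extract_response()] maps.
#' @return List with `t` (named per node), `df`, `excluded` (node ids with
#'   zero variance).
#' @export
paired_t_map <- function(resp_exp, resp_base) {
  e <- as_response_matrix(resp_exp)
  b <- as_response_matrix(resp_base)
  if (!identical(dim(e), dim(b)) || !identical(colnames(e), colnames(b))) {
    stop("experimental and baseline responses must match in subjects and nodes", call. = FALSE)
  }
  n <- nrow(e)
  if (n < 2L) stop("at least 2 subjects are required", call. = FALSE)
  d <- e - b
  m <- colMeans(d)
  s <- apply(d, 2L, stats::sd)
  t <- m / (s / sqrt(n))
  bad <- s == 0
  if (any(bad)) {
    t[bad] <- NA_real_
    warning(sprintf("%d node(s) with zero difference variance excluded from t map", sum(bad)),
            call. = FALSE)
  }
  list(t = t, df = n - 1L, excluded = colnames(d)[bad])
}

# Connected components of suprathreshold nodes. tv: numeric (NA = excluded),
# adj: integer adjacency list. Returns list of integer member vectors.
clusters_above <- function(tv, thresh, adj) {
  supra <- !is.na(tv) & tv > thresh
  out <- list()
  visited <- !supra
  for (s in which(supra)) {
    if (visited[s]) next
    comp <- integer(0)
    queue <- s
    visited[s] <- TRUE
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      comp <- c(comp, v)
      for (w in adj[[v]]) {
        if (!visited[w]) {
          visited[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    out[[length(out) + 1L]] <- sort(comp)
  }
  out
}

cluster_stat <- function(tv, members, statistic) {
  if (statistic == "size") length(members) else sum(tv[members])
}

# Largest cluster statistic for one t map (0 when no node is suprathreshold).
max_cluster_stat <- function(tv, thresh, adj, statistic) {
  cl <- clusters_above(tv, thresh, adj)
  if (!length(cl)) return(0)
  max(vapply(cl, function(m) cluster_stat(tv, m, statistic), numeric(1)))
}

# All permutation t maps from sign flips in one matrix product: per-node sums
# of squares are invariant under sign flips, so only the means move.
signflip_t_maps <- function(d, signs) {
  n <- nrow(d)
  m <- (signs %*% d) / n
  ss <- rep(colSums(d^2), each = nrow(signs))
  v <- (ss - n * m^2) / (n - 1L)
  v[v < 0] <- 0                       # numerical guard
  m / sqrt(v / n)
}

exhaustive_sign_matrix <- function(n, rows) {
  s <- matrix(1, nrow = length(rows), ncol = n)
  for (j in seq_len(n)) {
    s[, j] <- ifelse(bitwAnd(rows, bitwShiftL(1L, j - 1L)) > 0L, -1, 1)
  }
  s
}

cluster_engine <- function(d, graph, cfg, exhaustive) {
  nodes <- colnames(d)
  if (!all(nodes %in% graph$nodes)) stop("graph does not cover all nodes", call. = FALSE)
  n <- nrow(d)
  df <- n - 1L
  adj <- adjacency_index_list(graph, nodes)

  m <- colMeans(d)
  s <- apply(d, 2L, stats::sd)
  tv <- m / (s / sqrt(n))
  keep <- s > 0
  if (!all(keep)) {
    warning(sprintf("%d node(s) with zero difference variance excluded from clustering",
                    sum(!keep)), call. = FALSE)
    tv[!keep] <- NA_real_
  }
  thresh <- stats::qt(1 - cfg$cluster_forming_alpha, df)

  cl_members <- clusters_above(tv, thresh, adj)
  masses <- vapply(cl_members, function(mm) cluster_stat(tv, mm, cfg$statistic), numeric(1))

  if (exhaustive) {
    total <- 2^n
    chunk <- 2^14
    null_dist <- numeric(0)
    start <- 0
    while (start < total) {
      rows <- as.integer(start:min(start + chunk - 1, total - 1))
      tm <- signflip_t_maps(d, exhaustive_sign_matrix(n, rows))
      tm[, !keep] <- NA_real_
      null_dist <- c(null_dist, apply_max_stat(tm, thresh, adj, cfg$statistic))
      start <- start + chunk
    }
    p <- vapply(masses, function(ms) mean(null_dist >= ms), numeric(1))
    method <- "exhaustive"
  } else {
    signs <- with_seed(cfg$seed,
                       matrix(sample(c(-1, 1), cfg$n_permutations * n, replace = TRUE),
                              nrow = cfg$n_permutations))
    tm <- signflip_t_maps(d, signs)
    tm[, !keep] <- NA_real_
    null_dist <- apply_max_stat(tm, thresh, adj, cfg$statistic)
    p <- vapply(masses, function(ms) (1 + sum(null_dist >= ms)) / (1 + cfg$n_permutations),
                numeric(1))
    method <- "montecarlo"
  }

  ord <- order(masses, decreasing = TRUE)
  clusters <- lapply(ord, function(i) list(
    members = nodes[cl_members[[i]]],
    mass = masses[i],
    p = p[i],
    significant = p[i] < cfg$alpha
  ))
  structure(list(
    clusters = clusters,
    t_map = tv, df = df, threshold = thresh,
    null_distribution = null_dist,
    method = method, config = cfg
  ), class = "cluster_result")
}

apply_max_stat <- function(t_maps, thresh, adj, statistic) {
  apply(t_maps, 1L, max_cluster_stat, thresh = thresh, adj = adj, statistic = statistic)
}

#' Paired cluster-based permutation test on an adjacency graph
#'
#' Tests whether experimental responses exceed baseline responses anywhere on
#' the graph while controlling the family-wise error rate. Node-wise paired t
#' statistics are thresholded at the one-tailed critical value
#' (`cluster_forming_alpha`, `df = n - 1`); suprathreshold nodes are grouped
#' into connected components; each component's statistic (mass = sum of t) is
#' compared with the permutation null of the maximum statistic under random
#' per-subject sign flips of the difference maps — the exact exchangeability
#' scheme for a paired design. Monte Carlo p values use the
#' `(1 + exceedances) / (1 + n_permutations)` correction. When
#' `n_permutations` is at least the number of distinct sign assignments
#' (`2^n`), the test falls back to exhaustive enumeration and reports exact
#' permutation p values.
#'
#' @param resp_exp,resp_base Subjects x nodes matrices or lists of
#'   `response_map`s.
#' @param graph An [adjacency_graph] covering all nodes.
#' @param cfg A [cluster_config()].
#' @return A `cluster_result`: `clusters` (members, mass, p, significant),
#'   `t_map`, `df`, `threshold`, `null_distribution`, `method`.
#' @export
cluster_permutation_test <- function(resp_exp, resp_base, graph, cfg = cluster_config()) {
  e <- as_response_matrix(resp_exp)
  b <- as_response_matrix(resp_base)
  if (!identical(dim(e), dim(b)) || !identical(colnames(e), colnames(b))) {
    stop("experimental and baseline responses must match in subjects and nodes", call. = FALSE)
  }
  if (nrow(e) < 2L) stop("at least 2 subjects are required", call. = FALSE)
  d <- e - b
  n <- nrow(d)
  exhaustive <- n <= 20 && cfg$n_permutations >= 2^n
  if (exhaustive) {
    message(sprintf(
      "n_permutations (%d) >= 2^%d unique sign flips: using exhaustive enumeration",
      cfg$n_permutations, n
    ))
  }
  cluster_engine(d, graph, cfg, exhaustive = exhaustive)
}

#' Exhaustive sign-flip cluster test
#'
#' Same contract as [cluster_permutation_test()] but enumerates all `2^n`
#' per-subject sign assignments, giving exact permutation p values
#' (`p = #\{null >= observed\} / 2^n`, never below `1 / 2^n` since the identity
#' assignment is included). Serves as the oracle for the Monte Carlo engine.
#'
#' @inheritParams cluster_permutation_test
#' @return A `cluster_result` with `method = "exhaustive"`.
#' @export
exhaustive_signflip_test <- function(resp_exp, resp_base, graph, cfg = cluster_config()) {
  e <- as_response_matrix(resp_exp)
  b <- as_response_matrix(resp_base)
  if (!identical(dim(e), dim(b)) || !identical(colnames(e), colnames(b))) {
    stop("experimental and baseline responses must match in subjects and nodes", call. = FALSE)
  }
  n <- nrow(e)
  if (n < 2L) stop("at least 2 subjects are required", call. = FALSE)
  if (n > 20L) stop("n > 20: 2^n sign assignments are not enumerable; use cluster_permutation_test",
                    call. = FALSE)
  cluster_engine(e - b, graph, cfg, exhaustive = TRUE)
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %s, df = %d, %d cluster(s)\n",
              x$method, x$df, length(x$clusters)))
  for (cl in x$clusters) {
    cat(sprintf("  %s = %.2f over %d node(s), p = %.4g%s\n",
                x$config$statistic, cl$mass, length(cl$members), cl$p,
                if (cl$significant) " *" else ""))
  }
  invisible(x)
}
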