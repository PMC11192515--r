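make_line_graph <- function(p) {
  build_adjacency(cbind(x = seq_len(p) / 10, y = 0, z = 0), max_dist = 0.15)
}

test_that("paired t map equals the textbook formula and flags zero variance", {
  set.seed(5)
  n <- 21
  e <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("v", 1:6)))
  b <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("v", 1:6)))
  tm <- paired_t_map(e, b)
  expect_equal(tm$df, 20L)
  for (j in 1:6) {
    expect_equal(unname(tm$t[j]),
                 unname(t.test(e[, j], b[, j], paired = TRUE)$statistic),
                 tolerance = 1e-12)
  }

  # exp = base + constant at one node: zero difference variance, excluded
  e2 <- b + matrix(rnorm(n * 6), n, 6)
  e2[, 2] <- b[, 2]
  e2[, 2][] <- 1
  b2 <- b
  b2[, 2][] <- 0
  expect_warning(tm2 <- paired_t_map(e2, b2), "zero difference variance")
  expect_true(is.na(tm2$t[2]))
  expect_equal(tm2$excluded, "v2")
  # antisymmetric differences: mean zero, t = 0
  d <- rnorm(n)
  d <- d - mean(d)
  e3 <- b + matrix(rnorm(n * 6), n, 6)
  e3[, 1] <- b[, 1] + d
  expect_equal(unname(paired_t_map(e3, b)$t[1]), 0, tolerance = 1e-12)
})

test_that("identical conditions produce no clusters", {
  set.seed(9)
  b <- matrix(rnorm(10 * 8), 10, 8, dimnames = list(NULL, paste0("v", 1:8)))
  g <- make_line_graph(8)
  expect_warning(res <- cluster_permutation_test(b, b, g,
                                                 cluster_config(n_permutations = 50, seed = 1)),
                 "zero difference variance")
  expect_length(res$clusters, 0L)
})

test_that("a strong connected effect is detected with the p-value floor", {
  g <- make_line_graph(20)
  hits <- vapply(1:20, function(r) {
    set.seed(100 + r)
    n <- 12
    b <- matrix(rnorm(n * 20), n, 20, dimnames = list(NULL, g$nodes))
    e <- b + matrix(rnorm(n * 20, 0, 1), n, 20)
    e[, 1:5] <- e[, 1:5] + 10
    res <- cluster_permutation_test(e, b, g, cluster_config(n_permutations = 500, seed = r))
    top <- res$clusters[[1]]
    # the p-value floor is 1/(n_permutations + 1); random draws may include the
    # identity assignment, which ties the observed mass, so allow a few ties
    top$significant && all(g$nodes[1:5] %in% top$members) &&
      top$p >= 1 / 501 - 1e-12 && top$p <= 4 / 501
  }, logical(1))
  expect_true(all(hits))
})

test_that("n = 3 exhaustive p matches hand enumeration on a 2-node graph", {
  g <- adjacency_graph(c("a", "b"), rbind(c("a", "b")))
  e <- matrix(c(1, 2, 3, 0.5, 1, 1.5), ncol = 2, dimnames = list(NULL, c("a", "b")))
  b <- matrix(0, 3, 2, dimnames = list(NULL, c("a", "b")))
  res <- exhaustive_signflip_test(e, b, g, cluster_config())
  expect_equal(res$method, "exhaustive")
  expect_length(res$clusters, 1L)

  # independent enumeration over all 8 sign assignments
  d <- e - b
  thresh <- qt(0.95, df = 2)
  enum_mass <- function(dd) {
    tt <- apply(dd, 2, function(x) mean(x) / (sd(x) / sqrt(3)))
    supra <- which(tt > thresh)
    if (!length(supra)) return(0)
    sum(tt[supra])      # both nodes adjacent: one cluster if both supra
  }
  null <- numeric(8)
  k <- 0
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
    k <- k + 1
    null[k] <- enum_mass(d * c(s1, s2, s3))
  }
  obs <- enum_mass(d)
  expect_equal(res$clusters[[1]]$mass, obs, tolerance = 1e-12)
  expect_equal(res$clusters[[1]]$p, mean(null >= obs))
  expect_gte(res$clusters[[1]]$p, 1 / 8)
})

test_that("Monte Carlo falls back to exhaustive enumeration and matches it exactly", {
  for (n in c(8, 10)) {
    set.seed(n)
    p <- 12
    g <- make_line_graph(p)
    b <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, g$nodes))
    e <- b + matrix(rnorm(n * p, 0.9), n, p)
    expect_message(
      mc <- cluster_permutation_test(e, b, g, cluster_config(n_permutations = 5000, seed = 2)),
      "exhaustive enumeration"
    )
    ex <- exhaustive_signflip_test(e, b, g, cluster_config())
    expect_equal(mc$method, "exhaustive")
    expect_equal(vapply(mc$clusters, `[[`, numeric(1), "p"),
                 vapply(ex$clusters, `[[`, numeric(1), "p"))
    expect_equal(vapply(mc$clusters, `[[`, numeric(1), "mass"),
                 vapply(ex$clusters, `[[`, numeric(1), "mass"))
    expect_identical(lapply(mc$clusters, `[[`, "members"),
                     lapply(ex$clusters, `[[`, "members"))
  }
  expect_error(exhaustive_signflip_test(matrix(0, 21, 2), matrix(0, 21, 2),
                                        adjacency_graph(c("v1", "v2"))),
               "not enumerable")
})

test_that("cluster p values are super-uniform under the null", {
  g <- make_line_graph(10)
  n <- 12
  pm <- vapply(1:400, function(r) {
    set.seed(3000 + r)
    b <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, g$nodes))
    e <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, g$nodes))
    res <- cluster_permutation_test(e, b, g, cluster_config(n_permutations = 250, seed = r))
    ps <- vapply(res$clusters, `[[`, numeric(1), "p")
    if (length(ps)) min(ps) else 1
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pm, "punif", alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(mean(pm < 0.05), 0.1)
})

test_that("cluster size statistic is available and clusters stay graph-connected", {
  set.seed(77)
  g <- make_line_graph(15)
  n <- 10
  b <- matrix(rnorm(n * 15), n, 15, dimnames = list(NULL, g$nodes))
  e <- b + 1.2
  e <- e + matrix(rnorm(n * 15, 0, 0.5), n, 15)
  res <- cluster_permutation_test(e, b, g, cluster_config(n_permutations = 200,
                                                          statistic = "size", seed = 5))
  for (cl in res$clusters) {
    expect_equal(cl$mass, length(cl$members))
    idx <- sort(match(cl$members, g$nodes))
    # on a line graph a connected component is a contiguous index run
    expect_true(all(diff(idx) == 1))
  }
})
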