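two_node_graph <- function(weight = 1) {
  bgcrank:::new_graph(
    data.frame(node = c("S1", "C1"), class = c("section", "feature"),
               stringsAsFactors = FALSE),
    data.frame(from = "S1", to = "C1", weight = weight,
               stringsAsFactors = FALSE))
}

test_that("graphs are built from positive cells only", {
  m <- matrix(5, 1, 1, dimnames = list("s1", "c1"))
  g <- build_graph(m)
  expect_equal(nrow(g$nodes), 2L)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$weight, 5)

  m2 <- matrix(c(1, 2, 3, 4), 2, 2,
               dimnames = list(c("s1", "s2"), c("c1", "c2")))
  g2 <- build_graph(m2)
  expect_equal(nrow(g2$nodes), 4L)
  expect_equal(nrow(g2$edges), 4L)

  m3 <- matrix(c(1, 0, 0, 0), 2, 2,
               dimnames = list(c("s1", "s2"), c("c1", "c2")))
  g3 <- build_graph(m3)
  expect_false("c2" %in% g3$nodes$node)  # all-zero column dropped
  g3k <- build_graph(m3, keep_isolated = TRUE)
  expect_true("c2" %in% g3k$nodes$node)
  expect_equal(nrow(g3k$edges), 1L)

  expect_error(build_graph(matrix(numeric(0), 0, 0)),
               class = "bgcrank_validation_error")
  expect_error(build_graph(matrix(0, 1, 1, dimnames = list("s", "c"))),
               class = "bgcrank_validation_error")
})

test_that("node strengths sum edge weights and balance globally", {
  m <- matrix(c(2, 0, 1, 4), 2, 2,
              dimnames = list(c("S1", "S2"), c("C1", "C2")))
  g <- build_graph(m)
  s <- node_strength(g)
  str_of <- function(col, n) s[[col]][s$node == n]
  expect_equal(str_of("out_strength", "S1"), 3)
  expect_equal(str_of("in_strength", "C1"), 2)
  expect_equal(str_of("in_strength", "S1"), 0)
  expect_equal(str_of("out_strength", "C2"), 0)
  expect_equal(sum(s$out_strength), sum(s$in_strength))
  expect_equal(sum(s$out_strength), sum(g$edges$weight))
})

test_that("the two-node chain reproduces the closed-form stationary vector", {
  pr <- pagerank(two_node_graph())
  expect_equal(unname(pr[["S1"]]), 0.35087719298, tolerance = 1e-9)
  expect_equal(unname(pr[["C1"]]), 0.64912280702, tolerance = 1e-9)
  expect_equal(sum(pr), 1, tolerance = 1e-12)
})

test_that("symmetric components get identical scores and vectors are stochastic", {
  g <- bgcrank:::new_graph(
    data.frame(node = c("S1", "S2", "C1", "C2"),
               class = c("section", "section", "feature", "feature"),
               stringsAsFactors = FALSE),
    data.frame(from = c("S1", "S2"), to = c("C1", "C2"), weight = c(2, 2),
               stringsAsFactors = FALSE))
  pr <- pagerank(g)
  expect_equal(pr[["S1"]], pr[["S2"]])
  expect_equal(pr[["C1"]], pr[["C2"]])
  for (seed in 1:10) {
    pr <- pagerank(random_graph(sample(2:8, 1L), seed + 500))
    expect_lt(abs(sum(pr) - 1), 1e-9)
    expect_true(all(pr > 0))
  }
})

test_that("power iteration agrees with the dense linear-solve oracle", {
  worst <- 0
  for (seed in 1:100) {
    set.seed(seed)
    g <- random_graph(sample(2:8, 1L), seed)
    pr <- pagerank(g)
    oracle <- dense_pagerank_oracle(g)
    worst <- max(worst, max(abs(pr[names(oracle)] - oracle)))
  }
  expect_lt(worst, 1e-8)
})

test_that("pagerank is invariant to edge-weight scaling; strengths are not", {
  g <- random_graph(6, 321)
  scaled <- bgcrank:::new_graph(g$nodes, transform(g$edges, weight = weight * 7))
  expect_equal(as.numeric(pagerank(g)), as.numeric(pagerank(scaled)),
               tolerance = 1e-9)
  expect_equal(node_strength(scaled)$out_strength,
               node_strength(g)$out_strength * 7)
})

test_that("non-convergence raises an error carrying the residual", {
  g <- random_graph(6, 11)
  params <- pagerank_params(tolerance = 1e-14, max_iterations = 2L)
  err <- tryCatch(pagerank(g, params), bgcrank_convergence_error = identity)
  expect_s3_class(err, "bgcrank_convergence_error")
  expect_true(is.numeric(err$residual) && err$residual > 0)
})

test_that("broadcasting equals receiving on the reversed graph", {
  for (seed in 1:50) {
    set.seed(seed)
    g <- random_graph(sample(2:8, 1L), seed + 1000)
    res_g <- suppressWarnings(broadcast_receive(g))
    res_rev <- suppressWarnings(broadcast_receive(reverse_graph(g)))
    expect_identical(res_g$broadcast_raw, res_rev$receive_raw)
    expect_identical(res_g$receive_raw, res_rev$broadcast_raw)
  }
})

test_that("broadcasting favors the sender in a single-edge graph", {
  res <- suppressWarnings(broadcast_receive(two_node_graph()))
  b <- setNames(res$broadcast_raw, res$node)
  expect_gt(b[["S1"]], b[["C1"]])
  r <- setNames(res$receive_raw, res$node)
  expect_gt(r[["C1"]], r[["S1"]])
})

test_that("a five-fold dominant section tops the normalized broadcast scores", {
  m <- matrix(c(5, 1, 1,
                5, 1, 1,
                5, 1, 1), nrow = 3,
              dimnames = list(c("sA", "sB", "sC"), c("c1", "c2", "c3")))
  res <- suppressWarnings(broadcast_receive(build_graph(m)))
  sec <- res[res$class == "section", ]
  expect_equal(sec$broadcast_norm[sec$node == "sA"], 1.0)
  expect_true(all(sec$broadcast_norm[sec$node != "sA"] < 1))
  # cross-check the raw vector against the dense oracle on this small graph
  oracle <- dense_pagerank_oracle(reverse_graph(build_graph(m)))
  expect_equal(setNames(res$broadcast_raw, res$node)[names(oracle)], oracle,
               tolerance = 1e-8)
})

test_that("min-max normalization maps affinely onto [0, 1]", {
  x <- c(a = 1, b = 3, c = 5)
  expect_equal(minmax_normalize(x), c(a = 0, b = 0.5, c = 1))
  expect_warning(z <- minmax_normalize(c(a = 2, b = 2)), "degenerate")
  expect_equal(unname(z), c(0, 0))
  set.seed(1)
  y <- setNames(rnorm(20), paste0("n", 1:20))
  ny <- minmax_normalize(y)
  expect_equal(order(ny), order(y))
  expect_true(all(ny >= 0 & ny <= 1))
})

test_that("normalized argmax coincides with raw argmax per node class", {
  for (seed in 1:10) {
    fx <- random_count_fixture(seed + 300)
    m <- section_average(fx$counts, fx$species)
    g <- tryCatch(build_graph(m), bgcrank_validation_error = function(e) NULL)
    if (is.null(g)) next
    res <- suppressWarnings(broadcast_receive(g))
    sec <- res[res$class == "section", ]
    if (nrow(sec) > 1L && max(sec$broadcast_norm) > 0) {
      expect_equal(which.max(sec$broadcast_raw), which.max(sec$broadcast_norm))
    }
    feat <- res[res$class == "feature", ]
    if (nrow(feat) > 1L && max(feat$receive_norm) > 0) {
      expect_equal(which.max(feat$receive_raw), which.max(feat$receive_norm))
    }
  }
})

test_that("weighted pagerank matches igraph on random graphs", {
  skip_if_not_installed("igraph")
  for (seed in c(2, 17, 42)) {
    g <- random_graph(7, seed, p = 0.5)
    ig <- igraph::graph_from_data_frame(g$edges, directed = TRUE,
                                        vertices = g$nodes$node)
    ref <- igraph::page_rank(ig, damping = 0.85,
                             weights = igraph::E(ig)$weight)$vector
    pr <- pagerank(g)
    expect_equal(unname(pr[names(ref)]), unname(ref), tolerance = 1e-6)
  }
})
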