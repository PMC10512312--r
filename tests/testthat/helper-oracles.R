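# Independent oracles and random-instance generators shared across tests.

# Random directed weighted graph on n_nodes (possibly with dangling nodes,
# cycles, etc.) -- deliberately more general than the bipartite graphs the
# pipeline builds.
random_graph <- function(n_nodes, seed, p = 0.4) {
  set.seed(seed)
  nodes <- sprintf("N%d", seq_len(n_nodes))
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  keep <- stats::runif(nrow(pairs)) < p
  if (!any(keep)) keep[sample.int(nrow(pairs), 1L)] <- TRUE
  e <- pairs[keep, , drop = FALSE]
  e$weight <- stats::runif(nrow(e), 0.1, 5)
  rownames(e) <- NULL
  bgcrank:::new_graph(
    data.frame(node = nodes, class = "section", stringsAsFactors = FALSE),
    e)
}

# Closed-form PageRank: with the dangling rows of the row-stochastic
# transition matrix replaced by uniform rows, the stationary vector solves
# (I - alpha * t(M)) pi = (1 - alpha)/n * 1.
dense_pagerank_oracle <- function(graph, damping = 0.85) {
  nodes <- graph$nodes$node
  n <- length(nodes)
  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- graph$edges
  if (nrow(e) > 0L) {
    out <- tapply(e$weight, e$from, sum)
    M[cbind(e$from, e$to)] <- e$weight / as.numeric(out[e$from])
  }
  dang <- rowSums(M) == 0
  M[dang, ] <- 1 / n
  pi_v <- solve(diag(n) - damping * t(M), rep((1 - damping) / n, n))
  stats::setNames(pi_v, nodes)
}

# Random long-format count fixture over a random species/section layout.
random_count_fixture <- function(seed) {
  set.seed(seed)
  n_sections <- sample(2:4, 1L)
  per <- sample(1:5, n_sections, replace = TRUE)
  sections <- sprintf("sec%d", seq_len(n_sections))
  sp <- species_table(
    species_id = sprintf("sp%02d", seq_len(sum(per))),
    section = rep(sections, per)
  )
  cats <- sprintf("cat%d", seq_len(sample(2:6, 1L)))
  grid <- expand.grid(species_id = sp$species_id, category = cats,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  # leave some (species, category) pairs unrecorded to exercise implicit zeros
  grid <- grid[stats::runif(nrow(grid)) < 0.8, , drop = FALSE]
  counts <- if (nrow(grid) == 0L) {
    count_table(sp$species_id[1L], cats[1L], 1L)
  } else {
    count_table(grid$species_id, grid$category,
                stats::rpois(nrow(grid), 3))
  }
  list(species = sp, counts = counts)
}

expect_same_table <- function(a, b) {
  expect_equal(as.data.frame(a), as.data.frame(b))
}
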