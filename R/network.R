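#' Build the weighted directed section-to-feature graph
#'
#' Each section and each feature category with at least one positive cell
#' becomes a node; every positive cell (s, c) becomes a directed edge
#' s -> c weighted by the section-average count. Zero cells produce no
#' edge. Categories whose column is entirely zero are dropped unless
#' `keep_isolated = TRUE`, in which case they appear as isolated feature
#' nodes.
#'
#' @param matrix A `section_matrix` from [section_average()] (any numeric
#'   matrix with dimnames works).
#' @param keep_isolated Keep all-zero categories as isolated nodes.
#' @return An object of class `section_graph`: list with `nodes`
#'   (data frame `node`, `class`) and `edges` (data frame `from`, `to`,
#'   `weight`).
#' @export
build_graph <- function(matrix, keep_isolated = FALSE) {
  m <- unclass(matrix)
  if (is.null(dim(m)) || nrow(m) == 0L || ncol(m) == 0L) {
    stop_validation("section matrix is empty: no graph can be built")
  }
  if (any(!is.finite(m)) || any(m < 0)) {
    stop_validation("section matrix cells must be finite and non-negative")
  }
  sections <- rownames(m)
  categories <- colnames(m)
  if (is.null(sections) || is.null(categories)) {
    stop_validation("section matrix needs row and column names")
  }
  keep_cat <- if (keep_isolated) rep(TRUE, ncol(m)) else colSums(m) > 0
  if (!any(keep_cat)) {
    stop_validation("all categories have zero counts: the graph has no edges")
  }
  categories <- categories[keep_cat]
  m <- m[, keep_cat, drop = FALSE]
  clash <- intersect(sections, categories)
  if (length(clash) > 0L) {
    stop_validation(sprintf("labels used both as section and category: %s",
                            paste(clash, collapse = ", ")))
  }
  idx <- which(m > 0, arr.ind = TRUE)
  edges <- data.frame(
    from = sections[idx[, 1L]],
    to = categories[idx[, 2L]],
    weight = m[idx],
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  new_graph(
    nodes = data.frame(
      node = c(sections, categories),
      class = rep(c("section", "feature"),
                  c(length(sections), length(categories))),
      stringsAsFactors = FALSE
    ),
    edges = edges
  )
}

new_graph <- function(nodes, edges) {
  if (anyDuplicated(nodes$node)) {
    stop_validation("node labels must be unique")
  }
  if (nrow(edges) > 0L) {
    if (any(!edges$from %in% nodes$node) || any(!edges$to %in% nodes$node)) {
      stop_validation("edges refer to unknown nodes")
    }
    if (any(!is.finite(edges$weight)) || any(edges$weight <= 0)) {
      stop_validation("edge weights must be strictly positive and finite")
    }
  }
  structure(list(nodes = nodes, edges = edges), class = "section_graph")
}

#' Reverse every edge of a graph
#'
#' @param graph A `section_graph`.
#' @return The graph with each edge direction flipped, weights unchanged.
#' @export
reverse_graph <- function(graph) {
  e <- graph$edges
  new_graph(graph$nodes,
            data.frame(from = e$to, to = e$from, weight = e$weight,
                       stringsAsFactors = FALSE))
}

#' Node strength (weighted degree)
#'
#' Out-strength is the summed weight of a node's outgoing edges,
#' in-strength of its incoming edges. In the bipartite section graph,
#' feature nodes have zero out-strength and section nodes zero
#' in-strength.
#'
#' @param graph A `section_graph`.
#' @return Data frame with columns `node`, `class`, `out_strength`,
#'   `in_strength` (node order as in the graph).
#' @export
node_strength <- function(graph) {
  nodes <- graph$nodes
  out_s <- stats::setNames(numeric(nrow(nodes)), nodes$node)
  in_s <- out_s
  if (nrow(graph$edges) > 0L) {
    o <- tapply(graph$edges$weight, graph$edges$from, sum)
    i <- tapply(graph$edges$weight, graph$edges$to, sum)
    out_s[names(o)] <- o
    in_s[names(i)] <- i
  }
  data.frame(node = nodes$node, class = nodes$class,
             out_strength = as.numeric(out_s),
             in_strength = as.numeric(in_s),
             stringsAsFactors = FALSE)
}

#' PageRank solver parameters
#'
#' @param damping Probability of following an edge rather than teleporting
#'   uniformly; in (0, 1), default 0.85.
#' @param tolerance Convergence threshold on the L1 residual between
#'   successive iterates.
#' @param max_iterations Iteration cap; exceeding it is an error.
#' @return A list of class `pagerank_params`.
#' @export
pagerank_params <- function(damping = 0.85, tolerance = 1e-10,
                            max_iterations = 1000L) {
  if (!(length(damping) == 1L && damping > 0 && damping < 1)) {
    stop_config("damping must lie strictly between 0 and 1")
  }
  if (!(length(tolerance) == 1L && tolerance > 0)) {
    stop_config("tolerance must be positive")
  }
  if (!(length(max_iterations) == 1L && max_iterations >= 1)) {
    stop_config("max_iterations must be a positive integer")
  }
  structure(list(damping = as.numeric(damping),
                 tolerance = as.numeric(tolerance),
                 max_iterations = as.integer(max_iterations)),
            class = "pagerank_params")
}

#' Weighted PageRank by power iteration
#'
#' Computes the stationary distribution of the damped random walk on a
#' weighted directed graph: from a node with out-edges the walker follows
#' edge (v, u) with probability `w(v, u) / out_strength(v)`; from a
#' dangling node (no out-edges) it jumps uniformly over all nodes; with
#' probability `1 - damping` it teleports uniformly. Iteration stops when
#' the L1 residual between successive iterates drops below the tolerance.
#'
#' @param graph A `section_graph`.
#' @param params A [pagerank_params()].
#' @return Named numeric vector summing to 1, with attributes
#'   `iterations` and `residual`.
#' @export
pagerank <- function(graph, params = pagerank_params()) {
  nodes <- graph$nodes$node
  n <- length(nodes)
  if (n == 0L) stop_validation("graph has no nodes")
  alpha <- params$damping
  e <- graph$edges
  # row-stochastic transition matrix restricted to non-dangling rows
  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(e) > 0L) {
    out_s <- tapply(e$weight, e$from, sum)
    M[cbind(e$from, e$to)] <- e$weight / as.numeric(out_s[e$from])
  }
  dangling <- !(nodes %in% e$from)
  pi_v <- rep(1 / n, n)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    new_v <- alpha * (drop(pi_v %*% M) + sum(pi_v[dangling]) / n) +
      (1 - alpha) / n
    res <- sum(abs(new_v - pi_v))
    pi_v <- new_v
    if (res < params$tolerance) break
    if (iter >= params$max_iterations) {
      stop_bgcrank("bgcrank_convergence_error",
                   sprintf("PageRank did not converge in %d iterations (last L1 residual %.3e)",
                           iter, res),
                   residual = res, iterations = iter)
    }
  }
  pi_v <- pi_v / sum(pi_v)
  structure(stats::setNames(pi_v, nodes), iterations = iter, residual = res)
}

#' Min-max normalize scores over a node subset
#'
#' Affine rescaling onto `[0, 1]` within `subset`: the minimum maps to 0
#' and the maximum to 1, preserving order. A degenerate range (all scores
#' equal) maps every value to 0 with a warning, since no variation carries
#' no ranking signal.
#'
#' @param scores Named numeric vector.
#' @param subset Node names to normalize over (default: all).
#' @return Named numeric vector over `subset`, values in `[0, 1]`.
#' @export
minmax_normalize <- function(scores, subset = names(scores)) {
  if (length(subset) == 0L) stop_config("subset must be non-empty")
  x <- scores[subset]
  rng <- range(x)
  if (rng[1L] == rng[2L]) {
    warning("degenerate range in min-max normalization: all values map to 0",
            call. = FALSE)
    return(stats::setNames(rep(0, length(x)), subset))
  }
  stats::setNames((x - rng[1L]) / (rng[2L] - rng[1L]), subset)
}

#' Broadcasting and receiving centrality of a section graph
#'
#' Receiving centrality is the weighted PageRank of the graph as built
#' (influence accumulates along section -> feature edges); broadcasting
#' centrality is the PageRank of the edge-reversed graph, so a section is
#' influential when it points at strongly receiving features. Raw scores
#' are min-max normalized separately within the section nodes and within
#' the feature nodes, mirroring how each node class is displayed on its
#' own `[0, 1]` axis.
#'
#' @param graph A `section_graph`.
#' @param params A [pagerank_params()].
#' @param binarize Replace all edge weights by 1 before the PageRank
#'   computation (strengths are still reported from the true weights).
#' @return A data frame of class `centrality_result` with one row per node
#'   and columns `node`, `class`, `out_strength`, `in_strength`,
#'   `broadcast_raw`, `receive_raw`, `broadcast_norm`, `receive_norm`;
#'   solver metadata is attached as attributes `iterations` and
#'   `residuals`.
#' @export
broadcast_receive <- function(graph, params = pagerank_params(),
                              binarize = FALSE) {
  g <- graph
  if (binarize) {
    g <- new_graph(graph$nodes,
                   transform(graph$edges, weight = rep(1, nrow(graph$edges))))
  }
  receive <- pagerank(g, params)
  broadcast <- pagerank(reverse_graph(g), params)
  strength <- node_strength(graph)
  res <- strength
  res$broadcast_raw <- as.numeric(broadcast[res$node])
  res$receive_raw <- as.numeric(receive[res$node])
  res$broadcast_norm <- NA_real_
  res$receive_norm <- NA_real_
  for (cl in unique(res$class)) {
    sel <- res$class == cl
    res$broadcast_norm[sel] <- minmax_normalize(
      stats::setNames(res$broadcast_raw, res$node), res$node[sel])
    res$receive_norm[sel] <- minmax_normalize(
      stats::setNames(res$receive_raw, res$node), res$node[sel])
  }
  structure(res,
            iterations = c(receive = attr(receive, "iterations"),
                           broadcast = attr(broadcast, "iterations")),
            residuals = c(receive = attr(receive, "residual"),
                          broadcast = attr(broadcast, "residual")),
            params = params,
            class = c("centrality_result", "data.frame"))
}

#' Write a graph as an edge-list TSV
#'
#' @param graph A `section_graph`.
#' @param path Output path; columns `source`, `target`, `weight`.
#' @return The path, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  e <- graph$edges
  write_tsv_canonical(
    data.frame(source = e$from, target = e$to, weight = e$weight,
               stringsAsFactors = FALSE), path)
}

#' Write a centrality table as TSV
#'
#' @param result A `centrality_result`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_centrality <- function(result, path) {
  write_tsv_canonical(as.data.frame(result), path)
}

#' @export
print.centrality_result <- function(x, ...) {
  cat(sprintf("Centrality result: %d section node(s), %d feature node(s)\n",
              sum(x$class == "section"), sum(x$class == "feature")))
  it <- attr(x, "iterations")
  if (!is.null(it)) {
    cat(sprintf("PageRank converged in %d (receive) / %d (broadcast) iterations\n",
                it[["receive"]], it[["broadcast"]]))
  }
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
summary.centrality_result <- function(object, ...) {
  sec <- object[object$class == "section", , drop = FALSE]
  top_b <- sec$node[order(-sec$broadcast_raw, sec$node)][1L]
  feat <- object[object$class == "feature", , drop = FALSE]
  top_r <- feat$node[order(-feat$receive_raw, feat$node)][1L]
  out <- list(
    n_sections = nrow(sec), n_features = nrow(feat),
    top_broadcasting_section = top_b,
    top_receiving_feature = if (nrow(feat)) top_r else NA_character_,
    total_edge_weight = sum(object$out_strength)
  )
  class(out) <- "summary.centrality_result"
  out
}

#' @export
print.summary.centrality_result <- function(x, ...) {
  cat(sprintf(
    paste0("Sections: %d; features: %d; total edge weight %.3f\n",
           "Top broadcasting section: %s\nTop receiving feature: %s\n"),
    x$n_sections, x$n_features, x$total_edge_weight,
    x$top_broadcasting_section, x$top_receiving_feature))
  invisible(x)
}

#' Bar plot of normalized broadcasting/receiving centrality
#'
#' @param x A `centrality_result`.
#' @param measure `"broadcast"` or `"receive"`.
#' @param node_class `"section"` or `"feature"`.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the plotted values.
#' @export
plot.centrality_result <- function(x, measure = c("broadcast", "receive"),
                                   node_class = c("section", "feature"),
                                   ...) {
  measure <- match.arg(measure)
  node_class <- match.arg(node_class)
  sub <- x[x$class == node_class, , drop = FALSE]
  col <- paste0(measure, "_norm")
  vals <- stats::setNames(sub[[col]], sub$node)
  vals <- vals[order(-vals, names(vals))]
  graphics::barplot(vals, las = 2, ylim = c(0, 1),
                    ylab = sprintf("normalized %sing PageRank", measure),
                    main = sprintf("%s nodes", node_class), ...)
  invisible(vals)
}
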