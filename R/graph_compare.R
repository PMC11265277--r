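#' K-nearest-neighbor graph from a distance matrix
#'
#' Each genome selects its k nearest neighbors (excluding itself; ties broken
#' by label order); the directed selections are union-symmetrized into an
#' undirected graph, so node degree can exceed k. Edge weight is the distance
#' value, globally normalized by the maximum selected weight.
#'
#' @param d symmetric distance-scale [labeled_matrix()]; missing entries are
#'   filled with distance 1 first.
#' @param k number of neighbors, `1 <= k < n`.
#' @return object of class `knn_graph`: list with `nodes`, `edges`
#'   (data.frame `u`, `v`, `weight`, with `u < v` in label order) and `k`.
#' @export
knn_graph <- function(d, k) {
  v <- unclass_lm(fill_missing_distances(d))
  n <- nrow(v)
  if (k >= n || k < 1) stop("domain error: k must satisfy 1 <= k < n")
  labs <- rownames(v)
  edges <- list()
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    # nearest k by distance, ties broken by label order
    nn <- others[order(v[i, others], labs[others])][seq_len(k)]
    edges[[i]] <- data.frame(u = pmin(labs[i], labs[nn]),
                             v = pmax(labs[i], labs[nn]),
                             weight = v[cbind(i, nn)],
                             stringsAsFactors = FALSE)
  }
  e <- unique(do.call(rbind, edges))
  e <- e[order(e$u, e$v), , drop = FALSE]
  rownames(e) <- NULL
  wmax <- max(e$weight)
  if (wmax > 0) e$weight <- e$weight / wmax
  structure(list(nodes = sort(labs), edges = e, k = as.integer(k)),
            class = "knn_graph")
}

#' @export
print.knn_graph <- function(x, ...) {
  cat(sprintf("<knn_graph> %d nodes, %d edges, k=%d\n",
              length(x$nodes), nrow(x$edges), x$k))
  invisible(x)
}

#' Build a knn_graph object from an explicit edge list
#' @param nodes character vector of node labels.
#' @param u,v endpoint labels per edge.
#' @param weight edge weights (default 1).
#' @param k nominal k recorded on the object (default `NA`).
#' @return a `knn_graph`.
#' @export
graph_from_edges <- function(nodes, u, v, weight = rep(1, length(u)), k = NA) {
  stopifnot(all(c(u, v) %in% nodes), length(u) == length(v))
  uu <- pmin(u, v); vv <- pmax(u, v)
  if (any(uu == vv)) stop("self-loops are not allowed")
  e <- data.frame(u = uu, v = vv, weight = weight, stringsAsFactors = FALSE)
  e <- e[!duplicated(e[, c("u", "v")]), , drop = FALSE]
  e <- e[order(e$u, e$v), , drop = FALSE]
  structure(list(nodes = nodes, edges = e, k = k), class = "knn_graph")
}

as_igraph <- function(g, weighted = TRUE) {
  ig <- igraph::graph_from_data_frame(
    g$edges[, c("u", "v")], directed = FALSE,
    vertices = data.frame(name = g$nodes))
  if (weighted) igraph::E(ig)$weight <- g$edges$weight
  ig
}

edge_keys <- function(g) paste(g$edges$u, g$edges$v, sep = "\r")

#' Write a graph as an edge-list TSV (u, v, weight)
#' @param g a `knn_graph`.
#' @param path output file.
#' @export
write_graph_tsv <- function(g, path) {
  utils::write.table(g$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Newman modularity of a node partition
#'
#' @param g a `knn_graph`.
#' @param partition named vector (or vector in node order) of community
#'   labels covering every node.
#' @param weighted use edge weights (default `FALSE`: unweighted edge set).
#' @return modularity Q.
#' @export
graph_modularity <- function(g, partition, weighted = FALSE) {
  memb <- partition_membership(g, partition)
  ig <- as_igraph(g, weighted = weighted)
  igraph::modularity(ig, memb,
                     weights = if (weighted) igraph::E(ig)$weight else NULL)
}

partition_membership <- function(g, partition) {
  if (!is.null(names(partition))) {
    if (!all(g$nodes %in% names(partition))) {
      stop("partition error: nodes not covered: ",
           paste(setdiff(g$nodes, names(partition)), collapse = ", "))
    }
    partition <- partition[g$nodes]
  } else if (length(partition) != length(g$nodes)) {
    stop("partition error: partition must cover all nodes")
  }
  as.integer(factor(partition))
}

#' Edge-set similarities of two graphs on the same nodes
#'
#' Jaccard `|E1 n E2| / |E1 u E2|`, weighted Jaccard
#' `sum(min(w1, w2)) / sum(max(w1, w2))` over the edge union (absent edges
#' weigh 0), and Dice `2|E1 n E2| / (|E1| + |E2|)`.
#'
#' @param g1,g2 `knn_graph` objects over the same node set.
#' @return list with `jaccard`, `weighted_jaccard`, `dice`.
#' @export
edge_set_similarities <- function(g1, g2) {
  if (!setequal(g1$nodes, g2$nodes)) {
    stop("alignment error: graphs have different node sets")
  }
  k1 <- edge_keys(g1); k2 <- edge_keys(g2)
  un <- union(k1, k2)
  w1 <- stats::setNames(rep(0, length(un)), un); w1[k1] <- g1$edges$weight
  w2 <- stats::setNames(rep(0, length(un)), un); w2[k2] <- g2$edges$weight
  inter <- length(intersect(k1, k2))
  list(
    jaccard = if (length(un)) inter / length(un) else 1,
    weighted_jaccard = if (sum(pmax(w1, w2)) > 0) {
      sum(pmin(w1, w2)) / sum(pmax(w1, w2))
    } else 1,
    dice = if (length(k1) + length(k2) > 0) {
      2 * inter / (length(k1) + length(k2))
    } else 1
  )
}

# Fast-belief-propagation affinity matrix S = (I + eps^2 D - eps A)^-1.
deltacon_affinity <- function(g, epsilon, weighted = FALSE) {
  n <- length(g$nodes)
  a <- matrix(0, n, n, dimnames = list(g$nodes, g$nodes))
  if (nrow(g$edges)) {
    iu <- match(g$edges$u, g$nodes); iv <- match(g$edges$v, g$nodes)
    w <- if (weighted) g$edges$weight else rep(1, nrow(g$edges))
    a[cbind(iu, iv)] <- w
    a[cbind(iv, iu)] <- w
  }
  deg <- diag(rowSums(a), n)
  m <- diag(n) + epsilon^2 * deg - epsilon * a
  s <- tryCatch(solve(m), error = function(e) {
    stop("singular system in DeltaCon affinity; retry with smaller epsilon (",
         conditionMessage(e), ")")
  })
  # the linearized affinities are non-negative for admissible epsilon;
  # guard tiny numerical undershoots before the square roots
  s[s < 0] <- 0
  s
}

#' DeltaCon similarity of two graphs with node and edge attribution
#'
#' Computes per-graph node-affinity matrices from the linearized
#' belief-propagation system `S = (I + eps^2 D - eps A)^-1` and compares them
#' with the Matusita (root-Euclidean) distance
#' `d = sqrt(sum((sqrt(S1) - sqrt(S2))^2))`; similarity is the bounded
#' inverse `1 / (1 + d)`. Node attribution is the root-Euclidean distance
#' between corresponding affinity rows; edge attribution assigns each edge
#' present in exactly one graph the sum of its endpoints' node attributions,
#' signed `+` for edges gained in `g2` and `-` for edges lost from `g1`.
#'
#' @param g1,g2 `knn_graph` objects over the same node set.
#' @param epsilon coupling strength; `"auto"` (default) uses
#'   `1 / (1 + max degree)` over both graphs.
#' @param weighted use edge weights in the affinity system (default
#'   `FALSE`).
#' @return list with `epsilon`, `distance`, `similarity`,
#'   `node_attribution` (named, non-negative) and `edge_attribution`
#'   (data.frame `u`, `v`, `change`, `attribution`).
#' @export
deltacon <- function(g1, g2, epsilon = "auto", weighted = FALSE) {
  if (!setequal(g1$nodes, g2$nodes)) {
    stop("alignment error: graphs have different node sets")
  }
  nodes <- g1$nodes
  g2 <- reorder_graph_nodes(g2, nodes)
  if (identical(epsilon, "auto")) {
    maxdeg <- max(1, node_degrees(g1), node_degrees(g2))
    epsilon <- 1 / (1 + maxdeg)
  }
  s1 <- deltacon_affinity(g1, epsilon, weighted)
  s2 <- deltacon_affinity(g2, epsilon, weighted)
  diff2 <- (sqrt(s1) - sqrt(s2))^2
  d <- sqrt(sum(diff2))
  node_attr <- sqrt(rowSums(diff2))
  names(node_attr) <- nodes

  k1 <- edge_keys(g1); k2 <- edge_keys(g2)
  changed <- c(setdiff(k1, k2), setdiff(k2, k1))
  edge_attr <- if (length(changed)) {
    parts <- strsplit(changed, "\r", fixed = TRUE)
    u <- vapply(parts, `[`, character(1), 1)
    v <- vapply(parts, `[`, character(1), 2)
    sign <- ifelse(changed %in% k2, 1, -1)
    data.frame(u = u, v = v,
               change = ifelse(sign > 0, "added", "removed"),
               attribution = sign * (node_attr[u] + node_attr[v]),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(u = character(), v = character(), change = character(),
               attribution = numeric(), stringsAsFactors = FALSE)
  }
  if (nrow(edge_attr)) {
    edge_attr <- edge_attr[order(-abs(edge_attr$attribution)), ]
    row.names(edge_attr) <- NULL
  }
  list(epsilon = epsilon, distance = d, similarity = 1 / (1 + d),
       node_attribution = node_attr, edge_attribution = edge_attr)
}

node_degrees <- function(g) {
  if (!nrow(g$edges)) return(0)
  tabulate(factor(c(g$edges$u, g$edges$v), levels = g$nodes))
}

reorder_graph_nodes <- function(g, nodes) {
  g$nodes <- nodes
  g$edges$u2 <- pmin(g$edges$u, g$edges$v)
  g$edges$v2 <- pmax(g$edges$u, g$edges$v)
  g$edges <- data.frame(u = g$edges$u2, v = g$edges$v2,
                        weight = g$edges$weight, stringsAsFactors = FALSE)
  g$edges <- g$edges[order(g$edges$u, g$edges$v), , drop = FALSE]
  g
}

#' Girvan-Newman community detection
#'
#' Iteratively removes the edge of highest betweenness (recomputed after
#' every removal), recording the split hierarchy; the returned partition is
#' the level of maximum modularity. Disconnected components are handled
#' independently; an edgeless graph yields all-singleton communities.
#'
#' @param g a `knn_graph`.
#' @return list with `membership` (named community labels of the chosen
#'   partition), `modularity` (of that partition), `removed_edges`
#'   (data.frame in removal order) and the underlying igraph `communities`
#'   object as `detail`.
#' @export
girvan_newman <- function(g) {
  ig <- as_igraph(g, weighted = FALSE)
  if (nrow(g$edges) == 0) {
    memb <- stats::setNames(seq_along(g$nodes), g$nodes)
    return(list(membership = memb, modularity = 0,
                removed_edges = data.frame(u = character(), v = character()),
                detail = NULL))
  }
  comm <- igraph::cluster_edge_betweenness(ig, weights = NULL,
                                           directed = FALSE)
  memb <- igraph::membership(comm)
  removed <- igraph::ends(ig, comm$removed.edges)
  list(membership = stats::setNames(as.integer(memb), names(memb)),
       modularity = igraph::modularity(ig, memb),
       removed_edges = data.frame(u = removed[, 1], v = removed[, 2],
                                  stringsAsFactors = FALSE),
       detail = comm)
}
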