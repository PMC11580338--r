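#' Global species set of a network
#'
#' @param network igraph co-occurrence network.
#' @return Sorted character vector of node (species) names.
#' @export
global_species <- function(network) {
  if (igraph::vcount(network) == 0L) return(character(0L))
  sort(igraph::V(network)$name)
}

#' Default Leiden resolution from the degree quartile
#'
#' The resolution parameter is derived from the graph itself as the ratio
#' of the first quartile (25th percentile, linear-interpolation quantile)
#' of node strength to the number of nodes minus one. On unweighted graphs
#' strength equals degree. Both the quartile probability and the
#' denominator are configurable because the convention varies.
#'
#' @param network igraph object with at least 2 nodes.
#' @param prob quantile probability (default 0.25, the first quartile).
#' @param denominator `"n-1"` (default) or `"n"`.
#' @return Numeric resolution parameter gamma.
#' @export
default_resolution <- function(network, prob = 0.25,
                               denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  n <- igraph::vcount(network)
  if (n < 2L) stop("resolution undefined for graphs with < 2 nodes", call. = FALSE)
  q <- as.numeric(stats::quantile(igraph::degree(network), probs = prob,
                                  type = 7))
  den <- if (denominator == "n-1") n - 1L else n
  q / den
}

#' Constant Potts Model quality of a partition
#'
#' `Q = sum_c [ e_c - gamma * n_c (n_c - 1) / 2 ]` where `e_c` is the
#' number of intra-cluster edges of cluster `c` and `n_c` its size
#' (edge-count form, unweighted).
#'
#' @param network igraph object.
#' @param assignment named integer/character vector: node name -> cluster.
#' @param gamma resolution parameter.
#' @return CPM objective value.
#' @export
cpm_quality <- function(network, assignment, gamma) {
  nodes <- igraph::V(network)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(network)))
  if (!all(nodes %in% names(assignment))) {
    stop("assignment must cover every node", call. = FALSE)
  }
  memb <- assignment[nodes]
  el <- igraph::as_edgelist(network, names = TRUE)
  intra <- sum(memb[el[, 1L]] == memb[el[, 2L]])
  sizes <- table(memb)
  intra - gamma * sum(sizes * (sizes - 1)) / 2
}

#' Leiden community detection under CPM
#'
#' Runs the Leiden algorithm (local moving, refinement, aggregation) with
#' the Constant Potts Model objective. A single Leiden pass can stall in a
#' local optimum of the CPM landscape, so the search is restarted
#' `n_restarts` times from seeds `seed, seed+1, ...` and the partition with
#' the best [cpm_quality()] is kept (ties go to the earliest restart).
#' Cluster ids are relabelled to contiguous integers from 1 in order of
#' first appearance along the node list, and the reported quality is
#' recomputed with [cpm_quality()] so it is exactly the edge-count CPM
#' value of the returned assignment. Deterministic for a fixed seed.
#'
#' @param network non-empty igraph object.
#' @param gamma resolution parameter; `NULL` uses [default_resolution()].
#' @param seed base RNG seed for the Leiden randomization.
#' @param n_iterations Leiden iterations per restart.
#' @param n_restarts independent restarts (best-of selection).
#' @return Object of class `community_partition`: list with `assignment`
#'   (named integer vector), `gamma`, `quality`, `seed`.
#' @export
leiden_cpm <- function(network, gamma = NULL, seed = 42L, n_iterations = 10L,
                       n_restarts = 10L) {
  if (igraph::vcount(network) == 0L) stop("empty network", call. = FALSE)
  if (is.null(gamma)) gamma <- default_resolution(network)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  nodes <- igraph::V(network)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(network)))
  best <- NULL
  for (r in seq_len(max(1L, n_restarts)) - 1L) {
    set.seed(seed + r)
    cl <- igraph::cluster_leiden(network, objective_function = "CPM",
                                 resolution = gamma,
                                 n_iterations = n_iterations)
    raw <- as.integer(igraph::membership(cl))
    assignment <- stats::setNames(match(raw, unique(raw)), nodes)
    q <- cpm_quality(network, assignment, gamma)
    if (is.null(best) || q > best$quality) {
      best <- list(assignment = assignment, quality = q)
    }
  }
  structure(list(assignment = best$assignment, gamma = gamma,
                 quality = best$quality, seed = seed),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat("<community_partition> ", length(unique(x$assignment)), " clusters, ",
      "gamma = ", signif(x$gamma, 4), ", CPM quality = ",
      signif(x$quality, 6), "\n", sep = "")
  invisible(x)
}

#' Cluster membership and size summary
#'
#' @param partition a `community_partition`.
#' @param min_size smallest cluster size to keep (clusters below it carry
#'   no co-occurrence signal; default 2 drops singletons).
#' @return Named list of species character vectors, names `"CL <id>"`
#'   style cluster ids.
#' @export
cluster_members <- function(partition, min_size = 2L) {
  groups <- split(names(partition$assignment), partition$assignment)
  groups <- groups[vapply(groups, length, integer(1L)) >= min_size]
  if (length(groups) == 0L) return(stats::setNames(list(), character(0L)))
  stats::setNames(groups, paste0("CL", names(groups)))
}

#' Hub (eigenvector) centrality scores
#'
#' On an undirected graph the Kleinberg hub score coincides with
#' eigenvector centrality. Because the dominant eigenvector of a
#' disconnected graph zeroes all but one component, scores are computed per
#' connected component and then globally max-normalized, keeping every
#' node's score in `[0, 1]` with the maximum equal to 1 on any graph with
#' at least one edge. The per-component principal eigenvector is obtained
#' by exact symmetric eigendecomposition of the adjacency matrix, which is
#' deterministic (no random restart) and accurate to machine precision at
#' the network sizes this pipeline produces.
#'
#' @param network igraph object.
#' @return Named numeric vector of scores in `[0, 1]`.
#' @export
hub_scores <- function(network) {
  n <- igraph::vcount(network)
  if (n == 0L) return(stats::setNames(numeric(0L), character(0L)))
  comps <- igraph::components(network)
  out <- stats::setNames(numeric(n), igraph::V(network)$name)
  for (k in seq_len(comps$no)) {
    vs <- which(comps$membership == k)
    sub <- igraph::induced_subgraph(network, vs)
    sc <- if (length(vs) == 1L) {
      stats::setNames(0, igraph::V(sub)$name)
    } else {
      a <- igraph::as_adjacency_matrix(sub, sparse = FALSE)
      v <- eigen(a, symmetric = TRUE)$vectors[, 1L]
      # Perron-Frobenius: the leading eigenvector of a connected graph is
      # single-signed; fix the sign and rescale to a component max of 1
      v <- abs(v)
      stats::setNames(v / max(v), rownames(a))
    }
    out[names(sc)] <- sc
  }
  m <- max(out)
  if (m > 0) out <- out / m
  out
}

#' Betweenness centrality
#'
#' Unnormalized shortest-path betweenness on the undirected, unweighted
#' graph, each unordered pair counted once.
#'
#' @param network igraph object.
#' @return Named numeric vector.
#' @export
betweenness_scores <- function(network) {
  if (igraph::vcount(network) == 0L) {
    return(stats::setNames(numeric(0L), character(0L)))
  }
  igraph::betweenness(network, directed = FALSE, weights = NA,
                      normalized = FALSE)
}

#' Top-k nodes by score
#'
#' @param scores named numeric vector.
#' @param k number of nodes to return (all if fewer exist).
#' @return Character vector of node names, descending score, ties broken
#'   by ascending name.
#' @export
top_k <- function(scores, k = 5L) {
  if (length(scores) == 0L) return(character(0L))
  ord <- order(-scores, names(scores))
  names(scores)[ord][seq_len(min(k, length(scores)))]
}
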