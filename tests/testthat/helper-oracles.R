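# Independent oracles used by the unit and acceptance tests. Each is a
# deliberately naive computation kept separate from the package's own
# algorithms.

# Exact co-occurrence tail probabilities by direct summation of the
# combinatorial PMF with exact binomial coefficients (choose() is exact in
# doubles at these sizes).
oracle_cooccur_tails <- function(N, N1, N2, j_obs) {
  j <- max(0L, N1 + N2 - N):min(N1, N2)
  p <- choose(N1, j) * choose(N - N1, N2 - j) / choose(N, N2)
  list(p_gt = sum(p[j >= j_obs]), p_lt = sum(p[j <= j_obs]))
}

# Co-occurrence tails by enumerating every placement of the second species
# over C(N, N2) sample subsets, given a fixed placement of the first.
oracle_cooccur_enum <- function(N, N1, N2, j_obs) {
  occupied <- seq_len(N1)
  if (N2 == 0L) {
    overlaps <- 0L
  } else {
    draws <- utils::combn(N, N2)
    overlaps <- colSums(matrix(draws %in% occupied, nrow = N2))
  }
  list(p_gt = mean(overlaps >= j_obs), p_lt = mean(overlaps <= j_obs))
}

# Hypergeometric enrichment upper tail by enumerating all C(M, n) query
# draws from a universe 1..M whose pathway is 1..K.
oracle_enrich_tail <- function(M, K, n, k) {
  draws <- utils::combn(M, n)
  hits <- colSums(matrix(draws <= K, nrow = n))
  mean(hits >= k)
}

# Hand-computed Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, m * p[ord[i]] / i)
    adj[ord[i]] <- running
  }
  pmin(adj, 1)
}

# All set partitions of 1..n as membership vectors (restricted growth
# strings).
enum_partitions <- function(n) {
  out <- list()
  recur <- function(memb, next_id) {
    i <- length(memb) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- memb
      return(invisible())
    }
    for (g in seq_len(next_id)) {
      recur(c(memb, g), next_id + (g == next_id))
    }
  }
  recur(integer(0L), 1L)
  out
}

# CPM value of a membership vector computed straight from the edge list.
oracle_cpm <- function(graph, memb, gamma) {
  el <- igraph::as_edgelist(graph, names = FALSE)
  intra <- if (nrow(el) > 0L) sum(memb[el[, 1L]] == memb[el[, 2L]]) else 0L
  sizes <- tabulate(memb)
  intra - gamma * sum(sizes * (sizes - 1)) / 2
}

# Exhaustive-search CPM optimum.
oracle_cpm_optimum <- function(graph, gamma) {
  n <- igraph::vcount(graph)
  best <- -Inf
  for (memb in enum_partitions(n)) {
    q <- oracle_cpm(graph, memb, gamma)
    if (q > best) best <- q
  }
  best
}

# Betweenness by enumerating all shortest paths per unordered pair and
# counting interior vertices.
oracle_betweenness <- function(graph) {
  n <- igraph::vcount(graph)
  out <- stats::setNames(numeric(n), igraph::V(graph)$name)
  if (n < 3L) return(out)
  for (s in seq_len(n - 1L)) {
    for (t in (s + 1L):n) {
      paths <- suppressWarnings(
        igraph::all_shortest_paths(graph, from = s, to = t)$vpaths)
      paths <- Filter(function(p) length(p) > 0L, paths)
      np <- length(paths)
      if (np == 0L) next
      for (p in paths) {
        interior <- as.integer(p)[-c(1L, length(p))]
        out[interior] <- out[interior] + 1 / np
      }
    }
  }
  out
}

# Deterministic random test graph with named vertices.
random_test_graph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  g
}
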