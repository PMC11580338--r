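#' Exact probabilistic co-occurrence test for one species pair
#'
#' Under the null that two species occupy samples independently given their
#' occupancy counts, the number of jointly occupied samples `j` follows the
#' hypergeometric law
#' `P(j) = C(N1, j) C(N - N1, N2 - j) / C(N, N2)`
#' over the feasible range `max(0, N1 + N2 - N) <= j <= min(N1, N2)`.
#' `p_gt` is the probability of observing at least `j_obs` joint samples,
#' `p_lt` that of at most `j_obs`; both tails include `P(j_obs)`, so
#' `p_gt + p_lt >= 1`. Terms are evaluated in log space (`lchoose`) and the
#' tails renormalized by the total mass, which keeps the result accurate to
#' well over 10 significant digits for `N` up to 1e4.
#'
#' @param N number of samples.
#' @param N1,N2 occupancy counts of the two species (order-symmetric).
#' @param j_obs observed number of jointly occupied samples.
#' @return List with `p_gt`, `p_lt` and `expected` (`N1 * N2 / N`). All
#'   arguments may be equal-length vectors, in which case the components
#'   are vectors.
#' @export
pair_probability <- function(N, N1, N2, j_obs) {
  n <- max(length(N), length(N1), length(N2), length(j_obs))
  N <- rep_len(N, n); N1 <- rep_len(N1, n)
  N2 <- rep_len(N2, n); j_obs <- rep_len(j_obs, n)
  if (any(N1 < 0 | N2 < 0 | N1 > N | N2 > N)) {
    stop("occupancy counts must lie in [0, N]", call. = FALSE)
  }
  lo <- pmax(0, N1 + N2 - N)
  hi <- pmin(N1, N2)
  if (any(j_obs < lo | j_obs > hi)) {
    stop("j_obs outside the feasible range [max(0, N1+N2-N), min(N1, N2)]",
         call. = FALSE)
  }
  p_gt <- numeric(n)
  p_lt <- numeric(n)
  for (i in seq_len(n)) {
    j <- lo[i]:hi[i]
    logp <- lchoose(N1[i], j) + lchoose(N[i] - N1[i], N2[i] - j) -
      lchoose(N[i], N2[i])
    p <- exp(logp)
    total <- sum(p)
    p_gt[i] <- sum(p[j >= j_obs[i]]) / total
    p_lt[i] <- sum(p[j <= j_obs[i]]) / total
  }
  list(p_gt = p_gt, p_lt = p_lt, expected = N1 * N2 / N)
}

#' Test all species pairs of a presence matrix
#'
#' Computes occupancy counts and observed joint occupancy for every
#' unordered species pair, then the exact co-occurrence tails for pairs
#' whose expected joint occupancy `N1*N2/N` reaches `expected_threshold`
#' (pairs below it are not tested, mirroring common practice for the
#' probabilistic co-occurrence model; set `expected_threshold = 0` to test
#' everything). A pair is flagged significantly positive iff
#' `p_gt < alpha` (strict).
#'
#' @param matrix a `presence_matrix` (see [binarize()]).
#' @param alpha significance level for the positive tail.
#' @param expected_threshold minimum expected joint occupancy for a pair to
#'   be tested.
#' @return data.frame with one row per tested pair, ordered by the
#'   lexicographic pair key: `species_a < species_b`, `N`, `N1`, `N2`,
#'   `obs`, `expected`, `p_gt`, `p_lt`, `significant`.
#' @export
all_pairs <- function(matrix, alpha = 0.05, expected_threshold = 1.0) {
  cells <- matrix$cells
  if (nrow(cells) < 2L) stop("need at least 2 species", call. = FALSE)
  if (ncol(cells) < 1L) stop("need at least 1 sample", call. = FALSE)
  sp <- rownames(cells)
  ord <- order(sp)
  cells <- cells[ord, , drop = FALSE]
  sp <- sp[ord]
  N <- ncol(cells)
  occ <- rowSums(cells)
  joint <- tcrossprod(cells)          # j_obs for every ordered pair
  idx <- which(upper.tri(joint), arr.ind = TRUE)
  a <- idx[, 1L]; b <- idx[, 2L]
  expected <- occ[a] * occ[b] / N
  keep <- expected >= expected_threshold
  a <- a[keep]; b <- b[keep]
  pairs <- data.frame(species_a = sp[a], species_b = sp[b],
                      N = N, N1 = occ[a], N2 = occ[b],
                      obs = joint[cbind(a, b)],
                      expected = expected[keep],
                      stringsAsFactors = FALSE)
  if (nrow(pairs) > 0L) {
    pr <- pair_probability(pairs$N, pairs$N1, pairs$N2, pairs$obs)
    pairs$p_gt <- pr$p_gt
    pairs$p_lt <- pr$p_lt
  } else {
    pairs$p_gt <- numeric(0L)
    pairs$p_lt <- numeric(0L)
  }
  pairs$significant <- pairs$p_gt < alpha
  pairs <- pairs[order(pairs$species_a, pairs$species_b), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Build the unweighted co-occurrence network
#'
#' Nodes are the species incident to at least one significantly positive
#' pair (`p_gt < alpha`); edges are those pairs. The graph is simple and
#' undirected and carries `phenotype`, `dataset` and `alpha` as graph
#' attributes.
#'
#' @param pairs data.frame from [all_pairs()].
#' @param phenotype,dataset labels stored on the graph.
#' @param alpha significance level re-applied to `p_gt` (defaults to the
#'   conventional 0.05).
#' @param keep_isolated if `TRUE`, all tested species are retained as
#'   nodes, including isolated ones (diagnostic use).
#' @return igraph object.
#' @export
build_network <- function(pairs, phenotype = NA_character_,
                          dataset = NA_character_, alpha = 0.05,
                          keep_isolated = FALSE) {
  sig <- pairs[pairs$p_gt < alpha, c("species_a", "species_b"), drop = FALSE]
  vertices <- if (keep_isolated) {
    sort(unique(c(pairs$species_a, pairs$species_b)))
  } else {
    sort(unique(c(sig$species_a, sig$species_b)))
  }
  g <- igraph::graph_from_data_frame(sig, directed = FALSE,
                                     vertices = if (length(vertices)) vertices else NULL)
  if (length(vertices) == 0L) g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::set_graph_attr(g, "phenotype", phenotype)
  g <- igraph::set_graph_attr(g, "dataset", dataset)
  g <- igraph::set_graph_attr(g, "alpha", alpha)
  g
}

#' Write the pair table
#'
#' @param pairs data.frame from [all_pairs()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
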