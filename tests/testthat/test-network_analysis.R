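ring <- function(n) {
  g <- igraph::make_ring(n)
  igraph::V(g)$name <- letters[seq_len(n)]
  g
}

two_triangles <- function() {
  g <- igraph::make_graph(~ a - b, b - c, a - c, d - e, e - f, d - f)
  g
}

test_that("global species set is the node set", {
  g <- two_triangles()
  expect_setequal(global_species(g), letters[1:6])
  expect_equal(global_species(igraph::make_empty_graph(0, directed = FALSE)),
               character(0))
})

test_that("default resolution is the degree quartile over n-1", {
  expect_equal(default_resolution(ring(4)), 2 / 3, tolerance = 1e-12)
  expect_equal(default_resolution(ring(3)), 1.0, tolerance = 1e-12)
  # k-regular: quartile of a constant degree distribution is the constant
  cube <- igraph::make_graph("Cubical")   # 3-regular on 8 nodes
  expect_equal(default_resolution(cube), 3 / 7, tolerance = 1e-12)
  expect_equal(default_resolution(cube, denominator = "n"), 3 / 8,
               tolerance = 1e-12)
  expect_error(default_resolution(igraph::make_empty_graph(1, directed = FALSE)),
               "2 nodes")
})

test_that("CPM quality matches its closed form", {
  tri <- ring(3)
  one <- setNames(rep(1L, 3), letters[1:3])
  expect_equal(cpm_quality(tri, one, gamma = 1), 0)
  expect_equal(cpm_quality(tri, one, gamma = 0.5), 1.5)
  singles <- setNames(1:3, letters[1:3])
  expect_equal(cpm_quality(tri, singles, gamma = 0.8), 0)
})

test_that("Leiden/CPM recovers planted structures exactly", {
  g <- two_triangles()
  part <- leiden_cpm(g, gamma = 0.5)
  expect_equal(length(unique(part$assignment)), 2L)
  expect_equal(length(unique(part$assignment[c("a", "b", "c")])), 1L)
  expect_equal(length(unique(part$assignment[c("d", "e", "f")])), 1L)
  expect_equal(part$quality, 3.0)
  expect_equal(part$quality, cpm_quality(g, part$assignment, 0.5))

  # two 4-cliques joined by a single bridge
  k8 <- igraph::make_graph(~ a-b, a-c, a-d, b-c, b-d, c-d,
                           e-f, e-g, e-h, f-g, f-h, g-h, d-e)
  part <- leiden_cpm(k8, gamma = 0.9)
  expect_equal(length(unique(part$assignment)), 2L)
  expect_equal(unname(part$assignment["a"]), unname(part$assignment["d"]))
  expect_equal(unname(part$assignment["e"]), unname(part$assignment["h"]))
  expect_equal(part$quality, oracle_cpm_optimum(k8, 0.9), tolerance = 1e-12)
})

test_that("disconnected components are never merged under CPM", {
  set.seed(21)
  for (rep in 1:10) {
    g1 <- random_test_graph(4, 0.8, rep)
    g2 <- random_test_graph(4, 0.8, rep + 100)
    igraph::V(g2)$name <- paste0(igraph::V(g2)$name, "b")
    g <- igraph::disjoint_union(g1, g2)
    igraph::V(g)$name <- letters[1:8]
    part <- leiden_cpm(g, gamma = 0.4, seed = rep)
    comp <- igraph::components(g)$membership
    for (cl in unique(part$assignment)) {
      nodes <- names(part$assignment)[part$assignment == cl]
      expect_equal(length(unique(comp[nodes])), 1L)
    }
  }
})

test_that("identical seeds give identical partitions", {
  g <- random_test_graph(25, 0.2, 77)
  p1 <- leiden_cpm(g, gamma = 0.3, seed = 11)
  p2 <- leiden_cpm(g, gamma = 0.3, seed = 11)
  expect_identical(p1$assignment, p2$assignment)
  expect_identical(p1$quality, p2$quality)
})

test_that("hub scores match eigenvector closed forms", {
  star <- igraph::make_star(5, mode = "undirected")
  igraph::V(star)$name <- c("hub", "l1", "l2", "l3", "l4")
  hs <- hub_scores(star)
  expect_equal(unname(hs["hub"]), 1.0, tolerance = 1e-9)
  expect_equal(unname(hs[c("l1", "l4")]), c(0.5, 0.5), tolerance = 1e-9)

  path <- igraph::make_graph(~ A - B, B - C)
  hs <- hub_scores(path)
  expect_equal(unname(hs["B"]), 1.0, tolerance = 1e-9)
  expect_equal(unname(hs["A"]), 1 / sqrt(2), tolerance = 1e-6)

  # k-regular connected graphs have a uniform dominant eigenvector
  expect_equal(unname(hub_scores(ring(6))), rep(1, 6), tolerance = 1e-9)
})

test_that("hub scores are relabel-invariant, bounded and cover components", {
  g <- random_test_graph(12, 0.3, 5)
  hs <- hub_scores(g)
  expect_true(all(hs >= 0 & hs <= 1 + 1e-12))
  expect_equal(max(hs), 1.0)
  perm <- sample(igraph::vcount(g))
  g2 <- igraph::permute(g, perm)
  hs2 <- hub_scores(g2)
  expect_equal(hs2[names(hs)], hs, tolerance = 1e-9)
  # disconnected graphs: every non-singleton component gets nonzero scores
  r4 <- ring(4)
  igraph::V(r4)$name <- paste0(igraph::V(r4)$name, "b")
  dg <- igraph::disjoint_union(ring(3), r4)
  igraph::V(dg)$name <- letters[1:7]
  hd <- hub_scores(dg)
  expect_true(all(hd > 0))
})

test_that("betweenness matches closed forms", {
  path <- igraph::make_graph(~ A - B, B - C)
  expect_equal(unname(betweenness_scores(path)[c("A", "B", "C")]),
               c(0, 1, 0))
  star <- igraph::make_star(5, mode = "undirected")
  igraph::V(star)$name <- c("hub", "l1", "l2", "l3", "l4")
  expect_equal(unname(betweenness_scores(star)["hub"]), choose(4, 2))
  expect_equal(unname(betweenness_scores(igraph::make_full_graph(5))),
               rep(0, 5))
})

test_that("top_k orders by score with lexicographic tie-break", {
  expect_identical(top_k(c(a = 3, b = 2, c = 1), 2), c("a", "b"))
  expect_identical(top_k(c(b = 1, a = 1), 1), "a")
  expect_identical(top_k(c(a = 1, b = 2), 10), c("b", "a"))
  expect_identical(top_k(setNames(numeric(0), character(0))), character(0))
})

test_that("cluster membership summary drops singletons", {
  part <- structure(list(assignment = c(a = 1L, b = 1L, c = 2L, d = 3L, e = 3L),
                         gamma = 0.5, quality = 0, seed = 1L),
                    class = "community_partition")
  m <- cluster_members(part)
  expect_setequal(names(m), c("CL1", "CL3"))
  expect_setequal(m$CL3, c("d", "e"))
  expect_equal(length(cluster_members(part, min_size = 1L)), 3L)
})
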