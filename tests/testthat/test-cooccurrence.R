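test_that("pair test matches closed forms", {
  # identical occupancy 5/10, complete overlap: single-term tail
  pr <- pair_probability(10, 5, 5, 5)
  expect_equal(pr$p_gt, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(pr$expected, 2.5)
  # N=4, N1=N2=2, j=2
  expect_equal(pair_probability(4, 2, 2, 2)$p_gt, 1 / 6, tolerance = 1e-12)
  # tail from the bottom of the support is the whole mass
  expect_equal(pair_probability(20, 8, 5, 0)$p_gt, 1, tolerance = 1e-12)
  # degenerate support: N1 = N forces j = N2
  pr <- pair_probability(10, 10, 4, 4)
  expect_equal(pr$p_gt, 1)
  expect_equal(pr$p_lt, 1)
})

test_that("pair test rejects infeasible inputs", {
  expect_error(pair_probability(10, 5, 5, 6), "feasible")
  expect_error(pair_probability(10, 8, 8, 5), "feasible")  # below N1+N2-N
  expect_error(pair_probability(10, 11, 5, 5), "occupancy")
})

test_that("pair test agrees with the exact-PMF oracle on a dense sweep", {
  for (N in 2:8) {
    for (N1 in 0:N) {
      for (N2 in 0:N1) {
        lo <- max(0L, N1 + N2 - N); hi <- min(N1, N2)
        for (j in lo:hi) {
          got <- pair_probability(N, N1, N2, j)
          ora <- oracle_cooccur_tails(N, N1, N2, j)
          expect_equal(got$p_gt, ora$p_gt, tolerance = 1e-12)
          expect_equal(got$p_lt, ora$p_lt, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("pair test agrees with the placement-enumeration oracle at tiny N", {
  set.seed(5)
  for (rep in 1:25) {
    N <- sample(2:7, 1)
    N1 <- sample(0:N, 1); N2 <- sample(0:N, 1)
    lo <- max(0L, N1 + N2 - N); hi <- min(N1, N2)
    j <- if (lo == hi) lo else sample(lo:hi, 1)
    got <- pair_probability(N, N1, N2, j)
    ora <- oracle_cooccur_enum(N, N1, N2, j)
    expect_equal(got$p_gt, ora$p_gt, tolerance = 1e-9)
    expect_equal(got$p_lt, ora$p_lt, tolerance = 1e-9)
  }
})

test_that("pair test is symmetric in the two species and monotone in j_obs", {
  set.seed(9)
  for (rep in 1:30) {
    N <- sample(5:40, 1)
    N1 <- sample(1:N, 1); N2 <- sample(1:N, 1)
    lo <- max(0L, N1 + N2 - N); hi <- min(N1, N2)
    j <- if (lo == hi) lo else sample(lo:hi, 1)
    expect_equal(pair_probability(N, N1, N2, j)$p_gt,
                 pair_probability(N, N2, N1, j)$p_gt, tolerance = 1e-12)
    tails <- pair_probability(rep(N, hi - lo + 1), N1, N2, lo:hi)
    expect_true(all(diff(tails$p_gt) <= 1e-12))
    expect_true(all(tails$p_gt + tails$p_lt >= 1 - 1e-12))
  }
})

test_that("both tails stay accurate at large N", {
  # p_gt + p_lt = 1 + P(j_obs); compare against the exact-PMF term
  pr <- pair_probability(10000, 4000, 5000, 2100)
  pmf <- exp(lchoose(4000, 2100) + lchoose(6000, 2900) - lchoose(10000, 5000))
  expect_equal(pr$p_gt + pr$p_lt - 1, pmf, tolerance = 1e-10)
})

test_that("all_pairs enumerates, filters and flags pairs deterministically", {
  set.seed(3)
  cells <- matrix(rbinom(8 * 20, 1, 0.5), nrow = 8,
                  dimnames = list(sprintf("Sp_%02d", 8:1), sprintf("s%02d", 1:20)))
  pm <- presence_fixture(cells)
  pr <- all_pairs(pm, expected_threshold = 0)
  expect_equal(nrow(pr), choose(8, 2))
  expect_true(all(pr$species_a < pr$species_b))
  expect_identical(pr, all_pairs(pm, expected_threshold = 0))
  # expected threshold removes exactly the low-expectation pairs
  pr1 <- all_pairs(pm, expected_threshold = 1)
  expect_setequal(paste(pr1$species_a, pr1$species_b),
                  paste(pr$species_a, pr$species_b)[pr$expected >= 1])
  # significance flag is the strict raw comparison
  expect_identical(pr$significant, pr$p_gt < 0.05)
})

test_that("identical presence patterns give the single-term minimal p", {
  patt <- rep(c(1L, 0L), each = 10)
  cells <- rbind(A_a = patt, B_b = patt)
  colnames(cells) <- sprintf("s%02d", 1:20)
  pr <- all_pairs(presence_fixture(cells))
  expect_equal(pr$p_gt, 1 / choose(20, 10), tolerance = 1e-12)
  expect_true(pr$significant)
})

test_that("species never co-present are not significantly positive", {
  cells <- rbind(A_a = c(1L, 1L, 0L, 0L, 0L, 0L),
                 B_b = c(0L, 0L, 1L, 1L, 0L, 0L))
  colnames(cells) <- sprintf("s%d", 1:6)
  pr <- all_pairs(presence_fixture(cells), expected_threshold = 0)
  expect_equal(pr$p_gt, 1, tolerance = 1e-12)
  expect_false(pr$significant)
})

test_that("network construction keeps only edge-incident species", {
  pairs <- data.frame(
    species_a = c("a", "a", "a", "d"), species_b = c("b", "c", "d", "e"),
    p_gt = c(0.01, 0.04, 0.049, 0.9))
  net <- build_network(pairs, phenotype = "CD", dataset = "d1")
  expect_equal(igraph::vcount(net), 4L)   # a, b, c, d share 3 significant pairs
  expect_equal(igraph::ecount(net), 3L)
  expect_false("e" %in% igraph::V(net)$name)
  expect_setequal(igraph::V(net)$name,
                  unique(c(igraph::as_edgelist(net))))
  # with no significant pair at all the network is empty but valid
  none <- build_network(pairs[pairs$p_gt > 0.5, , drop = FALSE])
  expect_equal(igraph::vcount(none), 0L)
  expect_equal(igraph::ecount(none), 0L)
  # keep_isolated retains all tested species for diagnostics
  iso <- build_network(pairs, keep_isolated = TRUE)
  expect_equal(igraph::vcount(iso), 5L)
})

test_that("edge count equals the significant pair count on simulated data", {
  cfg <- small_sim_config()
  sim <- simulate_dataset(cfg, 1)
  pp <- preprocess(sim$abundance, sim$metadata)
  pr <- all_pairs(pp$presence$CD)
  net <- build_network(pr, "CD", "d1")
  expect_equal(igraph::ecount(net), sum(pr$significant))
})
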