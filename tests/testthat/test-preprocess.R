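test_that("sample selection applies age bounds, visits, duplicates, medication", {
  md <- fixture_metadata()
  kept <- select_samples(md, filter_criteria())
  # S03 (17y) and S04 (66y) out; ages 18 and 65 in (bounds inclusive);
  # S05 medicated; S02 and S10 are later visits of their subjects
  expect_setequal(kept, c("S01", "S06", "S07", "S08", "S09"))

  # duplicate sample ids: first occurrence wins
  dup <- rbind(md, md[1, ])
  expect_equal(sum(select_samples(dup) == "S01"), 1L)

  # inert criteria are the identity
  loose <- filter_criteria(min_age = -Inf, max_age = Inf,
                           exclude_medicated = FALSE,
                           first_visit_only = FALSE,
                           drop_duplicate_ids = FALSE)
  expect_identical(select_samples(md, loose), md$sample_id)
})

test_that("first-visit restriction keeps the minimal visit per subject", {
  md <- data.frame(sample_id = c("a", "b", "c"), subject_id = "X",
                   phenotype = "CD", age = 30, visit_index = c(3L, 1L, 2L),
                   medication_excluded = FALSE)
  expect_identical(select_samples(md), "b")
})

test_that("taxon filtering drops excluded kingdoms and zero-prevalence species", {
  vals <- rbind(Methanobrevibacter_smithii = c(1, 1, 1),
                Bacteroides_fragilis = c(0, 0, 0),
                Escherichia_coli = c(0, 0.5, 0))
  colnames(vals) <- c("S1", "S2", "S3")
  tab <- abundance_table(vals, data.frame(
    canonical = rownames(vals),
    kingdom = c("Archaea", "Bacteria", "Bacteria"),
    lineage = rownames(vals)))
  out <- filter_taxa(tab)
  # archaeon excluded by kingdom; all-zero species by prevalence;
  # a species present in a single sample is retained
  expect_identical(rownames(out$values), "Escherichia_coli")
})

test_that("Shannon index matches closed forms and its invariances", {
  expect_equal(shannon_index(c(5, 0, 0)), 0)
  expect_equal(shannon_index(rep(2, 4)), log(4), tolerance = 1e-12)
  expect_equal(shannon_index(c(0.5, 0.5, 0)), log(2), tolerance = 1e-12)
  expect_equal(shannon_index(numeric(3)), 0)
  expect_error(shannon_index(c(1, -1)), "negative")
  # agreement with the community-ecology reference implementation
  set.seed(11)
  for (i in 1:20) {
    x <- runif(12) * rbinom(12, 1, 0.7)
    if (sum(x) == 0) next
    expect_equal(shannon_index(x), as.numeric(vegan::diversity(x)),
                 tolerance = 1e-12)
    # permutation and scale invariance
    expect_equal(shannon_index(sample(x)), shannon_index(x), tolerance = 1e-12)
    expect_equal(shannon_index(3.7 * x), shannon_index(x), tolerance = 1e-12)
  }
})

test_that("zero-diversity samples are removed", {
  vals <- rbind(A_a = c(1, 1, 0, 0), B_b = c(0, 2, 0, 1))
  colnames(vals) <- paste0("S", 1:4)
  tab <- abundance_table(vals, data.frame(canonical = rownames(vals),
                                          kingdom = "Bacteria",
                                          lineage = rownames(vals)))
  out <- drop_zero_diversity_samples(tab)
  # S1 (one species), S3 (empty) and S4 (one species) have H = 0
  expect_identical(colnames(out$values), "S2")
})

test_that("binarization thresholds strictly at zero and splits phenotypes", {
  md <- data.frame(sample_id = paste0("S", 1:6),
                   subject_id = paste0("U", 1:6),
                   phenotype = rep(c("control", "CD", "UC"), each = 2),
                   age = 30, visit_index = 1L, medication_excluded = FALSE)
  vals <- matrix(c(0.0001, 0, 1, 0, 2, 3,
                   0, 5, 0, 1, 0, 0), nrow = 2, byrow = TRUE,
                 dimnames = list(c("A_a", "B_b"), md$sample_id))
  tab <- abundance_table(vals, data.frame(canonical = rownames(vals),
                                          kingdom = "Bacteria",
                                          lineage = rownames(vals)))
  pms <- lapply(c("control", "CD", "UC"), binarize, table = tab, metadata = md)
  expect_equal(unname(pms[[1]]$cells["A_a", "S1"]), 1L)  # tiny but positive
  expect_equal(unname(pms[[1]]$cells["A_a", "S2"]), 0L)
  expect_true(all(unlist(lapply(pms, function(p) p$cells %in% c(0L, 1L)))))
  got <- sort(unlist(lapply(pms, function(p) colnames(p$cells))))
  expect_identical(got, sort(md$sample_id))  # disjoint column partition
})

test_that("the filter cascade is idempotent", {
  set.seed(42)
  for (rep in 1:5) {
    n_sp <- 12; n_sa <- 15
    vals <- matrix(rbinom(n_sp * n_sa, 1, 0.25) * runif(n_sp * n_sa, 0, 5),
                   nrow = n_sp,
                   dimnames = list(sprintf("Sp_x%02d", 1:n_sp),
                                   sprintf("S%02d", 1:n_sa)))
    md <- data.frame(sample_id = colnames(vals),
                     subject_id = colnames(vals),
                     phenotype = rep(c("control", "CD", "UC"), length.out = n_sa),
                     age = sample(15:70, n_sa, replace = TRUE),
                     visit_index = 1L,
                     medication_excluded = rbinom(n_sa, 1, 0.2) == 1)
    tab <- abundance_table(vals, data.frame(canonical = rownames(vals),
                                            kingdom = "Bacteria",
                                            lineage = rownames(vals)))
    once <- preprocess(tab, md)
    again <- preprocess(once$table, md)
    expect_identical(again$table$values, once$table$values)
    expect_identical(lapply(again$presence, `[[`, "cells"),
                     lapply(once$presence, `[[`, "cells"))
  }
})

test_that("the filter report mirrors the cascade stages", {
  md <- fixture_metadata()
  vals <- matrix(runif(3 * 10), nrow = 3,
                 dimnames = list(c("A_a", "B_b", "C_c"), md$sample_id))
  tab <- abundance_table(vals, data.frame(canonical = rownames(vals),
                                          kingdom = "Bacteria",
                                          lineage = rownames(vals)))
  pp <- preprocess(tab, md)
  expect_identical(pp$report$stage,
                   c("input", "sample_selection", "taxon_filter",
                     "zero_diversity"))
  expect_equal(pp$report$n_samples[1], 10)
  expect_equal(pp$report$n_samples[2], 5)  # survivors of the metadata filter
})
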