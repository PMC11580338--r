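#' Sample and taxon filter criteria
#'
#' Encodes the pre-network filter cascade applied to each cohort: sample
#' selection from metadata (age window, medication exclusion, first-visit
#' restriction, duplicate removal), taxonomic kingdom exclusion,
#' zero-prevalence species removal and zero-Shannon-diversity sample
#' removal.
#'
#' @param min_age,max_age inclusive age bounds in years. Participants
#'   strictly younger than `min_age` or strictly older than `max_age` are
#'   excluded.
#' @param exclude_medicated drop samples flagged `medication_excluded`.
#' @param first_visit_only keep only each subject's minimal `visit_index`.
#' @param drop_duplicate_ids keep the first occurrence of each sample id.
#' @param excluded_kingdoms kingdoms removed from the taxonomic table;
#'   archaea and eukaryotes are dropped by default for their low prevalence
#'   in stool metagenomes.
#' @return Object of class `filter_criteria`.
#' @export
filter_criteria <- function(min_age = 18, max_age = 65,
                            exclude_medicated = TRUE,
                            first_visit_only = TRUE,
                            drop_duplicate_ids = TRUE,
                            excluded_kingdoms = c("Archaea", "Eukaryota")) {
  if (min_age > max_age) stop("min_age > max_age", call. = FALSE)
  structure(list(min_age = min_age, max_age = max_age,
                 exclude_medicated = exclude_medicated,
                 first_visit_only = first_visit_only,
                 drop_duplicate_ids = drop_duplicate_ids,
                 excluded_kingdoms = excluded_kingdoms),
            class = "filter_criteria")
}

#' Select samples from metadata
#'
#' Applies the metadata-level exclusions: duplicate sample ids, medication
#' interventions, age outside the inclusive `[min_age, max_age]` window, and
#' (for longitudinal cohorts) visits after the subject's initial one.
#'
#' @param metadata data.frame with the columns of [read_metadata()].
#' @param criteria a [filter_criteria()] object.
#' @return Character vector of retained sample ids, in metadata order.
#' @export
select_samples <- function(metadata, criteria = filter_criteria()) {
  md <- metadata
  if (isTRUE(criteria$drop_duplicate_ids)) {
    md <- md[!duplicated(md$sample_id), , drop = FALSE]
  }
  keep <- md$age >= criteria$min_age & md$age <= criteria$max_age
  if (isTRUE(criteria$exclude_medicated)) {
    keep <- keep & !md$medication_excluded
  }
  md <- md[keep, , drop = FALSE]
  if (isTRUE(criteria$first_visit_only) && nrow(md) > 0L) {
    first <- stats::ave(md$visit_index, md$subject_id, FUN = min)
    md <- md[md$visit_index == first, , drop = FALSE]
  }
  md$sample_id
}

#' Filter taxa by kingdom and prevalence
#'
#' Removes species whose kingdom is excluded and species absent (abundance
#' zero) in every retained sample. Prevalence is assessed on the full set of
#' columns present, i.e. across all phenotypes jointly.
#'
#' @param table an [abundance_table()], species-level.
#' @param criteria a [filter_criteria()].
#' @return Filtered [abundance_table()].
#' @export
filter_taxa <- function(table, criteria = filter_criteria()) {
  keep <- !(table$taxonomy$kingdom %in% criteria$excluded_kingdoms)
  vals <- table$values[keep, , drop = FALSE]
  tax <- table$taxonomy[keep, , drop = FALSE]
  prevalent <- rowSums(vals > 0) > 0L
  abundance_table(vals[prevalent, , drop = FALSE],
                  tax[prevalent, , drop = FALSE])
}

#' Shannon diversity index
#'
#' `H = -sum p_i log p_i` with natural logarithm, `p_i = a_i / sum(a)`;
#' zero-abundance terms contribute 0, and an all-zero vector is defined to
#' have `H = 0` so that empty samples fall under the zero-diversity
#' exclusion rule. Delegates to [vegan::diversity()].
#'
#' @param abundances non-negative numeric vector.
#' @return Shannon index (nats).
#' @export
shannon_index <- function(abundances) {
  if (any(abundances < 0)) stop("negative abundance", call. = FALSE)
  if (sum(abundances) == 0) return(0)
  as.numeric(vegan::diversity(abundances, index = "shannon"))
}

#' Drop samples with zero Shannon diversity
#'
#' A sample in which at most one species is present has `H = 0` and is
#' excluded.
#'
#' @param table an [abundance_table()].
#' @return [abundance_table()] restricted to samples with `H > 0`.
#' @export
drop_zero_diversity_samples <- function(table) {
  h <- apply(table$values, 2L, shannon_index)
  abundance_table(table$values[, h > 0, drop = FALSE], table$taxonomy)
}

#' Binarize abundances into a per-phenotype presence matrix
#'
#' A species is "present" in a sample iff its relative abundance is
#' strictly greater than zero. Columns are restricted to samples of the
#' requested phenotype.
#'
#' @param table an [abundance_table()].
#' @param phenotype one of `"control"`, `"CD"`, `"UC"`.
#' @param metadata metadata data.frame mapping samples to phenotypes.
#' @param dataset optional dataset label carried on the result.
#' @return Object of class `presence_matrix`: list with binary `cells`
#'   (species x samples), `phenotype`, `dataset`.
#' @export
binarize <- function(table, phenotype, metadata, dataset = NA_character_) {
  samples <- intersect(colnames(table$values),
                       metadata$sample_id[metadata$phenotype == phenotype])
  cells <- (table$values[, samples, drop = FALSE] > 0) * 1L
  structure(list(cells = cells, phenotype = phenotype, dataset = dataset),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("<presence_matrix> ", nrow(x$cells), " species x ", ncol(x$cells),
      " samples [", x$phenotype, "]\n", sep = "")
  invisible(x)
}

#' Run the full pre-network filter cascade
#'
#' Order is fixed: sample selection -> kingdom exclusion -> zero-prevalence
#' removal (across all phenotypes jointly) -> zero-diversity sample removal
#' -> per-phenotype binarization. The cascade is idempotent.
#'
#' @inheritParams binarize
#' @inheritParams select_samples
#' @param phenotypes phenotypes to binarize (those present by default).
#' @return List with `presence` (named list of `presence_matrix`),
#'   `table` (the filtered [abundance_table()]), `samples` (retained ids)
#'   and `report` (data.frame of counts after each stage).
#' @export
preprocess <- function(table, metadata, criteria = filter_criteria(),
                       dataset = NA_character_, phenotypes = NULL) {
  n0 <- c(samples = ncol(table$values), species = nrow(table$values))
  kept <- intersect(colnames(table$values), select_samples(metadata, criteria))
  tab <- abundance_table(table$values[, kept, drop = FALSE], table$taxonomy)
  n1 <- c(samples = ncol(tab$values), species = nrow(tab$values))
  tab <- filter_taxa(tab, criteria)
  n2 <- c(samples = ncol(tab$values), species = nrow(tab$values))
  tab <- drop_zero_diversity_samples(tab)
  # a species present only in just-dropped samples is now zero-prevalence;
  # one final sweep makes the cascade a fixpoint (retained samples'
  # compositions, hence diversities, are unaffected)
  tab <- filter_taxa(tab, criteria)
  n3 <- c(samples = ncol(tab$values), species = nrow(tab$values))
  md <- metadata[metadata$sample_id %in% colnames(tab$values), , drop = FALSE]
  if (is.null(phenotypes)) phenotypes <- intersect(c("control", "CD", "UC"),
                                                   unique(md$phenotype))
  presence <- lapply(phenotypes, function(p) binarize(tab, p, md, dataset))
  names(presence) <- phenotypes
  report <- data.frame(
    stage = c("input", "sample_selection", "taxon_filter", "zero_diversity"),
    n_samples = c(n0[["samples"]], n1[["samples"]], n2[["samples"]], n3[["samples"]]),
    n_species = c(n0[["species"]], n1[["species"]], n2[["species"]], n3[["species"]]),
    stringsAsFactors = FALSE
  )
  list(presence = presence, table = tab, samples = colnames(tab$values),
       report = report)
}
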