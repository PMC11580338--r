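#' Map species to the KOs they contribute
#'
#' A species contributes a KO when its stratified abundance for that KO is
#' strictly positive in at least `min_samples` of the given samples.
#' Presence, not abundance magnitude, drives the mapping. Species of the
#' query set with no stratified entry at all are dropped with a warning.
#'
#' @param ko_profile a `ko_profile` (see [read_ko_profile()]) or a
#'   long-form data.frame with columns `ko`, `species`, `sample`,
#'   `abundance`.
#' @param species_set character vector of canonical species names.
#' @param sample_subset character vector of sample ids (non-empty).
#' @param min_samples minimum number of subset samples with positive
#'   stratified abundance (default 1).
#' @return Named list species -> character vector of KO ids (class
#'   `species_ko_map`); species with empty KO sets are omitted.
#' @export
species_to_kos <- function(ko_profile, species_set, sample_subset,
                           min_samples = 1L) {
  if (length(sample_subset) == 0L) stop("empty sample subset", call. = FALSE)
  e <- if (inherits(ko_profile, "ko_profile")) ko_profile$entries else ko_profile
  e <- e[!is.na(e$species) & e$species %in% species_set &
           e$sample %in% sample_subset & e$abundance > 0, , drop = FALSE]
  if (nrow(e) > 0L) {
    counts <- stats::aggregate(list(n = e$sample),
                               by = list(species = e$species, ko = e$ko),
                               FUN = length)
    counts <- counts[counts$n >= min_samples, , drop = FALSE]
    map <- lapply(split(counts$ko, counts$species), function(x) sort(unique(x)))
  } else {
    map <- list()
  }
  missing <- setdiff(species_set, names(map))
  if (length(missing) > 0L) {
    warning(length(missing), " species without stratified KO entries dropped",
            call. = FALSE)
  }
  structure(map[order(names(map))], class = "species_ko_map")
}

#' Union of a species-KO map
#' @param map a `species_ko_map`.
#' @return Sorted character vector of all KOs contributed by the mapped
#'   species.
#' @export
query_kos <- function(map) sort(unique(unlist(map, use.names = FALSE)))

#' Hypergeometric pathway over-representation test
#'
#' For each pathway with at least one query hit: `k` = query KOs in the
#' pathway, `n` = query KOs in the universe, `K` = pathway KOs, `M` =
#' universe size; the p-value is the upper hypergeometric tail
#' `P(X >= k)` (including `k`). P-values are BH-adjusted across the
#' reported pathways. Rows are sorted by p-value, ties by pathway id.
#'
#' @param query character vector of KO ids (typically [query_kos()] of a
#'   [species_to_kos()] map).
#' @param annotation a [pathway_annotation()].
#' @param universe_mode `"annotation"` (default: all annotated KOs) or
#'   `"observed"` (annotated KOs restricted to `observed_kos`).
#' @param observed_kos KOs observed in the dataset's KO profile; required
#'   for `universe_mode = "observed"`.
#' @param adjust_method multiple-testing adjustment passed to
#'   [stats::p.adjust()] (default `"BH"`).
#' @return data.frame with columns `pathway_id`, `description`, `k`, `n`,
#'   `K`, `M`, `pvalue`, `p_adjust` and list-column `ko_hits`.
#' @export
enrich <- function(query, annotation,
                   universe_mode = c("annotation", "observed"),
                   observed_kos = NULL, adjust_method = "BH") {
  universe_mode <- match.arg(universe_mode)
  universe <- annotation$universe
  if (universe_mode == "observed") {
    if (is.null(observed_kos)) {
      stop("observed_kos required for universe_mode = \"observed\"", call. = FALSE)
    }
    universe <- intersect(universe, observed_kos)
  }
  q <- intersect(unique(query), universe)
  if (length(q) == 0L) {
    stop("query has no KOs in the annotation universe", call. = FALSE)
  }
  n <- length(q)
  M <- length(universe)
  rows <- lapply(names(annotation$pathways), function(pid) {
    pk <- intersect(annotation$pathways[[pid]], universe)
    hits <- intersect(q, pk)
    k <- length(hits)
    if (k == 0L) return(NULL)
    K <- length(pk)
    data.frame(pathway_id = pid,
               description = unname(annotation$description[pid]),
               k = k, n = n, K = K, M = M,
               pvalue = stats::phyper(k - 1L, K, M - K, n, lower.tail = FALSE),
               ko_hits = I(list(sort(hits))),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    rows <- data.frame(pathway_id = character(0L), description = character(0L),
                       k = integer(0L), n = integer(0L), K = integer(0L),
                       M = integer(0L), pvalue = numeric(0L),
                       ko_hits = I(list()), stringsAsFactors = FALSE)
    rows$p_adjust <- numeric(0L)
    return(rows)
  }
  rows$p_adjust <- bh_adjust(rows$pvalue, method = adjust_method)
  rows <- rows[order(rows$pvalue, rows$pathway_id), , drop = FALSE]
  rownames(rows) <- NULL
  rows[c("pathway_id", "description", "k", "n", "K", "M", "pvalue",
         "p_adjust", "ko_hits")]
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjustment, returned in input order (thin wrapper over
#' [stats::p.adjust()]).
#'
#' @param pvalues numeric vector of raw p-values.
#' @param method adjustment method (default `"BH"`).
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(pvalues, method = "BH") {
  stats::p.adjust(pvalues, method = method)
}

#' Significant pathways of an enrichment table
#'
#' @param rows data.frame from [enrich()].
#' @param alpha significance level (strict `<`).
#' @param use_adjusted use the adjusted p-value (default) or the raw one.
#' @return Character vector of pathway ids.
#' @export
significant_pathways <- function(rows, alpha = 0.05, use_adjusted = TRUE) {
  if (is.null(rows) || nrow(rows) == 0L) return(character(0L))
  p <- if (use_adjusted) rows$p_adjust else rows$pvalue
  sort(rows$pathway_id[p < alpha])
}
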