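#' Pathways unique to the disease condition
#'
#' @param disease_pathways,control_pathways character vectors of pathway
#'   ids enriched in the disease and control phenotype.
#' @return Set difference `disease \ control`, sorted.
#' @export
disease_unique <- function(disease_pathways, control_pathways) {
  sort(setdiff(disease_pathways, control_pathways))
}

#' Intersection of disease-unique pathways across datasets
#'
#' @param per_dataset_unique list of pathway-id character vectors, one per
#'   dataset.
#' @return Pathways present in every dataset's set, sorted. A single
#'   dataset is returned unchanged with a warning (no replication
#'   evidence).
#' @export
robust_intersection <- function(per_dataset_unique) {
  if (length(per_dataset_unique) == 0L) return(character(0L))
  if (length(per_dataset_unique) == 1L) {
    warning("single dataset: no cross-dataset replication", call. = FALSE)
    return(sort(unique(per_dataset_unique[[1L]])))
  }
  sort(Reduce(intersect, per_dataset_unique))
}

#' Node-overlap Jaccard index of two networks
#'
#' `|V1 n V2| / |V1 u V2|` on species (node) sets; 0 when both are empty.
#' Edge-set Jaccard (on unordered name pairs) is available as a secondary
#' metric.
#'
#' @param net1,net2 igraph networks.
#' @param on `"nodes"` (default) or `"edges"`.
#' @return Jaccard index in `[0, 1]`.
#' @export
network_jaccard <- function(net1, net2, on = c("nodes", "edges")) {
  on <- match.arg(on)
  set_of <- function(g) {
    if (on == "nodes") {
      if (igraph::vcount(g) == 0L) return(character(0L))
      igraph::V(g)$name
    } else {
      el <- igraph::as_edgelist(g)
      if (nrow(el) == 0L) return(character(0L))
      apply(el, 1L, function(e) paste(sort(e), collapse = "|"))
    }
  }
  s1 <- set_of(net1); s2 <- set_of(net2)
  u <- union(s1, s2)
  if (length(u) == 0L) return(0)
  length(intersect(s1, s2)) / length(u)
}

#' Per-species KO contribution counts for one pathway
#'
#' For each species `s` contributing at least one KO to the pathway,
#' reports `k_s = |map[s] n pathway|` against the pathway size `K`,
#' rendered `"k_s/K"`. The attribute `union_coverage` gives the number of
#' distinct pathway KOs covered by the species jointly (never exceeding
#' `K`; no single species need carry the full pathway).
#'
#' @param pathway_id pathway id present in `annotation`.
#' @param species_ko_map a [species_to_kos()] map.
#' @param annotation a [pathway_annotation()].
#' @return data.frame (`species`, `k_s`, `K`, `label`) sorted by
#'   descending `k_s` then species name, with attribute `union_coverage`.
#' @export
ko_contribution_counts <- function(pathway_id, species_ko_map, annotation) {
  pk <- annotation$pathways[[pathway_id]]
  if (is.null(pk)) stop("unknown pathway: ", pathway_id, call. = FALSE)
  K <- length(pk)
  hits <- lapply(species_ko_map, intersect, y = pk)
  k_s <- vapply(hits, length, integer(1L))
  keep <- k_s >= 1L
  df <- data.frame(species = names(species_ko_map)[keep],
                   k_s = unname(k_s[keep]), K = K,
                   stringsAsFactors = FALSE)
  df$label <- sprintf("%d/%d", df$k_s, df$K)
  df <- df[order(-df$k_s, df$species), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "union_coverage") <-
    length(unique(unlist(hits[keep], use.names = FALSE)))
  df
}

#' Build a per-level signature report
#'
#' Generic comparison used by all granularity levels: per dataset, subtract
#' the control pathway pool from the disease pool, then intersect the
#' disease-unique sets across datasets.
#'
#' @param level one of `"global"`, `"community"`, `"centrality-hub"`,
#'   `"centrality-betweenness"`.
#' @param phenotype disease phenotype label.
#' @param disease_pools,control_pools lists (one element per dataset) of
#'   enriched pathway-id vectors.
#' @param dataset_labels labels for the datasets.
#' @return Object of class `signature_report`: list with `level`,
#'   `phenotype`, `per_dataset_unique` and `robust_pathways`.
#' @export
signature_report <- function(level, phenotype, disease_pools, control_pools,
                             dataset_labels = names(disease_pools)) {
  stopifnot(length(disease_pools) == length(control_pools))
  uniq <- Map(disease_unique, disease_pools, control_pools)
  names(uniq) <- dataset_labels
  structure(list(level = level, phenotype = phenotype,
                 per_dataset_unique = uniq,
                 robust_pathways = robust_intersection(uniq)),
            class = "signature_report")
}

#' @export
print.signature_report <- function(x, ...) {
  cat("<signature_report> level=", x$level, " phenotype=", x$phenotype,
      "\n  robust pathways: ",
      if (length(x$robust_pathways)) paste(x$robust_pathways, collapse = ", ")
      else "None", "\n", sep = "")
  invisible(x)
}

#' Community-level signature with contributing-cluster detail
#'
#' Per dataset, the disease pathway pool is the union of significantly
#' enriched pathways over all disease clusters (control likewise when
#' `subtract_control` is on); disease-unique pools are then intersected
#' across datasets. For every robust pathway the report records, per
#' dataset, each contributing cluster with its id, total species count and
#' the count of member species carrying at least one query KO of the
#' pathway (the Cluster no. / Total species / Contrib. species columns).
#'
#' @param phenotype disease phenotype label.
#' @param disease_clusters list (per dataset) of lists: `enrichment`
#'   (cluster id -> [enrich()] rows), `members` (cluster id -> species),
#'   `ko_map` (the dataset/phenotype [species_to_kos()] map).
#' @param control_pools list (per dataset) of control pathway pools
#'   (character vectors); ignored when `subtract_control = FALSE`.
#' @param annotation a [pathway_annotation()].
#' @param alpha,use_adjusted significance settings for
#'   [significant_pathways()].
#' @param subtract_control subtract the control pool per dataset (default
#'   `TRUE`); `FALSE` relies on cross-dataset consistency alone.
#' @return `signature_report` with an extra `details` data.frame
#'   (`pathway_id`, `dataset`, `cluster`, `total_species`,
#'   `contrib_species`).
#' @export
community_level_signature <- function(phenotype, disease_clusters,
                                      control_pools, annotation,
                                      alpha = 0.05, use_adjusted = TRUE,
                                      subtract_control = TRUE) {
  pool_of <- function(enr) {
    sort(unique(unlist(lapply(enr, significant_pathways, alpha = alpha,
                              use_adjusted = use_adjusted),
                       use.names = FALSE)))
  }
  disease_pools <- lapply(disease_clusters, function(d) pool_of(d$enrichment))
  if (!subtract_control) {
    control_pools <- rep(list(character(0L)), length(disease_pools))
  }
  rep <- signature_report("community", phenotype, disease_pools,
                          control_pools,
                          dataset_labels = names(disease_clusters))
  details <- list()
  for (ds in names(disease_clusters)) {
    dcl <- disease_clusters[[ds]]
    for (pw in rep$robust_pathways) {
      pk <- annotation$pathways[[pw]]
      for (cl in names(dcl$enrichment)) {
        if (!(pw %in% significant_pathways(dcl$enrichment[[cl]],
                                           alpha = alpha,
                                           use_adjusted = use_adjusted))) next
        members <- dcl$members[[cl]]
        contrib <- sum(vapply(members, function(s) {
          kos <- dcl$ko_map[[s]]
          !is.null(kos) && length(intersect(kos, pk)) >= 1L
        }, logical(1L)))
        details[[length(details) + 1L]] <- data.frame(
          pathway_id = pw, dataset = ds, cluster = cl,
          total_species = length(members),
          contrib_species = contrib, stringsAsFactors = FALSE)
      }
    }
  }
  rep$details <- if (length(details)) {
    do.call(rbind, details)
  } else {
    data.frame(pathway_id = character(0L), dataset = character(0L),
               cluster = character(0L), total_species = integer(0L),
               contrib_species = integer(0L), stringsAsFactors = FALSE)
  }
  rep
}
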