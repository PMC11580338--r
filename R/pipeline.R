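#' Pipeline run configuration
#'
#' Collects every tunable of the pipeline in one place. Knobs whose
#' conventions vary in the literature (expected-count threshold for the
#' pair test, enrichment universe, adjusted vs raw significance, community
#' resolution) are all surfaced here and echoed into the run report.
#'
#' @param datasets list of dataset inputs: either directory paths holding
#'   `taxonomic_profile.tsv`, `ko_profile.tsv`, `metadata.tsv`,
#'   `pathway_annotation.tsv`, or in-memory lists as returned by
#'   [simulate_dataset()]. Names default to `dataset1`, `dataset2`, ...
#' @param criteria a [filter_criteria()].
#' @param alpha_cooccur significance level for the pair test.
#' @param alpha_enrich significance level for pathway enrichment.
#' @param expected_threshold minimum expected joint occupancy for a pair
#'   to be tested (see [all_pairs()]).
#' @param resolution fixed Leiden resolution; `NULL` derives it per network
#'   with [default_resolution()].
#' @param leiden_seed,leiden_iterations Leiden determinism settings.
#' @param top_k size of the hub / betweenness top lists.
#' @param min_cluster_size smallest community enriched (default 2).
#' @param universe_mode enrichment universe (see [enrich()]).
#' @param use_adjusted use BH-adjusted p-values for significance calls.
#' @param subtract_control_community subtract the control cluster-pathway
#'   pool at the community level (see [community_level_signature()]).
#' @param out_dir output directory; `NULL` keeps everything in memory.
#' @return Object of class `run_config`.
#' @export
run_config <- function(datasets,
                       criteria = filter_criteria(),
                       alpha_cooccur = 0.05,
                       alpha_enrich = 0.05,
                       expected_threshold = 1.0,
                       resolution = NULL,
                       leiden_seed = 42L,
                       leiden_iterations = 10L,
                       top_k = 5L,
                       min_cluster_size = 2L,
                       universe_mode = c("annotation", "observed"),
                       use_adjusted = TRUE,
                       subtract_control_community = TRUE,
                       out_dir = NULL) {
  if (length(datasets) == 0L) stop("no datasets configured", call. = FALSE)
  if (!(alpha_cooccur > 0 && alpha_cooccur < 1) ||
      !(alpha_enrich > 0 && alpha_enrich < 1)) {
    stop("alpha levels must lie in (0, 1)", call. = FALSE)
  }
  if (is.null(names(datasets))) {
    names(datasets) <- sprintf("dataset%d", seq_along(datasets))
  }
  structure(list(datasets = datasets, criteria = criteria,
                 alpha_cooccur = alpha_cooccur, alpha_enrich = alpha_enrich,
                 expected_threshold = expected_threshold,
                 resolution = resolution, leiden_seed = as.integer(leiden_seed),
                 leiden_iterations = as.integer(leiden_iterations),
                 top_k = as.integer(top_k),
                 min_cluster_size = as.integer(min_cluster_size),
                 universe_mode = match.arg(universe_mode),
                 use_adjusted = use_adjusted,
                 subtract_control_community = subtract_control_community,
                 out_dir = out_dir),
            class = "run_config")
}

load_dataset <- function(input, label) {
  if (is.character(input)) {
    if (!dir.exists(input)) stop("dataset directory not found: ", input,
                                 call. = FALSE)
    list(abundance = read_taxonomic_profile(file.path(input, "taxonomic_profile.tsv")),
         ko = read_ko_profile(file.path(input, "ko_profile.tsv")),
         metadata = read_metadata(file.path(input, "metadata.tsv")),
         annotation = read_pathway_annotation(file.path(input, "pathway_annotation.tsv")),
         dataset = label)
  } else {
    input$dataset <- label
    input
  }
}

enrich_or_empty <- function(query, annotation, universe_mode, observed_kos) {
  if (length(query) == 0L) return(empty_enrichment())
  tryCatch(enrich(query, annotation, universe_mode = universe_mode,
                  observed_kos = observed_kos),
           error = function(e) empty_enrichment())
}

empty_enrichment <- function() {
  df <- data.frame(pathway_id = character(0L), description = character(0L),
                   k = integer(0L), n = integer(0L), K = integer(0L),
                   M = integer(0L), pvalue = numeric(0L),
                   p_adjust = numeric(0L), stringsAsFactors = FALSE)
  df$ko_hits <- I(list())
  df[c("pathway_id", "description", "k", "n", "K", "M", "pvalue",
       "p_adjust", "ko_hits")]
}

analyze_phenotype <- function(pm, dataset, cfg, ko_profile, annotation,
                              observed_kos) {
  pairs <- all_pairs(pm, alpha = cfg$alpha_cooccur,
                     expected_threshold = cfg$expected_threshold)
  net <- build_network(pairs, phenotype = pm$phenotype, dataset = dataset,
                       alpha = cfg$alpha_cooccur)
  species <- global_species(net)
  samples <- colnames(pm$cells)
  ko_map <- if (length(species) > 0L) {
    suppressWarnings(species_to_kos(ko_profile, species, samples))
  } else {
    structure(list(), class = "species_ko_map")
  }

  # community structure
  partition <- NULL
  members <- list()
  if (igraph::vcount(net) >= 2L) {
    gamma <- if (is.null(cfg$resolution)) default_resolution(net) else cfg$resolution
    partition <- leiden_cpm(net, gamma = gamma, seed = cfg$leiden_seed,
                            n_iterations = cfg$leiden_iterations)
    members <- cluster_members(partition, min_size = cfg$min_cluster_size)
  }

  hub <- hub_scores(net)
  btw <- betweenness_scores(net)
  top_hub <- top_k(hub, cfg$top_k)
  top_btw <- top_k(btw, cfg$top_k)

  sub_map <- function(sp) {
    structure(ko_map[intersect(names(ko_map), sp)], class = "species_ko_map")
  }
  enr <- function(sp) {
    enrich_or_empty(query_kos(sub_map(sp)), annotation,
                    cfg$universe_mode, observed_kos)
  }
  cluster_enrichment <- lapply(members, enr)

  list(phenotype = pm$phenotype, pairs = pairs, network = net,
       species = species, ko_map = ko_map,
       partition = partition, members = members,
       hub = hub, betweenness = btw,
       top_hub = top_hub, top_betweenness = top_btw,
       enrichment = list(global = enr(species),
                         clusters = cluster_enrichment,
                         hub = enr(top_hub),
                         betweenness = enr(top_btw)))
}

#' Run the full signature-mining pipeline
#'
#' For every dataset: filter cascade, per-phenotype presence matrices,
#' co-occurrence pair tests and network, Leiden/CPM communities, hub and
#' betweenness top lists, species-to-KO mapping and hypergeometric pathway
#' enrichment at every granularity level. Disease phenotypes are then
#' compared against control per dataset, and disease-unique pathways
#' intersected across datasets into signature reports. When
#' `config$out_dir` is set, all tables, networks and a JSON run report are
#' written there (byte-reproducible for a fixed config).
#'
#' @param config a [run_config()].
#' @return Object of class `coocsig_run`: list with `datasets`
#'   (per-dataset, per-phenotype analyses), `signatures` (per disease
#'   phenotype, per level `signature_report`s), `jaccard` (per phenotype
#'   node-overlap between dataset pairs) and `config`.
#' @export
run_all <- function(config) {
  cfg <- config
  labels <- names(cfg$datasets)
  ds <- lapply(seq_along(cfg$datasets), function(i) {
    d <- load_dataset(cfg$datasets[[i]], labels[i])
    pp <- preprocess(d$abundance, d$metadata, cfg$criteria, dataset = d$dataset)
    observed <- unique(d$ko$entries$ko[d$ko$entries$abundance > 0])
    phen <- lapply(pp$presence, analyze_phenotype, dataset = d$dataset,
                   cfg = cfg, ko_profile = d$ko, annotation = d$annotation,
                   observed_kos = observed)
    list(label = labels[i], annotation = d$annotation, preprocess = pp,
         phenotypes = phen)
  })
  names(ds) <- labels

  annotation <- ds[[1L]]$annotation
  sig_of <- function(res, slot) {
    significant_pathways(res$enrichment[[slot]], alpha = cfg$alpha_enrich,
                         use_adjusted = cfg$use_adjusted)
  }
  diseases <- intersect(c("CD", "UC"),
                        unique(unlist(lapply(ds, function(d) names(d$phenotypes)))))
  signatures <- lapply(diseases, function(dis) {
    have <- vapply(ds, function(d) {
      dis %in% names(d$phenotypes) && "control" %in% names(d$phenotypes)
    }, logical(1L))
    dsl <- ds[have]
    pools <- function(slot, phen) {
      lapply(dsl, function(d) sig_of(d$phenotypes[[phen]], slot))
    }
    lev <- list(
      global = signature_report("global", dis, pools("global", dis),
                                pools("global", "control"),
                                dataset_labels = names(dsl)),
      community = community_level_signature(
        dis,
        lapply(dsl, function(d) {
          p <- d$phenotypes[[dis]]
          list(enrichment = p$enrichment$clusters, members = p$members,
               ko_map = p$ko_map)
        }),
        lapply(dsl, function(d) {
          p <- d$phenotypes[["control"]]
          sort(unique(unlist(lapply(p$enrichment$clusters,
                                    significant_pathways,
                                    alpha = cfg$alpha_enrich,
                                    use_adjusted = cfg$use_adjusted),
                             use.names = FALSE)))
        }),
        annotation, alpha = cfg$alpha_enrich,
        use_adjusted = cfg$use_adjusted,
        subtract_control = cfg$subtract_control_community),
      `centrality-hub` = signature_report("centrality-hub", dis,
                                          pools("hub", dis),
                                          pools("hub", "control"),
                                          dataset_labels = names(dsl)),
      `centrality-betweenness` = signature_report("centrality-betweenness",
                                                  dis,
                                                  pools("betweenness", dis),
                                                  pools("betweenness", "control"),
                                                  dataset_labels = names(dsl))
    )
    lev
  })
  names(signatures) <- diseases

  phens <- unique(unlist(lapply(ds, function(d) names(d$phenotypes))))
  jaccard <- list()
  if (length(ds) >= 2L) {
    combos <- utils::combn(names(ds), 2L, simplify = FALSE)
    for (p in phens) {
      v <- vapply(combos, function(cm) {
        n1 <- ds[[cm[1L]]]$phenotypes[[p]]
        n2 <- ds[[cm[2L]]]$phenotypes[[p]]
        if (is.null(n1) || is.null(n2)) return(NA_real_)
        network_jaccard(n1$network, n2$network)
      }, numeric(1L))
      names(v) <- vapply(combos, paste, character(1L), collapse = "-")
      jaccard[[p]] <- v
    }
  }

  run <- structure(list(datasets = ds, signatures = signatures,
                        jaccard = jaccard, config = cfg),
                   class = "coocsig_run")
  if (!is.null(cfg$out_dir)) write_run(run, cfg$out_dir)
  run
}

#' @export
print.coocsig_run <- function(x, ...) {
  cat("<coocsig_run> ", length(x$datasets), " dataset(s)\n", sep = "")
  for (d in x$datasets) {
    for (p in d$phenotypes) {
      cat(sprintf("  %s/%s: %d nodes, %d edges, %d clusters (>=%d)\n",
                  d$label, p$phenotype, igraph::vcount(p$network),
                  igraph::ecount(p$network), length(p$members),
                  x$config$min_cluster_size))
    }
  }
  for (dis in names(x$signatures)) {
    for (lev in names(x$signatures[[dis]])) {
      rb <- x$signatures[[dis]][[lev]]$robust_pathways
      cat(sprintf("  %s [%s] robust: %s\n", dis, lev,
                  if (length(rb)) paste(rb, collapse = ", ") else "None"))
    }
  }
  invisible(x)
}

#' Write all pipeline outputs of a run
#'
#' Creates `networks/`, `pairs/`, `partitions/`, `centrality/`,
#' `enrichment/`, `signatures/` and `report.json` under `dir`. Output is a
#' pure function of the run (no timestamps), so identical runs produce
#' byte-identical trees.
#'
#' @param run a `coocsig_run`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  for (sub in c("networks", "pairs", "partitions", "centrality",
                "enrichment", "signatures")) {
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  }
  fmtnum <- function(x) formatC(x, digits = 15, format = "g")
  for (d in run$datasets) {
    for (p in d$phenotypes) {
      stem <- sprintf("%s_%s", d$label, p$phenotype)
      write_pairs(p$pairs, file.path(dir, "pairs", paste0(stem, "_pairs.tsv")))
      write_network(p$network,
                    file.path(dir, "networks", paste0(stem, ".tsv")),
                    format = "edgelist")
      write_network(p$network,
                    file.path(dir, "networks", paste0(stem, ".graphml")),
                    format = "graphml")
      if (!is.null(p$partition)) {
        utils::write.table(
          data.frame(species = names(p$partition$assignment),
                     cluster_id = unname(p$partition$assignment)),
          file.path(dir, "partitions", paste0(stem, "_partition.tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
        sizes <- table(p$partition$assignment)
        utils::write.table(
          data.frame(cluster_id = names(sizes),
                     n_species = as.integer(sizes)),
          file.path(dir, "partitions", paste0(stem, "_clusters.tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
      if (length(p$hub) > 0L) {
        cent <- data.frame(species = names(p$hub),
                           hub = fmtnum(unname(p$hub)),
                           betweenness = fmtnum(unname(p$betweenness[names(p$hub)])),
                           top_hub = names(p$hub) %in% p$top_hub,
                           top_betweenness = names(p$hub) %in% p$top_betweenness)
        cent <- cent[order(cent$species), , drop = FALSE]
        utils::write.table(cent,
                           file.path(dir, "centrality", paste0(stem, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      write_enrichment(p$enrichment$global,
                       file.path(dir, "enrichment", paste0(stem, "_global.tsv")))
      clus <- p$enrichment$clusters
      if (length(clus) > 0L) {
        all <- do.call(rbind, lapply(names(clus), function(cl) {
          rows <- clus[[cl]]
          if (nrow(rows) == 0L) return(NULL)
          rows$cluster <- cl
          rows
        }))
        if (!is.null(all)) {
          write_enrichment(all, file.path(dir, "enrichment",
                                          paste0(stem, "_clusters.tsv")))
        }
      }
      write_enrichment(p$enrichment$hub,
                       file.path(dir, "enrichment", paste0(stem, "_hub.tsv")))
      write_enrichment(p$enrichment$betweenness,
                       file.path(dir, "enrichment",
                                 paste0(stem, "_betweenness.tsv")))
    }
  }
  for (dis in names(run$signatures)) {
    for (lev in names(run$signatures[[dis]])) {
      rep <- run$signatures[[dis]][[lev]]
      rb <- rep$robust_pathways
      utils::write.table(
        data.frame(phenotype = dis, level = lev,
                   pathway_id = if (length(rb)) rb else "None"),
        file.path(dir, "signatures", sprintf("%s_%s.tsv", dis, lev)),
        sep = "\t", quote = FALSE, row.names = FALSE)
      if (lev == "community" && nrow(rep$details) > 0L) {
        utils::write.table(rep$details,
                           file.path(dir, "signatures",
                                     sprintf("%s_community_details.tsv", dis)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }
  report <- run_report(run)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

run_report <- function(run) {
  cfg <- run$config
  list(
    package_version = as.character(utils::packageVersion("coocsig")),
    config = list(alpha_cooccur = cfg$alpha_cooccur,
                  alpha_enrich = cfg$alpha_enrich,
                  expected_threshold = cfg$expected_threshold,
                  resolution = if (is.null(cfg$resolution)) "degree-quartile"
                  else cfg$resolution,
                  leiden_seed = cfg$leiden_seed,
                  leiden_iterations = cfg$leiden_iterations,
                  top_k = cfg$top_k,
                  min_cluster_size = cfg$min_cluster_size,
                  universe_mode = cfg$universe_mode,
                  use_adjusted = cfg$use_adjusted,
                  subtract_control_community = cfg$subtract_control_community,
                  criteria = unclass(cfg$criteria)),
    filter_cascade = lapply(run$datasets, function(d) d$preprocess$report),
    networks = lapply(run$datasets, function(d) {
      lapply(d$phenotypes, function(p) {
        list(nodes = igraph::vcount(p$network),
             edges = igraph::ecount(p$network),
             clusters = length(p$members),
             resolution = if (is.null(p$partition)) NULL else p$partition$gamma)
      })
    }),
    jaccard = run$jaccard,
    signatures = lapply(run$signatures, function(levels) {
      lapply(levels, function(r) {
        list(robust_pathways = as.list(r$robust_pathways),
             per_dataset_unique = lapply(r$per_dataset_unique, as.list))
      })
    })
  )
}
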