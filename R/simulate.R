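#' Configuration for paired synthetic datasets
#'
#' Describes the generative model used for end-to-end validation: a pool of
#' background species occurring independently across samples, one planted
#' co-occurrence block per disease phenotype driven by a shared latent
#' per-sample indicator, and a planted pathway whose KOs are split in
#' disjoint slices across the block species so that no single species
#' carries the full pathway. Background species names are shared between
#' datasets while block species names are dataset-specific, emulating low
#' species-level overlap with a conserved pathway signal across cohorts.
#'
#' @param n_datasets number of independent synthetic datasets.
#' @param samples_per_phenotype named integer vector of sample counts for
#'   `control`, `CD`, `UC`.
#' @param n_background_species background species pool size.
#' @param bg_occupancy per-sample presence probability of a background
#'   species.
#' @param blocks list of planted blocks, each a list with `phenotype`,
#'   `size`, `q` (latent co-presence probability in the target phenotype)
#'   and `p0` (baseline occupancy elsewhere); requires `0 <= p0 < q <= 1`
#'   and `size >= 2`.
#' @param block_dropout per-species retention probability given the latent
#'   indicator is on, so blocks are strong but not degenerate identical
#'   rows.
#' @param planted_pathway list with `pathway_id` and `n_kos`
#'   (`n_kos >= max block size`).
#' @param n_background_pathways,background_pathway_size background pathway
#'   count and KO count per pathway, drawn uniformly from the background
#'   KO pool.
#' @param n_background_kos background KO pool size.
#' @param kos_per_species background KOs assigned to every species.
#' @param seed base RNG seed; all randomness derives from it.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_datasets = 2L,
                              samples_per_phenotype = c(control = 30L,
                                                        CD = 30L, UC = 30L),
                              n_background_species = 60L,
                              bg_occupancy = 0.25,
                              blocks = list(
                                list(phenotype = "CD", size = 5L,
                                     q = 0.65, p0 = 0.05),
                                list(phenotype = "UC", size = 5L,
                                     q = 0.65, p0 = 0.05)),
                              block_dropout = 0.9,
                              planted_pathway = list(pathway_id = "map99001",
                                                     n_kos = 12L),
                              n_background_pathways = 30L,
                              background_pathway_size = 20L,
                              n_background_kos = 600L,
                              kos_per_species = 5L,
                              seed = 1L) {
  for (b in blocks) {
    if (!(b$p0 >= 0 && b$p0 < b$q && b$q <= 1)) {
      stop("block requires 0 <= p0 < q <= 1", call. = FALSE)
    }
    if (b$size < 2L) stop("block size must be >= 2", call. = FALSE)
    if (planted_pathway$n_kos < b$size) {
      stop("planted pathway must have at least as many KOs as the block size",
           call. = FALSE)
    }
  }
  if (!all(c("control", "CD", "UC") %in% names(samples_per_phenotype))) {
    stop("samples_per_phenotype needs control, CD and UC entries", call. = FALSE)
  }
  structure(list(n_datasets = n_datasets,
                 samples_per_phenotype = samples_per_phenotype,
                 n_background_species = n_background_species,
                 bg_occupancy = bg_occupancy,
                 blocks = blocks, block_dropout = block_dropout,
                 planted_pathway = planted_pathway,
                 n_background_pathways = n_background_pathways,
                 background_pathway_size = background_pathway_size,
                 n_background_kos = n_background_kos,
                 kos_per_species = kos_per_species,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

background_ko_pool <- function(config) sprintf("K%05d", seq_len(config$n_background_kos))

planted_kos <- function(config) sprintf("K9%04d", seq_len(config$planted_pathway$n_kos))

bg_species_names <- function(config) {
  genera <- c("Bacteroides", "Clostridium", "Faecalibacterium", "Roseburia",
              "Prevotella", "Ruminococcus", "Blautia", "Alistipes",
              "Eubacterium", "Streptococcus")
  i <- seq_len(config$n_background_species)
  sprintf("%s_synthetica%03d", genera[((i - 1L) %% length(genera)) + 1L], i)
}

block_species_names <- function(config, dataset_index) {
  out <- list()
  for (b in config$blocks) {
    out[[b$phenotype]] <- sprintf("Plantibacter_%s_d%d_sp%d",
                                  tolower(b$phenotype), dataset_index,
                                  seq_len(b$size))
  }
  out
}

#' Planted pathway annotation shared by all datasets
#'
#' Background pathways draw KOs uniformly from the background pool; the
#' planted pathway holds its own KO set. Deterministic given the config
#' seed.
#'
#' @param config a [simulation_config()].
#' @return A [pathway_annotation()].
#' @export
simulate_annotation <- function(config) {
  set.seed(config$seed + 77L)
  pool <- background_ko_pool(config)
  paths <- lapply(seq_len(config$n_background_pathways), function(i) {
    sort(sample(pool, config$background_pathway_size))
  })
  names(paths) <- sprintf("map%05d", seq_len(config$n_background_pathways))
  paths[[config$planted_pathway$pathway_id]] <- planted_kos(config)
  desc <- stats::setNames(paste("synthetic pathway", names(paths)), names(paths))
  desc[config$planted_pathway$pathway_id] <- "planted signature pathway (synthetic)"
  pathway_annotation(paths, desc)
}

split_slices <- function(kos, n_slices) {
  split(kos, sort(rep_len(seq_len(n_slices), length(kos))))
}

#' Simulate one synthetic dataset
#'
#' Generates a species-level abundance table, a stratified KO profile,
#' sample metadata and the (dataset-independent) pathway annotation, with
#' the planted structure described in [simulation_config()]. Abundances
#' when present are drawn log-uniform in `[1e-4, 10]` percent; only their
#' positivity matters downstream. Deterministic given
#' `(config$seed, dataset_index)`.
#'
#' @param config a [simulation_config()].
#' @param dataset_index 1-based dataset number.
#' @return List with `abundance` ([abundance_table()]), `ko`
#'   (`ko_profile`), `metadata` (data.frame), `annotation`
#'   ([pathway_annotation()]) and `dataset` (label `"dataset<i>"`).
#' @export
simulate_dataset <- function(config, dataset_index = 1L) {
  if (dataset_index < 1L || dataset_index > config$n_datasets) {
    stop("dataset_index out of range", call. = FALSE)
  }
  annotation <- simulate_annotation(config)
  set.seed((config$seed %% 100000L) * 1000L + dataset_index)

  spp <- config$samples_per_phenotype
  phen <- rep(names(spp), times = spp)
  n_samples <- length(phen)
  samples <- sprintf("D%dS%03d", dataset_index, seq_len(n_samples))
  metadata <- data.frame(
    sample_id = samples,
    subject_id = sprintf("D%dSUBJ%03d", dataset_index, seq_len(n_samples)),
    phenotype = phen,
    age = sample(20:60, n_samples, replace = TRUE),
    visit_index = 1L,
    medication_excluded = FALSE,
    stringsAsFactors = FALSE
  )

  bg_sp <- bg_species_names(config)
  blk_sp <- block_species_names(config, dataset_index)
  species <- c(bg_sp, unlist(blk_sp, use.names = FALSE))

  presence <- matrix(0L, nrow = length(species), ncol = n_samples,
                     dimnames = list(species, samples))
  presence[bg_sp, ] <- matrix(
    stats::rbinom(length(bg_sp) * n_samples, 1L, config$bg_occupancy),
    nrow = length(bg_sp))
  for (b in config$blocks) {
    sp <- blk_sp[[b$phenotype]]
    target <- phen == b$phenotype
    z <- stats::rbinom(sum(target), 1L, b$q)
    for (s in sp) {
      p <- rep(b$p0, n_samples)
      p[target] <- ifelse(z == 1L, config$block_dropout, b$p0)
      presence[s, ] <- stats::rbinom(n_samples, 1L, p)
    }
  }

  abund <- matrix(0, nrow = length(species), ncol = n_samples,
                  dimnames = list(species, samples))
  npos <- sum(presence)
  abund[presence == 1L] <- 10^stats::runif(npos, -4, 1)

  genus <- sub("_.*$", "", species)
  lineage <- sprintf(
    "k__Bacteria|p__Synthphyla|c__Synthclassia|o__Synthales|f__Synthaceae|g__%s|s__%s",
    genus, species)
  table <- abundance_table(abund, data.frame(canonical = species,
                                             kingdom = "Bacteria",
                                             lineage = lineage,
                                             stringsAsFactors = FALSE))

  # KO repertoires: background KOs for everyone, planted slices for blocks
  pool <- background_ko_pool(config)
  repertoire <- lapply(species, function(s) sort(sample(pool, config$kos_per_species)))
  names(repertoire) <- species
  for (b in config$blocks) {
    slices <- split_slices(planted_kos(config), b$size)
    sp <- blk_sp[[b$phenotype]]
    for (i in seq_along(sp)) {
      repertoire[[sp[i]]] <- sort(c(repertoire[[sp[i]]], slices[[i]]))
    }
  }

  strat <- lapply(species, function(s) {
    kos <- repertoire[[s]]
    present <- abund[s, ] > 0
    vals <- outer(rep(1, length(kos)), abund[s, ]) *
      matrix(stats::runif(length(kos) * n_samples, 0.1, 1),
             nrow = length(kos))
    vals[, !present] <- 0
    data.frame(ko = rep(kos, times = n_samples),
               species = s,
               sample = rep(samples, each = length(kos)),
               abundance = as.vector(vals),
               stringsAsFactors = FALSE)
  })
  entries <- do.call(rbind, strat)
  totals <- stats::aggregate(list(abundance = entries$abundance),
                             by = list(ko = entries$ko, sample = entries$sample),
                             FUN = sum)
  totals$species <- NA_character_
  entries <- rbind(entries[c("ko", "species", "sample", "abundance")],
                   totals[c("ko", "species", "sample", "abundance")])
  ko <- structure(list(entries = entries), class = "ko_profile")

  list(abundance = table, ko = ko, metadata = metadata,
       annotation = annotation,
       dataset = sprintf("dataset%d", dataset_index))
}

#' Ground truth of the planted signal
#'
#' @param config a [simulation_config()].
#' @return List with `pathway_id`, `planted_kos`, and `blocks`: per
#'   dataset, the block species names per disease phenotype.
#' @export
planted_truth <- function(config) {
  blocks <- lapply(seq_len(config$n_datasets), function(d) {
    block_species_names(config, d)
  })
  names(blocks) <- sprintf("dataset%d", seq_len(config$n_datasets))
  list(pathway_id = config$planted_pathway$pathway_id,
       planted_kos = planted_kos(config),
       blocks = blocks)
}

#' Write a simulated dataset in the pipeline's input formats
#'
#' Emits `taxonomic_profile.tsv` (merged MetaPhlAn-style),
#' `ko_profile.tsv` (HUMAnN-style stratified, including community totals
#' and an `UNMAPPED` row), `metadata.tsv` and `pathway_annotation.tsv`
#' into `dir`.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vals <- sim$abundance$values
  tax <- data.frame(clade_name = sim$abundance$taxonomy$lineage,
                    stringsAsFactors = FALSE, check.names = FALSE)
  tax <- cbind(tax, as.data.frame(vals, check.names = FALSE))
  utils::write.table(tax, file.path(dir, "taxonomic_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  e <- sim$ko$entries
  genus <- sub("_.*$", "", e$species)
  key <- ifelse(is.na(e$species), e$ko,
                sprintf("%s|g__%s.s__%s", e$ko, genus, e$species))
  wide <- stats::reshape(
    data.frame(key = key, sample = e$sample, abundance = e$abundance,
               stringsAsFactors = FALSE),
    idvar = "key", timevar = "sample", direction = "wide")
  names(wide) <- sub("^abundance\\.", "", names(wide))
  wide[is.na(wide)] <- 0
  wide <- wide[order(wide$key), , drop = FALSE]
  samples <- colnames(vals)
  wide <- wide[c("key", samples)]
  unmapped <- as.data.frame(as.list(c(key = "UNMAPPED",
                                      stats::setNames(rep("1.0", length(samples)),
                                                      samples))),
                            stringsAsFactors = FALSE, check.names = FALSE)
  names(wide)[1L] <- "# Gene Family"
  names(unmapped) <- names(wide)
  utils::write.table(rbind(unmapped, wide), file.path(dir, "ko_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  utils::write.table(sim$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ann <- sim$annotation
  adf <- data.frame(
    pathway_id = rep(names(ann$pathways), lengths(ann$pathways)),
    ko_id = unlist(ann$pathways, use.names = FALSE),
    description = rep(unname(ann$description[names(ann$pathways)]),
                      lengths(ann$pathways)),
    stringsAsFactors = FALSE)
  utils::write.table(adf, file.path(dir, "pathway_annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
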