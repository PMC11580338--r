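#' Parse a taxonomic lineage string
#'
#' Lineage strings are `|`-separated, with each token prefixed by a
#' one-letter rank code and a double underscore, e.g.
#' `k__Bacteria|p__Proteobacteria|...|s__Escherichia_coli`.
#'
#' @param lineage character scalar lineage string.
#' @return Named character vector of rank -> name (names are the one-letter
#'   rank codes `k,p,c,o,f,g,s,t`).
#' @keywords internal
parse_lineage <- function(lineage) {
  tokens <- strsplit(lineage, "|", fixed = TRUE)[[1]]
  ok <- grepl("^[a-z]__", tokens)
  if (!all(ok) || length(tokens) == 0L) {
    stop("malformed lineage token in: ", lineage, call. = FALSE)
  }
  ranks <- substr(tokens, 1L, 1L)
  names <- substring(tokens, 4L)
  stats::setNames(names, ranks)
}

is_species_level <- function(ranks) {
  "s" %in% names(ranks) && !("t" %in% names(ranks))
}

#' Canonical species name from a stratified profile key
#'
#' Both MetaPhlAn-style lineages and HUMAnN-style stratified keys name a
#' species by the same underscored binomial after `s__`; that token is the
#' join key across taxonomic and functional profiles.
#'
#' @param key character, e.g. `"g__Escherichia.s__Escherichia_coli"`.
#' @return character canonical name, e.g. `"Escherichia_coli"`.
#' @keywords internal
canonical_from_stratum <- function(key) {
  m <- regmatches(key, regexpr("s__[^.|]+$", key))
  if (length(m) == 0L) stop("cannot find species token in: ", key, call. = FALSE)
  substring(m, 4L)
}

# Read a profile TSV whose header line may be "#"-prefixed (HUMAnN writes
# "# Gene Family"); leading tab-less "#" lines (MetaPhlAn version stamps)
# and interior "#" lines are skipped.
read_profile_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  i <- 1L
  while (i <= length(lines) && startsWith(lines[i], "#") &&
         !grepl("\t", lines[i])) {
    i <- i + 1L
  }
  if (i > length(lines)) stop("no tabular content in ", path, call. = FALSE)
  header <- sub("^#\\s*", "", lines[i])
  body <- lines[-seq_len(i)]
  body <- body[!startsWith(body, "#")]
  utils::read.delim(text = paste(c(header, body), collapse = "\n"),
                    header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Construct an abundance table
#'
#' @param values numeric matrix, species x samples, rownames canonical
#'   species names, colnames sample ids. Values are relative abundances;
#'   either the 0-100 or the 0-1 scale is accepted (only positivity is used
#'   downstream).
#' @param taxonomy data.frame with columns `canonical`, `kingdom`,
#'   `lineage`, one row per row of `values` in the same order.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, taxonomy) {
  stopifnot(is.matrix(values), is.data.frame(taxonomy),
            nrow(values) == nrow(taxonomy))
  if (any(values < 0)) stop("negative abundance value", call. = FALSE)
  if (anyDuplicated(rownames(values))) {
    stop("duplicate species identifiers", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids", call. = FALSE)
  structure(list(values = values, taxonomy = taxonomy),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("<abundance_table> ", nrow(x$values), " species x ",
      ncol(x$values), " samples\n", sep = "")
  invisible(x)
}

#' Read a merged species-level taxonomic profile
#'
#' Reads a MetaPhlAn-style merged relative-abundance TSV: the first column
#' holds full taxonomic lineage strings, remaining columns are per-sample
#' abundances. Only species-level rows (lineage contains rank `s` and no
#' strain rank `t`) are retained; comment lines starting with `#` are
#' skipped.
#'
#' @param path path to the TSV file.
#' @return An [abundance_table()].
#' @export
read_taxonomic_profile <- function(path) {
  df <- read_profile_table(path)
  if (ncol(df) < 2L) stop("taxonomic profile needs a lineage column and >= 1 sample", call. = FALSE)
  lineages <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  if (anyNA(vals)) stop("non-numeric abundance value in ", path, call. = FALSE)
  parsed <- lapply(seq_along(lineages), function(i) {
    tryCatch(parse_lineage(lineages[i]),
             error = function(e) stop("line ", i + 1L, ": ", conditionMessage(e),
                                      call. = FALSE))
  })
  keep <- vapply(parsed, is_species_level, logical(1L))
  parsed <- parsed[keep]
  vals <- vals[keep, , drop = FALSE]
  canonical <- vapply(parsed, function(r) unname(r[["s"]]), character(1L))
  kingdom <- vapply(parsed, function(r) {
    if ("k" %in% names(r)) unname(r[["k"]]) else NA_character_
  }, character(1L))
  if (any(!nzchar(canonical))) stop("empty species name in lineage", call. = FALSE)
  rownames(vals) <- canonical
  abundance_table(vals, data.frame(canonical = canonical, kingdom = kingdom,
                                   lineage = lineages[keep],
                                   stringsAsFactors = FALSE))
}

#' Read a stratified KO abundance profile
#'
#' Reads a HUMAnN-style KO table ("genefamilies" regrouped to KEGG
#' Orthologs): row keys are either `K#####` (community total) or
#' `K#####|g__Genus.s__Genus_species` (per-species stratified abundance).
#' `UNMAPPED` / `UNGROUPED` rows are discarded.
#'
#' @param path path to the TSV file.
#' @return Object of class `ko_profile`: a list with `entries`, a long-form
#'   data.frame with columns `ko`, `species` (canonical name, `NA` for
#'   unstratified community totals), `sample`, `abundance`.
#' @export
read_ko_profile <- function(path) {
  df <- read_profile_table(path)
  keys <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  samples <- colnames(vals)
  drop <- grepl("^(UNMAPPED|UNGROUPED)", keys)
  keys <- keys[!drop]
  vals <- vals[!drop, , drop = FALSE]
  if (any(vals < 0)) stop("negative KO abundance", call. = FALSE)
  plain <- grepl("^K\\d{5}$", keys)
  strat <- grepl("^K\\d{5}\\|", keys)
  if (any(!plain & !strat)) {
    bad <- keys[!plain & !strat][1L]
    stop("unrecognized KO row key: ", bad, call. = FALSE)
  }
  ko <- sub("\\|.*$", "", keys)
  species <- rep(NA_character_, length(keys))
  species[strat] <- vapply(sub("^K\\d{5}\\|", "", keys[strat]),
                           canonical_from_stratum, character(1L),
                           USE.NAMES = FALSE)
  entries <- data.frame(
    ko = rep(ko, times = length(samples)),
    species = rep(species, times = length(samples)),
    sample = rep(samples, each = length(keys)),
    abundance = as.vector(vals),
    stringsAsFactors = FALSE
  )
  structure(list(entries = entries), class = "ko_profile")
}

#' @export
print.ko_profile <- function(x, ...) {
  e <- x$entries
  cat("<ko_profile> ", length(unique(e$ko)), " KOs, ",
      length(unique(e$species[!is.na(e$species)])), " species, ",
      length(unique(e$sample)), " samples\n", sep = "")
  invisible(x)
}

metadata_required_cols <- c("sample_id", "subject_id", "phenotype", "age",
                            "visit_index", "medication_excluded")

#' Read sample metadata
#'
#' @param path TSV with columns `sample_id`, `subject_id`, `phenotype`
#'   (one of `control`, `CD`, `UC`), `age` (years), `visit_index`
#'   (integer >= 1), `medication_excluded` (logical).
#' @return data.frame with the validated columns.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  missing <- setdiff(metadata_required_cols, names(df))
  if (length(missing) > 0L) {
    stop("metadata missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in metadata", call. = FALSE)
  }
  bad <- setdiff(unique(df$phenotype), c("control", "CD", "UC"))
  if (length(bad) > 0L) {
    stop("unknown phenotype(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  df$medication_excluded <- as.logical(df$medication_excluded)
  df$visit_index <- as.integer(df$visit_index)
  df[metadata_required_cols]
}

#' Read a pathway -> KO annotation table
#'
#' @param path TSV with columns `pathway_id`, `ko_id` and an optional
#'   `description` column; when absent, descriptions default to the pathway
#'   id.
#' @return Object of class `pathway_annotation`: list with `pathways`
#'   (named list of KO character vectors), `description` (named character)
#'   and `universe` (union of all annotated KOs).
#' @export
read_pathway_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("pathway_id", "ko_id") %in% names(df))) {
    stop("annotation needs columns pathway_id and ko_id", call. = FALSE)
  }
  if (nrow(df) == 0L) stop("empty pathway annotation", call. = FALSE)
  pathways <- lapply(split(df$ko_id, df$pathway_id), function(x) sort(unique(x)))
  desc <- if ("description" %in% names(df)) {
    d <- df$description[!duplicated(df$pathway_id)]
    stats::setNames(d, df$pathway_id[!duplicated(df$pathway_id)])
  } else {
    stats::setNames(names(pathways), names(pathways))
  }
  desc[is.na(desc) | !nzchar(desc)] <- names(desc)[is.na(desc) | !nzchar(desc)]
  pathway_annotation(pathways, desc[names(pathways)])
}

#' Construct a pathway annotation object
#'
#' @param pathways named list mapping pathway id to a character vector of
#'   KO ids.
#' @param description optional named character of pathway descriptions.
#' @return `pathway_annotation` object.
#' @export
pathway_annotation <- function(pathways, description = NULL) {
  stopifnot(is.list(pathways), length(pathways) > 0L)
  if (any(lengths(pathways) == 0L)) stop("pathway with empty KO set", call. = FALSE)
  if (is.null(description)) {
    description <- stats::setNames(names(pathways), names(pathways))
  }
  structure(list(pathways = lapply(pathways, function(x) sort(unique(x))),
                 description = description,
                 universe = sort(unique(unlist(pathways, use.names = FALSE)))),
            class = "pathway_annotation")
}

#' @export
print.pathway_annotation <- function(x, ...) {
  cat("<pathway_annotation> ", length(x$pathways), " pathways, universe of ",
      length(x$universe), " KOs\n", sep = "")
  invisible(x)
}

#' Write / read a co-occurrence network
#'
#' Networks are igraph objects carrying graph attributes `phenotype`,
#' `dataset` and `alpha`. The edge-list TSV keeps node names plus the graph
#' attributes in `#`-prefixed header comments; GraphML keeps everything.
#'
#' @param network igraph object (see [build_network()]).
#' @param path output path.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (a in c("phenotype", "dataset", "alpha")) {
      v <- igraph::graph_attr(network, a)
      if (!is.null(v)) writeLines(sprintf("# %s=%s", a, as.character(v)), con)
    }
    writeLines(paste("species_a", "species_b", sep = "\t"), con)
    el <- igraph::as_edgelist(network)
    if (nrow(el) > 0L) {
      swap <- el[, 1L] > el[, 2L]
      el[swap, ] <- el[swap, c(2L, 1L)]
      el <- el[order(el[, 1L], el[, 2L]), , drop = FALSE]
      writeLines(paste(el[, 1L], el[, 2L], sep = "\t"), con)
    }
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    return(g)
  }
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  for (m in meta) {
    kv <- sub("^#\\s*", "", m)
    key <- sub("=.*$", "", kv)
    val <- sub("^[^=]*=", "", kv)
    if (key == "alpha") val <- as.numeric(val)
    g <- igraph::set_graph_attr(g, key, val)
  }
  g
}

enrichment_cols <- c("pathway_id", "description", "GeneRatio", "BgRatio",
                     "pvalue", "p.adjust", "geneID")

#' Write an enrichment result table
#'
#' Columns follow the conventional over-representation output: pathway id,
#' description, GeneRatio (`"k/n"`), BgRatio (`"K/M"`), raw and
#' BH-adjusted p-values, and the `;`-joined KO hits. A `cluster` column is
#' appended when present in `rows`.
#'
#' @param rows data.frame as returned by [enrich()] (possibly with an extra
#'   `cluster` column); may have zero rows.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(rows, path) {
  cols <- enrichment_cols
  if ("cluster" %in% names(rows)) cols <- c(cols, "cluster")
  if (is.null(rows) || nrow(rows) == 0L) {
    out <- as.data.frame(stats::setNames(rep(list(character(0L)), length(cols)),
                                         cols))
  } else {
    out <- data.frame(pathway_id = rows$pathway_id,
                      description = rows$description,
                      GeneRatio = sprintf("%d/%d", rows$k, rows$n),
                      BgRatio = sprintf("%d/%d", rows$K, rows$M),
                      pvalue = rows$pvalue,
                      p.adjust = rows$p_adjust,
                      geneID = vapply(rows$ko_hits, paste, character(1L),
                                      collapse = ";"),
                      stringsAsFactors = FALSE, check.names = FALSE)
    names(out)[names(out) == "p.adjust"] <- "p.adjust"
    if ("cluster" %in% cols) out$cluster <- rows$cluster
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
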