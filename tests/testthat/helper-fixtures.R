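# Small in-code fixtures shared across test files.

write_lines_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# 3 species rows (one archaeal), 2 genus rows, 1 strain row, 2 samples.
fixture_taxonomic_file <- function() {
  write_lines_tmp(c(
    "#mpa_v31_synthetic",
    paste("clade_name", "S1", "S2", sep = "\t"),
    paste("k__Bacteria|p__Bacteroidota|g__Bacteroides", "10", "20", sep = "\t"),
    paste("k__Bacteria|p__Bacteroidota|g__Bacteroides|s__Bacteroides_fragilis",
          "5.5", "0", sep = "\t"),
    paste("k__Bacteria|p__Proteobacteria|g__Escherichia|s__Escherichia_coli",
          "1.25", "2.5", sep = "\t"),
    paste("k__Archaea|p__Euryarchaeota|g__Methanobrevibacter|s__Methanobrevibacter_smithii",
          "0.1", "0.4", sep = "\t"),
    paste("k__Bacteria|p__Firmicutes|g__Clostridium", "3", "3", sep = "\t"),
    paste("k__Bacteria|p__Proteobacteria|g__Escherichia|s__Escherichia_coli|t__SGB10068",
          "1.0", "1.0", sep = "\t")))
}

# 4 stratified rows, 2 community-total rows, UNMAPPED/UNGROUPED noise.
fixture_ko_file <- function() {
  write_lines_tmp(c(
    paste("# Gene Family", "S1", "S2", sep = "\t"),
    paste("UNMAPPED", "100", "120", sep = "\t"),
    paste("UNGROUPED", "7", "8", sep = "\t"),
    paste("K02010", "4.5", "1.0", sep = "\t"),
    paste("K02010|g__Escherichia.s__Escherichia_coli", "4.0", "0", sep = "\t"),
    paste("K02010|g__Bacteroides.s__Bacteroides_fragilis", "0.5", "1.0", sep = "\t"),
    paste("K00927", "2.0", "2.0", sep = "\t"),
    paste("K00927|g__Escherichia.s__Escherichia_coli", "2.0", "1.5", sep = "\t"),
    paste("K00401|g__Bacteroides.s__Bacteroides_fragilis", "0", "0.25", sep = "\t")))
}

fixture_metadata <- function() {
  data.frame(
    sample_id = sprintf("S%02d", 1:10),
    subject_id = c("A", "A", "B", "C", "D", "E", "F", "G", "H", "H"),
    phenotype = c("CD", "CD", "control", "control", "UC",
                  "UC", "CD", "control", "UC", "UC"),
    age = c(30, 31, 17, 66, 40, 45, 50, 18, 65, 41),
    visit_index = c(1L, 2L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 2L),
    medication_excluded = c(FALSE, FALSE, FALSE, FALSE, TRUE,
                            FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

fixture_annotation <- function() {
  pathway_annotation(list(
    mapA = c("K00001", "K00002", "K00003"),
    mapB = c("K00002", "K00004"),
    mapC = c("K00005", "K00006", "K00007", "K00008")))
}

# A presence matrix wrapped in the class the pair test expects.
presence_fixture <- function(cells, phenotype = "CD", dataset = "d1") {
  structure(list(cells = cells, phenotype = phenotype, dataset = dataset),
            class = "presence_matrix")
}

small_sim_config <- function(seed = 7L) {
  simulation_config(
    samples_per_phenotype = c(control = 16L, CD = 16L, UC = 16L),
    n_background_species = 20L,
    n_background_pathways = 8L,
    background_pathway_size = 10L,
    n_background_kos = 120L,
    seed = seed)
}
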