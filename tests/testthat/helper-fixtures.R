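# Fixture builders shared across test files. All fixtures are generated in
# code; nothing is read from disk except what the tests themselves write.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random DNA avoiding the screening motifs, so planted motif positions
# stay under the test's control.
rand_dna_clean <- function(n, banned = c("GACAG", "TAGTCCTTT", "TAGTCCCTT", "GGTGGT")) {
  repeat {
    x <- rand_dna(n)
    if (!any(vapply(banned, grepl, logical(1), x = x, fixed = TRUE))) return(x)
  }
}

TEST_UPSTREAM <- "TTCCTTGGCCATTCCTTGGCCATT"  # motif-free conserved segment

# Full amplicon around a 37F core (core must start with the GACAG anchor).
make_amplicon <- function(core, upstream = TEST_UPSTREAM, terminal = "TAGTCCTTT") {
  paste0(upstream, core, terminal)
}

# Write a dataset triplet (FASTA/counts/meta) and return the paths.
write_tiny_dataset <- function(dir, seqs, counts, meta) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "otus.fasta"),
             counts = file.path(dir, "counts.tsv"),
             meta = file.path(dir, "meta.tsv"))
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), paths["fasta"])
  counts_df <- data.frame(otu_id = rownames(counts), counts,
                          check.names = FALSE, stringsAsFactors = FALSE)
  write.table(counts_df, paths["counts"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(meta, paths["meta"], sep = "\t", quote = FALSE, row.names = FALSE)
  paths
}

default_meta <- function(sample_ids, areas = NULL, habitats = NULL) {
  n <- length(sample_ids)
  data.frame(sample_id = sample_ids,
             area = if (is.null(areas)) rep("OMS", n) else areas,
             habitat = if (is.null(habitats)) rep("CCFZ", n) else habitats,
             stringsAsFactors = FALSE)
}

# Minimal cores data.frame for discovery tests.
make_cores_df <- function(otu_id, core, total_reads, upstream = TEST_UPSTREAM) {
  data.frame(otu_id = otu_id, core = core, total_reads = total_reads,
             upstream = upstream, stringsAsFactors = FALSE)
}

make_refs_df <- function(sequence, category, ref_id = NULL, taxon = NULL) {
  n <- length(sequence)
  data.frame(ref_id = if (is.null(ref_id)) sprintf("REF%02d", seq_len(n)) else ref_id,
             sequence = sequence,
             taxon = if (is.null(taxon)) sprintf("taxon%02d", seq_len(n)) else taxon,
             category = category, stringsAsFactors = FALSE)
}

# Membership sets of a signature table as a canonical sorted list, for
# order-independent comparison against ground truth.
member_sets <- function(signatures) {
  sets <- lapply(signatures$member_otus, sort)
  sets[order(vapply(sets, paste, character(1), collapse = "|"))]
}

planted_sets <- function(truth) {
  keep <- truth$kind == "member" & truth$recoverable %in% TRUE
  sets <- unname(split(truth$otu_id[keep], truth$lineage[keep]))
  sets <- lapply(sets, sort)
  sets[order(vapply(sets, paste, character(1), collapse = "|"))]
}
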