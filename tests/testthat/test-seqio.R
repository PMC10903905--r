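test_that("load_dataset computes totals, zero-fills absent cells, keeps empty rows", {
  dir <- withr::local_tempdir()
  seqs <- c(o1 = "ACGTACGT", o2 = "GGTTAACC", o3 = "TTTTAAAA")
  counts <- matrix(c(5L, 10L, 0L, NA, 7L, 0L), nrow = 3,
                   dimnames = list(c("o1", "o2", "o3"), c("s1", "s2")))
  meta <- default_meta(c("s1", "s2", "s3"))  # s3 absent from counts
  paths <- write_tiny_dataset(dir, seqs, counts, meta)
  ds <- load_dataset(paths["fasta"], paths["counts"], paths["meta"])

  expect_s3_class(ds, "foram_dataset")
  expect_equal(ds$otus$total_reads, c(5, 17, 0))  # NA cell read as 0
  expect_equal(dim(ds$counts), c(3L, 3L))
  expect_equal(unname(ds$counts[, "s3"]), c(0, 0, 0))
  # zero-read OTU retained
  expect_true("o3" %in% ds$otus$otu_id)
  # read conservation
  expect_equal(sum(ds$otus$total_reads), sum(ds$counts))
})

test_that("load_dataset rejects broken cross-references and bad characters", {
  dir <- withr::local_tempdir()
  seqs <- c(o1 = "ACGT", o2 = "GGCC")
  counts <- matrix(c(1L, 2L), nrow = 2, dimnames = list(c("o1", "oX"), "s1"))
  paths <- write_tiny_dataset(dir, seqs, counts, default_meta("s1"))
  expect_error(load_dataset(paths["fasta"], paths["counts"], paths["meta"]), "o2")
  expect_error(load_dataset(paths["fasta"], paths["counts"], paths["meta"]), "oX")

  # non-IUPAC character named with record and position
  seqs_bad <- c(o1 = "ACZT")
  counts2 <- matrix(1L, dimnames = list("o1", "s1"))
  p2 <- write_tiny_dataset(file.path(dir, "b"), seqs_bad, counts2, default_meta("s1"))
  expect_error(load_dataset(p2["fasta"], p2["counts"], p2["meta"]),
               "o1.*'Z' at position 3")

  # unknown sample in counts
  counts3 <- matrix(1L, dimnames = list("o1", "sZ"))
  p3 <- write_tiny_dataset(file.path(dir, "c"), c(o1 = "ACGT"), counts3,
                           default_meta("s1"))
  expect_error(load_dataset(p3["fasta"], p3["counts"], p3["meta"]), "sZ")
})

test_that("sequences are uppercased and U is mapped to T on load", {
  dir <- withr::local_tempdir()
  paths <- write_tiny_dataset(dir, c(o1 = "acgu"),
                              matrix(1L, dimnames = list("o1", "s1")),
                              default_meta("s1"))
  ds <- load_dataset(paths["fasta"], paths["counts"], paths["meta"])
  expect_equal(ds$otus$sequence, "ACGT")
})

test_that("load_dataset conserves reads on randomly generated tables", {
  set.seed(41)
  dir <- withr::local_tempdir()
  n <- 20
  seqs <- setNames(replicate(n, rand_dna(30)), sprintf("otu%02d", 1:n))
  counts <- matrix(sample(0:500, n * 4, TRUE), nrow = n,
                   dimnames = list(names(seqs), paste0("s", 1:4)))
  paths <- write_tiny_dataset(dir, seqs, counts, default_meta(paste0("s", 1:4)))
  ds <- load_dataset(paths["fasta"], paths["counts"], paths["meta"])
  expect_equal(sum(ds$otus$total_reads), sum(counts))
  expect_equal(ds$otus$total_reads, unname(rowSums(counts)))
})

test_that("load_references maps taxon labels to categories and validates", {
  dir <- withr::local_tempdir()
  fasta <- file.path(dir, "refs.fasta")
  annot <- file.path(dir, "refs.tsv")
  writeLines(c(">r1", "ACGTACGT", ">r2", "GGTTGGTT", ">r3", "AACCAACC"), fasta)
  write.table(data.frame(ref_id = c("r1", "r2", "r3"),
                         taxon = c("Clade A", "ENFOR1", "Monothalamids X")),
              annot, sep = "\t", quote = FALSE, row.names = FALSE)
  refs <- load_references(fasta, annot)
  expect_equal(refs$category,
               c("described_clade", "ENFOR", "monothalamids_X"))

  # empty annotation -> empty result with warning
  write.table(data.frame(ref_id = character(0), taxon = character(0)),
              annot, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(refs0 <- load_references(fasta, annot), "empty")
  expect_equal(nrow(refs0), 0)

  # annotation id with no FASTA entry
  write.table(data.frame(ref_id = "missing", taxon = "Clade A"),
              annot, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_references(fasta, annot), "missing")

  # duplicate ref_id and unknown explicit category
  write.table(data.frame(ref_id = c("r1", "r1"), taxon = c("Clade A", "Clade A")),
              annot, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_references(fasta, annot), "duplicate")
  write.table(data.frame(ref_id = "r1", taxon = "x", category = "mystery"),
              annot, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_references(fasta, annot), "unknown reference category")
})

test_that("signature tables round-trip losslessly", {
  set.seed(5)
  path <- withr::local_tempfile(fileext = ".tsv")
  sig <- data.frame(name = c("L1", "L2A"),
                    pattern = c("GACAGGTTTTCCCC", "GACAGGAAAACCCC"),
                    placement = c("prefix_anchored", "suffix_anchored"),
                    length = c(14L, 14L), n_otus = c(2L, 3L),
                    total_reads = c(6500L, 8000L), stringsAsFactors = FALSE)
  sig$member_otus <- list(c("o1", "o2"), c("o3", "o4", "o5"))
  write_signatures(sig, path)
  back <- read_signatures(path)
  expect_equal(back, sig)

  # many synthetic signatures: row count is preserved
  n <- 61
  big <- data.frame(name = sprintf("L%d", 1:n),
                    pattern = vapply(1:n, function(i) paste0("GACAGG", rand_dna(10)),
                                     character(1)),
                    placement = "prefix_anchored", length = 16L,
                    n_otus = 2L, total_reads = 6000L, stringsAsFactors = FALSE)
  big$member_otus <- replicate(n, c("a", "b"), simplify = FALSE)
  write_signatures(big, path)
  expect_equal(length(readLines(path)), n + 1L)  # header + rows
  expect_equal(nrow(read_signatures(path)), n)

  # ambiguity character in a pattern is rejected with a line number
  lines <- readLines(path)
  lines[3] <- sub("^(L2\tGACAGG)[ACGT]", "\\1N", lines[3])
  writeLines(lines, path)
  expect_error(read_signatures(path), "line 3.*A/C/G/T")
})

test_that("assignment tables round-trip and reject duplicate otu_id", {
  path <- withr::local_tempfile(fileext = ".tsv")
  asg <- data.frame(otu_id = c("o1", "o2", "o3"),
                    label = c("L1", "Clade A", "unassigned"),
                    source = c("signature", "prior", NA),
                    matched_pattern = c("GACAGGTT", NA, NA),
                    conflict_note = c(NA, "signature L1 (GACAGGTT) also matches", NA),
                    stringsAsFactors = FALSE)
  write_assignments(asg, path)
  expect_equal(read_assignments(path), asg)

  # empty list -> header-only file
  write_assignments(asg[0, ], path)
  expect_equal(length(readLines(path)), 1L)
  expect_equal(nrow(read_assignments(path)), 0L)

  write.table(data.frame(otu_id = c("o1", "o1"), label = "L1", source = "signature",
                         matched_pattern = "A", conflict_note = ""),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_assignments(path), "duplicate")
})
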