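# Readers and writers for every on-disk artifact: FASTA sequences, OTU x
# sample count matrices, sample metadata, reference annotations, signature
# tables and assignment tables. All tabular formats are UTF-8 TSV with a
# header row; count matrices are OTU rows x sample columns with the first
# column named "otu_id".

.clean_sequence <- function(x, id) {
  x <- chartr("u", "U", toupper(x))
  x <- chartr("U", "T", x)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% IUPAC_DNA)
  if (length(bad)) {
    stop(sprintf("record '%s' contains non-IUPAC character '%s' at position %d",
                 id, chars[bad[1]], bad[1]), call. = FALSE)
  }
  x
}

#' Read a FASTA file of nucleotide sequences
#'
#' Sequences are uppercased and U is mapped to T on load, so downstream
#' exact matching is always over the DNA alphabet. Wrapped and single-line
#' FASTA are both accepted.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences; names are the FASTA ids
#'   (first whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- as.character(set)
  seqs <- vapply(seq_along(seqs), function(i) .clean_sequence(seqs[i], ids[i]),
                 character(1))
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), length(names(seqs)) == length(seqs))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

.read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Load an OTU dataset: sequences, read counts, and sample metadata
#'
#' Cross-references the three files and builds a single dataset object.
#' FASTA ids and count-matrix row keys must agree in both directions;
#' count-matrix columns must be declared in the metadata. Samples present
#' in the metadata but absent from the count matrix get all-zero columns
#' (sparse merges of multi-study tables), and empty count cells read as 0.
#'
#' @param fasta_path FASTA of OTU representative sequences.
#' @param counts_path TSV count matrix; first column "otu_id", one column
#'   per sample.
#' @param meta_path TSV with columns `sample_id`, `area`, `habitat`
#'   (habitat one of `CCFZ`, `deep_sea`, `shallow`).
#' @return An object of class `foram_dataset`: a list with `otus`
#'   (data.frame: `otu_id`, `sequence`, `total_reads`), `counts`
#'   (integer matrix, OTU x sample) and `samples` (the metadata).
#' @export
load_dataset <- function(fasta_path, counts_path, meta_path) {
  seqs <- read_fasta(fasta_path)

  ctab <- .read_tsv(counts_path)
  if (ncol(ctab) < 1) stop("count matrix has no columns: ", counts_path)
  ids <- as.character(ctab[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate otu_id rows in count matrix: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  cm <- as.matrix(ctab[, -1, drop = FALSE])
  storage.mode(cm) <- "double"
  cm[is.na(cm)] <- 0
  if (any(cm < 0) || any(cm != floor(cm))) {
    stop("count matrix must contain non-negative integers")
  }
  rownames(cm) <- ids

  meta <- .read_tsv(meta_path)
  need <- c("sample_id", "area", "habitat")
  if (!all(need %in% names(meta))) {
    stop("sample metadata must have columns: ", paste(need, collapse = ", "))
  }
  meta <- meta[, need]
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  }
  bad_hab <- setdiff(unique(meta$habitat), FORAM_HABITATS)
  if (length(bad_hab)) {
    stop("unknown habitat value(s): ", paste(bad_hab, collapse = ", "),
         " (expected ", paste(FORAM_HABITATS, collapse = ", "), ")")
  }

  only_fasta <- setdiff(names(seqs), ids)
  only_counts <- setdiff(ids, names(seqs))
  if (length(only_fasta) || length(only_counts)) {
    stop("otu_id cross-reference mismatch between FASTA and count matrix.",
         if (length(only_fasta))
           paste0(" Missing from counts: ", paste(only_fasta, collapse = ", "), "."),
         if (length(only_counts))
           paste0(" Missing from FASTA: ", paste(only_counts, collapse = ", "), "."))
  }
  extra_samples <- setdiff(colnames(cm), meta$sample_id)
  if (length(extra_samples)) {
    stop("count-matrix sample(s) absent from metadata: ",
         paste(extra_samples, collapse = ", "))
  }
  missing_samples <- setdiff(meta$sample_id, colnames(cm))
  if (length(missing_samples)) {
    zero <- matrix(0, nrow = nrow(cm), ncol = length(missing_samples),
                   dimnames = list(rownames(cm), missing_samples))
    cm <- cbind(cm, zero)
  }
  cm <- cm[names(seqs), meta$sample_id, drop = FALSE]

  otus <- data.frame(otu_id = names(seqs),
                     sequence = unname(seqs),
                     total_reads = unname(rowSums(cm)),
                     stringsAsFactors = FALSE)
  structure(list(otus = otus, counts = cm, samples = meta),
            class = "foram_dataset")
}

#' @export
print.foram_dataset <- function(x, ...) {
  cat(sprintf("foram_dataset: %d OTUs x %d samples, %s reads total\n",
              nrow(x$otus), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

.normalize_category <- function(x) {
  key <- gsub("[ .-]+", "_", tolower(trimws(x)))
  out <- ifelse(key %in% c("described_clade", "clade", "described"), "described_clade",
         ifelse(key == "enfor", "ENFOR",
         ifelse(key %in% c("monothalamids_x", "monothalamid_x"), "monothalamids_X",
         ifelse(key %in% c("undetermined", "undetermined_monothalamid",
                           "undetermined_monothalamids"), "undetermined",
                NA_character_))))
  if (anyNA(out)) {
    stop("unknown reference category value(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "),
         " (expected one of ", paste(REF_CATEGORIES, collapse = ", "), ")")
  }
  out
}

.infer_category <- function(taxon) {
  ifelse(grepl("^ENFOR", taxon, ignore.case = TRUE), "ENFOR",
  ifelse(grepl("monothalamids?[ _-]?X", taxon, ignore.case = TRUE), "monothalamids_X",
  ifelse(grepl("clade", taxon, ignore.case = TRUE), "described_clade",
         "undetermined")))
}

#' Load a reference database with category annotations
#'
#' The annotation table needs columns `ref_id` and `taxon`, and optionally
#' `category`. When `category` is absent it is inferred from the taxon
#' label: names starting with "ENFOR" become `ENFOR`, names containing
#' "Monothalamids X" become `monothalamids_X`, names containing "Clade"
#' become `described_clade`, anything else `undetermined`.
#'
#' @param fasta_path FASTA of reference sequences.
#' @param annot_path TSV annotation table.
#' @return data.frame with columns `ref_id`, `sequence`, `taxon`,
#'   `category`.
#' @export
load_references <- function(fasta_path, annot_path) {
  seqs <- read_fasta(fasta_path)
  annot <- .read_tsv(annot_path, colClasses = "character")
  if (!all(c("ref_id", "taxon") %in% names(annot))) {
    stop("reference annotation must have columns ref_id and taxon")
  }
  if (nrow(annot) == 0) {
    warning("empty reference annotation file: ", annot_path)
    return(data.frame(ref_id = character(0), sequence = character(0),
                      taxon = character(0), category = character(0),
                      stringsAsFactors = FALSE))
  }
  if (anyDuplicated(annot$ref_id)) {
    stop("duplicate ref_id in annotation: ",
         paste(unique(annot$ref_id[duplicated(annot$ref_id)]), collapse = ", "))
  }
  unknown <- setdiff(annot$ref_id, names(seqs))
  if (length(unknown)) {
    stop("annotation ref_id with no FASTA entry: ",
         paste(unknown, collapse = ", "))
  }
  category <- if ("category" %in% names(annot)) {
    .normalize_category(annot$category)
  } else {
    .infer_category(annot$taxon)
  }
  unused <- setdiff(names(seqs), annot$ref_id)
  if (length(unused)) {
    warning(length(unused), " reference sequence(s) without annotation dropped")
  }
  data.frame(ref_id = annot$ref_id,
             sequence = unname(seqs[annot$ref_id]),
             taxon = annot$taxon,
             category = category,
             stringsAsFactors = FALSE)
}

#' Write and read signature tables
#'
#' Persists validated signatures as a TSV with columns `name`, `pattern`,
#' `placement`, `length`, `n_otus`, `total_reads`, `member_otus`
#' (comma-joined). A write-then-read round trip is lossless.
#'
#' @param signatures Signature data.frame as returned by
#'   [discover_signatures()] / [name_lineages()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_signatures <- function(signatures, path) {
  df <- data.frame(name = signatures$name,
                   pattern = signatures$pattern,
                   placement = signatures$placement,
                   length = signatures$length,
                   n_otus = signatures$n_otus,
                   total_reads = signatures$total_reads,
                   member_otus = vapply(signatures$member_otus,
                                        paste, character(1), collapse = ","),
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' @rdname write_signatures
#' @return For `read_signatures`, the signature data.frame (with
#'   `member_otus` as a list column).
#' @export
read_signatures <- function(path) {
  df <- .read_tsv(path, colClasses = "character")
  need <- c("name", "pattern", "placement", "length", "n_otus",
            "total_reads", "member_otus")
  if (!all(need %in% names(df))) {
    stop("malformed signature table (missing columns): ", path)
  }
  for (i in seq_len(nrow(df))) {
    line <- i + 1L  # header is line 1
    if (!grepl("^[ACGT]+$", df$pattern[i])) {
      stop(sprintf("line %d: pattern contains characters outside A/C/G/T", line))
    }
    if (!df$placement[i] %in% SIG_PLACEMENTS) {
      stop(sprintf("line %d: unknown placement '%s'", line, df$placement[i]))
    }
    if (is.na(suppressWarnings(as.integer(df$total_reads[i])))) {
      stop(sprintf("line %d: malformed total_reads", line))
    }
  }
  members <- lapply(strsplit(df$member_otus, ",", fixed = TRUE),
                    function(x) x[nzchar(x)])
  out <- data.frame(name = ifelse(nzchar(df$name), df$name, NA_character_),
                    pattern = df$pattern,
                    placement = df$placement,
                    length = as.integer(df$length),
                    n_otus = as.integer(df$n_otus),
                    total_reads = as.integer(df$total_reads),
                    stringsAsFactors = FALSE)
  out$member_otus <- members
  bad_n <- which(out$n_otus != lengths(out$member_otus))
  if (length(bad_n)) {
    stop(sprintf("line %d: n_otus does not match member_otus", bad_n[1] + 1L))
  }
  if (nrow(out) && any(out$length != nchar(out$pattern))) {
    stop("signature table: length column disagrees with pattern")
  }
  out
}

#' Write and read assignment tables
#'
#' One row per OTU with columns `otu_id`, `label`, `source`,
#' `matched_pattern`, `conflict_note`. Missing values are written as empty
#' fields and read back as `NA`; round trips are lossless.
#'
#' @param assignments Assignment data.frame as returned by
#'   [match_signatures()] or [merge_with_prior()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  cols <- c("otu_id", "label", "source", "matched_pattern", "conflict_note")
  .write_tsv(assignments[, cols], path)
}

#' @rdname write_assignments
#' @export
read_assignments <- function(path) {
  df <- .read_tsv(path, colClasses = "character")
  need <- c("otu_id", "label", "source", "matched_pattern", "conflict_note")
  if (!all(need %in% names(df))) {
    stop("malformed assignment table (missing columns): ", path)
  }
  if (anyDuplicated(df$otu_id)) {
    stop("duplicate otu_id in assignment table: ",
         paste(unique(df$otu_id[duplicated(df$otu_id)]), collapse = ", "))
  }
  for (col in c("source", "matched_pattern", "conflict_note")) {
    df[[col]][!nzchar(df[[col]])] <- NA_character_
  }
  df[, need]
}

#' Read a prior (similarity-based) assignment table
#'
#' Expects columns `otu_id`, `label`, `status`, with `status` one of
#' `assigned`, `enfor`, `monothalamids_X`, `undetermined_monothalamid`,
#' `unassigned`.
#'
#' @param path TSV path.
#' @return data.frame with one row per OTU.
#' @export
read_prior_assignments <- function(path) {
  df <- .read_tsv(path, colClasses = "character")
  if (!all(c("otu_id", "label", "status") %in% names(df))) {
    stop("prior assignment table must have columns otu_id, label, status")
  }
  if (anyDuplicated(df$otu_id)) {
    stop("duplicate otu_id in prior assignment table")
  }
  bad <- setdiff(unique(df$status), PRIOR_STATUSES)
  if (length(bad)) {
    stop("unknown prior status value(s): ", paste(bad, collapse = ", "))
  }
  df[, c("otu_id", "label", "status")]
}
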