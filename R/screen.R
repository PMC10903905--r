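# Conserved-motif screening of amplicons. The 37F hypervariable region is
# bounded upstream by the "GACAG" anchor at the end of conserved helix 37(I)
# and downstream by "TAGTCCTTT"/"TAGTCCCTT" at the end of the 37 conserved
# region (or "GGTGGT" in region 38 for two-region amplicons). All reported
# coordinates are 0-based, half-open.

#' Screening filter configuration
#'
#' Defaults follow the published retention rules for foraminiferal 37F
#' amplicons: the "GACAG" anchor adjacent to 37F, the two terminal motif
#' variants (a T>C substitution is seen in some species), retention of
#' sequences with strictly more than 70 bp and strictly more than 100
#' reads, and at most 2 edits in the conserved region upstream of the
#' anchor.
#'
#' @param anchor_motif Conserved anchor immediately upstream of 37F.
#' @param terminal_motifs Accepted motifs at the end of the 37 conserved
#'   region (one-region amplicons).
#' @param alt_terminal_motif Motif in the 38 conserved region used for
#'   two-region (37F+41F) amplicons.
#' @param min_length Minimum length in bp, exclusive (`> min_length` kept).
#' @param min_reads Minimum total reads, exclusive (`> min_reads` kept).
#' @param max_conserved_edits Maximum edits (substitutions, indels, plus
#'   ambiguity characters) tolerated in the conserved upstream segment.
#' @param length_on Whether `min_length` applies to the full retained
#'   sequence (default) or to the anchored 37F core only.
#' @return A `filter_config` list.
#' @export
filter_config <- function(anchor_motif = "GACAG",
                          terminal_motifs = c("TAGTCCTTT", "TAGTCCCTT"),
                          alt_terminal_motif = "GGTGGT",
                          min_length = 70L,
                          min_reads = 100L,
                          max_conserved_edits = 2L,
                          length_on = c("full", "core")) {
  length_on <- match.arg(length_on)
  motifs <- c(anchor_motif, terminal_motifs, alt_terminal_motif)
  if (!all(grepl("^[ACGTRYSWKMBDHVN]+$", motifs))) {
    stop("motifs must be IUPAC nucleotide strings")
  }
  if (min_length < 0 || min_reads < 0 || max_conserved_edits < 0) {
    stop("thresholds must be non-negative")
  }
  structure(list(anchor_motif = anchor_motif,
                 terminal_motifs = terminal_motifs,
                 alt_terminal_motif = alt_terminal_motif,
                 min_length = as.integer(min_length),
                 min_reads = as.integer(min_reads),
                 max_conserved_edits = as.integer(max_conserved_edits),
                 length_on = length_on),
            class = "filter_config")
}

# All 1-based start positions of a fixed pattern in x, including
# overlapping occurrences (a motif can straddle another's tail, e.g.
# "GACAGACAGG" carries "GACAG" at positions 1 and 5).
.find_all <- function(pattern, x) {
  n <- nchar(x)
  L <- nchar(pattern)
  if (L > n) return(integer(0))
  starts <- seq_len(n - L + 1L)
  starts[substring(x, starts, starts + L - 1L) == pattern]
}

#' Locate the conserved anchors and the 37F variable span in a sequence
#'
#' Finds the last terminal-motif occurrence and the last anchor occurrence
#' preceding it; the biologically meaningful anchor abuts the variable
#' region, so when the anchor occurs more than once the last occurrence
#' before the terminal motif is used and the annotation is flagged
#' `ambiguous_anchor`. Coordinates are 0-based, half-open.
#'
#' @param sequence Uppercase DNA string.
#' @param config A [filter_config()].
#' @param mode `"one_region"` (37F-only amplicons, terminal pair) or
#'   `"two_region"` (37F+41F amplicons, `alt_terminal_motif`).
#' @return A `region_annotation` list. On success `status` is `"ok"` and
#'   the fields `anchor_start`, `anchor_end`, `terminal_motif`,
#'   `terminal_start`, `var_start`, `var_end`, `ambiguous_anchor` are set;
#'   on failure `status` is `"no_terminal"` or `"no_anchor"` and `detail`
#'   names the missing motif.
#' @export
annotate_regions <- function(sequence, config = filter_config(),
                             mode = c("one_region", "two_region")) {
  mode <- match.arg(mode)
  if (length(sequence) != 1 || is.na(sequence) || !nzchar(sequence)) {
    stop("empty sequence")
  }
  sequence <- toupper(sequence)
  terms <- if (mode == "one_region") config$terminal_motifs else config$alt_terminal_motif
  hits <- lapply(terms, .find_all, x = sequence)
  starts <- unlist(hits)
  if (!length(starts)) {
    return(structure(list(status = "no_terminal",
                          detail = paste0("terminal motif not found (",
                                          paste(terms, collapse = "/"), ")")),
                     class = "region_annotation"))
  }
  motifs <- rep(terms, lengths(hits))
  i <- which.max(starts)
  t1 <- starts[i]            # 1-based start of last terminal occurrence
  anchors <- .find_all(config$anchor_motif, sequence)
  anchors <- anchors[anchors + nchar(config$anchor_motif) - 1L < t1]
  if (!length(anchors)) {
    return(structure(list(status = "no_anchor",
                          detail = paste0("anchor motif '", config$anchor_motif,
                                          "' not found before terminal")),
                     class = "region_annotation"))
  }
  a1 <- max(anchors)
  structure(list(status = "ok",
                 anchor_start = a1 - 1L,
                 anchor_end = a1 - 1L + nchar(config$anchor_motif),
                 terminal_motif = motifs[i],
                 terminal_start = t1 - 1L,
                 var_start = a1 - 1L + nchar(config$anchor_motif),
                 var_end = t1 - 1L,
                 ambiguous_anchor = length(anchors) > 1L),
            class = "region_annotation")
}

#' Per-position majority consensus of the conserved segment upstream of the
#' anchor
#'
#' The conserved region before 37F should look alike across all
#' foraminiferal sequences; this builds its per-position majority consensus
#' from the reference database, right-aligned at the anchor and truncated
#' to the shortest upstream segment. Ties are broken alphabetically
#' (A < C < G < T). Reference sequences without a locatable anchor are
#' skipped; references lacking a terminal motif fall back to their last
#' anchor occurrence.
#'
#' @param references Reference data.frame from [load_references()].
#' @param config A [filter_config()].
#' @return The consensus nucleotide string.
#' @export
conserved_consensus <- function(references, config = filter_config()) {
  ups <- character(0)
  for (i in seq_len(nrow(references))) {
    s <- references$sequence[i]
    ann <- annotate_regions(s, config)
    a0 <- if (ann$status == "ok") {
      ann$anchor_start
    } else {
      a <- .find_all(config$anchor_motif, s)
      if (length(a)) max(a) - 1L else NA_integer_
    }
    if (!is.na(a0) && a0 > 0L) ups <- c(ups, substr(s, 1L, a0))
  }
  if (!length(ups)) {
    stop("no reference sequence with a locatable anchor and upstream segment")
  }
  L <- min(nchar(ups))
  segs <- substring(ups, nchar(ups) - L + 1L)
  mat <- do.call(rbind, strsplit(segs, "", fixed = TRUE))
  cons <- apply(mat, 2, function(col) {
    counts <- table(factor(col, levels = c("A", "C", "G", "T")))
    if (sum(counts) == 0L) return("N")
    names(counts)[which.max(counts)]  # first max => alphabetical tie-break
  })
  paste(cons, collapse = "")
}

#' Conserved-region quality control of a screened amplicon
#'
#' Compares the segment immediately upstream of the anchor (right-aligned,
#' trimmed to the consensus length) with the conserved-region consensus.
#' The edit count is the Levenshtein distance plus the number of non-ACGT
#' (ambiguity) characters in the segment; the record passes when
#' `edits <= max_edits`.
#'
#' @param upstream The sequence upstream of the anchor motif.
#' @param consensus Consensus from [conserved_consensus()].
#' @param max_edits Maximum tolerated edits (default 2).
#' @return list with `pass` (logical) and `edits` (integer).
#' @export
qc_conserved <- function(upstream, consensus, max_edits = 2L) {
  if (!nzchar(consensus)) stop("consensus must be non-empty")
  L <- nchar(consensus)
  seg <- substring(upstream, max(1L, nchar(upstream) - L + 1L))
  ambig <- nchar(gsub("[ACGT]", "", seg))
  edits <- as.integer(utils::adist(seg, consensus)) + ambig
  list(pass = edits <= max_edits, edits = edits)
}

#' Screen a dataset with the foraminiferal retention rules
#'
#' Applies, in order: motif annotation (terminal then anchor), the strict
#' length filter (`> min_length`), the strict abundance filter
#' (`> min_reads`), and, when a reference database is supplied,
#' conserved-region QC against the upstream consensus. Every input OTU
#' receives exactly one verdict; records with verdict `kept` or
#' `ambiguous_anchor` are retained with their region annotation.
#'
#' @param dataset A `foram_dataset` from [load_dataset()] (or any
#'   data.frame with columns `otu_id`, `sequence`, `total_reads`).
#' @param config A [filter_config()].
#' @param mode `"one_region"` or `"two_region"` (see [annotate_regions()]).
#' @param references Optional reference data.frame; enables conserved
#'   region QC.
#' @return list with `kept` (data.frame of retained OTUs plus annotation
#'   columns `anchor_start`, `anchor_end`, `terminal_motif`,
#'   `terminal_start`, `var_start`, `var_end`) and `log` (data.frame
#'   `otu_id`, `verdict`, `detail`, one row per input OTU).
#' @export
screen_dataset <- function(dataset, config = filter_config(),
                           mode = c("one_region", "two_region"),
                           references = NULL) {
  mode <- match.arg(mode)
  otus <- if (is.data.frame(dataset)) dataset else dataset$otus
  consensus <- if (!is.null(references) && nrow(references) > 0) {
    conserved_consensus(references, config)
  } else NULL

  n <- nrow(otus)
  verdict <- character(n)
  detail <- character(n)
  ann_cols <- data.frame(anchor_start = rep(NA_integer_, n),
                         anchor_end = NA_integer_,
                         terminal_motif = NA_character_,
                         terminal_start = NA_integer_,
                         var_start = NA_integer_,
                         var_end = NA_integer_)
  for (i in seq_len(n)) {
    s <- otus$sequence[i]
    ann <- annotate_regions(s, config, mode)
    if (ann$status != "ok") {
      verdict[i] <- ann$status
      detail[i] <- ann$detail
      next
    }
    eff_len <- if (config$length_on == "full") nchar(s) else ann$var_end - ann$anchor_start
    if (eff_len <= config$min_length) {
      verdict[i] <- "too_short"
      detail[i] <- sprintf("length %d <= %d", eff_len, config$min_length)
      next
    }
    if (otus$total_reads[i] <= config$min_reads) {
      verdict[i] <- "too_rare"
      detail[i] <- sprintf("reads %d <= %d", otus$total_reads[i], config$min_reads)
      next
    }
    if (!is.null(consensus)) {
      up <- substr(s, 1L, ann$anchor_start)
      qc <- qc_conserved(up, consensus, config$max_conserved_edits)
      if (!qc$pass) {
        verdict[i] <- "failed_qc"
        detail[i] <- sprintf("%d edit(s) in conserved region (max %d)",
                             qc$edits, config$max_conserved_edits)
        next
      }
    }
    if (ann$ambiguous_anchor) {
      verdict[i] <- "ambiguous_anchor"
      detail[i] <- "multiple anchor occurrences; last before terminal used"
    } else {
      verdict[i] <- "kept"
      detail[i] <- ""
    }
    ann_cols$anchor_start[i] <- ann$anchor_start
    ann_cols$anchor_end[i] <- ann$anchor_end
    ann_cols$terminal_motif[i] <- ann$terminal_motif
    ann_cols$terminal_start[i] <- ann$terminal_start
    ann_cols$var_start[i] <- ann$var_start
    ann_cols$var_end[i] <- ann$var_end
  }
  keep <- verdict %in% c("kept", "ambiguous_anchor")
  kept <- cbind(otus[keep, , drop = FALSE], ann_cols[keep, , drop = FALSE])
  rownames(kept) <- NULL
  log <- data.frame(otu_id = otus$otu_id, verdict = verdict, detail = detail,
                    stringsAsFactors = FALSE)
  list(kept = kept, log = log)
}
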