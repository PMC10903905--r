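# Zero-mismatch classification: exact multi-pattern substring matching of
# validated signatures against any dataset, and reconciliation with prior
# (similarity-based) taxonomic assignments. Matching is placement-blind and
# single-strand: the published pattern search matched signatures directly
# against amplicon sequences at 100% similarity.

#' Precedence configuration for merging with prior assignments
#'
#' @param overridable_prior_statuses Prior statuses a signature match may
#'   override. By default everything except a well-defined taxon:
#'   unassigned OTUs, environmental ENFOR clades, Monothalamids X, and
#'   undetermined monothalamids.
#' @return A `precedence_config` list.
#' @export
precedence_config <- function(overridable_prior_statuses =
                                c("unassigned", "enfor", "monothalamids_X",
                                  "undetermined_monothalamid")) {
  bad <- setdiff(overridable_prior_statuses, PRIOR_STATUSES)
  if (length(bad)) stop("unknown prior status: ", paste(bad, collapse = ", "))
  structure(list(overridable_prior_statuses = overridable_prior_statuses),
            class = "precedence_config")
}

#' Assign OTUs to lineages by exact signature matching
#'
#' An OTU is assigned to a lineage iff its sequence contains that lineage's
#' pattern exactly (substring, no mismatch, single strand). An OTU matching
#' several patterns is assigned to the longest one — longer signatures
#' better define the lower taxonomic level — and carries a `conflict_note`
#' listing all matches. Non-matching OTUs are labelled `"unassigned"`.
#'
#' @param signatures Named signature data.frame from [name_lineages()].
#' @param records A `foram_dataset` or data.frame with `otu_id`,
#'   `sequence`.
#' @return Assignment data.frame: `otu_id`, `label`, `source`
#'   (`"signature"` or `NA`), `matched_pattern`, `conflict_note`.
#' @export
match_signatures <- function(signatures, records) {
  otus <- if (is.data.frame(records)) records else records$otus
  n <- nrow(otus)
  out <- data.frame(otu_id = otus$otu_id,
                    label = rep("unassigned", n),
                    source = rep(NA_character_, n),
                    matched_pattern = rep(NA_character_, n),
                    conflict_note = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  if (is.null(signatures) || nrow(signatures) == 0) return(out)
  if (anyNA(signatures$name)) stop("signatures must be named; see name_lineages()")

  hits <- vapply(signatures$pattern,
                 function(p) grepl(p, otus$sequence, fixed = TRUE),
                 logical(n))
  hits <- matrix(hits, nrow = n)
  for (i in seq_len(n)) {
    idx <- which(hits[i, ])
    if (!length(idx)) next
    # longest pattern wins; deterministic tie-break on lineage name
    idx <- idx[order(-signatures$length[idx], signatures$name[idx])]
    best <- idx[1]
    out$label[i] <- signatures$name[best]
    out$source[i] <- "signature"
    out$matched_pattern[i] <- signatures$pattern[best]
    if (length(idx) > 1) {
      out$conflict_note[i] <- paste0("matches multiple signatures: ",
                                     paste(sprintf("%s (%s)",
                                                   signatures$name[idx],
                                                   signatures$pattern[idx]),
                                           collapse = "; "))
    }
  }
  out
}

#' Merge signature assignments with prior taxonomic assignments
#'
#' Implements the combined inner-to-outer ring logic: when the prior status
#' is overridable (unassigned, ENFOR, Monothalamids X, undetermined
#' monothalamid) and a signature matched, the lineage label wins; when the
#' prior is a well-defined taxon, the prior label is kept and the signature
#' hit is recorded in `conflict_note`. OTUs absent from the prior table are
#' treated as unassigned.
#'
#' @param prior Prior assignment data.frame (`otu_id`, `label`, `status`),
#'   e.g. from [read_prior_assignments()].
#' @param sig_assign Assignment data.frame from [match_signatures()].
#' @param config A [precedence_config()].
#' @return Combined assignment data.frame, one row per OTU in
#'   `sig_assign`.
#' @export
merge_with_prior <- function(prior, sig_assign, config = precedence_config()) {
  if (anyDuplicated(prior$otu_id)) stop("duplicate otu_id in prior assignments")
  bad <- setdiff(unique(prior$status), PRIOR_STATUSES)
  if (length(bad)) stop("unknown prior status value(s): ", paste(bad, collapse = ", "))

  m <- match(sig_assign$otu_id, prior$otu_id)
  status <- ifelse(is.na(m), "unassigned", prior$status[m])
  plabel <- ifelse(is.na(m), "unassigned", prior$label[m])
  out <- sig_assign
  for (i in seq_len(nrow(out))) {
    sig_hit <- identical(out$source[i], "signature")
    if (sig_hit && status[i] %in% config$overridable_prior_statuses) {
      next  # signature label wins; row already carries it
    }
    if (sig_hit) {
      # well-defined prior taxon: keep it, record the signature hit
      note <- sprintf("signature %s (%s) also matches",
                      out$label[i], out$matched_pattern[i])
      out$conflict_note[i] <- if (is.na(out$conflict_note[i])) note else
        paste(note, out$conflict_note[i], sep = "; ")
      out$label[i] <- plabel[i]
      out$source[i] <- "prior"
      out$matched_pattern[i] <- NA_character_
    } else {
      out$label[i] <- plabel[i]
      out$source[i] <- if (status[i] == "unassigned") NA_character_ else "prior"
    }
  }
  out
}

#' Composition summary of a combined assignment
#'
#' Per-label OTU and read totals with read fractions, the tabular backbone
#' of before/after assignment pie charts.
#'
#' @param combined Assignment data.frame covering all OTUs of `records`.
#' @param records A `foram_dataset` or data.frame with `otu_id`,
#'   `total_reads`.
#' @param collapse_lineages If `TRUE`, all signature-assigned lineage
#'   labels are pooled into one `"new_lineages"` category.
#' @return data.frame `category`, `n_otus`, `n_reads`,
#'   `fraction_of_reads`, ordered by decreasing reads; fractions sum to 1.
#' @export
composition_summary <- function(combined, records, collapse_lineages = FALSE) {
  otus <- if (is.data.frame(records)) records else records$otus
  m <- match(otus$otu_id, combined$otu_id)
  if (anyNA(m)) {
    stop("assignments do not cover all OTUs: ",
         paste(otus$otu_id[is.na(m)], collapse = ", "))
  }
  label <- combined$label[m]
  if (collapse_lineages) {
    label[!is.na(combined$source[m]) & combined$source[m] == "signature"] <- "new_lineages"
  }
  agg <- stats::aggregate(cbind(n_otus = 1, n_reads = otus$total_reads),
                          by = list(category = label), FUN = sum)
  total <- sum(otus$total_reads)
  agg$fraction_of_reads <- if (total > 0) agg$n_reads / total else 0
  agg <- agg[order(-agg$n_reads, agg$category), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
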