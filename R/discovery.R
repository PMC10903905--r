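# Diagnostic signature discovery in the 37F hypervariable core. Candidate
# patterns come in three placement classes, mirroring where lineage-defining
# variation sits in the gene:
#   prefix_anchored   - starts at the core's first base (the GACAGG hexamer
#                       closing helix 37(I)),
#   upstream_extended - a prefix candidate rescued from a reference conflict
#                       by extending leftward into the conserved region,
#   suffix_anchored   - anchored at the end of the core (end of 37F /
#                       37(II)), used to split prefix-indistinguishable sets.

#' Signature discovery configuration
#'
#' Defaults reflect the validation rules for lineage signatures: length
#' between 12 and 53 nt, at least 2 member OTUs, strictly more than 5000
#' supporting reads, and the reference-exclusion rule with its exemption
#' for environmental (ENFOR) and Monothalamids X reference groups.
#'
#' @param min_sig_len Minimum signature length (nt).
#' @param max_sig_len Maximum signature length (nt).
#' @param min_otus Minimum member OTUs per lineage (inclusive).
#' @param min_reads Minimum supporting reads, exclusive (`> min_reads`).
#' @param allowed_reference_categories Reference categories a signature may
#'   hit without being rejected.
#' @param anchor_hexamer The six conserved nucleotides closing helix 37(I).
#' @param minimal_patterns If `TRUE`, report the shortest prefix that still
#'   selects exactly the member set instead of the longest common prefix.
#'   Longer signatures reduce the risk of misidentification, so the long
#'   form is the default.
#' @return A `discovery_config` list.
#' @export
discovery_config <- function(min_sig_len = 12L,
                             max_sig_len = 53L,
                             min_otus = 2L,
                             min_reads = 5000L,
                             allowed_reference_categories = c("ENFOR", "monothalamids_X"),
                             anchor_hexamer = "GACAGG",
                             minimal_patterns = FALSE) {
  if (min_sig_len > max_sig_len) stop("min_sig_len must be <= max_sig_len")
  if (min_sig_len <= 0 || min_otus <= 0 || min_reads <= 0) {
    stop("thresholds must be positive")
  }
  structure(list(min_sig_len = as.integer(min_sig_len),
                 max_sig_len = as.integer(max_sig_len),
                 min_otus = as.integer(min_otus),
                 min_reads = as.integer(min_reads),
                 allowed_reference_categories = allowed_reference_categories,
                 anchor_hexamer = anchor_hexamer,
                 minimal_patterns = isTRUE(minimal_patterns)),
            class = "discovery_config")
}

# --- small string utilities -------------------------------------------------

.revstr <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1),
         USE.NAMES = FALSE)
}

.lcp2 <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return("")
  ca <- strsplit(substr(a, 1L, n), "", fixed = TRUE)[[1]]
  cb <- strsplit(substr(b, 1L, n), "", fixed = TRUE)[[1]]
  d <- which(ca != cb)
  k <- if (length(d)) d[1] - 1L else n
  substr(a, 1L, k)
}

# Longest common prefix / suffix of a character vector.
.lcp <- function(xs) Reduce(.lcp2, xs)
.lcs <- function(xs) .revstr(.lcp(.revstr(xs)))

.hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

# Longest ACGT-only prefix / suffix of a string.
.acgt_prefix <- function(x) {
  m <- regexpr("[^ACGT]", x)
  if (m > 0L) substr(x, 1L, m - 1L) else x
}
.acgt_suffix <- function(x) .revstr(.acgt_prefix(.revstr(x)))

# --- core extraction --------------------------------------------------------

#' Extract the anchored 37F core from an annotated sequence
#'
#' The core is the anchor motif plus the variable span, up to but excluding
#' the terminal motif; when the base following "GACAG" is G the core starts
#' with the full conserved hexamer "GACAGG".
#'
#' @param sequence The full amplicon sequence.
#' @param annotation A successful `region_annotation` from
#'   [annotate_regions()].
#' @return The core nucleotide string.
#' @export
extract_core <- function(sequence, annotation) {
  if (!identical(annotation$status, "ok")) {
    stop("annotation is not a successful region annotation")
  }
  if (annotation$var_end <= annotation$var_start) {
    stop("variable span is empty")
  }
  substr(sequence, annotation$anchor_start + 1L, annotation$var_end)
}

#' Extract cores and upstream segments for all screened OTUs
#'
#' @param kept The `kept` data.frame from [screen_dataset()].
#' @param on_empty What to do with records whose variable span is empty:
#'   `"error"` (default) or `"drop"` with a warning.
#' @return `kept` with added columns `core` and `upstream`.
#' @export
extract_cores <- function(kept, on_empty = c("error", "drop")) {
  on_empty <- match.arg(on_empty)
  empty <- kept$var_end <= kept$var_start
  if (any(empty)) {
    if (on_empty == "error") {
      stop("variable span is empty for: ",
           paste(kept$otu_id[empty], collapse = ", "))
    }
    warning(sum(empty), " record(s) with empty variable span dropped")
    kept <- kept[!empty, , drop = FALSE]
  }
  kept$core <- substr(kept$sequence, kept$anchor_start + 1L, kept$var_end)
  kept$upstream <- substr(kept$sequence, 1L, kept$anchor_start)
  rownames(kept) <- NULL
  kept
}

# --- discovery --------------------------------------------------------------

.sig_df <- function(pattern = character(0), placement = character(0),
                    members = list(), reads = integer(0)) {
  df <- data.frame(name = rep(NA_character_, length(pattern)),
                   pattern = pattern,
                   placement = placement,
                   length = nchar(pattern),
                   n_otus = lengths(members),
                   total_reads = as.integer(reads),
                   stringsAsFactors = FALSE)
  df$member_otus <- members
  df
}

#' Discover candidate lineage signatures among unassigned OTUs
#'
#' Three-tier search over the anchored 37F cores:
#'
#' * **Tier 1 (prefix-anchored):** cores are grouped by their first
#'   `min_sig_len` bases (the maximal sets sharing a qualifying common
#'   prefix); each group's candidate pattern is the longest common prefix
#'   of its members, capped at `max_sig_len`.
#' * **Tier 2 (upstream-extended):** a Tier-1 candidate whose pattern
#'   occurs in a disallowed reference sequence is extended leftward, one
#'   base at a time, into the members' shared conserved upstream segment
#'   (up to `max_sig_len`) and retested; if no extension escapes the
#'   conflict the candidate is rejected.
#' * **Tier 3 (suffix-anchored):** within a prefix group, member subsets
#'   that share their last `min_sig_len` bases but cannot be told apart by
#'   prefix (their common prefix equals the whole group's) yield a
#'   suffix-anchored candidate: the subset's longest common suffix, capped
#'   at `max_sig_len`.
#'
#' Every emitted candidate satisfies the validation rules (length bounds,
#' `>= min_otus` members, `> min_reads` supporting reads) and the
#' reference-exclusion rule: its pattern occurs in no reference sequence
#' whose category is outside `allowed_reference_categories`. Membership is
#' closed: `member_otus` is exactly the set of input OTUs whose core
#' matches the pattern at the required placement. Cores carrying non-ACGT
#' characters inside a candidate window are excluded from that candidate's
#' membership.
#'
#' @param cores data.frame with columns `otu_id`, `core`, `total_reads`,
#'   and optionally `upstream` (needed for Tier 2), e.g. from
#'   [extract_cores()].
#' @param references Optional reference data.frame from
#'   [load_references()]; `NULL` disables the exclusion rule.
#' @param config A [discovery_config()].
#' @return Unnamed signature data.frame (columns `name` = NA, `pattern`,
#'   `placement`, `length`, `n_otus`, `total_reads`, and list column
#'   `member_otus`), ordered by decreasing `total_reads` then pattern.
#' @export
discover_signatures <- function(cores, references = NULL,
                                config = discovery_config()) {
  if (is.null(cores) || nrow(cores) == 0) return(.sig_df())
  if (is.null(cores$upstream)) cores$upstream <- ""
  k <- config$min_sig_len

  disallowed <- if (!is.null(references) && nrow(references) > 0) {
    references$sequence[!references$category %in% config$allowed_reference_categories]
  } else character(0)
  in_disallowed <- function(p) {
    length(disallowed) > 0 && any(grepl(p, disallowed, fixed = TRUE))
  }

  eligible <- cores[nchar(cores$core) >= k, , drop = FALSE]
  if (nrow(eligible) == 0) return(.sig_df())
  key <- substr(eligible$core, 1L, k)
  clean_key <- grepl("^[ACGT]+$", key)

  out <- .sig_df()
  group_info <- list()  # per prefix group: rows, lcp (for Tier 3)

  for (gk in unique(key[clean_key])) {
    g <- eligible[clean_key & key == gk, , drop = FALSE]
    lcp_raw <- .lcp(g$core)
    group_info[[gk]] <- list(rows = g, lcp = lcp_raw)
    if (nrow(g) < config$min_otus) next
    pat <- .acgt_prefix(lcp_raw)
    if (nchar(pat) > config$max_sig_len) pat <- substr(pat, 1L, config$max_sig_len)
    if (nchar(pat) < k) next
    mem <- g[startsWith(g$core, pat), , drop = FALSE]
    if (config$minimal_patterns) {
      # shortest prefix (>= k) selecting the same member set among all cores
      for (len in k:nchar(pat)) {
        p2 <- substr(pat, 1L, len)
        sel <- eligible$otu_id[startsWith(eligible$core, p2) &
                                 grepl("^[ACGT]+$", substr(eligible$core, 1L, len))]
        if (setequal(sel, mem$otu_id)) { pat <- p2; break }
      }
    }
    if (nrow(mem) < config$min_otus) next
    reads <- sum(mem$total_reads)
    if (reads <= config$min_reads) next
    placement <- "prefix_anchored"
    if (in_disallowed(pat)) {
      # Tier 2: extend leftward into the shared conserved upstream segment
      ext <- .acgt_suffix(.lcs(mem$upstream))
      rescued <- FALSE
      jmax <- min(nchar(ext), config$max_sig_len - nchar(pat))
      if (jmax >= 1L) {
        for (j in seq_len(jmax)) {
          p2 <- paste0(substring(ext, nchar(ext) - j + 1L), pat)
          if (!in_disallowed(p2)) {
            pat <- p2
            placement <- "upstream_extended"
            rescued <- TRUE
            break
          }
        }
      }
      if (!rescued) next
    }
    out <- rbind(out, .sig_df(pat, placement, list(sort(mem$otu_id)), reads))
  }

  # Tier 3: suffix-anchored discrimination inside prefix groups
  skey <- substring(eligible$core, nchar(eligible$core) - k + 1L)
  clean_skey <- grepl("^[ACGT]+$", skey)
  for (sk in unique(skey[clean_skey])) {
    S <- eligible[clean_skey & skey == sk, , drop = FALSE]
    if (nrow(S) < config$min_otus) next
    gks <- unique(substr(S$core, 1L, k))
    if (length(gks) != 1L || is.null(group_info[[gks]])) next
    G <- group_info[[gks]]
    if (nrow(S) >= nrow(G$rows)) next                 # proper subset only
    if (!identical(.lcp(S$core), G$lcp)) next         # prefix-indistinguishable
    pat <- .acgt_suffix(.lcs(S$core))
    if (nchar(pat) > config$max_sig_len) {
      pat <- substring(pat, nchar(pat) - config$max_sig_len + 1L)
    }
    if (nchar(pat) < k) next
    mem <- S[endsWith(S$core, pat), , drop = FALSE]
    if (nrow(mem) < config$min_otus) next
    reads <- sum(mem$total_reads)
    if (reads <= config$min_reads) next
    if (in_disallowed(pat)) next
    out <- rbind(out, .sig_df(pat, "suffix_anchored", list(sort(mem$otu_id)), reads))
  }

  # Resolve overlapping candidates (one pattern nested in another at the
  # same placement): keep the candidate with more member OTUs; tie goes to
  # the longer pattern.
  if (nrow(out) > 1) {
    drop <- rep(FALSE, nrow(out))
    for (i in seq_len(nrow(out) - 1)) {
      for (j in (i + 1):nrow(out)) {
        if (drop[i] || drop[j]) next
        if (out$placement[i] != out$placement[j]) next
        pi <- out$pattern[i]; pj <- out$pattern[j]
        nested <- if (out$placement[i] == "suffix_anchored") {
          endsWith(pi, pj) || endsWith(pj, pi)
        } else {
          startsWith(pi, pj) || startsWith(pj, pi)
        }
        if (!nested) next
        keep_i <- if (out$n_otus[i] != out$n_otus[j]) {
          out$n_otus[i] > out$n_otus[j]
        } else {
          out$length[i] >= out$length[j]
        }
        if (keep_i) drop[j] <- TRUE else drop[i] <- TRUE
      }
    }
    out <- out[!drop, , drop = FALSE]
  }

  ord <- order(-out$total_reads, out$pattern)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Name validated signatures as lineages and sub-lineages
#'
#' Lineages are named "L" plus a number (L1, L43, ...); closely related
#' candidates become sub-lineages sharing the number with letters appended
#' (L2A, L2B, ...). Two candidates belong to the same lineage when their
#' patterns have equal length and Hamming distance 1 (a single SNP), or
#' when they share an identical first `min_sig_len`-mer; the relation is
#' closed transitively. Numbers are assigned in descending order of
#' supporting reads (ties broken by pattern), letters likewise within each
#' lineage, so naming is deterministic under input permutation.
#'
#' @param candidates Signature data.frame from [discover_signatures()].
#' @param config A [discovery_config()] (supplies `min_sig_len`).
#' @return The same data.frame with the `name` column filled, ordered by
#'   name.
#' @export
name_lineages <- function(candidates, config = discovery_config()) {
  n <- nrow(candidates)
  if (n == 0) return(candidates)
  ord <- order(-candidates$total_reads, candidates$pattern)
  sig <- candidates[ord, , drop = FALSE]
  k <- config$min_sig_len

  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        p1 <- sig$pattern[i]; p2 <- sig$pattern[j]
        same <- (nchar(p1) == nchar(p2) && .hamming(p1, p2) == 1L) ||
          identical(substr(p1, 1L, k), substr(p2, 1L, k))
        if (same) union(i, j)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  number <- match(roots, unique(roots))  # first appearance = highest reads
  name <- character(n)
  for (g in unique(number)) {
    idx <- which(number == g)
    if (length(idx) == 1L) {
      name[idx] <- sprintf("L%d", g)
    } else {
      name[idx] <- sprintf("L%d%s", g, LETTERS[seq_along(idx)])
    }
  }
  sig$name <- name
  sig <- sig[order(number, name), , drop = FALSE]
  rownames(sig) <- NULL
  sig
}

#' Per-column Shannon entropy of aligned cores
#'
#' @param aligned_cores Character vector of equal-length (gapped) sequences.
#'   Gap and ambiguity characters are excluded from the frequency counts.
#' @return Numeric vector of per-column entropies in bits. A column with
#'   no usable (A/C/G/T) characters gets entropy 0 with a warning.
#' @export
positional_entropy <- function(aligned_cores) {
  if (length(aligned_cores) < 1) stop("need at least one sequence")
  lens <- unique(nchar(aligned_cores))
  if (length(lens) != 1) stop("sequences must have equal length")
  mat <- do.call(rbind, strsplit(toupper(aligned_cores), "", fixed = TRUE))
  apply(mat, 2, function(col) {
    counts <- table(factor(col, levels = c("A", "C", "G", "T")))
    tot <- sum(counts)
    if (tot == 0L) {
      warning("alignment column with no usable characters; entropy set to 0")
      return(0)
    }
    p <- counts[counts > 0] / tot
    -sum(p * log2(p))
  })
}
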