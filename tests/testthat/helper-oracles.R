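# Independent brute-force oracles. These deliberately avoid the package's
# internal helpers: occurrence scans use regex lookahead, common prefixes
# and suffixes are computed character by character, and discovery
# enumerates every substring at every placement before filtering.

# All occurrence positions (1-based, overlapping) via regex lookahead;
# patterns here are plain nucleotide motifs, no escaping needed.
oracle_find_all <- function(pattern, x) {
  m <- gregexpr(paste0("(?=", pattern, ")"), x, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

oracle_contains <- function(x, pattern) length(oracle_find_all(pattern, x)) > 0

# Naive region annotation: scan all occurrences of every motif.
oracle_annotate <- function(sequence, anchor = "GACAG",
                            terminals = c("TAGTCCTTT", "TAGTCCCTT")) {
  t_pos <- integer(0); t_mot <- character(0)
  for (tm in terminals) {
    p <- oracle_find_all(tm, sequence)
    t_pos <- c(t_pos, p); t_mot <- c(t_mot, rep(tm, length(p)))
  }
  if (!length(t_pos)) return(list(status = "no_terminal"))
  i <- which.max(t_pos)
  anchors <- oracle_find_all(anchor, sequence)
  anchors <- anchors[anchors + nchar(anchor) - 1 < t_pos[i]]
  if (!length(anchors)) return(list(status = "no_anchor"))
  a <- max(anchors)
  list(status = "ok",
       anchor_start = a - 1L, anchor_end = a - 1L + nchar(anchor),
       terminal_motif = t_mot[i], terminal_start = t_pos[i] - 1L,
       var_start = a - 1L + nchar(anchor), var_end = t_pos[i] - 1L,
       ambiguous_anchor = length(anchors) > 1)
}

# Position-by-position substring scan, one pattern against one sequence.
oracle_match_one <- function(pattern, sequence) {
  np <- nchar(pattern); ns <- nchar(sequence)
  if (np > ns) return(FALSE)
  pc <- strsplit(pattern, "")[[1]]
  sc <- strsplit(sequence, "")[[1]]
  for (start in 1:(ns - np + 1)) {
    if (all(sc[start:(start + np - 1)] == pc)) return(TRUE)
  }
  FALSE
}

# Naive multi-pattern assignment: longest matching pattern wins, ties on
# lineage name.
oracle_assign <- function(signatures, otus) {
  out <- data.frame(otu_id = otus$otu_id, label = "unassigned",
                    matched_pattern = NA_character_, n_matches = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(otus))) {
    hits <- which(vapply(signatures$pattern, oracle_match_one, logical(1),
                         sequence = otus$sequence[i]))
    if (!length(hits)) next
    hits <- hits[order(-nchar(signatures$pattern[hits]), signatures$name[hits])]
    out$label[i] <- signatures$name[hits[1]]
    out$matched_pattern[i] <- signatures$pattern[hits[1]]
    out$n_matches[i] <- length(hits)
  }
  out
}

oracle_lcp <- function(xs) {
  chars <- strsplit(xs, "")
  n <- min(lengths(chars))
  k <- 0L
  while (k < n && length(unique(vapply(chars, `[`, character(1), k + 1L))) == 1L) {
    k <- k + 1L
  }
  substr(xs[1], 1, k)
}

oracle_lcs <- function(xs) {
  chars <- strsplit(xs, "")
  n <- min(lengths(chars))
  k <- 0L
  while (k < n && length(unique(vapply(chars, function(ch) ch[length(ch) - k],
                                       character(1)))) == 1L) {
    k <- k + 1L
  }
  substring(xs[1], nchar(xs[1]) - k + 1L)
}

acgt_only <- function(x) grepl("^[ACGT]*$", x)

# Exhaustive discovery oracle: enumerate every substring at every
# placement, collect member sets by naive matching, keep maximal sets,
# then apply the validation, reference-exclusion and nesting rules.
oracle_discover <- function(cores, references, config) {
  k <- config$min_sig_len; K <- config$max_sig_len
  if (is.null(cores$upstream)) cores$upstream <- ""
  disallowed <- if (!is.null(references) && nrow(references)) {
    references$sequence[!references$category %in% config$allowed_reference_categories]
  } else character(0)
  in_dis <- function(p) {
    any(vapply(disallowed, oracle_match_one, logical(1), pattern = p))
  }
  elig <- cores[nchar(cores$core) >= k, , drop = FALSE]
  if (!nrow(elig)) {
    return(data.frame(pattern = character(0), placement = character(0),
                      members = character(0), stringsAsFactors = FALSE))
  }

  # prefix candidates: every qualifying prefix of every core
  pref <- list()
  for (i in seq_len(nrow(elig))) {
    co <- elig$core[i]
    for (len in k:min(K, nchar(co))) {
      p <- substr(co, 1, len)
      if (!acgt_only(p)) break
      mem <- sort(elig$otu_id[substr(elig$core, 1, len) == p])
      key <- paste(mem, collapse = "|")
      if (is.null(pref[[key]]) || nchar(pref[[key]]) < len) pref[[key]] <- p
    }
  }
  sets <- lapply(names(pref), function(kk) strsplit(kk, "|", fixed = TRUE)[[1]])
  maximal <- vapply(seq_along(sets), function(i) {
    !any(vapply(seq_along(sets), function(j) {
      j != i && length(sets[[j]]) > length(sets[[i]]) && all(sets[[i]] %in% sets[[j]])
    }, logical(1)))
  }, logical(1))

  rows <- list()
  emit <- function(p, placement, mem) {
    rows[[length(rows) + 1]] <<- data.frame(
      pattern = p, placement = placement,
      members = paste(sort(mem), collapse = "|"), stringsAsFactors = FALSE)
  }
  validate <- function(mem) {
    length(mem) >= config$min_otus &&
      sum(elig$total_reads[elig$otu_id %in% mem]) > config$min_reads
  }
  for (i in which(maximal)) {
    mem <- sets[[i]]
    p <- pref[[paste(mem, collapse = "|")]]
    if (!validate(mem)) next
    if (!in_dis(p)) {
      emit(p, "prefix_anchored", mem)
    } else {
      ups <- elig$upstream[elig$otu_id %in% mem]
      ext <- oracle_lcs(ups)
      m <- regexpr("[^ACGT]*$", ext)  # keep only the ACGT tail of the extension
      ext <- sub("^.*?([ACGT]*)$", "\\1", ext)
      jmax <- min(nchar(ext), K - nchar(p))
      if (jmax >= 1) {
        for (j in 1:jmax) {
          p2 <- paste0(substring(ext, nchar(ext) - j + 1), p)
          if (!in_dis(p2)) {
            emit(p2, "upstream_extended", mem)
            break
          }
        }
      }
    }
  }

  # suffix candidates: every qualifying suffix of every core
  suf <- list()
  for (i in seq_len(nrow(elig))) {
    co <- elig$core[i]
    for (len in k:min(K, nchar(co))) {
      p <- substring(co, nchar(co) - len + 1)
      if (!acgt_only(p)) break
      mem <- sort(elig$otu_id[substring(elig$core, nchar(elig$core) - len + 1) == p])
      key <- paste(mem, collapse = "|")
      if (is.null(suf[[key]]) || nchar(suf[[key]]) < len) suf[[key]] <- p
    }
  }
  ssets <- lapply(names(suf), function(kk) strsplit(kk, "|", fixed = TRUE)[[1]])
  smax <- vapply(seq_along(ssets), function(i) {
    !any(vapply(seq_along(ssets), function(j) {
      j != i && length(ssets[[j]]) > length(ssets[[i]]) && all(ssets[[i]] %in% ssets[[j]])
    }, logical(1)))
  }, logical(1))
  for (i in which(smax)) {
    mem <- ssets[[i]]
    p <- suf[[paste(mem, collapse = "|")]]
    rows_mem <- elig[elig$otu_id %in% mem, , drop = FALSE]
    gkey <- unique(substr(rows_mem$core, 1, k))
    if (length(gkey) != 1 || !acgt_only(gkey)) next
    G <- elig[substr(elig$core, 1, k) == gkey, , drop = FALSE]
    if (nrow(rows_mem) >= nrow(G)) next
    if (oracle_lcp(rows_mem$core) != oracle_lcp(G$core)) next
    if (!validate(mem)) next
    if (in_dis(p)) next
    emit(p, "suffix_anchored", mem)
  }

  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(pattern = character(0), placement = character(0),
               members = character(0), stringsAsFactors = FALSE)
  }
  # nesting resolution, same rule as the implementation
  if (nrow(out) > 1) {
    drop <- rep(FALSE, nrow(out))
    nmem <- lengths(strsplit(out$members, "|", fixed = TRUE))
    for (i in seq_len(nrow(out) - 1)) {
      for (j in (i + 1):nrow(out)) {
        if (drop[i] || drop[j] || out$placement[i] != out$placement[j]) next
        pi <- out$pattern[i]; pj <- out$pattern[j]
        nested <- if (out$placement[i] == "suffix_anchored") {
          endsWith(pi, pj) || endsWith(pj, pi)
        } else {
          startsWith(pi, pj) || startsWith(pj, pi)
        }
        if (!nested) next
        keep_i <- if (nmem[i] != nmem[j]) nmem[i] > nmem[j] else nchar(pi) >= nchar(pj)
        if (keep_i) drop[j] <- TRUE else drop[i] <- TRUE
      }
    }
    out <- out[!drop, , drop = FALSE]
  }
  out[order(out$pattern, out$placement), , drop = FALSE]
}

# Canonical comparable form of a discovery result.
canon_sigs <- function(sig) {
  df <- data.frame(pattern = sig$pattern, placement = sig$placement,
                   members = vapply(lapply(sig$member_otus, sort),
                                    paste, character(1), collapse = "|"),
                   stringsAsFactors = FALSE)
  df <- df[order(df$pattern, df$placement), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Random small discovery instance with planted prefix families.
random_discovery_instance <- function(n_families = 3, n_singletons = 6) {
  mk <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  cores <- character(0)
  for (f in seq_len(n_families)) {
    stem_len <- sample(12:20, 1)
    stem <- mk(stem_len)
    n_mem <- sample(2:4, 1)
    cores <- c(cores, vapply(seq_len(n_mem), function(i) {
      paste0(stem, mk(sample(8:20, 1)))
    }, character(1)))
  }
  cores <- c(cores, vapply(seq_len(n_singletons), function(i) mk(sample(20:40, 1)),
                           character(1)))
  n <- length(cores)
  df <- data.frame(otu_id = sprintf("o%02d", seq_len(n)), core = cores,
                   total_reads = sample(500:6000, n, replace = TRUE),
                   upstream = paste0(mk(6), "CCATTGGA"),  # shared right context
                   stringsAsFactors = FALSE)
  refs <- NULL
  if (runif(1) < 0.5) {
    # embed a random core substring in a reference, sometimes exempt
    src <- sample(cores, 1)
    len <- min(nchar(src), sample(12:16, 1))
    refs <- make_refs_df(paste0(mk(5), substr(src, 1, len), mk(5)),
                         sample(c("described_clade", "ENFOR"), 1))
  }
  list(cores = df, refs = refs)
}
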