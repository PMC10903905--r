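# Biogeography analytics: per-area lineage read totals, within-area
# relative abundance, presence/absence, endemism, and exclusive habitat
# set intersections (UpSet semantics).

#' Reads per lineage per geographic area
#'
#' Sums the reads of every lineage-assigned OTU over the samples of each
#' area. Unassigned OTUs are excluded from the matrix but their reads are
#' reported as a per-area remainder, so reads are conserved:
#' `sum(matrix) + sum(remainder)` equals the dataset total.
#'
#' @param assignments Assignment data.frame covering all OTUs.
#' @param dataset A `foram_dataset` from [load_dataset()].
#' @return An `area_lineage_matrix`: list with `reads` (lineage x area
#'   integer matrix), `remainder` (named per-area vector of unassigned
#'   reads), `lineages`, `areas`.
#' @export
lineage_by_area <- function(assignments, dataset) {
  cm <- dataset$counts
  meta <- dataset$samples
  missing_meta <- setdiff(colnames(cm), meta$sample_id)
  if (length(missing_meta)) {
    stop("sample(s) without metadata: ", paste(missing_meta, collapse = ", "))
  }
  area <- meta$area[match(colnames(cm), meta$sample_id)]
  areas <- unique(meta$area)

  lab <- assignments$label[match(rownames(cm), assignments$otu_id)]
  if (anyNA(lab)) {
    stop("assignments do not cover all OTUs: ",
         paste(rownames(cm)[is.na(lab)], collapse = ", "))
  }
  by_area <- t(rowsum(t(cm), group = area))      # otu x area
  by_area <- by_area[, areas, drop = FALSE]
  assigned <- lab != "unassigned"
  lineages <- sort(unique(lab[assigned]))
  reads <- if (length(lineages)) {
    m <- rowsum(by_area[assigned, , drop = FALSE], group = lab[assigned])
    m[lineages, , drop = FALSE]
  } else {
    matrix(0, nrow = 0, ncol = length(areas), dimnames = list(NULL, areas))
  }
  remainder <- if (any(!assigned)) {
    colSums(by_area[!assigned, , drop = FALSE])
  } else {
    setNames(numeric(ncol(by_area)), colnames(by_area))
  }
  structure(list(reads = reads, remainder = remainder,
                 lineages = lineages, areas = areas),
            class = "area_lineage_matrix")
}

.alm_matrix <- function(x) {
  if (inherits(x, "area_lineage_matrix")) x$reads else as.matrix(x)
}

#' Within-area relative abundance
#'
#' Divides each area column by its column total; a nonzero column sums to
#' 1. All-zero columns stay zero, with a warning.
#'
#' @param x An `area_lineage_matrix` or a plain lineage x area matrix.
#' @return Matrix of proportions with the same shape.
#' @export
relative_abundance <- function(x) {
  m <- .alm_matrix(x)
  tot <- colSums(m)
  zero <- tot == 0
  if (any(zero)) {
    warning("area column(s) with zero reads left as all-zero: ",
            paste(colnames(m)[zero], collapse = ", "))
  }
  sweep(m, 2, ifelse(zero, 1, tot), "/")
}

#' Presence/absence of lineages per area
#'
#' @param x An `area_lineage_matrix` or a plain matrix.
#' @param min_reads Minimum reads to call a lineage present (inclusive;
#'   default 1).
#' @return Logical lineage x area matrix.
#' @export
presence_absence <- function(x, min_reads = 1L) {
  .alm_matrix(x) >= min_reads
}

#' Lineages endemic to a set of focal areas
#'
#' A lineage is endemic when it is present in at least one focal area and
#' absent from every non-focal area.
#'
#' @param presence Logical matrix from [presence_absence()].
#' @param focal_areas Character vector of area labels.
#' @return Character vector of endemic lineage names.
#' @export
endemic_lineages <- function(presence, focal_areas) {
  unknown <- setdiff(focal_areas, colnames(presence))
  if (length(unknown)) stop("unknown area(s): ", paste(unknown, collapse = ", "))
  if (!length(focal_areas)) return(character(0))
  foc <- presence[, colnames(presence) %in% focal_areas, drop = FALSE]
  non <- presence[, !colnames(presence) %in% focal_areas, drop = FALSE]
  rownames(presence)[rowSums(foc) >= 1 & rowSums(non) == 0]
}

#' Habitat-level OTU sets and exclusive (UpSet) intersections per lineage
#'
#' For each lineage, collects the set of member OTUs present in each
#' habitat (CCFZ, other deep sea, shallow water) and counts the exclusive
#' intersections over the habitat power set: each OTU is counted in
#' exactly one cell, the combination of all habitats it occurs in, so the
#' cells partition the lineage's (deduplicated) OTU set.
#'
#' @param assignments Assignment data.frame covering all OTUs.
#' @param dataset A `foram_dataset`.
#' @param lineages Lineages to tabulate; default all assigned labels.
#' @param min_reads Minimum reads in a habitat to count an OTU as present.
#' @return list with `sets` (per lineage, per habitat OTU id vectors) and
#'   `upset` (data.frame `lineage`, `combo`, `n_otus` over all non-empty
#'   habitat combinations, zeros included).
#' @export
shared_otu_sets <- function(assignments, dataset, lineages = NULL,
                            min_reads = 1L) {
  cm <- dataset$counts
  meta <- dataset$samples
  habitat <- meta$habitat[match(colnames(cm), meta$sample_id)]
  by_hab <- t(rowsum(t(cm), group = habitat))     # otu x habitat
  habs <- intersect(FORAM_HABITATS, colnames(by_hab))
  present <- by_hab[, habs, drop = FALSE] >= min_reads

  lab <- assignments$label[match(rownames(cm), assignments$otu_id)]
  if (is.null(lineages)) {
    lineages <- sort(unique(lab[!is.na(lab) & lab != "unassigned"]))
  }
  combos <- lapply(seq_len(2^length(habs) - 1), function(mask) {
    habs[bitwAnd(mask, 2^(seq_along(habs) - 1)) > 0]
  })
  combo_names <- vapply(combos, paste, character(1), collapse = "+")

  sets <- list()
  rows <- list()
  for (l in lineages) {
    ids <- unique(rownames(cm)[!is.na(lab) & lab == l])
    sets[[l]] <- lapply(setNames(habs, habs),
                        function(h) ids[present[ids, h]])
    key <- vapply(ids, function(id) {
      paste(habs[present[id, ]], collapse = "+")
    }, character(1))
    counts <- table(factor(key[nzchar(key)], levels = combo_names))
    rows[[l]] <- data.frame(lineage = l, combo = combo_names,
                            n_otus = as.integer(counts),
                            stringsAsFactors = FALSE)
  }
  upset <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(lineage = character(0), combo = character(0),
               n_otus = integer(0), stringsAsFactors = FALSE)
  }
  rownames(upset) <- NULL
  list(sets = sets, upset = upset, habitats = habs)
}
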