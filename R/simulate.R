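# Deterministic amplicon community simulator. Generates datasets with the
# structure the signature method assumes — a shared conserved segment
# upstream of the "GACAG" anchor, 37F-like variable cores (68-196 nt)
# flanked by terminal motifs, planted lineage signature windows, noise OTUs
# with unique prefixes or sub-threshold reads, contaminants lacking the
# anchor, degraded conserved regions, and a reference database including
# decoys that exercise the reference-exclusion rule — plus a ground-truth
# table, so every pipeline stage is testable without downloads.

.default_areas <- function() {
  data.frame(area = c("OMS", "UK-1", "BGR", "IFREMER", "North Atlantic", "Svalbard"),
             habitat = c("CCFZ", "CCFZ", "CCFZ", "CCFZ", "deep_sea", "shallow"),
             n_samples = c(3L, 3L, 2L, 2L, 3L, 3L),
             stringsAsFactors = FALSE)
}

#' Simulation parameters
#'
#' Defaults describe a community at desk scale: 10 planted lineages of 3-6
#' OTUs, each sharing a signature window (the conserved "GACAGG" hexamer
#' plus a drawn pattern, 12-53 nt total) at the start of a 68-196 nt 37F
#' core; 50 noise OTUs with unique prefixes, one fifth of which are
#' sub-threshold rare; contaminants without the anchor motif; a few
#' records with degraded conserved regions; and lognormal read abundances
#' spread multinomially over samples of randomly occupied areas.
#'
#' @param n_lineages Number of planted (recoverable) lineages.
#' @param otus_per_lineage Integer range (min, max) of member OTUs.
#' @param core_length Integer range of 37F core lengths in nt.
#' @param signature_length Integer range of planted signature lengths.
#' @param n_noise_otus Number of noise OTUs (unique 37F prefixes).
#' @param noise_rare_fraction Fraction of noise OTUs given sub-threshold
#'   (<= 100) read counts.
#' @param n_contaminants Records lacking the anchor motif.
#' @param n_degraded Records with a mutated conserved upstream segment.
#' @param reads_meanlog,reads_sdlog Lognormal read-abundance parameters.
#' @param min_member_reads Floor on planted-member and noise reads so they
#'   pass the `> 100` screen.
#' @param min_lineage_reads Planted lineages are topped up to exceed this
#'   total, matching the `> 5000` validation rule.
#' @param areas data.frame `area`, `habitat`, `n_samples`.
#' @param decoy_categories Reference categories in which decoy sequences
#'   containing a planted pattern are created. A `described_clade` decoy
#'   adds an extra "trap" lineage whose candidate must be rejected; decoys
#'   in exempt categories carry patterns of real lineages.
#' @param n_reference_per_category Plain reference sequences per category.
#' @param upstream_length Length of the shared conserved upstream segment.
#' @param terminal_motifs Terminal motifs sampled per OTU (the common
#'   variant is drawn 4:1 over the T>C variant).
#' @param seed Mandatory RNG seed.
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(n_lineages = 10L,
                              otus_per_lineage = c(3L, 6L),
                              core_length = c(68L, 196L),
                              signature_length = c(12L, 53L),
                              n_noise_otus = 50L,
                              noise_rare_fraction = 0.2,
                              n_contaminants = 5L,
                              n_degraded = 3L,
                              reads_meanlog = log(3000),
                              reads_sdlog = 1.2,
                              min_member_reads = 150L,
                              min_lineage_reads = 5000L,
                              areas = .default_areas(),
                              decoy_categories = c("described_clade", "ENFOR",
                                                   "monothalamids_X"),
                              n_reference_per_category = 2L,
                              upstream_length = 30L,
                              terminal_motifs = c("TAGTCCTTT", "TAGTCCCTT"),
                              seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (max(signature_length) > min(core_length)) {
    stop("infeasible parameters: signature longer than the shortest core")
  }
  if (min(signature_length) < 7L) {
    stop("signature_length must allow at least the anchor hexamer plus one base")
  }
  bad <- setdiff(decoy_categories, REF_CATEGORIES)
  if (length(bad)) stop("unknown decoy category: ", paste(bad, collapse = ", "))
  bad_hab <- setdiff(areas$habitat, FORAM_HABITATS)
  if (length(bad_hab)) stop("unknown habitat in areas: ", paste(bad_hab, collapse = ", "))
  structure(list(n_lineages = as.integer(n_lineages),
                 otus_per_lineage = as.integer(otus_per_lineage),
                 core_length = as.integer(core_length),
                 signature_length = as.integer(signature_length),
                 n_noise_otus = as.integer(n_noise_otus),
                 noise_rare_fraction = noise_rare_fraction,
                 n_contaminants = as.integer(n_contaminants),
                 n_degraded = as.integer(n_degraded),
                 reads_meanlog = reads_meanlog,
                 reads_sdlog = reads_sdlog,
                 min_member_reads = as.integer(min_member_reads),
                 min_lineage_reads = as.integer(min_lineage_reads),
                 areas = areas,
                 decoy_categories = decoy_categories,
                 n_reference_per_category = as.integer(n_reference_per_category),
                 upstream_length = as.integer(upstream_length),
                 terminal_motifs = terminal_motifs,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

# sample() treats a length-1 numeric as 1:x; draw ranges safely
.sample_range <- function(lo, hi, n = 1L) {
  if (lo == hi) rep(lo, n) else sample(lo:hi, n, replace = TRUE)
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random DNA containing none of the banned motifs.
.motif_free <- function(n, banned) {
  repeat {
    x <- .rand_dna(n)
    if (!any(vapply(banned, function(b) grepl(b, x, fixed = TRUE), logical(1)))) {
      return(x)
    }
  }
}

.BANNED <- c("GACAG", "TAGTCCTTT", "TAGTCCCTT", "GGTGGT")

# A 37F-like core: starts with GACAG, contains no second anchor, no
# terminal motif, and none of the `avoid` windows beyond an allowed prefix.
.make_core <- function(len, prefix, avoid) {
  repeat {
    core <- paste0(prefix, .rand_dna(len - nchar(prefix)))
    tail_part <- substring(core, 2L)  # allow the anchor at position 1 only
    if (grepl("GACAG", tail_part, fixed = TRUE)) next
    if (any(vapply(c("TAGTCCTTT", "TAGTCCCTT", "GGTGGT"),
                   function(b) grepl(b, core, fixed = TRUE), logical(1)))) next
    hit <- vapply(avoid, function(w) {
      grepl(w, core, fixed = TRUE) && !startsWith(core, w)
    }, logical(1))
    if (length(hit) && any(hit)) next
    return(core)
  }
}

#' Build a decoy reference record containing a given pattern
#'
#' The decoy embeds the pattern with its natural upstream context so that
#' leftward extension of a conflicting candidate cannot escape the match.
#' Used to exercise the reference-exclusion rule and its
#' ENFOR/Monothalamids-X exemption.
#'
#' @param pattern The planted pattern.
#' @param category Reference category of the decoy.
#' @param upstream Conserved upstream context placed before the pattern.
#' @param ref_id,taxon Identifier and taxon label.
#' @param flank Length of random flanking tail after the pattern.
#' @return One-row reference data.frame.
#' @export
plant_decoy_reference <- function(pattern, category, upstream = "",
                                  ref_id = "decoy", taxon = "decoy taxon",
                                  flank = 60L) {
  category <- .normalize_category(category)
  seqs <- paste0(upstream, pattern, .motif_free(flank, .BANNED), "TAGTCCTTT")
  data.frame(ref_id = ref_id, sequence = seqs, taxon = taxon,
             category = category, stringsAsFactors = FALSE)
}

#' Simulate an amplicon dataset with planted lineage signatures
#'
#' Output is fully determined by the parameters and seed. The generator
#' verifies feasibility before returning: every planted signature window
#' occurs in each of its members' cores and in no non-member core.
#'
#' @param params A [simulation_params()].
#' @return A `foram_simulation` list: `otus` (data.frame `otu_id`,
#'   `sequence`, `total_reads`), `counts` (OTU x sample matrix), `samples`
#'   (metadata), `references`, `truth` (per-OTU ground truth with `kind`,
#'   `lineage`, `pattern`, `recoverable`, `areas`), `upstream` (the shared
#'   conserved segment) and `params`.
#' @export
simulate_dataset <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(params$seed)

  upstream <- .motif_free(params$upstream_length, .BANNED)
  has_trap <- "described_clade" %in% params$decoy_categories
  n_total_lineages <- params$n_lineages + as.integer(has_trap)

  # signature windows with pairwise-distinct first-12 prefixes
  windows <- character(0)
  for (i in seq_len(n_total_lineages)) {
    repeat {
      len <- .sample_range(params$signature_length[1], params$signature_length[2])
      w <- paste0("GACAGG", .rand_dna(len - 6L))
      if (grepl("GACAG", substring(w, 2L), fixed = TRUE)) next
      if (any(vapply(c("TAGTCCTTT", "TAGTCCCTT", "GGTGGT"),
                     function(b) grepl(b, w, fixed = TRUE), logical(1)))) next
      if (substr(w, 1L, 12L) %in% substr(windows, 1L, 12L)) next
      windows <- c(windows, w)
      break
    }
  }

  otu_seq <- character(0); otu_kind <- character(0)
  otu_lineage <- character(0); otu_pattern <- character(0)
  otu_recoverable <- logical(0); reads <- integer(0)
  cores <- character(0)
  used_prefixes <- substr(windows, 1L, 12L)

  draw_reads <- function(n, floor_at) {
    pmax(as.integer(round(stats::rlnorm(n, params$reads_meanlog,
                                        params$reads_sdlog))), floor_at)
  }
  pick_terminal <- function(n) {
    sample(params$terminal_motifs, n, replace = TRUE,
           prob = c(0.8, 0.2)[seq_along(params$terminal_motifs)])
  }

  # planted lineage members (last lineage is the described-clade trap)
  trap_core <- NULL
  for (i in seq_len(n_total_lineages)) {
    k <- .sample_range(params$otus_per_lineage[1], params$otus_per_lineage[2])
    lens <- .sample_range(params$core_length[1], params$core_length[2], k)
    member_cores <- vapply(lens, .make_core, character(1),
                           prefix = windows[i], avoid = setdiff(windows, windows[i]))
    r <- draw_reads(k, params$min_member_reads)
    deficit <- params$min_lineage_reads + 1L - sum(r)
    if (deficit > 0) r[which.max(r)] <- r[which.max(r)] + deficit
    is_trap <- has_trap && i == n_total_lineages
    if (is_trap) trap_core <- member_cores[1]
    cores <- c(cores, member_cores)
    otu_seq <- c(otu_seq, paste0(upstream, member_cores, pick_terminal(k)))
    otu_kind <- c(otu_kind, rep("member", k))
    otu_lineage <- c(otu_lineage,
                     rep(if (is_trap) "lineage_trap" else sprintf("lineage_%02d", i), k))
    otu_pattern <- c(otu_pattern, rep(windows[i], k))
    otu_recoverable <- c(otu_recoverable, rep(!is_trap, k))
    reads <- c(reads, r)
  }

  # noise OTUs: unique 12-nt prefixes; a fraction are sub-threshold rare
  n_rare <- as.integer(round(params$n_noise_otus * params$noise_rare_fraction))
  n_main <- params$n_noise_otus - n_rare
  for (j in seq_len(params$n_noise_otus)) {
    repeat {
      len <- .sample_range(params$core_length[1], params$core_length[2])
      core <- .make_core(len, "GACAG", avoid = windows)
      if (!substr(core, 1L, 12L) %in% used_prefixes) break
    }
    used_prefixes <- c(used_prefixes, substr(core, 1L, 12L))
    rare <- j > n_main
    cores <- c(cores, core)
    otu_seq <- c(otu_seq, paste0(upstream, core, pick_terminal(1)))
    otu_kind <- c(otu_kind, if (rare) "noise_rare" else "noise")
    otu_lineage <- c(otu_lineage, NA_character_)
    otu_pattern <- c(otu_pattern, NA_character_)
    otu_recoverable <- c(otu_recoverable, NA)
    reads <- c(reads, if (rare) sample(5:100, 1) else draw_reads(1, params$min_member_reads))
  }

  # degraded conserved region: unique-prefix core, mutated upstream
  if (params$n_degraded > 0) {
    mutate <- function(s, n_mut) {
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      pos <- sample(seq_along(ch), n_mut)
      for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      paste(ch, collapse = "")
    }
    for (j in seq_len(params$n_degraded)) {
      repeat {
        core <- .make_core(.sample_range(params$core_length[1], params$core_length[2]),
                           "GACAG", avoid = windows)
        if (!substr(core, 1L, 12L) %in% used_prefixes) break
      }
      used_prefixes <- c(used_prefixes, substr(core, 1L, 12L))
      bad_up <- mutate(upstream, 4L)
      cores <- c(cores, core)
      otu_seq <- c(otu_seq, paste0(bad_up, core, pick_terminal(1)))
      otu_kind <- c(otu_kind, "degraded")
      otu_lineage <- c(otu_lineage, NA_character_)
      otu_pattern <- c(otu_pattern, NA_character_)
      otu_recoverable <- c(otu_recoverable, NA)
      reads <- c(reads, draw_reads(1, params$min_member_reads))
    }
  }

  # contaminants: no anchor motif at all, terminal motif present
  for (j in seq_len(params$n_contaminants)) {
    body <- .motif_free(sample(80:150, 1), .BANNED)
    cores <- c(cores, NA_character_)
    otu_seq <- c(otu_seq, paste0(body, pick_terminal(1)))
    otu_kind <- c(otu_kind, "contaminant")
    otu_lineage <- c(otu_lineage, NA_character_)
    otu_pattern <- c(otu_pattern, NA_character_)
    otu_recoverable <- c(otu_recoverable, NA)
    reads <- c(reads, draw_reads(1, params$min_member_reads))
  }

  otu_id <- sprintf("OTU_%04d", seq_along(otu_seq))

  # feasibility: each window occurs in all member cores and nowhere else
  for (i in seq_len(n_total_lineages)) {
    lin <- if (has_trap && i == n_total_lineages) "lineage_trap" else sprintf("lineage_%02d", i)
    inside <- !is.na(cores) & grepl(windows[i], cores, fixed = TRUE)
    member <- !is.na(otu_lineage) & otu_lineage == lin
    if (!identical(inside, member)) {
      stop("internal error: planted signature not exclusive to its lineage")
    }
  }

  # samples and counts: multinomial spread over occupied areas
  areas <- params$areas
  sample_id <- unlist(lapply(seq_len(nrow(areas)), function(a) {
    sprintf("%s_s%d", gsub("[^A-Za-z0-9]", "", areas$area[a]),
            seq_len(areas$n_samples[a]))
  }))
  sample_area <- rep(areas$area, areas$n_samples)
  sample_hab <- rep(areas$habitat, areas$n_samples)
  meta <- data.frame(sample_id = sample_id, area = sample_area,
                     habitat = sample_hab, stringsAsFactors = FALSE)

  cm <- matrix(0L, nrow = length(otu_id), ncol = nrow(meta),
               dimnames = list(otu_id, meta$sample_id))
  occupied <- character(length(otu_id))
  for (i in seq_along(otu_id)) {
    occ <- areas$area[stats::runif(nrow(areas)) < 0.6]
    if (!length(occ)) occ <- sample(areas$area, 1)
    w <- as.numeric(meta$area %in% occ)
    cm[i, ] <- as.integer(stats::rmultinom(1, reads[i], prob = w / sum(w)))
    occupied[i] <- paste(occ, collapse = ";")
  }

  # references: plain records per category plus decoys
  refs <- list()
  taxon_of <- list(described_clade = function(i) paste("Clade", LETTERS[i]),
                   ENFOR = function(i) paste0("ENFOR", i),
                   monothalamids_X = function(i) paste("Monothalamids X", i))
  for (cat in names(taxon_of)) {
    for (i in seq_len(params$n_reference_per_category)) {
      repeat {
        core <- .make_core(100L, "GACAG", avoid = windows)
        if (!substr(core, 1L, 12L) %in% used_prefixes) break
      }
      used_prefixes <- c(used_prefixes, substr(core, 1L, 12L))
      refs[[length(refs) + 1]] <- data.frame(
        ref_id = sprintf("REF_%s_%d", cat, i),
        sequence = paste0(upstream, core, "TAGTCCTTT"),
        taxon = taxon_of[[cat]](i), category = cat,
        stringsAsFactors = FALSE)
    }
  }
  if (has_trap) {
    # the trap decoy carries a full member core: the trap "lineage" is a
    # group already present in the database, so no prefix of its members
    # (nor any upstream extension) can escape the reference conflict
    refs[[length(refs) + 1]] <- plant_decoy_reference(
      trap_core, "described_clade", upstream = upstream,
      ref_id = "REF_decoy_described", taxon = "Clade Z")
  }
  if ("ENFOR" %in% params$decoy_categories && params$n_lineages >= 1) {
    refs[[length(refs) + 1]] <- plant_decoy_reference(
      windows[1], "ENFOR", upstream = upstream,
      ref_id = "REF_decoy_enfor", taxon = "ENFOR99")
  }
  if ("monothalamids_X" %in% params$decoy_categories && params$n_lineages >= 2) {
    refs[[length(refs) + 1]] <- plant_decoy_reference(
      windows[2], "monothalamids_X", upstream = upstream,
      ref_id = "REF_decoy_monox", taxon = "Monothalamids X 99")
  }
  references <- do.call(rbind, refs)

  truth <- data.frame(otu_id = otu_id, kind = otu_kind,
                      lineage = otu_lineage, pattern = otu_pattern,
                      recoverable = otu_recoverable, areas = occupied,
                      stringsAsFactors = FALSE)
  otus <- data.frame(otu_id = otu_id, sequence = otu_seq,
                     total_reads = as.integer(rowSums(cm)),
                     stringsAsFactors = FALSE)
  structure(list(otus = otus, counts = cm, samples = meta,
                 references = references, truth = truth,
                 upstream = upstream, params = params),
            class = "foram_simulation")
}

#' Write a simulated dataset to disk
#'
#' Emits `otus.fasta`, `counts.tsv`, `samples.tsv`, `references.fasta`,
#' `references.tsv` and `truth.tsv` under `dir`; output bytes are fully
#' determined by the simulation object.
#'
#' @param sim A `foram_simulation` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "otus.fasta"),
             counts = file.path(dir, "counts.tsv"),
             meta = file.path(dir, "samples.tsv"),
             refs_fasta = file.path(dir, "references.fasta"),
             refs_annot = file.path(dir, "references.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_fasta(setNames(sim$otus$sequence, sim$otus$otu_id), paths["fasta"])
  counts_df <- data.frame(otu_id = rownames(sim$counts), sim$counts,
                          check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(counts_df, paths["counts"])
  .write_tsv(sim$samples, paths["meta"])
  write_fasta(setNames(sim$references$sequence, sim$references$ref_id),
              paths["refs_fasta"])
  .write_tsv(sim$references[, c("ref_id", "taxon", "category")], paths["refs_annot"])
  .write_tsv(sim$truth, paths["truth"])
  invisible(paths)
}
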