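test_that("extract_core returns the anchored hexamer plus variable span", {
  s <- "AAGACAGGTTTTCCCCTAGTCCTTT"
  ann <- annotate_regions(s)
  expect_equal(extract_core(s, ann), "GACAGGTTTTCCCC")

  # empty variable span errors
  s0 <- paste0("AA", "GACAG", "TAGTCCTTT")
  ann0 <- annotate_regions(s0)
  expect_equal(ann0$status, "ok")
  expect_error(extract_core(s0, ann0), "empty")
})

test_that("prefix signatures are discovered with validation thresholds", {
  set.seed(21)
  shared <- "GACAGGTTTTCCCC"
  cores <- make_cores_df(
    sprintf("o%d", 1:5),
    c(paste0(shared, rand_dna_clean(40)),
      paste0(shared, rand_dna_clean(44)),
      paste0(shared, rand_dna_clean(48)),
      paste0("GACAGGAAAA", rand_dna_clean(40)),
      paste0("GACAGGCCCC", rand_dna_clean(40))),
    c(3000L, 2000L, 1500L, 1000L, 1000L))
  sig <- discover_signatures(cores)
  expect_equal(nrow(sig), 1L)
  expect_equal(sig$placement, "prefix_anchored")
  expect_true(startsWith(sig$pattern, shared))
  expect_equal(sig$member_otus[[1]], c("o1", "o2", "o3"))
  expect_equal(sig$total_reads, 6500L)

  # strict read threshold: total of exactly 5000 is rejected
  cores2 <- cores
  cores2$total_reads <- c(3000L, 1500L, 500L, 10L, 10L)  # group total 5000
  expect_equal(nrow(discover_signatures(cores2)), 0L)
  cores2$total_reads[3] <- 501L                          # 5001 passes
  expect_equal(nrow(discover_signatures(cores2)), 1L)

  # minimum group size
  expect_equal(nrow(discover_signatures(cores,
                                        config = discovery_config(min_otus = 4L))), 0L)
})

test_that("reference exclusion rejects described clades but exempts ENFOR/Monothalamids X", {
  set.seed(22)
  shared <- "GACAGGTTTTCCCCAAGG"
  cores <- make_cores_df(c("o1", "o2", "o3"),
                         paste0(shared, c(rand_dna_clean(30), rand_dna_clean(34),
                                          rand_dna_clean(38))),
                         c(4000L, 3000L, 2000L))
  decoy <- function(cat) make_refs_df(paste0(TEST_UPSTREAM, shared, rand_dna_clean(30)),
                                      cat)
  # described clade: candidate rejected (upstream context blocks extension)
  expect_equal(nrow(discover_signatures(cores, decoy("described_clade"))), 0L)
  # exempt categories: candidate survives
  expect_equal(nrow(discover_signatures(cores, decoy("ENFOR"))), 1L)
  expect_equal(nrow(discover_signatures(cores, decoy("monothalamids_X"))), 1L)
  # decoy absent: survives
  expect_equal(nrow(discover_signatures(cores, NULL)), 1L)
})

test_that("upstream extension rescues a conflicting candidate when context differs", {
  set.seed(23)
  shared <- "GACAGGTTTTCCCCAAGG"
  cores <- make_cores_df(c("o1", "o2"),
                         paste0(shared, c(rand_dna_clean(30), rand_dna_clean(34))),
                         c(4000L, 3000L))
  # reference contains the pattern but with a different upstream context
  ref <- make_refs_df(paste0("AAAAAAAA", shared, rand_dna_clean(30)),
                      "described_clade")
  sig <- discover_signatures(cores, ref)
  expect_equal(nrow(sig), 1L)
  expect_equal(sig$placement, "upstream_extended")
  expect_true(endsWith(sig$pattern, shared))
  expect_gt(sig$length, nchar(shared))
  # the extension is drawn from the members' shared conserved upstream
  ext <- substr(sig$pattern, 1, sig$length - nchar(shared))
  expect_true(endsWith(TEST_UPSTREAM, ext))
})

test_that("suffix signatures split prefix-indistinguishable subsets", {
  set.seed(24)
  stem <- paste0("GACAGG", rand_dna_clean(20))
  tailA <- rand_dna_clean(14)
  tailB <- rand_dna_clean(14)
  # member-private middles start with distinct bases, so no subset shares
  # a longer prefix than the whole group (prefix-indistinguishable)
  mid <- function(b) paste0(b, rand_dna_clean(9))
  cores <- make_cores_df(
    sprintf("o%d", 1:4),
    c(paste0(stem, mid("A"), tailA), paste0(stem, mid("C"), tailA),
      paste0(stem, mid("G"), tailB), paste0(stem, mid("T"), tailB)),
    c(4000L, 3000L, 3500L, 2500L))
  sig <- discover_signatures(cores)
  expect_setequal(sig$placement, c("prefix_anchored", "suffix_anchored"))
  suf <- sig[sig$placement == "suffix_anchored", ]
  expect_equal(nrow(suf), 2L)
  expect_setequal(vapply(suf$member_otus, paste, character(1), collapse = ","),
                  c("o1,o2", "o3,o4"))
  expect_true(all(vapply(seq_len(nrow(suf)), function(i) {
    all(endsWith(cores$core[cores$otu_id %in% suf$member_otus[[i]]],
                 suf$pattern[i]))
  }, logical(1))))
})

test_that("lineage naming groups SNP neighbours and is order-invariant", {
  sig <- data.frame(name = NA_character_,
                    pattern = c("GACAGGTTTTCCCA", "GACAGGTTTTCCCC",
                                "GACAGGAAAATTTTCC"),
                    placement = "prefix_anchored",
                    length = c(14L, 14L, 16L),
                    n_otus = c(2L, 2L, 2L),
                    total_reads = c(9000L, 6000L, 5500L),
                    stringsAsFactors = FALSE)
  sig$member_otus <- list(c("a", "b"), c("c", "d"), c("e", "f"))
  named <- name_lineages(sig)
  expect_equal(named$name[named$pattern == "GACAGGTTTTCCCA"], "L1A")
  expect_equal(named$name[named$pattern == "GACAGGTTTTCCCC"], "L1B")
  expect_equal(named$name[named$pattern == "GACAGGAAAATTTTCC"], "L2")

  # permutation invariance
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    renamed <- name_lineages(sig[perm, ])
    expect_equal(renamed$name[match(sig$pattern, renamed$pattern)],
                 named$name[match(sig$pattern, named$pattern)])
  }
})

test_that("positional entropy matches closed forms", {
  expect_equal(positional_entropy(c("AAAA"))[1], 0)
  expect_equal(unname(positional_entropy(c("A", "C", "G", "T"))), 2)
  expect_equal(unname(positional_entropy(c("AA", "AC", "CG", "CT"))),
               c(1, 2))
  # gaps are excluded from counts
  expect_equal(unname(positional_entropy(c("A-", "A-", "AC", "AC"))), c(0, 0))
  expect_warning(e <- positional_entropy(c("-", "-")), "no usable")
  expect_equal(unname(e), 0)
  expect_error(positional_entropy(c("AA", "A")), "equal length")
})

test_that("emitted signatures satisfy their invariants on simulated data", {
  cfg <- discovery_config()
  sim <- simulate_dataset(simulation_params(seed = 77))
  sc <- screen_dataset(sim, references = sim$references)
  cores <- extract_cores(sc$kept)
  sig <- discover_signatures(cores, sim$references, cfg)
  expect_gt(nrow(sig), 0)

  disallowed <- sim$references$sequence[
    !sim$references$category %in% cfg$allowed_reference_categories]
  for (i in seq_len(nrow(sig))) {
    expect_gte(sig$length[i], cfg$min_sig_len)
    expect_lte(sig$length[i], cfg$max_sig_len)
    expect_gte(sig$n_otus[i], cfg$min_otus)
    expect_gt(sig$total_reads[i], cfg$min_reads)
    expect_match(sig$pattern[i], "^[ACGT]+$")
    if (sig$placement[i] == "prefix_anchored") {
      expect_true(startsWith(sig$pattern[i], "GACAG"))
    }
    # exclusion soundness by naive scan
    expect_false(any(vapply(disallowed, oracle_match_one, logical(1),
                            pattern = sig$pattern[i])))
    # closure: re-matching at the required placement returns the members
    mem <- switch(sig$placement[i],
      prefix_anchored = cores$otu_id[startsWith(cores$core, sig$pattern[i])],
      suffix_anchored = cores$otu_id[endsWith(cores$core, sig$pattern[i])],
      upstream_extended = cores$otu_id[
        grepl(sig$pattern[i], paste0(cores$upstream, cores$core), fixed = TRUE)])
    expect_setequal(mem, sig$member_otus[[i]])
  }
})

test_that("discovery recovers planted lineages and is threshold-monotone", {
  sim <- simulate_dataset(simulation_params(seed = 13))
  sc <- screen_dataset(sim, references = sim$references)
  cores <- extract_cores(sc$kept)
  sig <- discover_signatures(cores, sim$references)
  expect_equal(member_sets(sig), planted_sets(sim$truth))

  n_base <- nrow(sig)
  for (mr in c(10000L, 30000L)) {
    n <- nrow(discover_signatures(cores, sim$references,
                                  discovery_config(min_reads = mr)))
    expect_lte(n, n_base)
    n_base <- n
  }
  n_base <- nrow(sig)
  for (mo in c(4L, 6L)) {
    n <- nrow(discover_signatures(cores, sim$references,
                                  discovery_config(min_otus = mo)))
    expect_lte(n, n_base)
    n_base <- n
  }
})

test_that("discovery equals the exhaustive substring oracle on random instances", {
  set.seed(55)
  cfg <- discovery_config(min_reads = 2000L)
  for (i in 1:40) {
    inst <- random_discovery_instance()
    got <- canon_sigs(discover_signatures(inst$cores, inst$refs, cfg))
    want <- oracle_discover(inst$cores, inst$refs, cfg)
    want <- data.frame(pattern = want$pattern, placement = want$placement,
                       members = want$members, stringsAsFactors = FALSE)
    rownames(want) <- NULL
    expect_equal(got, want, info = paste("instance", i))
  }
})
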