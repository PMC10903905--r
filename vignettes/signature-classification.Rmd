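---
title: "Signature-based classification of foraminiferal 37F metabarcodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature-based classification of foraminiferal 37F metabarcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foramsig)
```

## The problem

Environmental DNA surveys of deep-sea sediments recover enormous numbers of
foraminiferal metabarcodes — short amplicons of the 37F hypervariable
region of the nuclear 18S rRNA gene (68–196 bp), amplified with the
foraminifera-specific primers s14F1/s15. Because reference databases cover
only a small fraction of deep-sea diversity, roughly half of these OTUs
cannot be assigned by similarity-based tools and are usually discarded
from ecological analyses as "unknown".

`foramsig` implements a taxonomy-free alternative: among the unassigned
OTUs, it finds ultra-short diagnostic nucleotide patterns — DNA signatures
of 12–53 nt — that are shared exactly by groups of OTUs and absent from
the reference database, declares each such group a novel lineage (L1, L2A,
…), and then classifies any dataset by exact, zero-mismatch substring
matching of those signatures. Downstream summaries (per-area relative
abundance, endemism, exclusive habitat intersections) make the unassigned
fraction usable in biogeography.

## Amplicon anatomy and screening

Every retained amplicon is expected to look like

```
[conserved 33–37 region] GACAG [37F variable core] TAGTCCTTT|TAGTCCCTT
```

* The five conserved nucleotides `GACAG` close helix 37(I) and sit
  immediately upstream of the variable region; in most foraminifera the
  next base is also `G`, giving the conserved hexamer `GACAGG`.
* The 37 conserved region ends in `TAGTCCTTT`; some species carry a T>C
  substitution, so `TAGTCCCTT` is accepted equivalently.
* Amplicons obtained with the longer s14F1–s17 design span two variable
  regions (37F and 41F); for those, `two_region` mode requires `GACAG`
  together with `GGTGGT` in the 38 conserved region instead of the
  37-terminal pair.

`screen_dataset()` applies, in order: motif annotation, the strict size
filter (> 70 bp), the strict abundance filter (> 100 reads), and — when a
reference database is supplied — conserved-region quality control, which
compares the segment upstream of the anchor against a per-position
majority consensus of the references and discards records with more than
`max_conserved_edits` edits (Levenshtein distance plus ambiguity
characters). The published rule tolerates "2–3" edits; the default is the
conservative reading, 2, and the value is exposed in `filter_config()`.

Two boundary decisions deserve a note:

* **Anchor multiplicity.** If `GACAG` occurs more than once before the
  terminal motif, the *last* occurrence is used — the biologically
  meaningful anchor abuts 37F — and the record is flagged
  `ambiguous_anchor` but retained. Occurrences may overlap (e.g.
  `GACAGACAGG` contains the motif twice), and the scan accounts for that.
* **Length filter target.** Whether the 70-bp rule applies to the whole
  amplicon or to the 37F core alone is not specified by the screening
  rules as published; the default applies it to the full retained
  sequence, with `length_on = "core"` available.

Coordinates in all annotations are 0-based and half-open, which keeps span
arithmetic (`var_span = [anchor_end, terminal_start)`) free of off-by-one
ambiguity.

## Signature discovery

Discovery operates on the *core* of each unassigned OTU: the anchor plus
the variable span, up to but excluding the terminal motif
(`extract_core()`). Signatures come in three placement classes, found in
three tiers by `discover_signatures()`:

1. **Prefix-anchored.** Cores are grouped by their first `min_sig_len`
   (12) bases; each maximal group sharing such a prefix becomes a
   candidate whose pattern is the group's longest common prefix, capped at
   `max_sig_len` (53). This is where most real signatures live: variability
   rises steeply right after the conserved `GACAGG` hexamer, so the start
   of 37F is the most diagnostic window.
2. **Upstream-extended.** A candidate whose pattern also occurs in a
   disallowed reference sequence is not discarded immediately: the pattern
   is extended leftward, one base at a time, into the members' shared
   conserved upstream segment (regions 35/36) and retested, up to the
   53-nt cap. If some extension no longer matches any disallowed
   reference, the candidate survives with placement `upstream_extended`.
3. **Suffix-anchored.** Member subsets that cannot be told apart at the
   beginning of the core — they share the whole group's common prefix —
   but agree on their last 12 bases yield suffix-anchored candidates (the
   subset's longest common suffix), used to discriminate sub-lineages at
   the end of 37F / 37(II).

Every emitted signature must satisfy the validation rules exactly as
printed: at least 2 member OTUs, strictly more than 5000 supporting
reads, length within 12–53 nt. The *reference-exclusion rule* then drops
any candidate whose pattern occurs in a reference sequence from a
described clade — a signature that recognizes a group already present in
the database defines nothing new — with one exemption: hits to
environmental clades (ENFOR) and to the poorly defined Monothalamids X
groups are tolerated, since those reference groups are themselves only
placeholders for unknown diversity.

Design choices made where the published procedure was partly manual:

* **Formalization.** The original grouping of "similar molecular
  signatures" was done by expert inspection; the three-tier prefix-trie
  formalization above is this package's mechanistic reconstruction of the
  same placement classes. Its output is checked in the test suite against
  an exhaustive brute-force search over all substrings at the three
  placements on randomized instances.
* **Longest, not minimal, patterns.** The emitted pattern is the longest
  common prefix (or suffix) of the member set rather than the shortest
  discriminating one: longer signatures reduce the risk of
  misidentification. A `minimal_patterns` switch in `discovery_config()`
  selects the shortest prefix that still captures exactly the same member
  set.
* **Membership closure.** `member_otus` is always exactly the set of
  input OTUs whose core matches the pattern at the required placement;
  cores carrying ambiguity characters inside the candidate window are
  excluded, because exact matching is defined over unambiguous bases.
* **Nested candidates.** If one candidate's pattern is nested in
  another's at the same placement, the candidate with more member OTUs
  wins; ties go to the longer pattern (maximal-set semantics).

### Naming

Lineages are named `L` plus a number; closely related candidates become
sub-lineages sharing a number with letters (`L2A`, `L2B`). "Closely
related" is operationalized as *equal length and Hamming distance 1* (one
SNP — the preferred representation is two sub-lineages rather than one
degenerate signature) *or an identical first 12-mer*, closed
transitively. Numbers and letters are assigned in descending order of
supporting reads with lexicographic tie-breaks, so naming is deterministic
under permutation of the input. The exact sub-lineage grouping rule of the
original analysis was not published; this rule is an explicit,
configurable approximation.

## Classification and reconciliation

`match_signatures()` assigns an OTU to a lineage iff its sequence contains
the lineage's pattern exactly — no mismatches, single strand, placement
blind (the published search matched patterns directly). One base of
difference breaks the assignment by design; accepting even single-SNP
variants would erode the specificity that makes signatures unambiguous.
An OTU containing several signatures is assigned to the longest one and
carries a note listing all hits.

`merge_with_prior()` reconciles signature assignments with a prior
similarity-based table: lineages override priors whose status is
`unassigned`, `enfor`, `monothalamids_X` or `undetermined_monothalamid`;
a well-defined prior taxon is kept and the signature hit is recorded as a
conflict note. Genuinely ambiguous cases (a lineage matching OTUs assigned
to two classes) are recorded, not resolved — resolving them needs
single-cell confirmation, which is out of scope.

## Biogeography

`lineage_by_area()` accumulates reads per lineage per area; unassigned
reads are kept as an explicit remainder so the dataset total is conserved.
`relative_abundance()` normalizes per area column — "relative abundance of
lineages per area" is read as within-area proportions; a flag-free
alternative (normalizing over all foraminiferal reads) can be obtained by
dividing by the grand total instead. `presence_absence()` uses a default
threshold of one read, configurable since no presence cut-off is stated.
`shared_otu_sets()` computes exclusive habitat intersections with UpSet
semantics over the closed habitat set {CCFZ, deep_sea, shallow}: each
deduplicated OTU counts in exactly one cell, so cells partition each
lineage's OTU set.

## The simulator: what it emulates, and what it does not

`simulate_dataset()` generates the structure the method assumes, with
ground truth:

* a shared conserved upstream segment (default 30 nt) before the anchor;
* planted lineages (default 10, of 3–6 OTUs) whose members share a
  signature window — `GACAGG` plus a drawn pattern, 12–53 nt, pairwise
  distinct in their first 12 bases — followed by member-private random
  bases out to a 68–196 nt core;
* noise OTUs with unique 12-nt prefixes, a fifth of them below the
  100-read filter; contaminants lacking the anchor; records with degraded
  conserved regions (4 substitutions, failing QC at the default 2);
* lognormal read abundances (median ≈ 3000, log-sd 1.2), floored at 150
  reads per retained record, with lineage totals topped up above the
  5000-read validation threshold — the generator's contract is that
  planted lineages satisfy the validation rules, so recovery failures
  indicate algorithmic faults rather than unlucky draws;
* reads spread multinomially over the samples of a random subset of
  areas (default six areas spanning CCFZ, other deep sea and shallow
  habitats), which produces realistic presence patterns for the
  biogeography analytics;
* a reference database with described-clade, ENFOR and Monothalamids X
  records, plus decoys: a described-clade decoy carries the *full core*
  of an extra "trap" lineage (a group already present in the database),
  whose candidate must therefore be rejected — no prefix or upstream
  extension can escape the match — while ENFOR and Monothalamids X decoys
  carry patterns of real lineages and must *not* affect them.

Everything is deterministic given the seed; generated cores are rejected
and redrawn if they would contain a second anchor, a terminal motif, or
another lineage's window, and feasibility (every planted window present in
all members, absent everywhere else) is asserted before returning.

What the simulator does **not** model: sequencing error at read level,
chimeras, intragenomic polymorphism, length heterogeneity within a
lineage's conserved flanks, or phylogenetic correlation between lineage
patterns. Passing the recovery tests therefore shows that the algorithm
implements its own rules correctly on data satisfying its assumptions —
it does not show that real 37F amplicons satisfy those assumptions, nor
does it reproduce dataset-level counts from multi-study sequencing
archives, which require tens of millions of reads and external assignment
tools.

## Validation problem sizes and numerical choices

The test suite and the acceptance script validate at desk scale: the
analytic 123-bp shortest-amplicon identity; exact recovery of planted
memberships and described-clade decoy rejection on 100 seeded communities
(about 110 OTUs each); agreement of the matcher and of discovery with
naive brute-force scans on 1000 random small instances (matching on
800–1000, discovery on 200 instances of ≤ 20 cores); boundary behaviour
of every printed threshold (70 bp, 100 reads, 5000 reads, 2 OTUs,
zero-mismatch, the exclusion exemption); and the conservation identities
(screen partition, composition fractions summing to 1 within 1e-12,
column-normalized abundances, UpSet partitioning).

Other numerical conventions: all thresholds printed with ">" are strict
inequalities; consensus ties break alphabetically (A < C < G < T);
entropy columns with no usable characters are reported as 0 bits with a
warning; empty area columns stay all-zero under normalization, with a
warning.

## Limitations

* Phylogenetic placement of lineages into clades (alignment + maximum
  likelihood trees) is deliberately out of scope; signatures carry no
  rank information by themselves.
* Matching is single-strand; amplicons are expected primer-oriented.
* The sub-lineage grouping rule and the Tier-3 gating are explicit
  operationalizations of a partly manual published procedure and are kept
  configurable rather than claimed authoritative.

## A minimal session

```{r example}
sim <- simulate_dataset(simulation_params(seed = 7))
sc <- screen_dataset(sim, references = sim$references)
table(sc$log$verdict)

sig <- name_lineages(discover_signatures(extract_cores(sc$kept), sim$references))
sig[, c("name", "pattern", "placement", "n_otus", "total_reads")]

asg <- match_signatures(sig, sim$otus)
head(composition_summary(asg, sim$otus, collapse_lineages = TRUE))
```
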