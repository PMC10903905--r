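# The 37F metabarcoding amplicon design: foraminifera-specific primers
# around the 37F hypervariable region (68-196 bp insert), with 8-nt sample
# tags on both primers for multiplexing.

#' Foraminifera-specific 37F primers
#'
#' Forward primer s14F1 and reverse primer s15 flanking the 37F
#' hypervariable region of the foraminiferal 18S rRNA gene.
#' @export
foram_primer_s14F1 <- "AAGGGCACCACAAGAACGC"

#' @rdname foram_primer_s14F1
#' @export
foram_primer_s15 <- "CCACCTATCACAYAATCATG"

#' Shortest tagged amplicon length
#'
#' Length in bp of the shortest amplicon including primers and sample
#' tags: both primer lengths, plus one tag per primer, plus the minimum
#' insert. With the default s14F1/s15 primers (19 and 20 nt), two 8-nt
#' tags and the 68-bp minimum 37F insert this is 123 bp — the size
#' cut-off used to remove dimers and short amplicons before sequencing.
#'
#' @param primer_fwd,primer_rev Primer sequences.
#' @param tag_length Length of each multiplexing tag in nt.
#' @param n_tags Number of tagged primer ends.
#' @param min_insert Minimum insert (variable region) length in bp.
#' @return Integer amplicon length in bp.
#' @examples
#' min_amplicon_length()  # 123
#' @export
min_amplicon_length <- function(primer_fwd = foram_primer_s14F1,
                                primer_rev = foram_primer_s15,
                                tag_length = 8L, n_tags = 2L,
                                min_insert = 68L) {
  as.integer(nchar(primer_fwd) + nchar(primer_rev) +
               n_tags * tag_length + min_insert)
}
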