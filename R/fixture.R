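#' Demonstration gene model: an Scn1a-like gene with poison exon 20N
#'
#' Builds the package's default fixture: a minus-strand gene with 26
#' constitutive exons plus a 64-nt poison cassette exon ("ex20N") between
#' exons 20 and 21, mirroring the architecture of mouse *Scn1a* and its
#' poison exon 20N. Inclusion of the 64-nt exon shifts the reading frame
#' (64 mod 3 = 1) and brings a premature termination codon into exon 21.
#'
#' The exact exon sizes and primer placements are synthetic: the real
#' transcript sequence is not reproduced here, so the geometry is
#' reverse-engineered from the published amplicon sizes instead - amplicon 1
#' (exon 20 -> exon 21) yields 56 bp without and 120 bp with the poison
#' exon, junction-spanning amplicon 2 (20-20N / 20N-21) yields 96 bp only on
#' the inclusion isoform, and amplicon 3 (exon 19 -> exon 20) yields 111 bp
#' on either. The bundled exon sequences are likewise synthetic, constructed
#' so that the exclusion isoform encodes an open reading frame with its stop
#' codon in the last exon while the frameshifted inclusion isoform hits a
#' stop early in exon 21.
#'
#' @param with_sequence Attach the synthetic exon sequences (needed for
#'   sequence-mode [classify_isoform()]).
#' @return A [gene_model()] with primers attached.
#' @export
#' @examples
#' gm <- scn1a_gene_model()
#' gm
scn1a_gene_model <- function(with_sequence = TRUE) {
  lens <- c(
    237L, 141L, 90L, 274L, 186L, 92L, 273L, 216L, 273L, 92L,
    138L, 159L, 285L, 105L, 168L, 270L, 96L, 246L, 174L, 273L,
    130L, 162L, 114L, 228L, 183L, 1200L
  )
  ids <- sprintf("ex%02d", 1:26)
  # insert the 64-nt poison exon after exon 20 (rank 21 of 27)
  ids <- append(ids, "ex20N", after = 20)
  lens <- append(lens, 64L, after = 20)
  introns <- rep(c(901L, 1502L, 744L, 2050L, 1133L, 866L), length.out = 26)
  introns[20] <- 2451L # exon 20 -> 20N
  introns[21] <- 1807L # 20N -> exon 21

  # minus-strand layout: rank 1 sits at the highest genomic coordinate
  top <- 66300000L
  offsets <- cumsum(c(0L, head(lens + c(introns, 0L), -1)))
  ends <- top - offsets
  exons <- tibble(exon_id = ids, start = ends - lens, end = ends)

  primers <- dplyr::bind_rows(
    primer_pair("amplicon1", "ex20", 273L - 28L, 23L, "ex21", 8L, 20L),
    primer_pair("amplicon2", "ex20", 273L - 16L, 23L, "ex20N", 56L, 24L,
      left_junction = "ex20N", right_junction = "ex21"
    ),
    primer_pair("amplicon3", "ex19", 174L - 56L, 21L, "ex20", 34L, 21L)
  )

  sequence <- if (with_sequence) scn1a_fixture_sequence(ids, lens) else NULL

  gene_model(
    gene_id = "Scn1a", chrom = "chr2", strand = "-", exons = exons,
    poison_exon_id = "ex20N", primers = primers, sequence = sequence,
    cds_start = 150L
  )
}

# Synthetic spliced sequence, split per exon. Exclusion CDS (from offset 150)
# is a GCT repeat with two engineered edits: a shifted-frame-only TAA in
# exon 21 (in frame after the 64-nt insertion, silent AAT/GCT codons without
# it) and the natural TAA stop in exon 26.
scn1a_fixture_sequence <- function(ids, lens) {
  excl_ids <- ids[ids != "ex20N"]
  excl_lens <- lens[ids != "ex20N"]
  total <- sum(excl_lens)
  utr5 <- strsplit(strrep("GC", 75), "")[[1]]
  body <- rep(c("G", "C", "T"), length.out = total - 150L)
  seq <- c(utr5, body)
  seq[3798:3800] <- c("T", "A", "A") # 0-based 3797..3799, exon 21 offsets 9..11
  seq[4705:4707] <- c("T", "A", "A") # 0-based 4704..4706, natural stop in exon 26
  bounds <- cumsum(excl_lens)
  pieces <- substring(
    paste(seq, collapse = ""),
    c(1L, head(bounds, -1) + 1L), bounds
  )
  out <- setNames(pieces, excl_ids)
  out["ex20N"] <- paste0("G", strrep("GCA", 21)) # 64 nt, stop-free in frame
  out[ids]
}
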