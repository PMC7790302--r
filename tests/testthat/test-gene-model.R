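test_that("gene model validation catches malformed input", {
  exons <- tibble::tibble(
    exon_id = c("a", "b"), start = c(0L, 50L), end = c(100L, 150L)
  )
  expect_error(
    gene_model("g", "chr1", "+", exons, "a"),
    class = "pexquant_format_error"
  )
  ok <- tibble::tibble(
    exon_id = c("a", "b"), start = c(0L, 200L), end = c(100L, 300L)
  )
  expect_error(
    gene_model("g", "chr1", "+", ok, "zz"),
    class = "pexquant_config_error"
  )
  expect_error(
    gene_model("g", "chr1", "+",
      tibble::tibble(exon_id = "a", start = 10L, end = 10L), "a"
    ),
    class = "pexquant_format_error"
  )
})

test_that("a single-exon gene with that exon as poison is a valid degenerate model", {
  m <- toy_model(120L, poison_idx = 1)
  expect_s3_class(m, "gene_model")
  expect_equal(m$exons$kind, "poison")
  iso <- transcript_isoform(m, include_poison = TRUE)
  expect_equal(spliced_length(m, iso), 120L)
})

test_that("the default fixture has 27 exons with a 64-nt poison exon at rank 21", {
  gm <- scn1a_gene_model()
  expect_equal(nrow(gm$exons), 27L)
  pe <- gm$exons[gm$exons$kind == "poison", ]
  expect_equal(pe$length, 64L)
  expect_equal(pe$rank, 21L)
  # minus-strand gene: rank 1 at the highest genomic coordinate
  expect_true(all(diff(gm$exons$start) < 0))
})

test_that("spliced_length sums exon lengths and handles the empty isoform", {
  gm <- scn1a_gene_model(with_sequence = FALSE)
  inc <- transcript_isoform(gm, TRUE)
  exc <- transcript_isoform(gm, FALSE)
  expect_equal(spliced_length(gm, inc) - spliced_length(gm, exc), 64L)
  empty <- transcript_isoform(gm, exon_ids = character(0))
  expect_equal(spliced_length(gm, empty), 0L)
})

test_that("spliced_length matches a brute-force interval sum on random exon subsets", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      lens <- sample(30:400, sample(3:12, 1))
      m <- toy_model(lens, poison_idx = 1)
      keep <- sort(sample(seq_along(lens), sample(seq_along(lens), 1)))
      iso <- transcript_isoform(m, exon_ids = sprintf("e%02d", keep))
      manual <- sum(m$exons$end[keep] - m$exons$start[keep])
      expect_equal(spliced_length(m, iso), manual)
    }
  })
})

test_that("a 64-nt poison exon shifts the frame; a 63-nt one does not", {
  gm <- scn1a_gene_model(with_sequence = FALSE)
  expect_true(classify_isoform(gm, transcript_isoform(gm, TRUE))$reading_frame_shift)
  m63 <- toy_model(c(300L, 63L, 300L, 300L), poison_idx = 2)
  expect_false(classify_isoform(m63, transcript_isoform(m63, TRUE))$reading_frame_shift)
})

test_that("an isoform without the poison exon never gets a frame shift", {
  withr::with_seed(7, {
    for (rep in 1:10) {
      lens <- sample(c(30:100, 64), 5)
      m <- toy_model(lens, poison_idx = sample(5, 1))
      cls <- classify_isoform(m, transcript_isoform(m, FALSE))
      expect_false(cls$reading_frame_shift)
    }
  })
})

test_that("sequence mode finds the PTC in the exon after the poison exon", {
  gm <- scn1a_gene_model(with_sequence = TRUE)
  inc <- transcript_isoform(gm, TRUE)
  cls <- classify_isoform(gm, inc)
  p_rank <- gm$exons$rank[gm$exons$kind == "poison"]
  expect_equal(cls$mode, "sequence")
  expect_equal(cls$ptc_exon_rank, p_rank + 1L)
  expect_true(cls$nmd_candidate)

  # independent oracle: translate the spliced CDS and locate the first stop
  skip_if_not_installed("Biostrings")
  spliced <- paste(gm$sequence[inc$exon_ids], collapse = "")
  cds <- substring(spliced, gm$cds_start + 1L, nchar(spliced))
  cds <- substring(cds, 1, 3 * (nchar(cds) %/% 3))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds),
    if.fuzzy.codon = "X"
  ))
  stop_codon_idx <- regexpr("\\*", aa)[1]
  ptc_pos <- gm$cds_start + 3L * (stop_codon_idx - 1L) # 0-based spliced
  smap_ends <- cumsum(gm$exons$length[match(inc$exon_ids, gm$exons$exon_id)])
  oracle_rank <- which(ptc_pos < smap_ends)[1]
  expect_equal(cls$ptc_exon_rank, gm$exons$rank[
    match(inc$exon_ids[oracle_rank], gm$exons$exon_id)
  ])
  # the exclusion isoform reads through to its natural stop in the last exon
  exc_cls <- classify_isoform(gm, transcript_isoform(gm, FALSE))
  expect_equal(exc_cls$ptc_exon_rank, max(gm$exons$rank))
  expect_false(exc_cls$nmd_candidate)
})

test_that("in-silico PCR reproduces the fixture amplicon sizes", {
  gm <- scn1a_gene_model(with_sequence = FALSE)
  inc <- transcript_isoform(gm, TRUE)
  exc <- transcript_isoform(gm, FALSE)
  p_inc <- in_silico_pcr(gm, gm$primers, inc)
  p_exc <- in_silico_pcr(gm, gm$primers, exc)
  expect_equal(p_exc$product_length[p_exc$name == "amplicon1"], 56L)
  expect_equal(p_inc$product_length[p_inc$name == "amplicon1"], 120L)
  expect_true(is.na(p_exc$product_length[p_exc$name == "amplicon2"]))
  expect_equal(p_inc$product_length[p_inc$name == "amplicon2"], 96L)
  expect_equal(p_inc$product_length[p_inc$name == "amplicon3"], 111L)
  expect_equal(p_exc$product_length[p_exc$name == "amplicon3"], 111L)
})

test_that("primer pairs must face each other and be at least 15 nt", {
  expect_error(
    primer_pair("x", "a", 0, 20, "b", 0, 20, left_dir = "rev"),
    class = "pexquant_config_error"
  )
  expect_error(
    primer_pair("x", "a", 0, 10, "b", 0, 20),
    class = "pexquant_config_error"
  )
})

test_that("product difference equals poison length over randomised geometries", {
  withr::with_seed(11, {
    for (rep in 1:15) {
      lens <- c(
        sample(100:300, 1), sample(60:300, 1),
        sample(c(31:90) * 3 + 1, 1), # poison, not a multiple of 3
        sample(60:300, 1), sample(100:300, 1)
      )
      m <- toy_model(lens, poison_idx = 3, strand = sample(c("+", "-"), 1))
      pp <- primer_pair("p", "e02", 5L, 20L, "e04", 10L, 20L)
      inc <- in_silico_pcr(m, pp, transcript_isoform(m, TRUE))$product_length
      exc <- in_silico_pcr(m, pp, transcript_isoform(m, FALSE))$product_length
      expect_equal(inc - exc, lens[3])
    }
  })
})

test_that("GFF3 and BED12 encodings of the fixture load to the same model", {
  gm <- scn1a_gene_model(with_sequence = FALSE)
  gff <- withr::local_tempfile(fileext = ".gff3")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_gene_model(gm, gff)
  write_gene_model(gm, bed)
  from_gff <- load_gene_model(gff, "ex20N")
  from_bed <- load_gene_model(bed, "ex20N", exon_ids = gm$exons$exon_id)
  expect_equal(from_gff$exons, gm$exons)
  expect_equal(from_bed$exons, from_gff$exons)
  expect_equal(from_gff$strand, "-")
  # write -> load -> write round trip is stable for both formats
  gff2 <- withr::local_tempfile(fileext = ".gff3")
  write_gene_model(from_gff, gff2)
  expect_identical(readLines(gff), readLines(gff2))
  bed2 <- withr::local_tempfile(fileext = ".bed")
  write_gene_model(from_bed, bed2)
  expect_identical(readLines(bed), readLines(bed2))
})

test_that("shipped annotation fixtures load through the readers", {
  gff <- system.file("extdata", "scn1a_synthetic.gff3", package = "pexquant")
  bed <- system.file("extdata", "scn1a_synthetic.bed", package = "pexquant")
  csv <- system.file("extdata", "scn1a_primers.csv", package = "pexquant")
  m <- load_gene_model(gff, "ex20N", primers = read_primer_pairs(csv))
  expect_equal(m$exons, scn1a_gene_model(with_sequence = FALSE)$exons)
  expect_equal(nrow(m$primers), 3L)
  m2 <- load_gene_model(bed, "ex20N", exon_ids = m$exons$exon_id)
  expect_equal(m2$exons, m$exons)
})
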