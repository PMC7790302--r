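#' Read and write gene models as GFF3 or BED12
#'
#' `write_gene_model()` serialises the exon structure as either a GFF3
#' gene/mRNA/exon feature hierarchy (exon ids kept in `Name`) or a single
#' BED12 line whose blocks are the exons. `load_gene_model()` reads either
#' format back; exons are deduplicated, ranked 5'->3' in transcript
#' orientation, and the named exon is flagged as the poison exon. GFF3 uses
#' 1-based closed coordinates on disk and BED12 0-based half-open; both are
#' converted to the package's internal 0-based half-open convention.
#'
#' BED12 carries no exon identifiers, so exon ids are assigned by rank
#' (`"exon01"`, `"exon02"`, ...) unless `exon_ids` supplies names (in rank
#' order), in which case the two encodings of one gene load identically.
#'
#' @param path File path; format is guessed from the extension
#'   (`.gff`/`.gff3` vs `.bed`) unless `format` is given.
#' @param poison_exon_id Exon id to flag as the poison exon.
#' @param format `"gff3"` or `"bed12"`.
#' @param exon_ids Optional character vector renaming exons by rank.
#' @param primers,sequence,cds_start Passed through to [gene_model()].
#' @return `load_gene_model()` returns a [gene_model()];
#'   `write_gene_model()` returns `path` invisibly.
#' @export
load_gene_model <- function(path, poison_exon_id, format = NULL,
                            exon_ids = NULL, primers = NULL, sequence = NULL,
                            cds_start = 0L) {
  format <- format %||% guess_annotation_format(path)
  parsed <- switch(format,
    gff3 = parse_gff3_exons(path),
    bed12 = parse_bed12_exons(path),
    abort(paste("unsupported annotation format:", format),
      class = "pexquant_format_error"
    )
  )
  exons <- distinct(parsed$exons, .data$start, .data$end, .keep_all = TRUE)
  if (parsed$strand == "-") {
    exons <- arrange(exons, dplyr::desc(.data$start))
  } else {
    exons <- arrange(exons, .data$start)
  }
  if (!is.null(exon_ids)) {
    if (length(exon_ids) != nrow(exons)) {
      abort("exon_ids must name every exon (in rank order)",
        class = "pexquant_config_error"
      )
    }
    exons$exon_id <- exon_ids
  }
  gene_model(
    gene_id = parsed$gene_id, chrom = parsed$chrom, strand = parsed$strand,
    exons = exons, poison_exon_id = poison_exon_id, primers = primers,
    sequence = sequence, cds_start = cds_start
  )
}

#' @rdname load_gene_model
#' @param model A [gene_model()].
#' @export
write_gene_model <- function(model, path, format = NULL) {
  stopifnot(inherits(model, "gene_model"))
  format <- format %||% guess_annotation_format(path)
  ex <- arrange(model$exons, .data$start)
  span_start <- min(ex$start)
  span_end <- max(ex$end)
  if (format == "gff3") {
    mrna_id <- paste0(model$gene_id, ".t1")
    n <- nrow(ex)
    gr <- GenomicRanges::GRanges(
      model$chrom,
      IRanges::IRanges(
        c(span_start, span_start, ex$start) + 1L,
        c(span_end, span_end, ex$end)
      ),
      strand = model$strand
    )
    gr$type <- c("gene", "mRNA", rep("exon", n))
    gr$ID <- c(model$gene_id, mrna_id, paste0(mrna_id, ".", ex$exon_id))
    gr$Name <- c(model$gene_id, NA, ex$exon_id)
    gr$Parent <- IRanges::CharacterList(
      c(list(character(0), model$gene_id), as.list(rep(mrna_id, n)))
    )
    rtracklayer::export(gr, path, format = "gff3")
  } else if (format == "bed12") {
    gr <- GenomicRanges::GRanges(
      model$chrom, IRanges::IRanges(span_start + 1L, span_end),
      strand = model$strand
    )
    gr$name <- model$gene_id
    gr$blocks <- IRanges::IRangesList(
      IRanges::IRanges(start = ex$start - span_start + 1L, width = ex$length)
    )
    rtracklayer::export(gr, path, format = "bed")
  } else {
    abort(paste("unsupported annotation format:", format),
      class = "pexquant_format_error"
    )
  }
  invisible(path)
}

guess_annotation_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    gff = "gff3", gff3 = "gff3", bed = "bed12", bed12 = "bed12",
    abort(paste("cannot guess annotation format from extension:", ext),
      class = "pexquant_format_error"
    )
  )
}

parse_gff3_exons <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  ex <- gr[tolower(as.character(gr$type)) == "exon"]
  if (!length(ex)) {
    abort("no exon features found in GFF3", class = "pexquant_format_error")
  }
  chrom <- as.character(GenomicRanges::seqnames(ex))[1]
  strand <- as.character(GenomicRanges::strand(ex))[1]
  if (!strand %in% c("+", "-")) strand <- "+"
  ids <- if (!is.null(ex$Name) && !anyNA(ex$Name)) {
    as.character(ex$Name)
  } else if (!is.null(ex$ID) && !anyNA(ex$ID)) {
    as.character(ex$ID)
  } else {
    sprintf("exon%02d", seq_along(ex))
  }
  gene <- gr[tolower(as.character(gr$type)) == "gene"]
  gene_id <- if (length(gene) && !is.null(gene$ID)) {
    as.character(gene$ID)[1]
  } else {
    "gene"
  }
  list(
    gene_id = gene_id, chrom = chrom, strand = strand,
    exons = tibble(
      exon_id = ids,
      start = GenomicRanges::start(ex) - 1L,
      end = GenomicRanges::end(ex)
    )
  )
}

parse_bed12_exons <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (!length(gr)) {
    abort("empty BED file", class = "pexquant_format_error")
  }
  gr <- gr[1] # one transcript describes the gene
  chrom <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  if (!strand %in% c("+", "-")) strand <- "+"
  chrom_start <- GenomicRanges::start(gr) - 1L
  if (!is.null(gr$blocks) && length(gr$blocks[[1]])) {
    b <- gr$blocks[[1]]
    starts <- chrom_start + IRanges::start(b) - 1L
    ends <- starts + IRanges::width(b)
  } else {
    starts <- chrom_start
    ends <- GenomicRanges::end(gr)
  }
  ord <- order(starts)
  starts <- starts[ord]
  ends <- ends[ord]
  n <- length(starts)
  ranks <- if (strand == "-") rev(seq_len(n)) else seq_len(n)
  list(
    gene_id = if (!is.null(gr$name)) as.character(gr$name) else "gene",
    chrom = chrom, strand = strand,
    exons = tibble(
      exon_id = sprintf("exon%02d", ranks),
      start = as.integer(starts), end = as.integer(ends)
    )
  )
}
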