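#' Construct a gene model with a designated poison exon
#'
#' A gene model is the coordinate frame for everything downstream: a set of
#' non-overlapping exons on one strand, exactly one of which is flagged as the
#' "poison" cassette exon, plus (optionally) the qPCR primer pairs and the
#' exon sequences. Coordinates are 0-based half-open genomic intervals; exon
#' ranks run 5'->3' in transcript orientation, so on a minus-strand gene rank
#' 1 is the exon with the highest genomic coordinate.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome / sequence name.
#' @param strand `"+"` or `"-"`.
#' @param exons A data frame with columns `exon_id`, `start`, `end`
#'   (0-based half-open genomic coordinates).
#' @param poison_exon_id `exon_id` of the poison exon; must exist in `exons`.
#' @param primers Optional data frame of primer pairs (see [primer_pair()]).
#' @param sequence Optional named character vector of exon sequences, written
#'   5'->3' in transcript orientation (i.e. mRNA sense), named by `exon_id`.
#' @param cds_start 0-based offset of the first coding base in spliced
#'   (mRNA) coordinates of the poison-free isoform.
#'
#' @return An object of class `gene_model`: a list with elements `gene_id`,
#'   `chrom`, `strand`, `exons` (tibble with `exon_id`, `start`, `end`,
#'   `length`, `kind`, `rank`), `poison_exon_id`, `primers`, `sequence`,
#'   `cds_start`.
#' @export
#' @examples
#' gm <- gene_model(
#'   "toy", "chr1", "+",
#'   exons = data.frame(
#'     exon_id = c("e1", "pe", "e2"),
#'     start = c(0, 200, 400), end = c(100, 264, 500)
#'   ),
#'   poison_exon_id = "pe"
#' )
#' gm$exons
gene_model <- function(gene_id, chrom, strand, exons, poison_exon_id,
                       primers = NULL, sequence = NULL, cds_start = 0L) {
  stopifnot(is.data.frame(exons), all(c("exon_id", "start", "end") %in% names(exons)))
  strand <- match.arg(strand, c("+", "-"))
  exons <- as_tibble(exons) %>%
    mutate(
      exon_id = as.character(.data$exon_id),
      start = as.integer(.data$start),
      end = as.integer(.data$end)
    )
  if (anyDuplicated(exons$exon_id)) {
    abort("duplicated exon_id in gene model", class = "pexquant_format_error")
  }
  if (any(exons$start >= exons$end)) {
    abort("every exon must satisfy start < end (0-based half-open)",
      class = "pexquant_format_error"
    )
  }
  exons <- arrange(exons, .data$start)
  if (nrow(exons) > 1 && any(exons$start[-1] < exons$end[-nrow(exons)])) {
    abort("exons of one gene must not overlap", class = "pexquant_format_error")
  }
  if (!poison_exon_id %in% exons$exon_id) {
    abort(
      paste0("poison_exon_id '", poison_exon_id, "' not found among exons"),
      class = "pexquant_config_error"
    )
  }
  if (strand == "-") exons <- arrange(exons, dplyr::desc(.data$start))
  exons <- exons %>%
    mutate(
      length = .data$end - .data$start,
      kind = ifelse(.data$exon_id == poison_exon_id, "poison", "constitutive"),
      rank = row_number()
    ) %>%
    select("exon_id", "start", "end", "length", "kind", "rank")
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    bad <- setdiff(names(sequence), exons$exon_id)
    if (length(bad)) {
      abort(paste("sequence names not in exon set:", paste(bad, collapse = ", ")),
        class = "pexquant_config_error"
      )
    }
    len_mismatch <- exons$exon_id[exons$exon_id %in% names(sequence) &
      nchar(sequence[exons$exon_id]) != exons$length]
    if (length(len_mismatch)) {
      abort(paste(
        "sequence length disagrees with exon length for:",
        paste(len_mismatch, collapse = ", ")
      ), class = "pexquant_format_error")
    }
  }
  structure(
    list(
      gene_id = gene_id, chrom = chrom, strand = strand, exons = exons,
      poison_exon_id = poison_exon_id,
      primers = if (!is.null(primers)) as_tibble(primers) else NULL,
      sequence = sequence, cds_start = as.integer(cds_start)
    ),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(
    "<gene_model> ", x$gene_id, " (", x$chrom, x$strand, "), ",
    nrow(x$exons), " exons, poison exon '", x$poison_exon_id, "' (",
    x$exons$length[x$exons$kind == "poison"], " nt)\n",
    sep = ""
  )
  if (!is.null(x$primers)) {
    cat("  primer pairs:", paste(x$primers$name, collapse = ", "), "\n")
  }
  invisible(x)
}

poison_exon <- function(model) {
  filter(model$exons, .data$kind == "poison")
}

gene_region <- function(model) {
  list(chrom = model$chrom, start = min(model$exons$start), end = max(model$exons$end))
}

#' Define a transcript isoform of a gene model
#'
#' Isoforms are defined relative to the full exon complement: the inclusion
#' isoform uses every exon, the exclusion (canonical) isoform skips the
#' poison exon. Arbitrary exon subsets can be supplied for degenerate or
#' test geometries.
#'
#' @param model A [gene_model()].
#' @param include_poison Include the poison exon?
#' @param exon_ids Optional explicit ordered exon subset (overrides
#'   `include_poison`); order must respect exon rank.
#' @param isoform_id Identifier; defaults to `"inclusion"`/`"exclusion"`.
#' @param cds_start 0-based coding start in this isoform's spliced
#'   coordinates; defaults to the model's.
#'
#' @return An object of class `transcript_isoform`: list with `isoform_id`,
#'   `exon_ids`, `includes_poison`, `cds_start`.
#' @export
transcript_isoform <- function(model, include_poison = FALSE, exon_ids = NULL,
                               isoform_id = NULL, cds_start = model$cds_start) {
  stopifnot(inherits(model, "gene_model"))
  if (is.null(exon_ids)) {
    exon_ids <- model$exons$exon_id
    if (!include_poison) exon_ids <- setdiff(exon_ids, model$poison_exon_id)
  } else {
    unknown <- setdiff(exon_ids, model$exons$exon_id)
    if (length(unknown)) {
      abort(paste("unknown exon ids:", paste(unknown, collapse = ", ")),
        class = "pexquant_config_error"
      )
    }
    ranks <- model$exons$rank[match(exon_ids, model$exons$exon_id)]
    if (is.unsorted(ranks, strictly = TRUE)) {
      abort("exon_ids must be given in rank order", class = "pexquant_config_error")
    }
  }
  includes_poison <- model$poison_exon_id %in% exon_ids
  if (is.null(isoform_id)) {
    isoform_id <- if (includes_poison) "inclusion" else "exclusion"
  }
  structure(
    list(
      isoform_id = isoform_id, exon_ids = exon_ids,
      includes_poison = includes_poison, cds_start = as.integer(cds_start)
    ),
    class = "transcript_isoform"
  )
}

#' @export
print.transcript_isoform <- function(x, ...) {
  cat(
    "<transcript_isoform> ", x$isoform_id, ": ", length(x$exon_ids),
    " exons, poison ", if (x$includes_poison) "included" else "excluded", "\n",
    sep = ""
  )
  invisible(x)
}

# Spliced coordinate map of an isoform: one row per exon with its
# half-open [sp_start, sp_end) interval on the mature mRNA.
spliced_map <- function(model, isoform) {
  ex <- model$exons[match(isoform$exon_ids, model$exons$exon_id), ]
  sp_end <- cumsum(ex$length)
  tibble(
    exon_id = ex$exon_id, rank = ex$rank, length = ex$length,
    start = ex$start, end = ex$end,
    sp_start = sp_end - ex$length, sp_end = sp_end
  )
}

#' Spliced (mature mRNA) length of an isoform
#'
#' @inheritParams transcript_isoform
#' @param isoform A [transcript_isoform()].
#' @return Integer number of nucleotides (0 for an empty isoform).
#' @export
spliced_length <- function(model, isoform) {
  stopifnot(inherits(model, "gene_model"), inherits(isoform, "transcript_isoform"))
  if (length(isoform$exon_ids) == 0) {
    return(0L)
  }
  sum(model$exons$length[match(isoform$exon_ids, model$exons$exon_id)])
}

# spliced sequence of an isoform (requires model$sequence for all its exons)
spliced_sequence <- function(model, isoform) {
  if (is.null(model$sequence) || !all(isoform$exon_ids %in% names(model$sequence))) {
    return(NULL)
  }
  paste(model$sequence[isoform$exon_ids], collapse = "")
}

#' Classify the consequence of poison-exon inclusion for an isoform
#'
#' Determines whether inclusion of the poison exon shifts the reading frame,
#' where the resulting premature termination codon (PTC) lands, and whether
#' the transcript is a nonsense-mediated-decay (NMD) candidate under the
#' exon-junction rule (PTC at least `nmd_rule_nt` nucleotides upstream of the
#' last exon-exon junction).
#'
#' When the model carries exon sequences the spliced CDS is scanned codon by
#' codon for the first stop at or downstream of the poison exon. In
#' sequence-free mode the PTC is reported in the exon immediately following
#' the poison exon (the expected location when the frameshift starts at the
#' poison exon) and assumed to lie at that exon's 5' end for the NMD-distance
#' computation.
#'
#' @inheritParams spliced_length
#' @param nmd_rule_nt Minimum PTC-to-last-junction distance for NMD
#'   candidacy; 55 nt by default (the canonical rule; the choice is
#'   configurable because decay is asserted, not measured, upstream).
#' @return One-row tibble: `isoform_id`, `reading_frame_shift`,
#'   `ptc_exon_rank` (NA when no PTC arises), `nmd_candidate`, `mode`
#'   (`"sequence"` or `"sequence_free"`).
#' @export
classify_isoform <- function(model, isoform, nmd_rule_nt = 55L) {
  stopifnot(inherits(model, "gene_model"), inherits(isoform, "transcript_isoform"))
  smap <- spliced_map(model, isoform)
  total <- if (nrow(smap)) max(smap$sp_end) else 0L
  if (isoform$cds_start < 0 || isoform$cds_start >= max(total, 1L)) {
    abort("cds_start falls outside the spliced transcript",
      class = "pexquant_input_error"
    )
  }
  plen <- poison_exon(model)$length
  shift <- isoform$includes_poison && (plen %% 3L != 0L)
  seq <- spliced_sequence(model, isoform)
  out <- function(ptc_rank, nmd, mode) {
    tibble(
      isoform_id = isoform$isoform_id, reading_frame_shift = shift,
      ptc_exon_rank = as.integer(ptc_rank), nmd_candidate = nmd, mode = mode
    )
  }
  last_junction <- if (nrow(smap) > 1) smap$sp_start[nrow(smap)] else NA_integer_

  if (!is.null(seq)) {
    ptc_pos <- scan_first_stop(
      seq, isoform$cds_start,
      from = if (isoform$includes_poison) {
        smap$sp_start[smap$exon_id == model$poison_exon_id]
      } else {
        0L
      }
    )
    if (is.na(ptc_pos)) {
      return(out(NA, FALSE, "sequence"))
    }
    rank <- smap$rank[ptc_pos >= smap$sp_start & ptc_pos < smap$sp_end]
    nmd <- !is.na(last_junction) && (last_junction - (ptc_pos + 3L)) >= nmd_rule_nt
    return(out(rank, nmd, "sequence"))
  }

  if (!shift) {
    return(out(NA, FALSE, "sequence_free"))
  }
  p_idx <- which(smap$exon_id == model$poison_exon_id)
  if (p_idx == nrow(smap)) {
    return(out(NA, FALSE, "sequence_free"))
  }
  ptc_pos <- smap$sp_start[p_idx + 1L] # assumed at 5' end of the next exon
  nmd <- !is.na(last_junction) && (last_junction - (ptc_pos + 3L)) >= nmd_rule_nt
  out(smap$rank[p_idx + 1L], nmd, "sequence_free")
}

# 0-based spliced position of the first in-frame stop codon whose start is
# >= `from`, scanning codons from cds_start; NA if none.
scan_first_stop <- function(seq, cds_start, from = 0L) {
  stops <- c("TAA", "TAG", "TGA")
  n <- nchar(seq)
  if (cds_start + 3L > n) {
    return(NA_integer_)
  }
  starts <- seq.int(cds_start + 1L, n - 2L, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  hit <- which(codons %in% stops & (starts - 1L) >= from)
  if (!length(hit)) {
    return(NA_integer_)
  }
  as.integer(starts[hit[1]] - 1L)
}
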