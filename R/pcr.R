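#' Define a qPCR primer pair on a gene model
#'
#' A primer binding site is anchored on an exon at a 0-based offset from that
#' exon's 5' end (transcript orientation) and extends `len` nucleotides
#' rightward along the spliced mRNA. A junction-spanning primer names the
#' exon its site must cross into: the named exon must immediately follow the
#' anchor exon in the isoform being amplified, and the site must actually
#' straddle that junction. The left primer is the forward (sense) oligo, the
#' right primer the reverse oligo; both sites are stored as sense-strand
#' spliced intervals, and the amplicon runs from the left site's 5' end to
#' the right site's 3'-most template base.
#'
#' @param name Amplicon name.
#' @param left_exon,left_offset,left_len Anchor exon, offset and length of
#'   the forward-primer site.
#' @param right_exon,right_offset,right_len Same for the reverse-primer site.
#' @param left_junction,right_junction Optional exon id the respective site
#'   must cross into (junction-spanning primers).
#' @param left_dir,right_dir Primer orientations; must be `"fwd"` and
#'   `"rev"` respectively (a pair on the same strand cannot amplify).
#' @return One-row tibble describing the pair.
#' @export
primer_pair <- function(name, left_exon, left_offset, left_len,
                        right_exon, right_offset, right_len,
                        left_junction = NA_character_,
                        right_junction = NA_character_,
                        left_dir = "fwd", right_dir = "rev") {
  if (!identical(left_dir, "fwd") || !identical(right_dir, "rev")) {
    abort("primer pair must be one forward and one reverse primer",
      class = "pexquant_config_error"
    )
  }
  if (left_len < 15 || right_len < 15) {
    abort("primer length must be >= 15 nt", class = "pexquant_config_error")
  }
  tibble(
    name = name,
    left_exon = left_exon, left_offset = as.integer(left_offset),
    left_len = as.integer(left_len), left_junction = as.character(left_junction),
    right_exon = right_exon, right_offset = as.integer(right_offset),
    right_len = as.integer(right_len), right_junction = as.character(right_junction)
  )
}

#' Read / write primer pairs as CSV
#'
#' Columns: `name, left_exon, left_offset, left_len, left_junction,
#' right_exon, right_offset, right_len, right_junction` (junction fields may
#' be empty).
#'
#' @param path File path.
#' @return `read_primer_pairs()` returns a tibble of primer pairs.
#' @export
read_primer_pairs <- function(path) {
  tab <- readr::read_csv(path,
    col_types = readr::cols(
      name = "c", left_exon = "c", left_offset = "i", left_len = "i",
      left_junction = "c", right_exon = "c", right_offset = "i",
      right_len = "i", right_junction = "c"
    )
  )
  purrr::pmap_dfr(tab, primer_pair)
}

#' @rdname read_primer_pairs
#' @param primers Tibble of primer pairs.
#' @export
write_primer_pairs <- function(primers, path) {
  readr::write_csv(primers, path, na = "")
  invisible(path)
}

# Resolve one primer site on an isoform's spliced coordinates.
# Returns c(start, end) half-open, or NULL if the site does not bind.
resolve_site <- function(smap, exon, offset, len, junction) {
  i <- which(smap$exon_id == exon)
  if (!length(i)) {
    return(NULL)
  }
  s <- smap$sp_start[i] + offset
  e <- s + len
  if (offset < 0 || offset >= smap$length[i]) {
    return(NULL)
  }
  if (e <= smap$sp_end[i]) {
    # site within the anchor exon: a junction-spanning primer must cross
    if (!is.na(junction)) {
      return(NULL)
    }
    return(c(s, e))
  }
  # site runs past the anchor exon: only allowed for junction primers
  if (is.na(junction)) {
    return(NULL)
  }
  if (i == nrow(smap) || smap$exon_id[i + 1L] != junction) {
    return(NULL)
  }
  if (e > smap$sp_end[i + 1L]) {
    return(NULL)
  }
  c(s, e)
}

#' In-silico PCR of a primer pair on one isoform
#'
#' Maps both primer sites onto the isoform's spliced sequence and, when both
#' bind (including any junction requirement), returns the amplicon length:
#' the distance from the forward primer's 5' base to the reverse primer's
#' template 3' boundary.
#'
#' @inheritParams spliced_length
#' @param primers A one-row primer-pair tibble ([primer_pair()]) or a
#'   multi-row tibble (each pair is amplified independently).
#' @return Tibble with one row per primer pair: `name`, `isoform_id`,
#'   `product_length` (NA when no product forms).
#' @export
#' @examples
#' gm <- scn1a_gene_model()
#' in_silico_pcr(gm, gm$primers, transcript_isoform(gm, include_poison = TRUE))
in_silico_pcr <- function(model, primers, isoform) {
  stopifnot(inherits(model, "gene_model"), inherits(isoform, "transcript_isoform"))
  smap <- spliced_map(model, isoform)
  one <- function(p) {
    left <- resolve_site(smap, p$left_exon, p$left_offset, p$left_len, p$left_junction)
    right <- resolve_site(smap, p$right_exon, p$right_offset, p$right_len, p$right_junction)
    len <- NA_integer_
    if (!is.null(left) && !is.null(right) && right[2] > left[1]) {
      len <- as.integer(right[2] - left[1])
    }
    tibble(name = p$name, isoform_id = isoform$isoform_id, product_length = len)
  }
  purrr::map_dfr(seq_len(nrow(primers)), function(k) one(primers[k, ]))
}
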