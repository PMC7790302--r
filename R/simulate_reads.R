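#' Sequencing-library protocol for the read simulator
#'
#' `"uniform"` mode emulates a conventional whole-transcript library: reads
#' are drawn per isoform with probability proportional to abundance times
#' spliced length and start positions are uniform along the mature mRNA.
#' `"three_prime"` mode emulates a 3'-tag protocol (QuantSeq-like): reads are
#' drawn proportional to abundance alone and start positions are
#' exponentially concentrated near the transcript 3' end with scale
#' `decay_length` (truncated at the transcript 5' end). Positions internal
#' exons far from the 3' end therefore receive essentially no coverage,
#' which is what makes such libraries blind to a poison exon ~2 kb upstream
#' of the 3' end.
#'
#' @param mode `"uniform"` or `"three_prime"`.
#' @param read_length Read length in nt.
#' @param total_reads Number of reads to draw for the gene.
#' @param decay_length Exponential positional scale (nt) in
#'   `"three_prime"` mode.
#' @param seed Optional integer seed stored with the protocol.
#' @return A list of class `library_protocol`.
#' @export
library_protocol <- function(mode = c("uniform", "three_prime"),
                             read_length = 50L, total_reads = 1e5L,
                             decay_length = 300, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(total_reads >= 0, read_length >= 1)
  if (mode == "three_prime" && decay_length <= 0) {
    abort("decay_length must be > 0 in three_prime mode",
      class = "pexquant_config_error"
    )
  }
  structure(
    list(
      mode = mode, read_length = as.integer(read_length),
      total_reads = as.integer(total_reads), decay_length = decay_length,
      seed = seed
    ),
    class = "library_protocol"
  )
}

#' Simulate spliced RNA-seq reads from a stable transcript pool
#'
#' Draws reads from the inclusion and exclusion isoforms of `model` in
#' proportion to the stable pool, places them on the mature mRNA according
#' to the protocol, and maps them back to genomic exon coordinates
#' (junction reads become multiple aligned blocks). All randomness is
#' governed by `seed`.
#'
#' @param pool A `stable_pool` from [steady_state_pool()].
#' @param model A [gene_model()].
#' @param protocol A [library_protocol()].
#' @param seed Integer seed; defaults to the protocol's.
#' @return A list with `reads` (tibble of aligned blocks: `read_id`,
#'   `isoform_id`, `chrom`, `start`, `end`, `strand`; 0-based half-open),
#'   `track` (a [depth_track()] over the gene region) and `mapped_reads`.
#' @export
simulate_reads <- function(pool, model, protocol, seed = protocol$seed) {
  stopifnot(inherits(model, "gene_model"), inherits(protocol, "library_protocol"))
  iso_inc <- transcript_isoform(model, include_poison = TRUE)
  iso_exc <- transcript_isoform(model, include_poison = FALSE)
  abund <- c(inclusion = sum(pool$included), exclusion = sum(pool$excluded))
  lens <- c(
    inclusion = spliced_length(model, iso_inc),
    exclusion = spliced_length(model, iso_exc)
  )
  rl <- protocol$read_length
  if (any(rl > lens[abund > 0])) {
    abort("read_length exceeds the spliced length of an expressed isoform",
      class = "pexquant_config_error"
    )
  }
  region <- gene_region(model)
  n <- protocol$total_reads
  if (n == 0 || sum(abund) == 0) {
    empty <- tibble(
      read_id = character(), isoform_id = character(), chrom = character(),
      start = integer(), end = integer(), strand = character()
    )
    return(list(
      reads = empty,
      track = depth_from_reads(empty, region, mapped_reads = 0L),
      mapped_reads = 0L
    ))
  }
  w <- switch(protocol$mode,
    uniform = abund * lens,
    three_prime = abund
  )
  sim <- function() {
    iso_draw <- sample(names(w), n, replace = TRUE, prob = w)
    s <- integer(n)
    for (nm in names(w)) {
      idx <- which(iso_draw == nm)
      if (!length(idx)) next
      L <- lens[[nm]]
      if (protocol$mode == "uniform") {
        s[idx] <- as.integer(floor(runif(length(idx), 0, L - rl + 1)))
        s[idx] <- pmin(s[idx], L - rl) # guard the open upper bound
      } else {
        # truncated exponential offset of the read end from the 3' end
        dmax <- L - rl
        u <- runif(length(idx))
        d <- -protocol$decay_length * log(1 - u * (1 - exp(-(dmax + 1) / protocol$decay_length)))
        s[idx] <- L - rl - pmin(as.integer(floor(d)), dmax)
      }
    }
    tibble(
      read_id = sprintf("r%07d", seq_len(n)),
      isoform_id = iso_draw, sp_start = s
    )
  }
  reads_sp <- if (is.null(seed)) sim() else withr::with_seed(seed, sim())
  blocks <- dplyr::bind_rows(
    map_spliced_reads(
      filter(reads_sp, .data$isoform_id == "inclusion"), model, iso_inc, rl
    ),
    map_spliced_reads(
      filter(reads_sp, .data$isoform_id == "exclusion"), model, iso_exc, rl
    )
  ) %>% arrange(.data$read_id, .data$start)
  list(
    reads = blocks,
    track = depth_from_reads(blocks, region, mapped_reads = n),
    mapped_reads = n
  )
}

# Map spliced read intervals [sp_start, sp_start + rl) of one isoform onto
# genomic blocks; vectorised over reads via expansion to read x exon pairs.
map_spliced_reads <- function(reads_sp, model, isoform, rl) {
  if (!nrow(reads_sp)) {
    return(tibble(
      read_id = character(), isoform_id = character(), chrom = character(),
      start = integer(), end = integer(), strand = character()
    ))
  }
  smap <- spliced_map(model, isoform)
  s <- reads_sp$sp_start
  e <- s + rl
  i1 <- findInterval(s, smap$sp_start)
  i2 <- findInterval(e - 1L, smap$sp_start)
  nb <- i2 - i1 + 1L
  row <- rep(seq_along(s), nb)
  exon <- sequence(nb, from = i1)
  ov_s <- pmax(s[row], smap$sp_start[exon])
  ov_e <- pmin(e[row], smap$sp_end[exon])
  a <- ov_s - smap$sp_start[exon]
  b <- ov_e - smap$sp_start[exon]
  if (model$strand == "+") {
    gs <- smap$start[exon] + a
    ge <- smap$start[exon] + b
  } else {
    gs <- smap$end[exon] - b
    ge <- smap$end[exon] - a
  }
  tibble(
    read_id = reads_sp$read_id[row],
    isoform_id = reads_sp$isoform_id[row],
    chrom = model$chrom,
    start = as.integer(gs), end = as.integer(ge),
    strand = model$strand
  )
}

#' Write / read aligned read blocks as BED6
#'
#' One BED line per aligned block; the read id is kept in the name column,
#' so junction reads appear as multiple lines sharing a name.
#'
#' @param reads Tibble of blocks as returned by [simulate_reads()].
#' @param path File path.
#' @export
write_reads_bed <- function(reads, path) {
  bed <- tibble(
    chrom = reads$chrom, start = reads$start, end = reads$end,
    name = reads$read_id, score = 0L, strand = reads$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_reads_bed
#' @return `read_reads_bed()` returns the block tibble.
#' @export
read_reads_bed <- function(path) {
  bed <- readr::read_tsv(path,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = "ciicic"
  )
  tibble(
    read_id = bed$name, isoform_id = NA_character_, chrom = bed$chrom,
    start = bed$start, end = bed$end, strand = bed$strand
  )
}
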