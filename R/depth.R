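#' Per-base depth track over a gene region
#'
#' A `depth_track` stores non-negative per-base coverage over a half-open
#' genomic window `[start, end)` plus the library's mapped-read total used
#' for across-sample normalisation. Positions are 0-based internally; the
#' on-disk samtools-depth dialect is 1-based.
#'
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open window.
#' @param depth Integer vector of length `end - start` (recycled from 0).
#' @param mapped_reads Mapped reads in the library (NA if unknown).
#' @return An object of class `depth_track`.
#' @export
depth_track <- function(chrom, start, end, depth = NULL, mapped_reads = NA_integer_) {
  start <- as.integer(start)
  end <- as.integer(end)
  stopifnot(end > start)
  if (is.null(depth)) depth <- integer(end - start)
  stopifnot(length(depth) == end - start, all(depth >= 0))
  structure(
    list(
      chrom = chrom, start = start, end = end,
      depth = as.numeric(depth), mapped_reads = mapped_reads
    ),
    class = "depth_track"
  )
}

#' @export
print.depth_track <- function(x, ...) {
  cat(
    "<depth_track> ", x$chrom, ":", x$start, "-", x$end, " (",
    x$end - x$start, " bp), total depth ", sum(x$depth),
    ", mapped reads ", x$mapped_reads, "\n",
    sep = ""
  )
  invisible(x)
}

#' @method as_tibble depth_track
#' @export
as_tibble.depth_track <- function(x, ...) {
  tibble(chrom = x$chrom, pos = seq.int(x$start, x$end - 1L), depth = x$depth)
}

as_region <- function(region) {
  if (inherits(region, "gene_model")) {
    return(gene_region(region))
  }
  stopifnot(is.list(region), all(c("chrom", "start", "end") %in% names(region)))
  region
}

#' Pile up aligned read blocks into a depth track
#'
#' Depth at a base is the number of aligned blocks overlapping it
#' (difference-array accumulation, exact).
#'
#' @param reads Tibble with `chrom`, `start`, `end` (0-based half-open
#'   aligned blocks), e.g. from [simulate_reads()] or [read_reads_bed()].
#' @param region A list `(chrom, start, end)` or a [gene_model()] whose
#'   exon span defines the window.
#' @param mapped_reads Library total to store on the track; defaults to the
#'   number of distinct `read_id`s (or rows).
#' @return A [depth_track()].
#' @export
depth_from_reads <- function(reads, region, mapped_reads = NULL) {
  region <- as_region(region)
  if (is.null(mapped_reads)) {
    mapped_reads <- if ("read_id" %in% names(reads)) {
      dplyr::n_distinct(reads$read_id)
    } else {
      nrow(reads)
    }
  }
  n <- region$end - region$start
  diffs <- numeric(n + 1L)
  if (nrow(reads)) {
    keep <- reads$chrom == region$chrom & reads$end > region$start &
      reads$start < region$end
    s <- pmax(reads$start[keep], region$start) - region$start
    e <- pmin(reads$end[keep], region$end) - region$start
    diffs[1:n] <- tabulate(s + 1L, nbins = n)
    diffs[2:(n + 1)] <- diffs[2:(n + 1)] - tabulate(e, nbins = n)
  }
  depth_track(region$chrom, region$start, region$end,
    depth = cumsum(diffs[1:n]), mapped_reads = mapped_reads
  )
}

#' Read / write per-base depth in samtools-depth format
#'
#' Three tab-separated columns without header: chromosome, 1-based position,
#' depth. Positions absent from the file are depth 0; by default only
#' non-zero positions are written (matching `samtools depth` without `-a`).
#'
#' @param path File path.
#' @param region Window for the returned track (list or [gene_model()]);
#'   when `NULL` the file's position span is used.
#' @param mapped_reads Library total to store on the track.
#' @return `load_depth()` returns a [depth_track()].
#' @export
load_depth <- function(path, region = NULL, mapped_reads = NA_integer_) {
  tab <- readr::read_tsv(path,
    col_names = c("chrom", "pos", "depth"), col_types = "cdd",
    progress = FALSE
  )
  if (nrow(tab) && (any(tab$pos != floor(tab$pos)) || any(tab$depth != floor(tab$depth)) ||
    any(tab$depth < 0))) {
    abort("depth file must contain integer positions and non-negative integer depths",
      class = "pexquant_format_error"
    )
  }
  pos0 <- tab$pos - 1L # 1-based on disk -> 0-based internal
  if (is.null(region)) {
    if (!nrow(tab)) {
      abort("cannot infer a region from an empty depth file; supply `region`",
        class = "pexquant_input_error"
      )
    }
    region <- list(chrom = tab$chrom[1], start = min(pos0), end = max(pos0) + 1L)
  } else {
    region <- as_region(region)
  }
  depth <- numeric(region$end - region$start)
  keep <- nrow(tab) > 0 & tab$chrom == region$chrom & pos0 >= region$start &
    pos0 < region$end
  depth[pos0[keep] - region$start + 1L] <- tab$depth[keep]
  depth_track(region$chrom, region$start, region$end,
    depth = depth, mapped_reads = mapped_reads
  )
}

#' @rdname load_depth
#' @param track A [depth_track()].
#' @param keep_zero Also write zero-depth positions.
#' @export
write_depth <- function(track, path, keep_zero = FALSE) {
  tab <- as_tibble(track) %>% mutate(pos = .data$pos + 1L)
  if (!keep_zero) tab <- filter(tab, .data$depth > 0)
  readr::write_tsv(tab, path, col_names = FALSE)
  invisible(path)
}
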