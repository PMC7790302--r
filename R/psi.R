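#' Per-exon depth summary of a track
#'
#' @param track A [depth_track()].
#' @param model A [gene_model()] whose exons lie within the track window.
#' @return Tibble: `exon_id`, `kind`, `length`, `total_depth`,
#'   `mean_depth` (= total / length; uncovered bases count as 0, they are
#'   not dropped).
#' @export
exon_depth_summary <- function(track, model) {
  stopifnot(inherits(track, "depth_track"), inherits(model, "gene_model"))
  if (model$chrom != track$chrom ||
    min(model$exons$start) < track$start || max(model$exons$end) > track$end) {
    abort("model exons must lie within the depth-track window",
      class = "pexquant_input_error"
    )
  }
  model$exons %>%
    mutate(
      total_depth = purrr::map2_dbl(
        .data$start, .data$end,
        function(s, e) sum(track$depth[(s - track$start + 1L):(e - track$start)])
      ),
      mean_depth = .data$total_depth / .data$length
    ) %>%
    select("exon_id", "kind", "length", "total_depth", "mean_depth")
}

#' Coverage-based percent poison-exon usage
#'
#' The coverage statistic: mean per-base depth over the poison-exon bases
#' divided by mean per-base depth over all annotated exon bases, times 100.
#' The denominator pools bases across exons by default (every exon base
#' contributes equally); `averaging = "per_exon_mean"` instead averages the
#' per-exon mean depths. The poison exon itself is part of the "all exons"
#' denominator unless `denominator = "exclude_poison"`. A within-sample
#' ratio cancels any library-size normalisation, so the statistic is
#' invariant to scaling every depth by a constant.
#'
#' @inheritParams exon_depth_summary
#' @param denominator `"all"` (literal formula, poison exon included) or
#'   `"exclude_poison"`.
#' @param averaging `"pooled"` bases (default) or `"per_exon_mean"`.
#' @return One-row tibble: `usage_percent` (NA with a warning when the
#'   denominator is 0 - undefined, not 0), `poison_mean_depth`,
#'   `exon_mean_depth`, `mapped_reads`.
#' @export
#' @examples
#' gm <- scn1a_gene_model(with_sequence = FALSE)
#' wt <- genotype_spec("+/+", allele_params(1, 0.7), allele_params(1, 0.7))
#' pool <- steady_state_pool(wt, nmd_params(s = 1))
#' sim <- simulate_reads(pool, gm, library_protocol("uniform", total_reads = 2e4), seed = 1)
#' poison_usage_percent(sim$track, gm)
poison_usage_percent <- function(track, model,
                                 denominator = c("all", "exclude_poison"),
                                 averaging = c("pooled", "per_exon_mean")) {
  denominator <- match.arg(denominator)
  averaging <- match.arg(averaging)
  summ <- exon_depth_summary(track, model)
  if (!nrow(summ)) {
    abort("gene model has no exons", class = "pexquant_config_error")
  }
  usage_from_summary(summ, denominator, averaging, track$mapped_reads)
}

usage_from_summary <- function(summ, denominator, averaging, mapped_reads) {
  pois <- filter(summ, .data$kind == "poison")
  den_tab <- if (denominator == "all") summ else filter(summ, .data$kind != "poison")
  num <- sum(pois$total_depth) / sum(pois$length)
  den <- if (averaging == "pooled") {
    sum(den_tab$total_depth) / sum(den_tab$length)
  } else {
    mean(den_tab$mean_depth)
  }
  usage <- if (den > 0) 100 * num / den else NA_real_
  if (is.na(usage)) {
    warn("all-exon mean depth is 0; usage percent is undefined (NA)")
  }
  tibble(
    usage_percent = usage, poison_mean_depth = num, exon_mean_depth = den,
    mapped_reads = mapped_reads
  )
}

#' Percent poison-exon usage from exon read counts
#'
#' The same contract as [poison_usage_percent()] computed at count
#' resolution: each exon's mean per-base depth is approximated by
#' `count / length`.
#'
#' @param counts Tibble with columns `exon_id`, `count` and optionally
#'   `sample` (computed per sample when present).
#' @inheritParams poison_usage_percent
#' @return A tibble with one row (per sample): `sample` (if given),
#'   `usage_percent`, `poison_mean_depth`, `exon_mean_depth`.
#' @export
usage_percent_from_counts <- function(counts, model,
                                      denominator = c("all", "exclude_poison"),
                                      averaging = c("pooled", "per_exon_mean")) {
  denominator <- match.arg(denominator)
  averaging <- match.arg(averaging)
  stopifnot(all(c("exon_id", "count") %in% names(counts)))
  unknown <- setdiff(counts$exon_id, model$exons$exon_id)
  if (length(unknown)) {
    abort(paste("counts refer to unknown exons:", paste(unknown, collapse = ", ")),
      class = "pexquant_input_error"
    )
  }
  one <- function(tab) {
    summ <- model$exons %>%
      left_join(select(tab, "exon_id", "count"), by = "exon_id") %>%
      mutate(
        total_depth = ifelse(is.na(.data$count), 0, .data$count),
        mean_depth = .data$total_depth / .data$length
      ) %>%
      select("exon_id", "kind", "length", "total_depth", "mean_depth")
    usage_from_summary(summ, denominator, averaging, NA_integer_)
  }
  if ("sample" %in% names(counts)) {
    counts %>%
      group_by(.data$sample) %>%
      dplyr::group_modify(~ one(.x)) %>%
      ungroup()
  } else {
    one(counts)
  }
}

#' Count reads per exon
#'
#' A read increments every exon it overlaps by at least one base, once per
#' exon (union-style semantics: a junction read supports both of its
#' exons). Overlap is computed on the aligned blocks.
#'
#' @param reads Tibble of aligned blocks (`read_id`, `chrom`, `start`,
#'   `end`).
#' @param model A [gene_model()].
#' @return Tibble: `exon_id`, `kind`, `length`, `count`.
#' @export
exon_read_counts <- function(reads, model) {
  stopifnot(inherits(model, "gene_model"))
  counts <- purrr::map_int(seq_len(nrow(model$exons)), function(i) {
    ex <- model$exons[i, ]
    hit <- reads$chrom == model$chrom & reads$start < ex$end & reads$end > ex$start
    dplyr::n_distinct(reads$read_id[hit])
  })
  model$exons %>%
    mutate(count = counts) %>%
    select("exon_id", "kind", "length", "count")
}

#' Median-of-ratios library size factors
#'
#' For each sample the factor is the median, over features whose geometric
#' mean across samples is positive, of the ratio of the sample's count to
#' that geometric mean (the DESeq-style size factor). Normalised counts are
#' counts divided by the factor.
#'
#' @param counts A numeric matrix (features x samples) or a data frame with
#'   a `feature` id column followed by one numeric column per sample.
#' @return Tibble: `sample`, `size_factor`.
#' @export
#' @examples
#' m <- cbind(s1 = c(10, 100, 4), s2 = c(20, 200, 8))
#' size_factors(m)
size_factors <- function(counts) {
  if (is.data.frame(counts)) {
    idcol <- which(!vapply(counts, is.numeric, logical(1)))
    m <- as.matrix(counts[setdiff(seq_along(counts), idcol)])
  } else {
    m <- as.matrix(counts)
  }
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  log_gm <- rowMeans(log(m))
  use <- is.finite(log_gm)
  if (!any(use)) {
    abort(paste(
      "no feature has non-zero counts in every sample;",
      "median-of-ratios needs at least one such feature"
    ), class = "pexquant_input_error")
  }
  sf <- apply(m[use, , drop = FALSE], 2, function(col) {
    exp(median(log(col) - log_gm[use]))
  })
  tibble(sample = colnames(m), size_factor = unname(sf))
}

#' Normalise a count matrix by size factors
#'
#' @param counts As in [size_factors()].
#' @param factors Optional tibble from [size_factors()]; computed if
#'   missing.
#' @return The counts with each sample column divided by its factor
#'   (matrix in, matrix out; data frame in, tibble out).
#' @export
normalize_counts <- function(counts, factors = NULL) {
  factors <- factors %||% size_factors(counts)
  if (is.data.frame(counts)) {
    out <- as_tibble(counts)
    for (i in seq_len(nrow(factors))) {
      out[[factors$sample[i]]] <- out[[factors$sample[i]]] / factors$size_factor[i]
    }
    out
  } else {
    sweep(counts, 2, setNames(factors$size_factor, factors$sample)[colnames(counts)], "/")
  }
}
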