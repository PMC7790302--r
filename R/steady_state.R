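#' Allele, NMD and genotype parameter constructors
#'
#' The two-allele steady-state model: each allele transcribes at rate `T`
#' (arbitrary units) and splices the poison exon in with propensity
#' `psi` in `[0, 1]`. Poison-including transcripts are degraded by
#' nonsense-mediated decay, of which only a fraction `s` survives at steady
#' state; excluded transcripts are stable. Hence per allele the stable pool
#' holds `T * (1 - psi)` excluded and `T * psi * s` included transcripts.
#'
#' @param T_rate Transcription rate, > 0.
#' @param psi Poison-exon inclusion propensity in `[0, 1]`.
#' @return `allele_params()`: a one-row tibble with `T_rate`, `psi`.
#' @export
allele_params <- function(T_rate = 1, psi = 0) {
  stopifnot(T_rate > 0, psi >= 0, psi <= 1)
  tibble(T_rate = T_rate, psi = psi)
}

#' @rdname allele_params
#' @param s Survival fraction of poison-including transcripts in `[0, 1]`.
#' @return `nmd_params()`: a list with `s`.
#' @export
nmd_params <- function(s = 0.031) {
  stopifnot(s >= 0, s <= 1)
  list(s = s)
}

#' @rdname allele_params
#' @param label Genotype label, e.g. `"+/+"` or `"+/KI"`.
#' @param allele1,allele2 [allele_params()] for the two alleles.
#' @return `genotype_spec()`: a list with `label` and an `alleles` tibble
#'   (two rows).
#' @export
genotype_spec <- function(label, allele1, allele2) {
  alleles <- dplyr::bind_rows(allele1, allele2)
  stopifnot(nrow(alleles) == 2)
  list(label = label, alleles = mutate(alleles, allele = c("a1", "a2"), .before = 1))
}

#' Steady-state stable transcript pool of a genotype
#'
#' Closed-form evaluation of the two-allele splicing/decay model: per allele
#' `excluded = T * (1 - psi)` and `included = T * psi * s`. The observed
#' stable inclusion fraction is `sum(included) / sum(included + excluded)` -
#' the quantity that both the qPCR amplicon ratio and the coverage statistic
#' estimate.
#'
#' @param genotype A [genotype_spec()].
#' @param nmd [nmd_params()].
#' @return An object of class `stable_pool`: a tibble with one row per
#'   allele (`allele`, `T_rate`, `psi`, `excluded`, `included`) carrying the
#'   genotype label as an attribute; see [pool_summary()].
#' @export
#' @examples
#' wt <- genotype_spec("+/+", allele_params(1, 0.24), allele_params(1, 0.24))
#' pool_summary(steady_state_pool(wt, nmd_params(0.031)))
steady_state_pool <- function(genotype, nmd) {
  pool <- genotype$alleles %>%
    mutate(
      excluded = .data$T_rate * (1 - .data$psi),
      included = .data$T_rate * .data$psi * nmd$s
    )
  structure(pool, class = c("stable_pool", class(pool)), label = attr(genotype, "label") %||% genotype$label)
}

#' Summarise a stable pool
#'
#' @param pool A `stable_pool` from [steady_state_pool()].
#' @return One-row tibble: `label`, `total` stable abundance,
#'   `included` abundance, `inclusion_fraction`.
#' @export
pool_summary <- function(pool) {
  total <- sum(pool$excluded + pool$included)
  inc <- sum(pool$included)
  tibble(
    label = attr(pool, "label") %||% NA_character_,
    total = total, included = inc,
    inclusion_fraction = if (total > 0) inc / total else NA_real_
  )
}
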