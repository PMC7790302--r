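#' qPCR assay model parameters
#'
#' Ct values are generated as `ct = ct_intercept - log_E(quantity) + noise`
#' with Gaussian noise on the Ct scale; an expected Ct beyond `ct_max` (or a
#' zero quantity) is reported as undetectable (UD, stored as `NA`).
#' `ct_intercept` is the Ct of a unit quantity. Efficiency `E` is the
#' per-cycle amplification factor: with `E = 2` halving the template raises
#' Ct by exactly one cycle.
#'
#' @param efficiency Amplification efficiency in `(1, 2]`; a scalar or a
#'   named vector with entries `amplicon2`, `amplicon3`, `reference`.
#' @param ct_intercept Ct of a unit quantity, cycles.
#' @param noise_sd Ct noise standard deviation, cycles.
#' @param ct_max Detection limit, cycles.
#' @param ref_quantity Fixed reference-assay quantity per tissue.
#' @param seed Optional integer seed stored with the parameters.
#' @return A list of class `qpcr_params`.
#' @export
qpcr_params <- function(efficiency = 2, ct_intercept = 22.2, noise_sd = 0.15,
                        ct_max = 40, ref_quantity = 1, seed = NULL) {
  stopifnot(all(efficiency > 1), all(efficiency <= 2), noise_sd >= 0, ct_max > 0)
  structure(
    list(
      efficiency = efficiency, ct_intercept = ct_intercept,
      noise_sd = noise_sd, ct_max = ct_max, ref_quantity = ref_quantity,
      seed = seed
    ),
    class = "qpcr_params"
  )
}

assay_efficiency <- function(params, assay) {
  e <- params$efficiency
  if (length(e) == 1 && is.null(names(e))) {
    return(unname(e))
  }
  if (!assay %in% names(e)) {
    abort(paste("no efficiency given for assay", assay),
      class = "pexquant_config_error"
    )
  }
  unname(e[[assay]])
}

# one quantity -> one Ct (NA = UD)
quantity_to_ct <- function(q, E, params, noise) {
  if (q <= 0) {
    return(NA_real_)
  }
  ct <- params$ct_intercept - log(q, base = E) + noise
  if (ct > params$ct_max) NA_real_ else ct
}

#' Simulate a long-format qPCR Ct table from a stable pool
#'
#' Emulates the three-assay design used to measure poison-exon inclusion:
#' the junction-specific assay (`amplicon2`) templates on the included
#' stable abundance, the total-transcript assay (`amplicon3`) on the whole
#' stable pool, and a housekeeping `reference` assay on a fixed per-tissue
#' quantity. One record per animal and assay; undetectable reactions are
#' `NA` in the `ct` column.
#'
#' @param pool A `stable_pool` from [steady_state_pool()].
#' @param params [qpcr_params()].
#' @param n Number of animals.
#' @param tissue,genotype Metadata for the records; `genotype` defaults to
#'   the pool's label.
#' @param sample_prefix Prefix for generated sample ids.
#' @param model Optional [gene_model()] with primers: when supplied, the
#'   template availability of the junction assay is checked by in-silico PCR
#'   (it must amplify the inclusion isoform only).
#' @param seed Integer seed; defaults to the parameters'.
#' @return A tibble with columns `sample_id`, `tissue`, `genotype`,
#'   `assay`, `ct`.
#' @export
simulate_qpcr <- function(pool, params, n = 1L, tissue = "brain",
                          genotype = NULL, sample_prefix = NULL,
                          model = NULL, seed = params$seed) {
  stopifnot(inherits(params, "qpcr_params"))
  genotype <- genotype %||% attr(pool, "label") %||% "NA"
  sample_prefix <- sample_prefix %||% gsub("[^A-Za-z0-9]", "", genotype)
  if (!is.null(model) && !is.null(model$primers) &&
    "amplicon2" %in% model$primers$name) {
    p2 <- filter(model$primers, .data$name == "amplicon2")
    prod <- dplyr::bind_rows(
      in_silico_pcr(model, p2, transcript_isoform(model, TRUE)),
      in_silico_pcr(model, p2, transcript_isoform(model, FALSE))
    )
    if (is.na(prod$product_length[1]) || !is.na(prod$product_length[2])) {
      abort("junction assay must amplify the inclusion isoform only",
        class = "pexquant_config_error"
      )
    }
  }
  quantities <- c(
    amplicon2 = sum(pool$included),
    amplicon3 = sum(pool$included) + sum(pool$excluded),
    reference = params$ref_quantity
  )
  sim <- function() {
    purrr::map_dfr(seq_len(n), function(i) {
      purrr::map_dfr(names(quantities), function(a) {
        tibble(
          sample_id = sprintf("%s_%02d", sample_prefix, i),
          tissue = tissue, genotype = genotype, assay = a,
          ct = quantity_to_ct(
            quantities[[a]], assay_efficiency(params, a), params,
            rnorm(1, 0, params$noise_sd)
          )
        )
      })
    })
  }
  if (is.null(seed)) sim() else withr::with_seed(seed, sim())
}

#' Read / write long-format Ct tables
#'
#' CSV with columns `sample_id`, `tissue`, `genotype`, `assay`, `ct`.
#' Undetectable reactions are written as the literal `UD` and read back as
#' `NA`; UD is a first-class value throughout the package, never dropped.
#'
#' @param path File path.
#' @return `read_ct_table()` returns the tibble with numeric `ct`.
#' @export
read_ct_table <- function(path) {
  tab <- readr::read_csv(path,
    col_types = readr::cols(
      sample_id = "c", tissue = "c", genotype = "c", assay = "c", ct = "c"
    ), progress = FALSE
  )
  ud <- !is.na(tab$ct) & toupper(trimws(tab$ct)) == "UD"
  ct <- suppressWarnings(as.numeric(tab$ct))
  if (any(is.na(ct) & !ud & !is.na(tab$ct))) {
    abort("ct column must be numeric or the literal 'UD'",
      class = "pexquant_format_error"
    )
  }
  ct[ud] <- NA_real_
  tab$ct <- ct
  tab
}

#' @rdname read_ct_table
#' @param ct_table Tibble as produced by [simulate_qpcr()].
#' @export
write_ct_table <- function(ct_table, path) {
  out <- mutate(ct_table, ct = ifelse(is.na(.data$ct), "UD", format(.data$ct, digits = 10)))
  readr::write_csv(out, path)
  invisible(path)
}
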