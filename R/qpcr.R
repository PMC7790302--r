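#' Delta-Ct relative to a reference assay
#'
#' `delta_ct = ct_target - ct_reference`, vectorised. An undetectable
#' target (NA) propagates to an undetectable delta-Ct; an undetectable
#' reference is an error, since the housekeeping assay must amplify for the
#' comparison to mean anything.
#'
#' @param ct_target,ct_reference Ct values in cycles (NA = undetectable).
#' @return Numeric vector of delta-Ct values.
#' @export
#' @examples
#' delta_ct(21.6, 23.7) # -2.1
delta_ct <- function(ct_target, ct_reference) {
  if (anyNA(ct_reference)) {
    abort("reference Ct is undetectable; the reference assay must amplify",
      class = "pexquant_input_error"
    )
  }
  ct_target - ct_reference
}

#' Relative expression from delta-Ct
#'
#' `E^(-delta_ct)`: the fold level of the target relative to the reference
#' gene, assuming per-cycle amplification factor `efficiency`.
#'
#' @param dct Delta-Ct values (cycles).
#' @param efficiency Amplification efficiency, default 2 (perfect
#'   doubling).
#' @return Numeric vector of fold levels.
#' @export
relative_expression <- function(dct, efficiency = 2) {
  stopifnot(all(efficiency > 1), all(efficiency <= 2))
  efficiency^(-dct)
}

#' Percent poison-exon inclusion from the amplicon Ct pair
#'
#' The amplicon-ratio estimator: inclusion percent = 100 x (level of the
#' junction assay) / (level of the total assay), with levels `E^(-ct)`. With
#' both efficiencies 2 this is `100 * 2^(ct_total - ct_junction)`. Adding a
#' constant to both Cts cancels, so the calibration intercept drops out. An
#' undetectable junction assay yields an upper bound computed at the
#' detection limit (`is_bound = TRUE`); an undetectable total assay is an
#' error.
#'
#' @param ct_amp2 Junction-assay Ct (NA = undetectable).
#' @param ct_amp3 Total-assay Ct.
#' @param e2,e3 Assay efficiencies.
#' @param ct_max Detection limit used for the upper bound.
#' @return Tibble: `percent`, `is_bound`.
#' @export
#' @examples
#' inclusion_percent_from_ct(28.3, 21.6) # ~0.96 %
inclusion_percent_from_ct <- function(ct_amp2, ct_amp3, e2 = 2, e3 = 2,
                                      ct_max = 40) {
  if (anyNA(ct_amp3)) {
    abort("total-assay Ct is undetectable; inclusion percent is not defined",
      class = "pexquant_input_error"
    )
  }
  is_bound <- is.na(ct_amp2)
  ct2 <- ifelse(is_bound, ct_max, ct_amp2)
  tibble(
    percent = 100 * e2^(-ct2) / e3^(-ct_amp3),
    is_bound = is_bound
  )
}

#' Per-sample inclusion estimates from a long Ct table
#'
#' Pivots a long-format Ct table (assays `amplicon2`, `amplicon3`,
#' `reference`) to one row per sample and applies
#' [inclusion_percent_from_ct()]. Technical replicates (duplicate
#' sample/assay rows) are averaged on the Ct scale first; a sample whose
#' replicates are all undetectable stays undetectable.
#'
#' @param ct_table Tibble with `sample_id`, `tissue`, `genotype`, `assay`,
#'   `ct` (see [read_ct_table()]).
#' @inheritParams inclusion_percent_from_ct
#' @return Tibble: `sample_id`, `tissue`, `genotype`, `ct_amp2`,
#'   `ct_amp3`, `percent`, `is_bound`.
#' @export
qpcr_inclusion <- function(ct_table, e2 = 2, e3 = 2, ct_max = 40) {
  wide <- ct_table %>%
    filter(.data$assay %in% c("amplicon2", "amplicon3")) %>%
    group_by(.data$sample_id, .data$tissue, .data$genotype, .data$assay) %>%
    summarise(ct = mean_ct(.data$ct), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "assay", values_from = "ct") %>%
    rename(ct_amp2 = "amplicon2", ct_amp3 = "amplicon3")
  dplyr::bind_cols(
    wide,
    inclusion_percent_from_ct(wide$ct_amp2, wide$ct_amp3, e2, e3, ct_max)
  )
}

# replicate averaging on the Ct scale; all-UD stays UD
mean_ct <- function(ct) {
  if (all(is.na(ct))) NA_real_ else mean(ct, na.rm = TRUE)
}

#' Group summary and two-group comparison
#'
#' Per-group n, mean and SEM of a per-animal quantity, plus the two-tailed
#' two-sample t test between the two groups when both have n >= 2.
#' Student's pooled-variance t is the default; Welch's is available by
#' flag. Estimates that are only upper bounds (undetectable junction
#' assays) are counted and flagged, not silently mixed in: they are
#' included in the means, and `n_bound` reports how many.
#'
#' @param data A data frame of per-animal values.
#' @param value Column holding the quantity (tidy-eval).
#' @param group Grouping column (tidy-eval); the test needs exactly two
#'   groups.
#' @param welch Use Welch's unequal-variance t instead of Student's.
#' @return A list of class `group_comparison` with `summary` (tibble:
#'   group, n, mean, sem, n_bound) and `test` (one-row tibble: `t`, `df`,
#'   `p`, `method`; all NA when a group has n < 2).
#' @export
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 4, 5, 6))
#' group_summary(d, y, g)
group_summary <- function(data, value, group, welch = FALSE) {
  value <- enquo(value)
  group <- enquo(group)
  has_bound <- "is_bound" %in% names(data)
  summ <- data %>%
    group_by(!!group) %>%
    summarise(
      n = sum(!is.na(!!value)),
      mean = mean(!!value, na.rm = TRUE),
      sem = sd(!!value, na.rm = TRUE) / sqrt(sum(!is.na(!!value))),
      n_bound = if (has_bound) sum(.data$is_bound, na.rm = TRUE) else 0L,
      .groups = "drop"
    )
  test <- tibble(
    t = NA_real_, df = NA_real_, p = NA_real_,
    method = if (welch) "welch" else "student"
  )
  groups <- dplyr::pull(summ, 1)
  if (length(groups) == 2 && all(summ$n >= 2)) {
    vals <- dplyr::pull(data, !!value)
    labs <- dplyr::pull(data, !!group)
    ht <- tryCatch(
      t.test(
        vals[labs == groups[1]], vals[labs == groups[2]],
        var.equal = !welch
      ),
      error = function(e) NULL # e.g. zero variance in both groups
    )
    if (!is.null(ht)) {
      test$t <- unname(ht$statistic)
      test$df <- unname(ht$parameter)
      test$p <- ht$p.value
    }
  }
  structure(list(summary = summ, test = test), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  print(x$summary)
  if (!is.na(x$test$p)) {
    cat(sprintf(
      "%s t = %.4g, df = %.4g, two-tailed p = %.4g\n",
      x$test$method, x$test$t, x$test$df, x$test$p
    ))
  } else {
    cat("no test performed (need exactly 2 groups with n >= 2)\n")
  }
  invisible(x)
}

#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) x$summary

#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) x$test
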