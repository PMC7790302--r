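#' Plot a developmental time course of usage and expression
#'
#' Paired bars per timepoint: poison-exon usage percent against normalised
#' total expression, the canonical display of the inverse developmental
#' relationship.
#'
#' @param table Data frame with `timepoint`, `usage_percent`,
#'   `expression`.
#' @return A ggplot object.
#' @export
plot_timecourse <- function(table) {
  long <- table %>%
    mutate(
      timepoint = factor(.data$timepoint, levels = unique(.data$timepoint)),
      expression_scaled = 100 * .data$expression / max(.data$expression)
    ) %>%
    tidyr::pivot_longer(
      c("usage_percent", "expression_scaled"),
      names_to = "series", values_to = "value"
    ) %>%
    mutate(series = dplyr::recode(.data$series,
      usage_percent = "poison-exon usage (%)",
      expression_scaled = "total expression (% of max)"
    ))
  ggplot2::ggplot(long, ggplot2::aes(.data$timepoint, .data$value, fill = .data$series)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "percent", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-base coverage with the exon layout
#'
#' @param track A [depth_track()].
#' @param model A [gene_model()]; exons are shaded, the poison exon in red.
#' @return A ggplot object.
#' @export
plot_coverage <- function(track, model) {
  d <- as_tibble(track)
  ex <- model$exons
  ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = ex,
      ggplot2::aes(
        xmin = .data$start, xmax = .data$end, ymin = -Inf, ymax = Inf,
        fill = .data$kind
      ),
      alpha = 0.15
    ) +
    ggplot2::geom_step(data = d, ggplot2::aes(.data$pos, .data$depth)) +
    ggplot2::scale_fill_manual(values = c(constitutive = "grey40", poison = "red")) +
    ggplot2::labs(x = paste0(track$chrom, " position"), y = "depth", fill = "exon") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier survival curves
#'
#' @param object A `km_fit` from [kaplan_meier()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot km_fit
#' @export
autoplot.km_fit <- function(object, ...) {
  d <- as_tibble(object) %>%
    group_by(.data$group) %>%
    dplyr::group_modify(~ dplyr::add_row(.x,
      time = 0, survival = 1, .before = 1
    )) %>%
    ungroup()
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$survival, colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "survival", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
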