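#' Breeding-cohort plan: weaning composition and survival
#'
#' Emulates a heterozygote x wild-type cross followed from weaning: each
#' weaned pup is knock-in with probability `ki_prob` (0.5 under Mendelian
#' expectation; the default 0.27 reflects a pre-weaning deficit of knock-in
#' pups), and post-weaning survival is exponential with a genotype-specific
#' hazard, censored administratively at `horizon` months.
#'
#' @param n Total number of weaned animals, or a named 2-vector of fixed
#'   per-genotype counts (e.g. `c("+/+" = 50, "+/KI" = 50)`), in which case
#'   no Bernoulli draw is made.
#' @param ki_prob Probability that a weaned pup is `+/KI`.
#' @param hazards Named per-month hazards for `"+/+"` and `"+/KI"`.
#' @param horizon Follow-up horizon in months (censoring time).
#' @param seed Optional integer seed stored with the plan.
#' @return A list of class `cohort_plan`.
#' @export
cohort_plan <- function(n = 73L, ki_prob = 0.27,
                        hazards = c("+/+" = 0.005, "+/KI" = 0.05),
                        horizon = 18, seed = NULL) {
  stopifnot(ki_prob >= 0, ki_prob <= 1, all(hazards >= 0), horizon > 0)
  stopifnot(length(hazards) == 2, !is.null(names(hazards)))
  structure(
    list(
      n = n, ki_prob = ki_prob, hazards = hazards, horizon = horizon,
      seed = seed
    ),
    class = "cohort_plan"
  )
}

#' Simulate a weaning + survival cohort
#'
#' @param plan A [cohort_plan()].
#' @param seed Integer seed; defaults to the plan's.
#' @return A list with `weaning` (tibble `genotype`, `n`) and `survival`
#'   (tibble `subject_id`, `genotype`, `time_months`, `event`; `event` is 1
#'   for death, 0 for censoring at the horizon).
#' @export
simulate_cohort <- function(plan, seed = plan$seed) {
  stopifnot(inherits(plan, "cohort_plan"))
  labels <- names(plan$hazards)
  run <- function() {
    if (length(plan$n) == 2) {
      genotype <- rep(names(plan$n), plan$n)
    } else {
      ki <- rbinom(plan$n, 1, plan$ki_prob)
      genotype <- ifelse(ki == 1, labels[2], labels[1])
    }
    h <- unname(plan$hazards[genotype])
    t_event <- ifelse(h > 0, rexp(length(genotype), pmax(h, 1e-300)), Inf)
    time <- pmin(t_event, plan$horizon)
    event <- as.integer(t_event <= plan$horizon)
    weaning <- tibble(genotype = factor(genotype, levels = labels)) %>%
      count(.data$genotype, .drop = FALSE, name = "n") %>%
      mutate(genotype = as.character(.data$genotype))
    list(
      weaning = weaning,
      survival = tibble(
        subject_id = sprintf("m%04d", seq_along(genotype)),
        genotype = genotype, time_months = time, event = event
      )
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Read / write survival records as CSV
#'
#' Columns `subject_id`, `genotype`, `time_months`, `event` (1 = death,
#' 0 = censored).
#'
#' @param path File path.
#' @export
read_survival_table <- function(path) {
  readr::read_csv(path,
    col_types = readr::cols(
      subject_id = "c", genotype = "c", time_months = "d", event = "i"
    ), progress = FALSE
  )
}

#' @rdname read_survival_table
#' @param survival Tibble of survival records.
#' @export
write_survival_table <- function(survival, path) {
  readr::write_csv(survival, path)
  invisible(path)
}
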