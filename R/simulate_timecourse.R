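#' Developmental time-course plan
#'
#' Describes a declining poison-exon inclusion trajectory with reciprocally
#' rising total expression, the pattern seen for sodium-channel poison exons
#' in developing brain: high fetal inclusion (~70% at the earliest
#' timepoint) falling to below 10% by P30 while total transcript output
#' rises. Inclusion follows a logistic decline in age, rescaled to hit
#' `psi_start` and `psi_end` exactly at the first and last timepoints;
#' expression interpolates linearly against the inclusion decline, which
#' makes the two series anti-monotone by construction. The trajectory
#' specifies the *stable* inclusion fraction at each age (fetal
#' poison-including transcripts are what the coverage data actually see),
#' so the per-timepoint pools are built with decay already absorbed.
#'
#' @param timepoints Character labels, in age order.
#' @param ages Numeric ages (days, postnatal = positive) matching
#'   `timepoints`.
#' @param psi_start,psi_end Stable inclusion fraction at the first / last
#'   timepoint.
#' @param midpoint,steepness Age of half-decline and logistic scale (days).
#' @param expression_start,expression_end Total transcription at first /
#'   last timepoint (arbitrary units).
#' @return A list of class `timecourse_plan`.
#' @export
timecourse_plan <- function(timepoints = c("E14.5", "E16.5", "P0", "P7", "P15", "P30", "P120"),
                            ages = c(-5, -3, 0, 7, 15, 30, 120),
                            psi_start = 0.70, psi_end = 0.08,
                            midpoint = 5, steepness = 6,
                            expression_start = 0.3, expression_end = 1) {
  stopifnot(length(timepoints) == length(ages), !is.unsorted(ages, strictly = TRUE))
  if (psi_start < psi_end) {
    abort("inclusion trajectory must be non-increasing (psi_start >= psi_end)",
      class = "pexquant_config_error"
    )
  }
  if (expression_end < expression_start) {
    abort("expression trajectory must be non-decreasing",
      class = "pexquant_config_error"
    )
  }
  stopifnot(psi_start >= 0, psi_start <= 1, psi_end >= 0, psi_end <= 1, steepness > 0)
  structure(
    list(
      timepoints = timepoints, ages = ages, psi_start = psi_start,
      psi_end = psi_end, midpoint = midpoint, steepness = steepness,
      expression_start = expression_start, expression_end = expression_end
    ),
    class = "timecourse_plan"
  )
}

#' Evaluate a time-course plan's trajectories
#'
#' @param plan A [timecourse_plan()].
#' @return Tibble: `timepoint`, `age`, `psi_true`, `expression`.
#' @export
timecourse_trajectory <- function(plan) {
  f <- function(t) 1 / (1 + exp((t - plan$midpoint) / plan$steepness))
  t <- plan$ages
  if (plan$psi_start == plan$psi_end || f(t[1]) == f(t[length(t)])) {
    psi <- rep(plan$psi_start, length(t))
  } else {
    frac <- (f(t) - f(t[length(t)])) / (f(t[1]) - f(t[length(t)]))
    psi <- plan$psi_end + (plan$psi_start - plan$psi_end) * frac
  }
  decline <- if (plan$psi_start == plan$psi_end) {
    seq(0, 1, length.out = length(t))
  } else {
    (plan$psi_start - psi) / (plan$psi_start - plan$psi_end)
  }
  expr <- plan$expression_start +
    (plan$expression_end - plan$expression_start) * decline
  tibble(
    timepoint = plan$timepoints, age = t,
    psi_true = psi, expression = expr
  )
}

#' Simulate an RNA-seq developmental time course
#'
#' For each timepoint the stable pool implied by the plan (both alleles at
#' the timepoint's stable inclusion fraction, total transcription split
#' equally) is read-simulated independently under `protocol`.
#'
#' @param plan A [timecourse_plan()].
#' @param model A [gene_model()].
#' @param protocol A [library_protocol()]; its `total_reads` is scaled by
#'   the timepoint's relative expression so that total output rises as
#'   inclusion falls.
#' @param seed Integer seed governing all timepoints.
#' @return A tibble with one row per timepoint: `timepoint`, `age`,
#'   `psi_true`, `expression`, `mapped_reads`, plus list-columns `pool`,
#'   `reads`, `track`.
#' @export
simulate_timecourse <- function(plan, model, protocol, seed = protocol$seed) {
  stopifnot(inherits(plan, "timecourse_plan"))
  traj <- timecourse_trajectory(plan)
  run <- function() {
    purrr::pmap_dfr(
      traj,
      function(timepoint, age, psi_true, expression) {
        gt <- genotype_spec(
          timepoint,
          allele_params(T_rate = expression / 2, psi = psi_true),
          allele_params(T_rate = expression / 2, psi = psi_true)
        )
        pool <- steady_state_pool(gt, nmd_params(s = 1)) # stable fraction given directly
        n_reads <- as.integer(round(protocol$total_reads * expression /
          max(traj$expression)))
        prot <- protocol
        prot$total_reads <- n_reads
        sim <- simulate_reads(pool, model, prot, seed = NULL)
        tibble(
          timepoint = timepoint, age = age, psi_true = psi_true,
          expression = expression, mapped_reads = sim$mapped_reads,
          pool = list(pool), reads = list(sim$reads), track = list(sim$track)
        )
      }
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
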