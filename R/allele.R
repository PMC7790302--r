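#' Per-allele inclusion baseline under the additive model
#'
#' Under the additive assumption - neither allele influences the other - the
#' two wild-type alleles contribute equally, so the per-allele baseline is
#' half the observed homozygote inclusion percentage.
#'
#' @param psi_obs_wt Observed inclusion percent in the wild-type
#'   homozygote.
#' @return Percent attributable to one allele.
#' @export
per_allele_baseline <- function(psi_obs_wt) {
  stopifnot(all(psi_obs_wt >= 0))
  psi_obs_wt / 2
}

#' Fold increase in stable poison-including transcripts due to the KI allele
#'
#' The literal additive-model arithmetic: the observed heterozygote
#' inclusion percent over the per-allele baseline
#' (`psi_obs_ki / (psi_obs_wt / 2)`), attributing the heterozygote's
#' inclusion predominantly to the knock-in allele. With the published
#' values (0.97, 4.8) this reproduces the ~10-fold figure. The
#' `"corrected"` variant first subtracts the wild-type allele's expected
#' contribution and expresses the increase against the whole wild-type
#' level: `(psi_obs_ki - psi_obs_wt / 2) / psi_obs_wt`, about 4-fold on the
#' same inputs. Both accept fractions or percentages (the units cancel).
#'
#' @param psi_obs_wt,psi_obs_ki Observed inclusion in the +/+ and +/KI
#'   animals (percent, or any common unit).
#' @param method `"literal"` (default) or `"corrected"`.
#' @return A ratio; `Inf` (with a warning) when `psi_obs_wt` is 0.
#' @export
#' @examples
#' ki_fold_increase(0.97, 4.8) # ~9.9
ki_fold_increase <- function(psi_obs_wt, psi_obs_ki,
                             method = c("literal", "corrected")) {
  method <- match.arg(method)
  if (any(psi_obs_wt == 0)) {
    warn("psi_obs_wt = 0: fold increase is undefined (Inf)")
  }
  switch(method,
    literal = psi_obs_ki / (psi_obs_wt / 2),
    corrected = (psi_obs_ki - psi_obs_wt / 2) / psi_obs_wt
  )
}

# stable inclusion fraction of a genotype with allele propensities psi1,
# psi2 (equal T) and NMD survival s
stable_inclusion <- function(psi1, psi2, s) {
  inc <- (psi1 + psi2) * s
  exc <- (1 - psi1) + (1 - psi2)
  inc / (inc + exc)
}

#' Fit the two-allele steady-state model to observed inclusion percentages
#'
#' Solves for the wild-type allele's inclusion propensity `psi_plus` and the
#' NMD survival fraction `s` such that the steady-state stable inclusion
#' fractions reproduce the observed wild-type and heterozygote inclusion
#' percentages, holding the knock-in allele's propensity at `psi_ki_allele`
#' (default 1: essentially every knock-in transcript includes the poison
#' exon). The wild-type equation gives `s` in closed form as a function of
#' `psi_plus`; the heterozygote equation is then solved by bracketed 1-D
#' root finding on `psi_plus` in `(0, 1)`.
#'
#' @param psi_obs_wt,psi_obs_ki Observed inclusion percentages, with
#'   `0 < psi_obs_wt < psi_obs_ki < 100`.
#' @param psi_ki_allele Knock-in allele inclusion propensity, in `(0, 1]`.
#' @param tol Root-finding tolerance.
#' @return An object of class `steady_state_fit`: list with `psi_plus`,
#'   `s`, `psi_ki_allele`, the inputs, `residuals` (both model equations
#'   evaluated at the solution) and `convergence`.
#' @export
#' @examples
#' fit <- fit_steady_state(0.97, 4.8)
#' glance(fit)
fit_steady_state <- function(psi_obs_wt, psi_obs_ki, psi_ki_allele = 1,
                             tol = 1e-10) {
  if (psi_obs_wt == psi_obs_ki) {
    abort("degenerate inputs: psi_obs_wt == psi_obs_ki leaves (psi, s) unidentifiable",
      class = "pexquant_input_error"
    )
  }
  stopifnot(
    psi_obs_wt > 0, psi_obs_wt < psi_obs_ki, psi_obs_ki < 100,
    psi_ki_allele > 0, psi_ki_allele <= 1
  )
  f1 <- psi_obs_wt / 100
  f2 <- psi_obs_ki / 100
  s_of_psi <- function(psi) f1 * (1 - psi) / (psi * (1 - f1))
  het_gap <- function(psi) {
    s <- s_of_psi(psi)
    stable_inclusion(psi, psi_ki_allele, s) - f2
  }
  lo <- 1e-6
  hi <- 1 - 1e-6
  glo <- het_gap(lo)
  ghi <- het_gap(hi)
  if (is.na(glo) || is.na(ghi) || glo * ghi > 0) {
    abort(
      paste0(
        "no root in (0, 1): het_gap(", format(lo), ") = ", format(glo),
        ", het_gap(", format(hi), ") = ", format(ghi),
        "; the observations are not reachable with psi_ki_allele = ",
        psi_ki_allele
      ),
      class = "pexquant_fit_error"
    )
  }
  root <- uniroot(het_gap, c(lo, hi), tol = tol)
  psi <- root$root
  s <- s_of_psi(psi)
  if (s > 1) {
    abort("fitted NMD survival exceeds 1; observations inconsistent with the model",
      class = "pexquant_fit_error"
    )
  }
  structure(
    list(
      psi_plus = psi, s = s, psi_ki_allele = psi_ki_allele,
      psi_obs_wt = psi_obs_wt, psi_obs_ki = psi_obs_ki,
      residuals = c(
        wt = stable_inclusion(psi, psi, s) - f1,
        ki = stable_inclusion(psi, psi_ki_allele, s) - f2
      ),
      convergence = root$estim.prec
    ),
    class = "steady_state_fit"
  )
}

#' @export
print.steady_state_fit <- function(x, ...) {
  cat(sprintf(
    "<steady_state_fit> psi_plus = %.4g, s = %.4g (psi_ki_allele = %.3g)\n",
    x$psi_plus, x$s, x$psi_ki_allele
  ))
  invisible(x)
}

#' @method tidy steady_state_fit
#' @export
tidy.steady_state_fit <- function(x, ...) {
  tibble(
    term = c("psi_plus", "s"),
    estimate = c(x$psi_plus, x$s)
  )
}

#' @method glance steady_state_fit
#' @export
glance.steady_state_fit <- function(x, ...) {
  tibble(
    psi_plus = x$psi_plus, s = x$s, psi_ki_allele = x$psi_ki_allele,
    resid_wt = unname(x$residuals["wt"]), resid_ki = unname(x$residuals["ki"]),
    predicted_total_reduction = predict_total_reduction(
      x$psi_plus, x$psi_ki_allele, x$s
    )
  )
}

#' Predicted reduction of total stable mRNA in the heterozygote
#'
#' Evaluates the steady-state closed forms for both genotypes and returns
#' `100 * (1 - stable(+/KI) / stable(+/+))`: the percent reduction in total
#' stable transcript caused by routing most knock-in-allele output through
#' the poison exon and decay. Monotone decreasing in `s` (the more decay
#' survivors, the smaller the loss).
#'
#' @param psi_plus Wild-type allele inclusion propensity in `[0, 1]`.
#' @param psi_ki_allele Knock-in allele inclusion propensity.
#' @param s NMD survival fraction in `[0, 1]`.
#' @return Percent reduction in `[0, 100]`.
#' @export
#' @examples
#' predict_total_reduction(0.24, 1, 0.031) # ~48
predict_total_reduction <- function(psi_plus, psi_ki_allele, s) {
  stopifnot(
    psi_plus >= 0, psi_plus <= 1, psi_ki_allele >= 0, psi_ki_allele <= 1,
    s >= 0, s <= 1
  )
  per_allele <- function(psi) (1 - psi) + psi * s
  stable_wt <- 2 * per_allele(psi_plus)
  stable_ki <- per_allele(psi_plus) + per_allele(psi_ki_allele)
  100 * (1 - stable_ki / stable_wt)
}

#' Additive-model allele inference, end to end
#'
#' Convenience wrapper combining [per_allele_baseline()],
#' [ki_fold_increase()], [fit_steady_state()] and
#' [predict_total_reduction()] into one record.
#'
#' @inheritParams fit_steady_state
#' @param fold_method Passed to [ki_fold_increase()].
#' @return One-row tibble: observed inputs, `per_allele_baseline`,
#'   `fold_increase`, fitted `psi_plus` and `s`,
#'   `predicted_total_reduction`, and the recorded assumptions.
#' @export
allele_model <- function(psi_obs_wt, psi_obs_ki, psi_ki_allele = 1,
                         fold_method = "literal") {
  fit <- fit_steady_state(psi_obs_wt, psi_obs_ki, psi_ki_allele)
  tibble(
    psi_obs_wt = psi_obs_wt, psi_obs_ki = psi_obs_ki,
    per_allele_baseline = per_allele_baseline(psi_obs_wt),
    fold_increase = ki_fold_increase(psi_obs_wt, psi_obs_ki, fold_method),
    fold_method = fold_method,
    psi_plus = fit$psi_plus, s = fit$s, psi_ki_allele = psi_ki_allele,
    predicted_total_reduction = predict_total_reduction(
      fit$psi_plus, psi_ki_allele, fit$s
    ),
    assumes_equal_allele_baseline = TRUE,
    assumes_ki_dominant_inclusion = fold_method == "literal"
  )
}
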