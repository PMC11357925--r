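# Two-step MR mediation: decompose the total exposure -> outcome effect
# into a direct component and a component carried by a mediator.
#
# With a = total effect (exposure -> outcome), c = exposure -> mediator,
# d = mediator -> outcome, the indirect effect is c*d, the direct effect
# is a - c*d, and the mediation ratio is c*d/a.  All three step effects
# come from the IVW estimator via the full instruments + harmonize path.

#' Mediation analysis configuration
#'
#' @param p_threshold instrument p-value threshold for both the exposure
#'   and the mediator steps (forward rule, default 1e-5).
#' @param f_min weak-instrument bound (default 10).
#' @param r2_clump,window_bp clumping parameters.
#' @param alpha significance level for the step gates (default 0.05).
#' @param a_floor smallest |total effect| for which the mediation ratio
#'   is reported; below it the proportion is undefined (division
#'   instability) and returned as NA with a warning.
#' @param exclude_exposure_instruments drop SNPs that are instruments for
#'   the exposure from the mediator's instrument set when estimating the
#'   mediator -> outcome effect (default TRUE).  This guards the
#'   mediator-instrument exclusion restriction: variants acting on the
#'   mediator only through the exposure would otherwise carry the
#'   exposure's direct effect into step d.
#' @param report_sign_inconsistent keep mediators whose indirect effect
#'   opposes the total effect in screen output (flagged, with negative
#'   proportion) rather than suppressing them (default TRUE).
#' @param ld LD specification passed to [select_instruments()].
#' @param palindrome_eaf_window passed to [harmonize()].
#' @return A list of class `mediation_config`.
#' @export
mediation_config <- function(p_threshold = 1e-5, f_min = 10,
                             r2_clump = 0.001, window_bp = 1e7,
                             alpha = 0.05, a_floor = 1e-3,
                             exclude_exposure_instruments = TRUE,
                             report_sign_inconsistent = TRUE,
                             ld = NULL,
                             palindrome_eaf_window = c(0.42, 0.58)) {
  structure(list(p_threshold = p_threshold, f_min = f_min,
                 r2_clump = r2_clump, window_bp = window_bp,
                 alpha = alpha, a_floor = a_floor,
                 exclude_exposure_instruments = exclude_exposure_instruments,
                 report_sign_inconsistent = report_sign_inconsistent,
                 ld = ld,
                 palindrome_eaf_window = palindrome_eaf_window),
            class = "mediation_config")
}

#' Decompose a total effect into direct and mediated components
#'
#' Pure arithmetic core of the two-step analysis: given the total effect
#' `a`, the exposure -> mediator effect `c` and the mediator -> outcome
#' effect `d` (with standard errors), computes indirect = `c*d`, direct
#' = `a - c*d`, proportion mediated = `c*d/a`, and first-order standard
#' errors treating the three estimates as independent.  The identities
#' `direct + indirect == a` and `proportion * a == indirect` hold to
#' machine precision; the proportion is invariant to rescaling the
#' mediator's units (`c -> s*c`, `d -> d/s`).
#'
#' @param a,se_a total effect and its SE.
#' @param c_,se_c exposure -> mediator effect and its SE.
#' @param d,se_d mediator -> outcome effect and its SE.
#' @param a_floor smallest |a| for which the proportion is defined.
#' @return list with `indirect`, `indirect_se`, `direct_b`,
#'   `proportion`, `proportion_se`, `sign_consistent`.
#' @export
mediation_decompose <- function(a, se_a, c_, se_c, d, se_d,
                                a_floor = 1e-3) {
  indirect <- c_ * d
  indirect_se <- sqrt(c_^2 * se_d^2 + d^2 * se_c^2)
  direct_b <- a - indirect
  if (abs(a) < a_floor) {
    warning("total effect |a| = ", format(abs(a), digits = 3),
            " below floor ", a_floor,
            "; mediation proportion undefined", call. = FALSE)
    proportion <- NA_real_
    proportion_se <- NA_real_
  } else {
    proportion <- indirect / a
    # Delta method for indirect/a treating the two as independent (the
    # step samples overlap in reality; documented approximation).
    proportion_se <- sqrt(indirect_se^2 / a^2 +
                            indirect^2 * se_a^2 / a^4)
  }
  list(indirect = indirect, indirect_se = indirect_se,
       direct_b = direct_b, proportion = proportion,
       proportion_se = proportion_se,
       sign_consistent = !is.na(proportion) && proportion > 0)
}

step_ivw <- function(iv, target, config) {
  h <- harmonize(iv, target,
                 palindrome_eaf_window = config$palindrome_eaf_window)
  r <- retained(h)
  if (nrow(r) < 2L)
    stop("fewer than 2 usable SNPs after harmonization against ",
         target$trait_id)
  list(estimate = mr_ivw(h), harmonized = h,
       pleiotropy = if (nrow(r) >= 3L) egger_intercept_test(h) else NULL)
}

#' Two-step MR mediation decomposition
#'
#' Estimates the total effect `a` (exposure -> outcome), the step effects
#' `c` (exposure -> mediator) and `d` (mediator -> outcome), all via
#' instrument selection, harmonization and IVW, and decomposes:
#' indirect = `c*d`, direct = `a - c*d`, proportion mediated = `c*d/a`.
#'
#' Uncertainty uses first-order (delta method) propagation treating the
#' step estimates as independent: `se(indirect)^2 = c^2 se_d^2 + d^2
#' se_c^2`, and the proportion SE combines `se(indirect)` with `se_a`
#' through the ratio rule.  A mediator whose indirect effect opposes the
#' total effect is flagged `sign_consistent = FALSE` and its proportion
#' is negative.
#'
#' @param exposure_stats,mediator_stats,outcome_stats [summary_stats]
#'   objects for the three traits.
#' @param config a [mediation_config()].
#' @return An object of class `mediation_result`: list with `a`, `se_a`,
#'   `c`, `se_c`, `d`, `se_d`, `indirect`, `indirect_se`, `direct_b`,
#'   `proportion`, `proportion_se` (both on the raw scale; multiply by
#'   100 for percent), `sign_consistent`, `method_provenance`, per-step
#'   `mr_estimate`s and pleiotropy tests, and the trait ids.
#' @export
two_step_mediation <- function(exposure_stats, mediator_stats,
                               outcome_stats,
                               config = mediation_config()) {
  stopifnot(inherits(exposure_stats, "summary_stats"),
            inherits(mediator_stats, "summary_stats"),
            inherits(outcome_stats, "summary_stats"))
  if (mediator_stats$trait_id == outcome_stats$trait_id)
    stop("validation error: mediator trait id equals outcome trait id (",
         outcome_stats$trait_id, ")")
  if (mediator_stats$trait_id == exposure_stats$trait_id)
    stop("validation error: mediator trait id equals exposure trait id")

  iv_x <- select_instruments(exposure_stats,
                             p_threshold = config$p_threshold,
                             ld = config$ld, f_min = config$f_min,
                             r2_clump = config$r2_clump,
                             window_bp = config$window_bp)
  iv_m <- select_instruments(mediator_stats,
                             p_threshold = config$p_threshold,
                             ld = config$ld, f_min = config$f_min,
                             r2_clump = config$r2_clump,
                             window_bp = config$window_bp)
  if (config$exclude_exposure_instruments) {
    iv_m$records <- iv_m$records[
      !iv_m$records$snp_id %in% iv_x$records$snp_id, , drop = FALSE]
  }
  step_a <- step_ivw(iv_x, outcome_stats, config)
  step_c <- step_ivw(iv_x, mediator_stats, config)
  step_d <- step_ivw(iv_m, outcome_stats, config)

  a <- step_a$estimate$beta; se_a <- step_a$estimate$se
  cc <- step_c$estimate$beta; se_c <- step_c$estimate$se
  dd <- step_d$estimate$beta; se_d <- step_d$estimate$se
  dec <- mediation_decompose(a, se_a, cc, se_c, dd, se_d,
                             a_floor = config$a_floor)
  structure(list(
    exposure_id = exposure_stats$trait_id,
    mediator_id = mediator_stats$trait_id,
    outcome_id = outcome_stats$trait_id,
    a = a, se_a = se_a, c = cc, se_c = se_c, d = dd, se_d = se_d,
    indirect = dec$indirect, indirect_se = dec$indirect_se,
    direct_b = dec$direct_b,
    proportion = dec$proportion, proportion_se = dec$proportion_se,
    sign_consistent = dec$sign_consistent,
    method_provenance = c(a = step_a$estimate$method,
                          c = step_c$estimate$method,
                          d = step_d$estimate$method),
    estimates = list(a = step_a$estimate, c = step_c$estimate,
                     d = step_d$estimate),
    pleiotropy = list(c = step_c$pleiotropy, d = step_d$pleiotropy),
    config = config),
    class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("<mediation_result>", x$exposure_id, "->", x$mediator_id, "->",
      x$outcome_id, "\n")
  cat(sprintf("  total a = %.4f (se %.4f); indirect c*d = %.4f; direct = %.4f\n",
              x$a, x$se_a, x$indirect, x$direct_b))
  if (is.na(x$proportion)) cat("  proportion mediated: undefined\n")
  else cat(sprintf("  proportion mediated = %.2f%% (se %.2f%%)%s\n",
                   100 * x$proportion, 100 * x$proportion_se,
                   if (x$sign_consistent) "" else " [sign-inconsistent]"))
  invisible(x)
}

#' Screen candidate mediators for one exposure-outcome pair
#'
#' Runs [two_step_mediation()] for every candidate, retains those whose
#' step effects `c` and `d` are both significant (IVW p < alpha) and
#' both pleiotropy-cleared (Egger intercept p > alpha), and ranks the
#' retained mediators by absolute proportion mediated.
#'
#' @param exposure_stats,outcome_stats [summary_stats] objects.
#' @param mediator_list list of [summary_stats] objects (candidates).
#' @param config a [mediation_config()].
#' @return data.frame (ranked, retained candidates; empty allowed) with
#'   columns exposure, mediator, outcome, a, se_a, c, se_c, d, se_d,
#'   indirect, direct, proportion_pct, proportion_se_pct,
#'   sign_consistent, c_pval, d_pval, c_pleiotropy_p, d_pleiotropy_p.
#'   The full (unfiltered) screen, including failed candidates, is
#'   attached as attribute `"screened"`.
#' @export
mediation_screen <- function(exposure_stats, mediator_list, outcome_stats,
                             config = mediation_config()) {
  rows <- lapply(mediator_list, function(med) {
    res <- two_step_mediation(exposure_stats, med, outcome_stats, config)
    pl_c <- res$pleiotropy$c; pl_d <- res$pleiotropy$d
    data.frame(
      exposure = res$exposure_id, mediator = res$mediator_id,
      outcome = res$outcome_id,
      a = res$a, se_a = res$se_a, c = res$c, se_c = res$se_c,
      d = res$d, se_d = res$se_d,
      indirect = res$indirect, direct = res$direct_b,
      proportion_pct = 100 * res$proportion,
      proportion_se_pct = 100 * res$proportion_se,
      sign_consistent = res$sign_consistent,
      c_pval = res$estimates$c$pval, d_pval = res$estimates$d$pval,
      c_pleiotropy_p = if (is.null(pl_c)) NA_real_ else pl_c$pval,
      d_pleiotropy_p = if (is.null(pl_d)) NA_real_ else pl_d$pval,
      stringsAsFactors = FALSE)
  })
  screened <- if (length(rows)) do.call(rbind, rows)
  else data.frame(exposure = character(0), mediator = character(0),
                  proportion_pct = numeric(0), stringsAsFactors = FALSE)
  rownames(screened) <- NULL
  if (nrow(screened) == 0L) {
    out <- screened
  } else {
    alpha <- config$alpha
    pass <- screened$c_pval < alpha & screened$d_pval < alpha &
      !is.na(screened$c_pleiotropy_p) & screened$c_pleiotropy_p > alpha &
      !is.na(screened$d_pleiotropy_p) & screened$d_pleiotropy_p > alpha
    if (!config$report_sign_inconsistent)
      pass <- pass & screened$sign_consistent
    out <- screened[pass, , drop = FALSE]
    out <- out[order(-abs(out$proportion_pct)), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "screened") <- screened
  out
}
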