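# Heterogeneity, pleiotropy, outlier and influence diagnostics.
#
# The screening pipeline reports heterogeneity but does not drop
# exposures for it; only the pleiotropy (Egger intercept) test gates an
# exposure out of downstream analysis.

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum_j w_j (by_j - fit_j)^2` with `w_j = 1/se_out_j^2`, where the
#' fit is the origin-constrained IVW regression (`df = n - 1`) or the
#' intercept-including MR-Egger regression (`df = n - 2`).  The p-value
#' is the upper chi-square tail.
#'
#' @param data harmonized dataset.
#' @param method `"ivw"` or `"mr_egger"`.
#' @return data.frame with `method`, `Q`, `Q_df`, `Q_pval`.
#' @export
cochran_q <- function(data, method = c("ivw", "mr_egger")) {
  method <- match.arg(method)
  d <- hd_rows(data)
  m <- nrow(d)
  df <- if (method == "ivw") m - 1L else m - 2L
  if (df < 1L) stop("insufficient instruments for Cochran's Q (", method, ")")
  w <- 1 / d$se_out^2
  if (method == "ivw") {
    beta <- sum(w * d$beta_exp * d$beta_out) / sum(w * d$beta_exp^2)
    q <- sum(w * (d$beta_out - beta * d$beta_exp)^2)
  } else {
    f <- egger_fit(d)
    o <- orient_positive(d)
    q <- sum(w * (o$beta_out - f$intercept - f$slope * o$beta_exp)^2)
  }
  data.frame(method = method, Q = q, Q_df = df,
             Q_pval = stats::pchisq(q, df, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' The intercept of the MR-Egger regression estimates the average
#' directional pleiotropic effect of the instruments; a two-sided normal
#' p-value above the chosen alpha is read as no evidence of horizontal
#' pleiotropy.
#'
#' @param data harmonized dataset with at least 3 variants.
#' @return data.frame with `egger_intercept`, `se`, `pval`.
#' @export
egger_intercept_test <- function(data) {
  d <- hd_rows(data)
  if (nrow(d) < 3L) stop("insufficient instruments: intercept test needs >= 3 SNPs")
  f <- egger_fit(d)
  data.frame(egger_intercept = f$intercept, se = f$se_intercept,
             pval = 2 * stats::pnorm(-abs(f$intercept / f$se_intercept)),
             stringsAsFactors = FALSE)
}

# Leave-one-out IVW slopes for every variant of (bx, by, w), vectorised:
# beta_{-j} = (S_xy - w_j bx_j by_j) / (S_xx - w_j bx_j^2).
loo_betas <- function(bx, by, w) {
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

#' MR-PRESSO: residual sum of squares outlier detection
#'
#' Simulation-based global, outlier and distortion tests:
#' \enumerate{
#'   \item Global test: the observed residual sum of squares
#'     `RSS = sum_j w_j (by_j - beta_{-j} bx_j)^2` (leave-one-out fits)
#'     is compared against `n_sim` parametric simulations drawing
#'     `bx* ~ N(bx_j, se_exp_j)` and `by* ~ N(beta_{-j} bx_j, se_out_j)`,
#'     each evaluated with its own leave-one-out fits; the p-value is the
#'     empirical exceedance with a +1 continuity correction.
#'   \item Outlier test: each SNP's observed weighted squared residual is
#'     compared against its simulated distribution; p-values are
#'     Bonferroni-adjusted (times the number of SNPs) and SNPs below
#'     `significance` are flagged.
#'   \item Distortion test: the relative change between the IVW estimate
#'     on all SNPs and on the complement of the outliers is compared with
#'     the distribution obtained by removing random subsets of the same
#'     size.
#' }
#' The procedure is fully deterministic given `seed`.
#'
#' @param data harmonized dataset with at least 4 variants.
#' @param n_sim number of simulated datasets, >= 100 (default 1000).
#' @param seed RNG seed (mandatory).
#' @param significance threshold for the Bonferroni-adjusted outlier
#'   p-values (default 0.05).
#' @return An object of class `presso_result`: list with
#'   `global_rss_obs`, `global_pval`, `outlier_pvals` (adjusted, named by
#'   snp_id), `outliers` (snp_ids), `distortion_pval`, `beta_raw` and
#'   `beta_corrected` (one-row `mr_estimate`s), `n_snp`.
#' @export
mr_presso <- function(data, n_sim = 1000, seed, significance = 0.05) {
  d <- hd_rows(data)
  m <- nrow(d)
  if (m < 4L)
    stop("MR-PRESSO requires at least 4 instruments; skip this exposure")
  if (n_sim < 100) stop("n_sim must be >= 100")
  set.seed(seed)
  bx <- d$beta_exp; by <- d$beta_out
  sx <- d$se_exp; sy <- d$se_out
  w <- 1 / sy^2
  ids <- if ("snp_id" %in% names(d)) d$snp_id else as.character(seq_len(m))

  b_loo <- loo_betas(bx, by, w)
  res2_obs <- w * (by - b_loo * bx)^2
  rss_obs <- sum(res2_obs)

  # Parametric null simulations, vectorised across n_sim x m matrices.
  bx_sim <- matrix(stats::rnorm(n_sim * m, mean = rep(bx, each = n_sim),
                                sd = rep(sx, each = n_sim)), n_sim, m)
  by_sim <- matrix(stats::rnorm(n_sim * m,
                                mean = rep(b_loo * bx, each = n_sim),
                                sd = rep(sy, each = n_sim)), n_sim, m)
  wm <- matrix(w, n_sim, m, byrow = TRUE)
  sxy <- rowSums(wm * bx_sim * by_sim)
  sxx <- rowSums(wm * bx_sim^2)
  b_loo_sim <- (sxy - wm * bx_sim * by_sim) / (sxx - wm * bx_sim^2)
  res2_sim <- wm * (by_sim - b_loo_sim * bx_sim)^2
  rss_sim <- rowSums(res2_sim)

  global_pval <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)

  p_raw <- (1 + colSums(res2_sim >= rep(res2_obs, each = n_sim))) /
    (n_sim + 1)
  p_adj <- pmin(1, p_raw * m)
  names(p_adj) <- ids
  out_idx <- which(p_adj < significance)

  beta_raw <- mr_ivw(d)
  beta_corrected <- beta_raw
  distortion_pval <- NA_real_
  if (length(out_idx) > 0L && m - length(out_idx) >= 2L) {
    beta_corrected <- mr_ivw(d[-out_idx, , drop = FALSE])
    d_obs <- (beta_corrected$beta - beta_raw$beta) / abs(beta_raw$beta)
    k <- length(out_idx)
    t_xy <- w * bx * by
    t_xx <- w * bx^2
    s_xy <- sum(t_xy); s_xx <- sum(t_xx)
    d_null <- vapply(seq_len(n_sim), function(i) {
      drop <- sample.int(m, k)
      b <- (s_xy - sum(t_xy[drop])) / (s_xx - sum(t_xx[drop]))
      (b - beta_raw$beta) / abs(beta_raw$beta)
    }, numeric(1))
    distortion_pval <- (1 + sum(abs(d_null) >= abs(d_obs))) / (n_sim + 1)
  }
  structure(list(global_rss_obs = rss_obs, global_pval = global_pval,
                 outlier_pvals = p_adj, outliers = ids[out_idx],
                 distortion_pval = distortion_pval,
                 beta_raw = beta_raw, beta_corrected = beta_corrected,
                 n_snp = m, n_sim = n_sim, seed = seed),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat("<presso_result>", x$n_snp, "SNPs; global RSS",
      format(x$global_rss_obs, digits = 5), "p =",
      format(x$global_pval, digits = 4), "\n")
  cat("  outliers:", if (length(x$outliers)) paste(x$outliers, collapse = ", ")
      else "none", "\n")
  if (!is.na(x$distortion_pval))
    cat("  distortion p =", format(x$distortion_pval, digits = 4), "\n")
  invisible(x)
}

#' Leave-one-out influence analysis
#'
#' Re-estimates the IVW effect with each instrument removed in turn and
#' flags any removal that changes the sign of the estimate or moves the
#' 95% confidence interval across zero relative to the full-data fit.
#'
#' @param data harmonized dataset with at least 3 variants.
#' @return data.frame with one row per excluded SNP: `left_out`, `beta`,
#'   `se`, `lo_ci`, `up_ci`, `pval`, `influential`.
#' @export
leave_one_out <- function(data) {
  d <- hd_rows(data)
  m <- nrow(d)
  if (m < 3L) stop("insufficient instruments: leave-one-out needs >= 3 SNPs")
  full <- mr_ivw(d)
  excl_zero_full <- full$lo_ci > 0 || full$up_ci < 0
  rows <- lapply(seq_len(m), function(j) {
    est <- mr_ivw(d[-j, , drop = FALSE])
    excl_zero <- est$lo_ci > 0 || est$up_ci < 0
    data.frame(left_out = if ("snp_id" %in% names(d)) d$snp_id[j]
               else as.character(j),
               beta = est$beta, se = est$se, lo_ci = est$lo_ci,
               up_ci = est$up_ci, pval = est$pval,
               influential = sign(est$beta) != sign(full$beta) ||
                 excl_zero != excl_zero_full,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pleiotropy gate for an exposure
#'
#' An exposure is "cleared" iff the Egger intercept p-value is strictly
#' greater than `alpha`; heterogeneity is recorded but never blocks.
#' The significance flag is raw IVW p strictly below `alpha`.  Boundary
#' p-values (exactly `alpha`) do not clear and are not significant.
#'
#' @param ivw_estimate one-row `mr_estimate` from [mr_ivw()].
#' @param pleiotropy result of [egger_intercept_test()].
#' @param heterogeneity optional [cochran_q()] result, recorded only.
#' @param alpha significance level (default 0.05).
#' @return list with `cleared`, `significant`, `category` (one of
#'   `"significant"`, `"not_significant"`, `"gated_out"`), and the inputs.
#' @export
gate_exposure <- function(ivw_estimate, pleiotropy, heterogeneity = NULL,
                          alpha = 0.05) {
  cleared <- !is.null(pleiotropy) && is.finite(pleiotropy$pval) &&
    pleiotropy$pval > alpha
  significant <- ivw_estimate$pval < alpha
  category <- if (!cleared) "gated_out"
  else if (significant) "significant" else "not_significant"
  list(cleared = cleared, significant = significant, category = category,
       ivw_pval = ivw_estimate$pval,
       intercept_pval = if (is.null(pleiotropy)) NA_real_
       else pleiotropy$pval,
       heterogeneity = heterogeneity, alpha = alpha)
}
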