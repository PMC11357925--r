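# The five causal estimators: inverse-variance weighted (main method),
# MR-Egger, weighted median, simple mode and weighted mode.
#
# All estimators consume a harmonized dataset (or any data.frame with
# beta_exp / se_exp / beta_out / se_out columns) and return a one-row
# `mr_estimate` data.frame produced by finalize_estimate().  p-values use
# the normal reference distribution throughout; confidence intervals are
# beta +/- 1.96 * se and odds ratios are the exponentials of the triple.

hd_rows <- function(data) {
  if (inherits(data, "harmonized_data")) data <- retained(data)
  need <- c("beta_exp", "se_exp", "beta_out", "se_out")
  stopifnot(all(need %in% names(data)))
  data
}

#' Assemble a one-row MR estimate
#'
#' Fills the 95% confidence bounds (`beta +/- 1.96 se`), the odds-ratio
#' triple (exponentials of beta and its bounds) and the two-sided normal
#' p-value `2 * (1 - Phi(|beta/se|))`.
#'
#' @param beta causal estimate (log-odds scale for binary outcomes).
#' @param se standard error, > 0.
#' @param method method code (e.g. `"ivw"`, `"mr_egger"`).
#' @param n_snp number of instruments used.
#' @param intercept,intercept_se MR-Egger intercept and its standard
#'   error (NA for other methods).
#' @return A one-row data.frame of class `mr_estimate` with columns
#'   `method`, `n_snp`, `beta`, `se`, `lo_ci`, `up_ci`, `or_`,
#'   `or_lci95`, `or_uci95`, `pval`, `intercept`, `intercept_se`,
#'   `intercept_p`.
#' @export
finalize_estimate <- function(beta, se, method, n_snp,
                              intercept = NA_real_,
                              intercept_se = NA_real_) {
  stopifnot(is.finite(beta), is.finite(se), se > 0)
  lo <- beta - 1.96 * se
  up <- beta + 1.96 * se
  structure(data.frame(
    method = method, n_snp = as.integer(n_snp),
    beta = beta, se = se, lo_ci = lo, up_ci = up,
    or_ = exp(beta), or_lci95 = exp(lo), or_uci95 = exp(up),
    pval = 2 * stats::pnorm(-abs(beta / se)),
    intercept = intercept, intercept_se = intercept_se,
    intercept_p = if (is.na(intercept) || is.na(intercept_se)) NA_real_
    else 2 * stats::pnorm(-abs(intercept / intercept_se)),
    stringsAsFactors = FALSE),
    class = c("mr_estimate", "data.frame"))
}

#' Per-SNP Wald ratios
#'
#' The atomic quantity all estimators consume: `ratio = beta_out /
#' beta_exp` with first-order standard error `se_out / |beta_exp|`.
#' Variants with `beta_exp == 0` are excluded with a message.
#'
#' @param data harmonized dataset.
#' @return data.frame with `snp_id` (if available), `ratio`, `ratio_se`.
#' @export
wald_ratios <- function(data) {
  d <- hd_rows(data)
  zero <- d$beta_exp == 0
  if (any(zero)) {
    message(sum(zero), " variant(s) excluded from Wald ratios: beta_exp = 0")
    d <- d[!zero, , drop = FALSE]
  }
  data.frame(snp_id = if ("snp_id" %in% names(d)) d$snp_id
             else as.character(seq_len(nrow(d))),
             ratio = d$beta_out / d$beta_exp,
             ratio_se = d$se_out / abs(d$beta_exp),
             stringsAsFactors = FALSE)
}

#' Inverse-variance weighted estimate
#'
#' Weighted least squares of the outcome betas on the exposure betas
#' through the origin with weights `1/se_out^2`, i.e.
#' `beta = sum(w bx by) / sum(w bx^2)`.  The standard error uses a
#' multiplicative random-effects model: the fixed-effect SE is scaled by
#' the residual standard deviation floored at 1, so it is never deflated
#' below the fixed-effect SE.
#'
#' A single retained variant falls back to the Wald ratio (method code
#' `"wald_ratio"`); fewer than one is an error.
#'
#' @param data harmonized dataset.
#' @return A one-row `mr_estimate`.
#' @export
mr_ivw <- function(data) {
  d <- hd_rows(data)
  m <- nrow(d)
  if (m < 1L) stop("insufficient instruments: IVW needs at least 1 SNP")
  if (m == 1L) {
    wr <- wald_ratios(d)
    return(finalize_estimate(wr$ratio, wr$ratio_se, "wald_ratio", 1L))
  }
  w <- 1 / d$se_out^2
  bx <- d$beta_exp; by <- d$beta_out
  beta <- sum(w * bx * by) / sum(w * bx^2)
  se_fixed <- sqrt(1 / sum(w * bx^2))
  sigma <- sqrt(sum(w * (by - beta * bx)^2) / (m - 1))
  finalize_estimate(beta, se_fixed * max(1, sigma), "ivw", m)
}

orient_positive <- function(d) {
  s <- sign(d$beta_exp)
  s[s == 0] <- 1
  d$beta_out <- d$beta_out * s
  d$beta_exp <- abs(d$beta_exp)
  d
}

egger_fit <- function(d) {
  d <- orient_positive(d)
  m <- nrow(d)
  w <- 1 / d$se_out^2
  x <- d$beta_exp; y <- d$beta_out
  sw <- sum(w); swx <- sum(w * x); swx2 <- sum(w * x^2)
  swy <- sum(w * y); swxy <- sum(w * x * y)
  det <- sw * swx2 - swx^2
  if (det <= 0) stop("degenerate design: exposure betas are collinear")
  a <- (swx2 * swy - swx * swxy) / det   # intercept
  b <- (sw * swxy - swx * swy) / det     # slope
  resid <- y - a - b * x
  sigma2 <- sum(w * resid^2) / (m - 2)
  scale <- max(1, sigma2)
  list(intercept = a, slope = b,
       se_intercept = sqrt(scale * swx2 / det),
       se_slope = sqrt(scale * sw / det),
       sigma2 = sigma2, n = m)
}

#' MR-Egger regression estimate
#'
#' Weighted least squares of the outcome betas on the exposure betas with
#' an intercept, weights `1/se_out^2`.  Each variant is first oriented so
#' its exposure beta is non-negative (joint sign flip of the pair), which
#' makes the intercept interpretable as the average directional
#' pleiotropic effect of the instruments; the slope is the
#' pleiotropy-adjusted causal estimate.  Standard errors use the same
#' floored residual-scale rule as [mr_ivw()].
#'
#' @param data harmonized dataset with at least 3 variants.
#' @return A one-row `mr_estimate` with intercept fields populated.
#' @export
mr_egger <- function(data) {
  d <- hd_rows(data)
  if (nrow(d) < 3L) stop("insufficient instruments: MR-Egger needs >= 3 SNPs")
  f <- egger_fit(d)
  finalize_estimate(f$slope, f$se_slope, "mr_egger", f$n,
                    intercept = f$intercept, intercept_se = f$se_intercept)
}

weighted_median_point <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]
  w <- w[ord] / sum(w)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(r[1])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  stats::approx(p, r, xout = 0.5, ties = "ordered")$y
}

boot_se <- function(ratio, ratio_se, n_boot, seed, point_fun) {
  set.seed(seed)
  m <- length(ratio)
  draws <- matrix(stats::rnorm(n_boot * m, mean = rep(ratio, each = n_boot),
                               sd = rep(ratio_se, each = n_boot)),
                  nrow = n_boot, ncol = m)
  stats::sd(apply(draws, 1L, point_fun))
}

#' Weighted median estimate
#'
#' Orders the Wald ratios and linearly interpolates the inverse-variance
#' weighted cumulative distribution at 50%; consistent as long as at
#' least half of the instrument weight comes from valid instruments.
#' The standard error is a seeded parametric bootstrap: each ratio is
#' resampled from `Normal(ratio_j, ratio_se_j)` and the SE is the
#' standard deviation of the `n_boot` re-estimates.
#'
#' @param data harmonized dataset with at least 3 variants.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap (mandatory: no hidden global
#'   RNG state is consulted).
#' @return A one-row `mr_estimate`.
#' @export
mr_weighted_median <- function(data, n_boot = 1000, seed) {
  d <- hd_rows(data)
  if (nrow(d) < 3L)
    stop("insufficient instruments: weighted median needs >= 3 SNPs")
  wr <- wald_ratios(d)
  w <- 1 / wr$ratio_se^2
  beta <- weighted_median_point(wr$ratio, w)
  se <- boot_se(wr$ratio, wr$ratio_se, n_boot, seed,
                function(r) weighted_median_point(r, w))
  finalize_estimate(beta, se, "weighted_median", nrow(d))
}

mode_bandwidth <- function(ratio, phi) {
  s <- min(stats::sd(ratio), stats::IQR(ratio) / 1.349)
  phi * 0.9 * s * length(ratio)^(-1 / 5)
}

mode_point <- function(ratio, w, h, grid_n = 512L) {
  if (h <= 0 || !is.finite(h)) return(ratio[which.max(w)])
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = grid_n)
  dens <- as.vector(stats::dnorm(outer(grid, ratio, "-") / h) %*% w)
  grid[which.max(dens)]
}

#' Mode-based estimate (simple or weighted)
#'
#' The kernel-smoothed mode of the Wald ratios: a Gaussian kernel with
#' bandwidth `phi * 0.9 * min(sd, IQR/1.349) * m^(-1/5)` is evaluated on
#' a 512-point grid spanning the ratio range padded by three bandwidths,
#' and the estimate is the grid argmax.  The simple mode uses equal
#' weights; the weighted mode uses normalized inverse-variance weights.
#' If all ratios coincide (zero bandwidth) the common ratio is returned.
#' The standard error is the same parametric bootstrap as
#' [mr_weighted_median()], with the bandwidth recomputed per replicate.
#'
#' @param data harmonized dataset with at least 3 variants.
#' @param weighted use inverse-variance weights (TRUE for the weighted
#'   mode, FALSE for the simple mode).
#' @param phi bandwidth inflation factor, > 0 (default 1).
#' @param n_boot,seed bootstrap control as in [mr_weighted_median()].
#' @return A one-row `mr_estimate` (method `"simple_mode"` or
#'   `"weighted_mode"`).
#' @export
mr_mode <- function(data, weighted = FALSE, phi = 1, n_boot = 1000, seed) {
  d <- hd_rows(data)
  if (nrow(d) < 3L)
    stop("insufficient instruments: mode estimators need >= 3 SNPs")
  stopifnot(phi > 0)
  wr <- wald_ratios(d)
  w <- if (weighted) {
    ww <- 1 / wr$ratio_se^2
    ww / sum(ww)
  } else rep(1 / nrow(wr), nrow(wr))
  point <- function(r) mode_point(r, w, mode_bandwidth(r, phi))
  beta <- point(wr$ratio)
  se <- boot_se(wr$ratio, wr$ratio_se, n_boot, seed, point)
  finalize_estimate(beta, se,
                    if (weighted) "weighted_mode" else "simple_mode",
                    nrow(d))
}

#' @rdname mr_mode
#' @export
mr_simple_mode <- function(data, phi = 1, n_boot = 1000, seed)
  mr_mode(data, weighted = FALSE, phi = phi, n_boot = n_boot, seed = seed)

#' @rdname mr_mode
#' @export
mr_weighted_mode <- function(data, phi = 1, n_boot = 1000, seed)
  mr_mode(data, weighted = TRUE, phi = phi, n_boot = n_boot, seed = seed)

.method_labels <- c(
  wald_ratio = "Wald ratio",
  ivw = "Inverse variance weighted",
  mr_egger = "MR Egger",
  weighted_median = "Weighted median",
  simple_mode = "Simple mode",
  weighted_mode = "Weighted mode")

#' Run the full estimator suite
#'
#' IVW as the main method plus MR-Egger, weighted median, simple mode and
#' weighted mode as validation, in the conventional reporting order.
#' Methods whose minimum instrument count is not met are skipped.
#'
#' @param data harmonized dataset.
#' @param n_boot bootstrap replicates for median/mode standard errors.
#' @param seed RNG seed for the bootstraps.
#' @param phi mode bandwidth factor.
#' @return An `mr_estimate` data.frame with one row per method.
#' @export
mr_all_methods <- function(data, n_boot = 1000, seed, phi = 1) {
  d <- hd_rows(data)
  m <- nrow(d)
  rows <- list()
  if (m >= 3L) rows$egger <- mr_egger(d)
  if (m >= 3L) rows$wmedian <- mr_weighted_median(d, n_boot, seed)
  rows$ivw <- mr_ivw(d)
  if (m >= 3L) {
    rows$smode <- mr_simple_mode(d, phi = phi, n_boot = n_boot, seed = seed)
    rows$wmode <- mr_weighted_mode(d, phi = phi, n_boot = n_boot, seed = seed)
  }
  ord <- intersect(c("egger", "wmedian", "ivw", "smode", "wmode"),
                   names(rows))
  out <- do.call(rbind, rows[ord])
  rownames(out) <- NULL
  out
}

#' Human-readable method label
#' @param method method code used in `mr_estimate` rows.
#' @export
method_label <- function(method) {
  out <- .method_labels[method]
  out[is.na(out)] <- method[is.na(out)]
  unname(out)
}
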