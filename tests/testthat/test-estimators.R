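# The five causal estimators against independent oracles and known
# truths.

test_that("Wald ratios are the per-SNP quotient with first-order SE", {
  d <- make_hd(bx = c(0.1, 0.2), by = c(0.05, -0.1),
               se_out = c(0.02, 0.05))
  wr <- wald_ratios(d)
  expect_equal(wr$ratio, c(0.5, -0.5))
  expect_equal(wr$ratio_se, c(0.2, 0.25))
  # beta_exp = 0 rows are excluded with a message
  d0 <- make_hd(bx = c(0.1, 0), by = c(0.05, 0.01), se_out = c(0.02, 0.02))
  expect_message(wr0 <- wald_ratios(d0), "beta_exp = 0")
  expect_equal(nrow(wr0), 1L)
})

test_that("IVW equals the closed form and the lm oracle to 1e-10", {
  bx <- c(0.12, -0.31, 0.22)
  by <- c(0.031, -0.074, 0.068)
  so <- c(0.011, 0.017, 0.023)
  est <- mr_ivw(make_hd(bx, by, so))
  w <- 1 / so^2
  expect_equal(est$beta, sum(w * bx * by) / sum(w * bx^2),
               tolerance = 1e-12)
  want <- oracle_ivw(bx, by, so)
  expect_equal(est$beta, want$beta, tolerance = 1e-10)
  expect_equal(est$se, want$se, tolerance = 1e-10)
  expect_equal(est$n_snp, 3L)

  # larger fixture where the residual scale exceeds 1
  set.seed(5)
  bx2 <- stats::rnorm(10, 0, 0.2)
  by2 <- 0.3 * bx2 + stats::rnorm(10, 0, 0.05)
  so2 <- stats::runif(10, 0.005, 0.02)
  est2 <- mr_ivw(make_hd(bx2, by2, so2))
  want2 <- oracle_ivw(bx2, by2, so2)
  expect_equal(est2$beta, want2$beta, tolerance = 1e-10)
  expect_equal(est2$se, want2$se, tolerance = 1e-10)
})

test_that("IVW never reports a smaller SE than the fixed-effect SE", {
  set.seed(11)
  for (i in 1:20) {
    m <- sample(3:30, 1)
    bx <- stats::rnorm(m, 0, 0.2)
    so <- stats::runif(m, 0.005, 0.03)
    by <- 0.1 * bx + stats::rnorm(m, 0, so / 2)  # under-dispersed
    est <- mr_ivw(make_hd(bx, by, so))
    expect_gte(est$se, sqrt(1 / sum(bx^2 / so^2)) * (1 - 1e-12))
  }
})

test_that("a single instrument falls back to the exact Wald ratio", {
  est <- mr_ivw(make_hd(0.1, 0.05, 0.02))
  expect_equal(est$method, "wald_ratio")
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.2)
  expect_error(mr_ivw(make_hd(numeric(0), numeric(0), numeric(0))),
               "insufficient")
})

test_that("MR-Egger reproduces exact fits and the regression oracle", {
  # exact proportional fit with equal weights: slope 0.5, intercept 0
  bx <- c(0.1, 0.2, 0.3, 0.4)
  est <- mr_egger(make_hd(bx, 0.5 * bx, rep(0.02, 4)))
  expect_equal(est$beta, 0.5, tolerance = 1e-12)
  expect_equal(est$intercept, 0, tolerance = 1e-12)

  # 5-SNP fixture with mixed signs against the normal-equations oracle
  bx2 <- c(0.15, -0.22, 0.31, -0.08, 0.27)
  by2 <- c(0.06, -0.05, 0.10, -0.01, 0.11)
  so2 <- c(0.012, 0.02, 0.015, 0.03, 0.01)
  est2 <- mr_egger(make_hd(bx2, by2, so2))
  want <- oracle_egger(bx2, by2, so2)
  expect_equal(est2$beta, want$slope, tolerance = 1e-10)
  expect_equal(est2$intercept, want$intercept, tolerance = 1e-10)
  expect_equal(est2$se, want$se_slope, tolerance = 1e-10)
  expect_equal(est2$intercept_se, want$se_intercept, tolerance = 1e-10)

  # estimates are invariant to per-SNP joint sign flips
  flip <- c(1, -1, 1, -1, 1)
  est3 <- mr_egger(make_hd(bx2 * flip, by2 * flip, so2))
  expect_equal(est3$beta, est2$beta, tolerance = 1e-12)
  expect_equal(est3$intercept, est2$intercept, tolerance = 1e-12)

  expect_error(mr_egger(make_hd(1:2 / 10, 1:2 / 10, c(0.1, 0.1))),
               "insufficient")
})

test_that("the weighted median interpolates the weighted breakpoints", {
  # equal weights, middle element
  d <- make_hd(bx = rep(1, 3), by = c(0.1, 0.2, 0.9),
               se_out = rep(0.1, 3))
  est <- mr_weighted_median(d, n_boot = 50, seed = 1)
  expect_equal(est$beta, 0.2)

  # random fixtures against the brute-force breakpoint oracle
  set.seed(31)
  for (i in 1:25) {
    m <- sample(3:40, 1)
    ratio <- stats::rnorm(m)
    rse <- stats::runif(m, 0.05, 1)
    d <- make_hd(bx = rep(1, m), by = ratio, se_out = rse)
    est <- mr_weighted_median(d, n_boot = 2, seed = 1)
    expect_equal(est$beta, oracle_weighted_median(ratio, 1 / rse^2),
                 tolerance = 1e-12)
  }
})

test_that("bootstrap standard errors are bit-reproducible under a seed", {
  set.seed(4)
  d <- make_hd(bx = stats::rnorm(12, 0, 0.2),
               by = stats::rnorm(12, 0, 0.05),
               se_out = stats::runif(12, 0.01, 0.05))
  a <- mr_weighted_median(d, n_boot = 1000, seed = 1)
  b <- mr_weighted_median(d, n_boot = 1000, seed = 1)
  expect_identical(a$se, b$se)
  c_ <- mr_weighted_median(d, n_boot = 1000, seed = 2)
  expect_false(identical(a$se, c_$se))
  m1 <- mr_mode(d, weighted = TRUE, n_boot = 500, seed = 7)
  m2 <- mr_mode(d, weighted = TRUE, n_boot = 500, seed = 7)
  expect_identical(m1$se, m2$se)
})

test_that("mode estimators find the dominant cluster and match a dense grid", {
  d <- make_hd(bx = rep(1, 4), by = c(0.3, 0.3, 0.3, 5),
               se_out = rep(0.1, 4))
  est <- mr_simple_mode(d, n_boot = 2, seed = 1)
  h <- 1 * 0.9 * min(stats::sd(d$beta_out), stats::IQR(d$beta_out) / 1.349) *
    4^(-1 / 5)
  expect_lt(abs(est$beta - 0.3), h / 2)

  # grid argmax vs a 1e5-point dense grid, within the coarse spacing
  set.seed(13)
  ratio <- c(stats::rnorm(7, 0.4, 0.05), stats::rnorm(3, 1.5, 0.1))
  rse <- stats::runif(10, 0.05, 0.3)
  d2 <- make_hd(bx = rep(1, 10), by = ratio, se_out = rse)
  for (weighted in c(FALSE, TRUE)) {
    est2 <- mr_mode(d2, weighted = weighted, n_boot = 2, seed = 1)
    w <- if (weighted) (1 / rse^2) / sum(1 / rse^2) else rep(0.1, 10)
    bw <- 0.9 * min(stats::sd(ratio), stats::IQR(ratio) / 1.349) *
      10^(-1 / 5)
    dense <- oracle_mode_dense(ratio, w, bw)
    spacing <- (diff(range(ratio)) + 6 * bw) / 511
    expect_lt(abs(est2$beta - dense), spacing)
  }

  # an outlier measured with the smallest SE pulls the weighted mode
  d3 <- make_hd(bx = rep(1, 5), by = c(0.28, 0.3, 0.32, 0.3, 1.2),
                se_out = c(0.2, 0.2, 0.2, 0.2, 0.005))
  sm <- mr_simple_mode(d3, n_boot = 2, seed = 1)
  wm <- mr_weighted_mode(d3, n_boot = 2, seed = 1)
  expect_lt(abs(wm$beta - 1.2), abs(sm$beta - 1.2))

  # identical ratios: zero bandwidth returns the common value
  d4 <- make_hd(bx = rep(1, 3), by = rep(0.4, 3), se_out = rep(0.1, 3))
  expect_equal(mr_simple_mode(d4, n_boot = 20, seed = 1)$beta, 0.4)
})

test_that("estimate finalization enforces the CI/OR/p identities", {
  set.seed(21)
  for (i in 1:50) {
    beta <- stats::rnorm(1)
    se <- stats::runif(1, 0.01, 1)
    est <- finalize_estimate(beta, se, "ivw", 10L)
    expect_equal(est$lo_ci, beta - 1.96 * se, tolerance = 1e-12)
    expect_equal(est$up_ci, beta + 1.96 * se, tolerance = 1e-12)
    expect_equal(est$or_, exp(beta), tolerance = 1e-12)
    expect_equal(est$or_lci95, exp(est$lo_ci), tolerance = 1e-12)
    expect_equal(est$or_uci95, exp(est$up_ci), tolerance = 1e-12)
    expect_equal(est$pval, 2 * stats::pnorm(-abs(beta / se)),
                 tolerance = 1e-15)
  }
  est0 <- finalize_estimate(0, 0.1, "ivw", 5L)
  expect_equal(est0$or_, 1)
  expect_equal(est0$pval, 1)
})

test_that("all five estimators recover the truth without pleiotropy", {
  # precise instruments (large exposure GWAS) so that the residual
  # weak-instrument attenuation is far below Monte-Carlo resolution
  theta <- 0.3
  R <- 150
  est <- matrix(NA_real_, R, 5,
                dimnames = list(NULL, c("mr_egger", "weighted_median",
                                        "ivw", "simple_mode",
                                        "weighted_mode")))
  spacing <- numeric(R)
  for (r in seq_len(R)) {
    cfg <- sim_config(m_snps = 100, theta = theta, seed = 5000 + r,
                      n_exposure = 1e6, n_outcome = 1e5,
                      palindromic_fraction = 0, scramble_fraction = 0)
    h <- quiet_pair_hd(cfg)
    suite <- mr_all_methods(h, n_boot = 2, seed = r)
    est[r, suite$method] <- suite$beta
    wr <- wald_ratios(retained(h))
    bw <- 0.9 * min(stats::sd(wr$ratio), stats::IQR(wr$ratio) / 1.349) *
      nrow(wr)^(-1 / 5)
    spacing[r] <- (diff(range(wr$ratio)) + 6 * bw) / 511
  }
  for (mth in colnames(est)) {
    bias <- mean(est[, mth]) - theta
    mcse <- stats::sd(est[, mth]) / sqrt(R)
    slack <- if (grepl("mode", mth)) mean(spacing) else 0
    expect_lt(abs(bias), 2 * mcse + slack)
  }
})

test_that("the weighted median resists up to half invalid weight", {
  # 40% of instruments get strong directional pleiotropy: the weighted
  # median stays near the truth while IVW is dragged upward
  cfg <- sim_config(m_snps = 200, theta = 0.2, seed = 909,
                    invalid_fraction = 0.4, pleiotropy_mean = 0.1,
                    pleiotropy_sd = 0.05, n_exposure = 1e5,
                    n_outcome = 1e5, palindromic_fraction = 0,
                    scramble_fraction = 0)
  h <- quiet_pair_hd(cfg)
  wm <- mr_weighted_median(h, n_boot = 500, seed = 2)
  ivw <- mr_ivw(h)
  expect_lt(abs(wm$beta - 0.2), abs(ivw$beta - 0.2))
  expect_gt(ivw$beta, 0.25)  # clearly dragged by the pleiotropy
})

test_that("the method suite reports rows in the conventional order", {
  d <- make_hd(bx = c(0.1, 0.2, 0.3, 0.4), by = c(0.03, 0.07, 0.1, 0.12),
               se_out = rep(0.02, 4))
  suite <- mr_all_methods(d, n_boot = 10, seed = 1)
  expect_equal(suite$method, c("mr_egger", "weighted_median", "ivw",
                               "simple_mode", "weighted_mode"))
  expect_equal(method_label(suite$method),
               c("MR Egger", "Weighted median", "Inverse variance weighted",
                 "Simple mode", "Weighted mode"))
  expect_true(all(suite$n_snp == 4L))
})
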