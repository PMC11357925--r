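# Independent oracle implementations used to cross-check the estimators,
# plus small fixture builders.  The oracles deliberately go through
# different code paths (stats::lm, explicit loops, dense grids) than the
# package's closed-form implementations.

# Origin-constrained weighted regression via lm(), with the same
# multiplicative random-effects rule (residual scale floored at 1).
oracle_ivw <- function(bx, by, se_out) {
  fit <- stats::lm(by ~ 0 + bx, weights = 1 / se_out^2)
  sm <- summary(fit)
  se_naive <- sm$coefficients[1, 2]
  list(beta = unname(stats::coef(fit)[1]),
       se = se_naive / min(1, sm$sigma))
}

# Intercept-including weighted regression via lm() after orienting each
# pair to a non-negative exposure beta.
oracle_egger <- function(bx, by, se_out) {
  s <- sign(bx); s[s == 0] <- 1
  x <- abs(bx); y <- by * s
  fit <- stats::lm(y ~ x, weights = 1 / se_out^2)
  sm <- summary(fit)
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       se_intercept = sm$coefficients[1, 2] / min(1, sm$sigma),
       se_slope = sm$coefficients[2, 2] / min(1, sm$sigma))
}

# Brute-force breakpoint search for the interpolated weighted median: walk
# the sorted ratios until the standardized cumulative weight crosses 1/2,
# then solve the linear interpolation on that segment explicitly.
oracle_weighted_median <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]
  w <- w[ord] / sum(w)
  p <- numeric(length(r))
  run <- 0
  for (j in seq_along(r)) {
    p[j] <- run + w[j] / 2
    run <- run + w[j]
  }
  if (0.5 <= p[1]) return(r[1])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  j <- max(which(p < 0.5))
  r[j] + (r[j + 1] - r[j]) * (0.5 - p[j]) / (p[j + 1] - p[j])
}

# Dense-grid argmax of the weighted Gaussian kernel density.
oracle_mode_dense <- function(ratio, w, h, n_grid = 1e5) {
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = n_grid)
  best_x <- grid[1]; best_d <- -Inf
  chunk <- 5000L
  for (start in seq(1L, n_grid, by = chunk)) {
    g <- grid[start:min(start + chunk - 1L, n_grid)]
    dens <- as.vector(stats::dnorm(outer(g, ratio, "-") / h) %*% w)
    if (max(dens) > best_d) {
      best_d <- max(dens)
      best_x <- g[which.max(dens)]
    }
  }
  best_x
}

# Brute-force re-statement of the greedy clumping rule, written as a
# direct loop over the sorted table.
oracle_clump <- function(v, ld_fun, r2_threshold, window_bp) {
  v <- v[order(v$pval, v$snp_id), , drop = FALSE]
  kept <- character(0)
  kept_rows <- list()
  for (i in seq_len(nrow(v))) {
    ok <- TRUE
    for (j in seq_along(kept)) {
      prev <- kept_rows[[j]]
      if (prev$chrom == v$chrom[i] &&
          abs(prev$pos - v$pos[i]) <= window_bp &&
          ld_fun(v$snp_id[i], prev$snp_id) >= r2_threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      kept <- c(kept, v$snp_id[i])
      kept_rows[[length(kept)]] <- v[i, ]
    }
  }
  kept
}

# A minimal harmonized-style data.frame for estimator fixtures.
make_hd <- function(bx, by, se_out, se_exp = rep(1e-3, length(bx)),
                    ids = sprintf("rs%03d", seq_along(bx))) {
  data.frame(snp_id = ids, beta_exp = bx, se_exp = se_exp,
             beta_out = by, se_out = se_out, stringsAsFactors = FALSE)
}

# Simulate one pair and return the retained harmonized rows, silencing
# the selection/harmonization chatter.
quiet_pair_hd <- function(config) {
  sim <- simulate_gwas_pair(config)
  harmonize(sim$exposure, sim$outcome)
}

quiet_select <- function(...) suppressMessages(suppressWarnings(
  select_instruments(...)))
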