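# Instrument strength statistics, greedy clumping, selection,
# harmonization.

test_that("explained variance is symmetric and vanishes with the effect", {
  expect_equal(compute_r2(0.5, 0), 0)
  expect_equal(compute_r2(0.3, 0.12), compute_r2(0.7, 0.12))
  expect_equal(compute_r2(0.3, 0.12), compute_r2(0.3, -0.12))
  expect_error(compute_r2(0, 0.1), "eaf")
  expect_error(compute_r2(1.2, 0.1), "eaf")
})

test_that("the F statistic evaluates the printed formula exactly", {
  expect_equal(compute_f(0, 1000, 1), 0)
  r2 <- 0.25
  expect_equal(compute_f(r2, 103, 2), r2 * 100 / (2 * 0.75))
  expect_error(compute_f(1, 100, 1), "r2")
  expect_error(compute_f(0.1, 2, 1), "n must exceed")
})

test_that("clumping keeps independent SNPs and prunes by LD greedily", {
  v <- table1_fixture()$variants[1:5, ]
  ss <- summary_stats(v, "t")
  # all pairwise r2 = 0 (no LD supplied): everything is retained
  expect_equal(n_variants(clump(ss)), 5L)

  # 3 SNPs on one chromosome, p = (1e-8, 1e-7, 1e-6); the top SNP kills
  # SNP 2 (r2 = 0.9) but not SNP 3
  v3 <- data.frame(snp_id = c("rs1", "rs2", "rs3"), chrom = 1,
                   pos = c(1e6, 2e6, 3e6),
                   effect_allele = "A", other_allele = "G",
                   eaf = 0.3, beta = 0.1, se = 0.01,
                   pval = c(1e-8, 1e-7, 1e-6), n = 1e4)
  ld <- data.frame(snp_a = c("rs1", "rs1", "rs2"),
                   snp_b = c("rs2", "rs3", "rs3"),
                   r2 = c(0.9, 0, 0))
  got <- clump(summary_stats(v3, "t"), ld = ld, r2_threshold = 0.001)
  expect_setequal(got$variants$snp_id, c("rs1", "rs3"))

  # identical p-values: exactly one survives, by lexicographic rsID
  v2 <- v3[1:2, ]; v2$pval <- 1e-8
  got2 <- clump(summary_stats(v2, "t"), ld = ld)
  expect_equal(got2$variants$snp_id, "rs1")

  # outside the window the LD is not consulted
  v3b <- v3; v3b$pos <- c(1e6, 5e7, 9e7)
  got3 <- clump(summary_stats(v3b, "t"), ld = ld, window_bp = 1e7)
  expect_equal(n_variants(got3), 3L)
})

test_that("clumping matches a brute-force validator and ignores row order", {
  set.seed(81)
  for (rep in 1:15) {
    m <- sample(5:20, 1)
    v <- data.frame(snp_id = sprintf("rs%02d", sample(m)), chrom = 1,
                    pos = sort(sample.int(4e7, m)),
                    effect_allele = "A", other_allele = "G", eaf = 0.3,
                    beta = 0.1, se = 0.01,
                    pval = signif(stats::runif(m, 1e-10, 1e-4), 3),
                    n = 1e4)
    pairs <- t(utils::combn(v$snp_id, 2))
    ld <- data.frame(snp_a = pairs[, 1], snp_b = pairs[, 2],
                     r2 = stats::rbinom(nrow(pairs), 1, 0.3) *
                       stats::runif(nrow(pairs)))
    lk <- ld_lookup(ld)
    got <- clump(summary_stats(v, "t"), ld = ld, r2_threshold = 0.1,
                 window_bp = 2e7)
    want <- oracle_clump(v, function(a, b) lk(a, b), 0.1, 2e7)
    expect_equal(got$variants$snp_id, want)

    # row-order invariance
    got_shuf <- clump(summary_stats(v[sample(m), ], "t"), ld = ld,
                      r2_threshold = 0.1, window_bp = 2e7)
    expect_equal(got_shuf$variants$snp_id, got$variants$snp_id)

    # every retained pair respects the constraint (exhaustive check)
    kept <- got$variants
    if (nrow(kept) > 1) {
      kp <- t(utils::combn(seq_len(nrow(kept)), 2))
      near <- abs(kept$pos[kp[, 1]] - kept$pos[kp[, 2]]) <= 2e7
      r2s <- lk(kept$snp_id[kp[, 1]], kept$snp_id[kp[, 2]])
      expect_true(all(r2s[near] < 0.1))
    }
  }
})

test_that("selection applies the p threshold, strength filter and logging", {
  # 100 SNPs: 80 clearly null, 20 below the threshold, of which 3 are
  # deliberately weak (F <= 10)
  n <- 1e4
  beta <- c(rep(0.002, 80), rep(0.1, 17), rep(0.02, 3))
  v <- data.frame(snp_id = sprintf("rs%03d", 1:100),
                  chrom = rep(1:20, each = 5),
                  pos = rep(seq(1e6, 5e8, length.out = 5), 20),
                  effect_allele = "A", other_allele = "G", eaf = 0.5,
                  beta = beta, se = 0.01,
                  pval = c(rep(0.5, 80), rep(1e-6, 20)), n = n)
  f_vals <- compute_f(compute_r2(0.5, beta), n, 1)
  expect_equal(sum(f_vals > 10 & v$pval < 1e-5), 17L)
  iv <- quiet_select(summary_stats(v, "t"), p_threshold = 1e-5,
                     window_bp = 1e5)
  expect_equal(nrow(iv$records), 17L)
  expect_true(all(iv$records$f_stat > 10))
  expect_true(all(iv$records$pval < 1e-5))
  # stored strength columns satisfy their defining identities
  expect_equal(iv$records$r2,
               2 * iv$records$eaf * (1 - iv$records$eaf) *
                 iv$records$beta^2, tolerance = 1e-12)

  # a p = 0.5 SNP at threshold 1e-5 is excluded
  expect_false("rs001" %in% iv$records$snp_id)

  # zero survivors: empty set plus warning
  expect_warning(iv0 <- suppressMessages(
    select_instruments(summary_stats(v[1:5, ], "t"), 1e-5)),
    "no instruments")
  expect_equal(nrow(iv0$records), 0L)
})

test_that("the seven-variant disease fixture all passes the reverse rule", {
  iv <- quiet_select(table1_fixture(), p_threshold = 5e-8)
  expect_equal(nrow(iv$records), 7L)
  expect_true(all(iv$records$f_stat > 10))
})

test_that("harmonization aligns alleles by swap and strand complement", {
  ex <- summary_stats(data.frame(
    snp_id = "rs1", chrom = 1, pos = 100, effect_allele = "A",
    other_allele = "G", eaf = 0.3, beta = 0.1, se = 0.01, pval = 1e-8,
    n = 1e4), "x")
  mk_out <- function(ea, oa, beta = -0.05, eaf = 0.7)
    summary_stats(data.frame(snp_id = "rs1", chrom = 1, pos = 100,
                             effect_allele = ea, other_allele = oa,
                             eaf = eaf, beta = beta, se = 0.02,
                             pval = 0.01, n = 1e4), "y")
  # pure allele swap: sign and frequency flipped
  h <- harmonize(ex, mk_out("G", "A"))
  expect_true(h$keep); expect_true(h$flipped)
  expect_equal(h$beta_out, 0.05)
  expect_equal(h$eaf_out, 0.3)
  # strand complement, no swap: kept as-is
  h2 <- harmonize(ex, mk_out("T", "C", beta = 0.07, eaf = 0.3))
  expect_true(h2$keep); expect_false(h2$flipped)
  expect_equal(h2$beta_out, 0.07)
  # complement plus swap
  h3 <- harmonize(ex, mk_out("C", "T"))
  expect_true(h3$keep); expect_true(h3$flipped)
  expect_equal(h3$beta_out, 0.05)
  # irreconcilable alleles and missing rsID are recorded drops
  h4 <- harmonize(ex, mk_out("A", "C"))
  expect_false(h4$keep)
  expect_equal(h4$dropped_reason, "incompatible_alleles")
  out5 <- mk_out("G", "A")
  out5$variants$snp_id <- "rs999"
  h5 <- harmonize(ex, out5)
  expect_equal(h5$dropped_reason, "snp_missing_in_outcome")
})

test_that("ambiguous palindromic variants are dropped, resolvable ones kept", {
  mk <- function(eaf_exp, ea_out, oa_out, eaf_out) {
    ex <- summary_stats(data.frame(
      snp_id = "rs1", chrom = 1, pos = 1, effect_allele = "A",
      other_allele = "T", eaf = eaf_exp, beta = 0.1, se = 0.01,
      pval = 1e-8, n = 1e4), "x")
    ou <- summary_stats(data.frame(
      snp_id = "rs1", chrom = 1, pos = 1, effect_allele = ea_out,
      other_allele = oa_out, eaf = eaf_out, beta = 0.05, se = 0.02,
      pval = 0.01, n = 1e4), "y")
    harmonize(ex, ou)
  }
  # frequency inside the default window: forced drop
  h <- mk(0.50, "A", "T", 0.50)
  expect_false(h$keep)
  expect_equal(h$dropped_reason, "palindromic_ambiguous")
  # both clearly on the same minor side: retained without flip
  h2 <- mk(0.10, "A", "T", 0.12)
  expect_true(h2$keep); expect_false(h2$flipped)
  # labels swapped, frequencies concordant after the flip: retained
  h3 <- mk(0.10, "T", "A", 0.90)
  expect_true(h3$keep); expect_true(h3$flipped)
  expect_equal(h3$beta_out, -0.05)
  # discordant sides after alignment: ambiguous, dropped
  h4 <- mk(0.10, "A", "T", 0.90)
  expect_false(h4$keep)
  expect_equal(h4$dropped_reason, "palindromic_ambiguous")
  # missing outcome frequency: always dropped for palindromes
  ex <- summary_stats(data.frame(
    snp_id = "rs1", chrom = 1, pos = 1, effect_allele = "C",
    other_allele = "G", eaf = 0.1, beta = 0.1, se = 0.01, pval = 1e-8,
    n = 1e4), "x")
  ou <- summary_stats(data.frame(
    snp_id = "rs1", chrom = 1, pos = 1, effect_allele = "C",
    other_allele = "G", eaf = NA, beta = 0.05, se = 0.02, pval = 0.01,
    n = 1e4), "y", validate = FALSE)
  h5 <- harmonize(ex, ou)
  expect_equal(h5$dropped_reason, "palindromic_ambiguous")
})

test_that("harmonized betas equal the generator's truth channel", {
  sim <- simulate_gwas_pair(sim_config(m_snps = 120, theta = 0.2,
                                       seed = 17))
  h <- harmonize(sim$exposure, sim$outcome)
  r <- retained(h)
  expect_gt(nrow(r), 80)
  tr <- sim$truth[match(r$snp_id, sim$truth$snp_id), ]
  # exact recovery of the aligned observed outcome effect
  expect_identical(r$beta_out, tr$beta_out_aligned)
  # scrambled rows really were exercised
  expect_gt(sum(tr$scramble != "none"), 10)
  # dropped palindromic rows are marked, never silently retained
  dropped <- h[!h$keep, ]
  expect_true(all(!is.na(dropped$dropped_reason)))
})

test_that("harmonization is idempotent", {
  sim <- simulate_gwas_pair(sim_config(m_snps = 60, theta = 0.2,
                                       seed = 23))
  h1 <- retained(harmonize(sim$exposure, sim$outcome))
  # rebuild both sides from the harmonized rows and harmonize again
  ex2 <- summary_stats(data.frame(
    snp_id = h1$snp_id, chrom = h1$chrom, pos = h1$pos,
    effect_allele = h1$effect_allele, other_allele = h1$other_allele,
    eaf = h1$eaf_exp, beta = h1$beta_exp, se = h1$se_exp,
    pval = h1$pval_exp, n = h1$n_exp), "x", validate = FALSE)
  ou2 <- summary_stats(data.frame(
    snp_id = h1$snp_id, chrom = h1$chrom, pos = h1$pos,
    effect_allele = h1$effect_allele, other_allele = h1$other_allele,
    eaf = h1$eaf_out, beta = h1$beta_out, se = h1$se_out,
    pval = h1$pval_out, n = h1$n_out), "y", validate = FALSE)
  h2 <- harmonize(ex2, ou2)
  expect_true(all(h2$keep))
  expect_false(any(h2$flipped))
  expect_equal(h2$beta_out, h1$beta_out)
  expect_equal(h2$eaf_out, h1$eaf_out)
})
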