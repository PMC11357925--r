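# Instrument selection and allele harmonization.
#
# Instruments are selected per exposure with a p-value threshold, greedy
# LD clumping, and strength filtering via the per-SNP explained variance
# R^2 and the F statistic.  Exposure and outcome associations are then
# joined per SNP on a common effect allele.

#' Per-SNP explained phenotypic variance
#'
#' For a variant with effect-allele frequency `eaf` and per-allele effect
#' `beta` on a unit-variance trait, the fraction of phenotypic variance
#' explained is `2 * eaf * (1 - eaf) * beta^2`.  The value is symmetric
#' under `eaf <-> 1 - eaf` and under `beta <-> -beta`.
#'
#' @param eaf effect-allele frequency, strictly inside (0, 1).
#' @param beta per-allele effect estimate.
#' @return Explained variance fraction(s) in \[0, 1).
#' @export
#' @examples
#' compute_r2(0.3103, 0.0689)
compute_r2 <- function(eaf, beta) {
  if (any(!is.finite(eaf)) || any(eaf <= 0) || any(eaf >= 1))
    stop("eaf must lie strictly inside (0, 1)")
  2 * eaf * (1 - eaf) * beta^2
}

#' Instrument F statistic
#'
#' Evaluates `F = R2 * (N - K - 1) / (K * (1 - R2))` for `K` instruments
#' jointly explaining a fraction `R2` of a trait measured on `N` samples.
#' The weak-instrument guard used throughout is per-SNP strength, i.e.
#' `k = 1` even when several instruments are carried forward.
#'
#' @param r2 explained variance fraction in \[0, 1).
#' @param n sample size; must exceed `k + 1`.
#' @param k number of instruments, >= 1.
#' @return F statistic(s) >= 0.
#' @export
#' @examples
#' compute_f(compute_r2(0.3103, 0.0689), 184683, 1)
compute_f <- function(r2, n, k = 1) {
  if (any(!is.finite(r2)) || any(r2 < 0) || any(r2 >= 1))
    stop("r2 must lie in [0, 1)")
  if (any(k < 1)) stop("k must be >= 1")
  if (any(n <= k + 1)) stop("n must exceed k + 1")
  r2 * (n - k - 1) / (k * (1 - r2))
}

#' Build a pairwise LD lookup
#'
#' Accepts `NULL` (all pairs independent), a function `f(snp_a, snp_b)`,
#' a data.frame with columns `snp_a`, `snp_b`, `r2`, or a dense labelled
#' square matrix, and returns a vectorised lookup function returning
#' pairwise r-squared.  Pairs absent from the source are treated as
#' independent (r2 = 0), which makes a diagonal lookup the default.
#'
#' @param ld LD specification as above.
#' @return A function `(snp_a, snp_b) -> r2`.
#' @export
ld_lookup <- function(ld = NULL) {
  if (is.null(ld)) return(function(a, b) rep(0, length(a)))
  if (is.function(ld)) return(ld)
  if (is.matrix(ld)) {
    if (is.null(rownames(ld)) || is.null(colnames(ld)))
      stop("an LD matrix must have row and column names")
    return(function(a, b) {
      r2 <- rep(0, length(a))
      hit <- a %in% rownames(ld) & b %in% colnames(ld)
      r2[hit] <- ld[cbind(a[hit], b[hit])]
      r2
    })
  }
  if (is.data.frame(ld)) {
    stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(ld)))
    key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
    env <- new.env(parent = emptyenv(), size = max(nrow(ld), 1L))
    for (i in seq_len(nrow(ld)))
      assign(key(ld$snp_a[i], ld$snp_b[i]), ld$r2[i], envir = env)
    return(function(a, b) {
      mapply(function(x, y) {
        v <- mget(key(x, y), envir = env, ifnotfound = list(0))[[1]]
        v
      }, a, b, USE.NAMES = FALSE)
    })
  }
  stop("unsupported LD specification")
}

#' Read an LD table or matrix from file
#'
#' Either a 3-column tab-separated file (`snp_a`, `snp_b`, `r2`) or a
#' dense labelled matrix (first column = row names).
#'
#' @param path file path.
#' @return A data.frame or matrix suitable for [ld_lookup()].
#' @export
read_ld <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (all(c("snp_a", "snp_b", "r2") %in% names(raw))) return(raw)
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- raw[[1]]
  storage.mode(m) <- "double"
  m
}

#' Greedy LD clumping
#'
#' Sorts variants by ascending p-value (ties broken by lexicographic
#' rsID) and accepts a variant iff its LD r-squared with every
#' already-accepted variant on the same chromosome within `window_bp` is
#' strictly below `r2_threshold`.  The result is deterministic and
#' invariant to the input row order.
#'
#' @param stats a [summary_stats] object.
#' @param ld LD specification for [ld_lookup()]; absent pairs are
#'   independent.
#' @param r2_threshold clumping threshold in (0, 1\].
#' @param window_bp window within which LD is consulted (default 10 Mb).
#' @return A [summary_stats] object containing the accepted subset,
#'   ordered by ascending p-value.
#' @export
clump <- function(stats, ld = NULL, r2_threshold = 0.001, window_bp = 1e7) {
  stopifnot(inherits(stats, "summary_stats"),
            r2_threshold > 0, r2_threshold <= 1)
  v <- stats$variants
  if (nrow(v) <= 1L) return(stats)
  lk <- ld_lookup(ld)
  v <- v[order(v$pval, v$snp_id), , drop = FALSE]
  accepted <- logical(nrow(v))
  for (i in seq_len(nrow(v))) {
    prior <- which(accepted)
    near <- prior[v$chrom[prior] == v$chrom[i] &
                    abs(v$pos[prior] - v$pos[i]) <= window_bp]
    accepted[i] <- length(near) == 0L ||
      all(lk(rep(v$snp_id[i], length(near)), v$snp_id[near]) < r2_threshold)
  }
  out <- v[accepted, , drop = FALSE]
  rownames(out) <- NULL
  summary_stats(out, stats$trait_id, stats$trait_label, validate = FALSE)
}

#' Select instruments for an exposure
#'
#' Applies the p-value threshold (strict `<`), greedy LD clumping, and
#' the strength filter: per-SNP explained variance via [compute_r2()],
#' F statistic via [compute_f()] with `k = 1`, dropping variants with
#' `F <= f_min`.  Counts at each stage are reported via `message()`.
#'
#' @param stats exposure [summary_stats].
#' @param p_threshold inclusion threshold (1e-5 forward; use 5e-8 for the
#'   reverse-direction analysis).
#' @param ld LD specification for [ld_lookup()].
#' @param f_min weak-instrument bound; instruments must have `F > f_min`.
#' @param r2_clump clumping r-squared threshold.
#' @param window_bp clumping window.
#' @return An object of class `instrument_set`: list with `exposure_id`,
#'   `records` (variant columns plus `r2` and `f_stat`), and the
#'   thresholds used.  Zero surviving SNPs yields an empty set with a
#'   warning so callers can skip the exposure.
#' @export
select_instruments <- function(stats, p_threshold = 1e-5, ld = NULL,
                               f_min = 10, r2_clump = 0.001,
                               window_bp = 1e7) {
  stopifnot(inherits(stats, "summary_stats"),
            p_threshold > 0, f_min >= 0)
  v <- stats$variants
  keep <- !is.na(v$pval) & v$pval < p_threshold
  sig <- summary_stats(v[keep, , drop = FALSE], stats$trait_id,
                       stats$trait_label, validate = FALSE)
  clumped <- clump(sig, ld = ld, r2_threshold = r2_clump,
                   window_bp = window_bp)
  rec <- clumped$variants
  if (nrow(rec) > 0L) {
    usable <- !is.na(rec$eaf) & !is.na(rec$n)
    rec$r2 <- NA_real_
    rec$f_stat <- NA_real_
    if (any(usable))
      rec$r2[usable] <- compute_r2(rec$eaf[usable], rec$beta[usable])
    # r2 >= 1 signals a trait scale incompatible with the unit-variance
    # convention; such variants cannot be strength-scored
    usable <- usable & !is.na(rec$r2) & rec$r2 < 1
    if (any(usable))
      rec$f_stat[usable] <- compute_f(rec$r2[usable], rec$n[usable], k = 1)
    strong <- !is.na(rec$f_stat) & rec$f_stat > f_min
    message(sprintf(
      "instrument selection for %s: %d below p<%g, %d after clumping, %d with F>%g",
      stats$trait_id, sum(keep), p_threshold, nrow(rec), sum(strong),
      f_min))
    rec <- rec[strong, , drop = FALSE]
  } else {
    rec$r2 <- numeric(0)
    rec$f_stat <- numeric(0)
  }
  rownames(rec) <- NULL
  if (nrow(rec) == 0L)
    warning("no instruments survive selection for ", stats$trait_id,
            call. = FALSE)
  structure(list(exposure_id = stats$trait_id, records = rec,
                 p_threshold = p_threshold, r2_clump_threshold = r2_clump,
                 f_min = f_min),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("<instrument_set>", x$exposure_id, "-", nrow(x$records),
      sprintf("instruments (p<%g, F>%g)\n", x$p_threshold, x$f_min))
  invisible(x)
}

revcomp <- function(alleles) {
  comp <- chartr("ACGT", "TGCA", alleles)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""), character(1))
}

is_palindromic <- function(effect, other) revcomp(effect) == other

#' Harmonize exposure instruments with outcome associations
#'
#' Joins instruments to outcome rows by rsID and aligns the outcome
#' effect to the exposure's effect allele:
#' \itemize{
#'   \item direct allele match: kept as-is;
#'   \item effect/other swapped: outcome beta sign-flipped and
#'     `eaf := 1 - eaf`, marked `flipped`;
#'   \item match only after strand complement: complemented, then the two
#'     rules above;
#'   \item palindromic pair (A/T or C/G): after label alignment, retained
#'     only when both allele frequencies are available and both fall
#'     outside `palindrome_eaf_window` on the same side; otherwise
#'     dropped with reason `"palindromic_ambiguous"`;
#'   \item irreconcilable alleles or rsID absent from the outcome:
#'     dropped with reason.
#' }
#' Every exclusion is a recorded row (`keep = FALSE` with a
#' `dropped_reason`), never a silent removal.
#'
#' @param exposure an `instrument_set` (from [select_instruments()]) or a
#'   [summary_stats] object whose variants are all used.
#' @param outcome outcome [summary_stats].
#' @param palindrome_eaf_window frequency interval within which a
#'   palindromic variant's strand is considered unresolvable; the default
#'   `c(0.42, 0.58)` is deliberately conservative.
#' @return A data.frame of class `harmonized_data` with one row per
#'   instrument: `snp_id`, aligned alleles, `beta_exp`, `se_exp`,
#'   `eaf_exp`, `pval_exp`, `n_exp`, `beta_out`, `se_out`, `eaf_out`,
#'   `pval_out`, `n_out`, `palindromic`, `flipped`, `keep`,
#'   `dropped_reason`; attributes `exposure_id` and `outcome_id`.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = c(0.42, 0.58)) {
  stopifnot(inherits(outcome, "summary_stats"),
            length(palindrome_eaf_window) == 2L,
            palindrome_eaf_window[1] <= palindrome_eaf_window[2])
  exp_id <- if (inherits(exposure, "instrument_set")) exposure$exposure_id
  else exposure$trait_id
  ev <- if (inherits(exposure, "instrument_set")) exposure$records
  else exposure$variants
  ov <- outcome$variants
  m <- nrow(ev)
  out <- data.frame(
    snp_id = ev$snp_id, chrom = ev$chrom, pos = ev$pos,
    effect_allele = ev$effect_allele, other_allele = ev$other_allele,
    beta_exp = ev$beta, se_exp = ev$se, eaf_exp = ev$eaf,
    pval_exp = ev$pval, n_exp = ev$n,
    beta_out = NA_real_, se_out = NA_real_, eaf_out = NA_real_,
    pval_out = NA_real_, n_out = NA_real_,
    palindromic = FALSE, flipped = FALSE, keep = FALSE,
    dropped_reason = NA_character_,
    stringsAsFactors = FALSE)
  idx <- match(ev$snp_id, ov$snp_id)
  lo <- palindrome_eaf_window[1]
  hi <- palindrome_eaf_window[2]
  same_side <- function(p, q) {
    !is.na(p) && !is.na(q) &&
      ((p < lo && q < lo) || (p > hi && q > hi))
  }
  for (i in seq_len(m)) {
    j <- idx[i]
    if (is.na(j)) {
      out$dropped_reason[i] <- "snp_missing_in_outcome"
      next
    }
    e1 <- ev$effect_allele[i]; o1 <- ev$other_allele[i]
    e2 <- ov$effect_allele[j]; o2 <- ov$other_allele[j]
    b2 <- ov$beta[j]; q2 <- ov$eaf[j]
    pal <- is_palindromic(e1, o1)
    out$palindromic[i] <- pal
    flipped <- FALSE
    matched <- FALSE
    if (e2 == e1 && o2 == o1) {
      matched <- TRUE
    } else if (e2 == o1 && o2 == e1) {
      matched <- TRUE
      flipped <- TRUE
    } else if (!pal) {
      e2c <- revcomp(e2); o2c <- revcomp(o2)
      if (e2c == e1 && o2c == o1) {
        matched <- TRUE
      } else if (e2c == o1 && o2c == e1) {
        matched <- TRUE
        flipped <- TRUE
      }
    }
    if (!matched) {
      out$dropped_reason[i] <- "incompatible_alleles"
      next
    }
    if (flipped) {
      b2 <- -b2
      if (!is.na(q2)) q2 <- 1 - q2
    }
    if (pal && !same_side(ev$eaf[i], q2)) {
      out$dropped_reason[i] <- "palindromic_ambiguous"
      next
    }
    out$beta_out[i] <- b2
    out$se_out[i] <- ov$se[j]
    out$eaf_out[i] <- q2
    out$pval_out[i] <- ov$pval[j]
    out$n_out[i] <- ov$n[j]
    out$flipped[i] <- flipped
    out$keep[i] <- TRUE
  }
  structure(out, exposure_id = exp_id, outcome_id = outcome$trait_id,
            palindrome_eaf_window = palindrome_eaf_window,
            class = c("harmonized_data", "data.frame"))
}

#' Retained rows of a harmonized dataset
#' @param data a `harmonized_data` object.
#' @return The subset of rows with `keep = TRUE`.
#' @export
retained <- function(data) {
  stopifnot(inherits(data, "harmonized_data"))
  data[data$keep, , drop = FALSE]
}
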