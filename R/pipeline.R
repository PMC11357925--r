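# Orchestration: forward/reverse screening of many exposures against one
# outcome, with sensitivity gating and report tables, plus the mediator
# screen for a chosen top exposure.

#' Screening run configuration
#'
#' @param exposures named list: trait id -> [summary_stats] object or
#'   file path (read with the canonical dialect).
#' @param outcome [summary_stats] object or file path.
#' @param mediators optional named list like `exposures`.
#' @param p_forward instrument threshold for exposure traits (default
#'   1e-5).
#' @param p_reverse instrument threshold for the disease trait in the
#'   reverse direction (default 5e-8).
#' @param r2_clump,f_min clumping and strength thresholds.
#' @param alpha significance level for gates (default 0.05).
#' @param multiple_testing `"none"` (default) or `"bh_fdr"`;
#'   Benjamini-Hochberg adjusted IVW p-values are added as an extra
#'   column, never silently substituted into the gate.
#' @param seed root seed; per-exposure bootstrap/simulation seeds are
#'   derived as `seed + index` in manifest order.
#' @param n_boot bootstrap replicates for median/mode SEs.
#' @param presso_nsim MR-PRESSO simulation count (set to 0 to skip
#'   MR-PRESSO in a screen).
#' @param ld LD specification for [ld_lookup()].
#' @param out_dir optional directory; when given, report tables are
#'   written there as TSV (`screen_estimates.tsv`,
#'   `screen_sensitivity.tsv`, `screen_gates.tsv`, `skipped.tsv`,
#'   `mediation.tsv`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(exposures, outcome, mediators = NULL,
                       p_forward = 1e-5, p_reverse = 5e-8,
                       r2_clump = 0.001, f_min = 10, alpha = 0.05,
                       multiple_testing = c("none", "bh_fdr"),
                       seed = 1, n_boot = 1000, presso_nsim = 1000,
                       ld = NULL, out_dir = NULL) {
  multiple_testing <- match.arg(multiple_testing)
  stopifnot(p_forward > 0, p_forward <= 1, p_reverse > 0, p_reverse <= 1,
            r2_clump > 0, r2_clump <= 1, f_min >= 0,
            alpha > 0, alpha < 1)
  structure(list(exposures = exposures, outcome = outcome,
                 mediators = mediators, p_forward = p_forward,
                 p_reverse = p_reverse, r2_clump = r2_clump,
                 f_min = f_min, alpha = alpha,
                 multiple_testing = multiple_testing, seed = seed,
                 n_boot = n_boot, presso_nsim = presso_nsim, ld = ld,
                 out_dir = out_dir),
            class = "run_config")
}

load_stats <- function(x, trait_id) {
  if (inherits(x, "summary_stats")) return(x)
  if (is.character(x) && length(x) == 1L)
    return(read_summary_stats(x, "canonical", trait_id = trait_id))
  stop("manifest entries must be summary_stats objects or file paths")
}

estimate_row <- function(exposure_id, outcome_id, est) {
  data.frame(Exposure = exposure_id, Outcome = outcome_id,
             Method = method_label(est$method), NSNPs = est$n_snp,
             Pval = est$pval, b = est$beta, lo_ci = est$lo_ci,
             up_ci = est$up_ci, OR = est$or_, OR_lci95 = est$or_lci95,
             OR_uci95 = est$or_uci95, stringsAsFactors = FALSE)
}

screen_one <- function(exposure_id, exposure, outcome, p_threshold,
                       config, task_seed) {
  iv <- suppressWarnings(
    select_instruments(exposure, p_threshold = p_threshold,
                       ld = config$ld, f_min = config$f_min,
                       r2_clump = config$r2_clump))
  h <- harmonize(iv, outcome)
  r <- retained(h)
  if (nrow(r) < 2L)
    return(list(skipped = sprintf("%d usable SNPs after harmonization",
                                  nrow(r))))
  ests <- mr_all_methods(h, n_boot = config$n_boot, seed = task_seed)
  m <- nrow(r)
  het <- rbind(
    if (m >= 3L) cochran_q(h, "mr_egger"),
    cochran_q(h, "ivw"))
  pleio <- if (m >= 3L) egger_intercept_test(h) else NULL
  presso <- if (m >= 4L && config$presso_nsim >= 100)
    mr_presso(h, n_sim = config$presso_nsim, seed = task_seed)
  else NULL
  loo <- if (m >= 3L) leave_one_out(h) else NULL
  ivw <- ests[ests$method == "ivw", , drop = FALSE]
  gate <- gate_exposure(ivw, pleio, het, alpha = config$alpha)
  list(harmonized = h, estimates = ests, heterogeneity = het,
       pleiotropy = pleio, presso = presso, loo = loo, gate = gate)
}

#' Run the MR screen over a manifest of exposures
#'
#' For each exposure: instrument selection (forward or reverse
#' threshold), harmonization against the outcome, the five-estimator
#' suite, heterogeneity and pleiotropy diagnostics, MR-PRESSO, the
#' leave-one-out series, and the pleiotropy gate.  In the reverse
#' direction the outcome trait plays the exposure role (threshold
#' `p_reverse`) against each manifest trait as outcome.  Exposures with
#' fewer than 2 usable SNPs are skipped with a recorded reason; other
#' per-exposure failures are isolated and recorded, never fatal for the
#' run.  Every manifest trait appears exactly once across the
#' categories significant / not_significant / gated_out / skipped.
#'
#' @param config a [run_config()].
#' @param direction `"forward"` or `"reverse"`.
#' @return An object of class `screen_report`: list with `estimates`
#'   (Table-style rows: Exposure, Outcome, Method, NSNPs, Pval, b,
#'   lo_ci, up_ci, OR, OR_lci95, OR_uci95), `sensitivity` (method, Q,
#'   Q_df, Q_pval, egger_intercept, SE, p-value per pair), `gates`,
#'   `presso`, `loo_flags`, `skipped`, and run metadata.
#' @export
run_screen <- function(config, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  stopifnot(inherits(config, "run_config"))
  outcome <- load_stats(config$outcome,
                        if (is.character(config$outcome)) "outcome"
                        else NULL)
  manifest <- config$exposures
  ids <- names(manifest)
  if (is.null(ids) && length(manifest))
    stop("the exposure manifest must be named by trait id")

  est_rows <- list(); sens_rows <- list(); gate_rows <- list()
  skip_rows <- list(); presso_rows <- list(); loo_rows <- list()
  for (i in seq_along(manifest)) {
    id <- ids[i]
    task_seed <- config$seed + i
    res <- tryCatch({
      expo <- load_stats(manifest[[i]], id)
      if (direction == "forward")
        screen_one(expo$trait_id, expo, outcome, config$p_forward,
                   config, task_seed)
      else
        screen_one(outcome$trait_id, outcome, expo, config$p_reverse,
                   config, task_seed)
    }, error = function(e) list(skipped = conditionMessage(e)))
    exposure_id <- if (direction == "forward") id else outcome$trait_id
    outcome_id <- if (direction == "forward") outcome$trait_id else id
    if (!is.null(res$skipped)) {
      skip_rows[[id]] <- data.frame(trait = id, reason = res$skipped,
                                    stringsAsFactors = FALSE)
      next
    }
    est_rows[[id]] <- do.call(rbind, lapply(seq_len(nrow(res$estimates)),
      function(k) estimate_row(exposure_id, outcome_id,
                               res$estimates[k, , drop = FALSE])))
    het <- res$heterogeneity
    pleio <- res$pleiotropy
    sens_rows[[id]] <- data.frame(
      Exposure = exposure_id, Outcome = outcome_id,
      Method = method_label(het$method), Q = het$Q, Q_df = het$Q_df,
      Q_pval = het$Q_pval,
      egger_intercept = c(if (is.null(pleio)) NA_real_
                          else pleio$egger_intercept,
                          rep(NA_real_, nrow(het) - 1L)),
      SE = c(if (is.null(pleio)) NA_real_ else pleio$se,
             rep(NA_real_, nrow(het) - 1L)),
      p_value = c(if (is.null(pleio)) NA_real_ else pleio$pval,
                  rep(NA_real_, nrow(het) - 1L)),
      stringsAsFactors = FALSE)
    gate_rows[[id]] <- data.frame(
      trait = id, n_snp = res$estimates$n_snp[1],
      ivw_beta = res$estimates$beta[res$estimates$method == "ivw"],
      ivw_pval = res$gate$ivw_pval,
      intercept_pval = res$gate$intercept_pval,
      cleared = res$gate$cleared, significant = res$gate$significant,
      category = res$gate$category, stringsAsFactors = FALSE)
    if (!is.null(res$presso))
      presso_rows[[id]] <- data.frame(
        trait = id, global_rss = res$presso$global_rss_obs,
        global_pval = res$presso$global_pval,
        n_outliers = length(res$presso$outliers),
        outliers = paste(res$presso$outliers, collapse = ","),
        distortion_pval = res$presso$distortion_pval,
        beta_corrected = res$presso$beta_corrected$beta,
        stringsAsFactors = FALSE)
    if (!is.null(res$loo))
      loo_rows[[id]] <- data.frame(
        trait = id, n_influential = sum(res$loo$influential),
        influential = paste(res$loo$left_out[res$loo$influential],
                            collapse = ","),
        stringsAsFactors = FALSE)
  }
  bind <- function(x) if (length(x)) {
    out <- do.call(rbind, x); rownames(out) <- NULL; out
  } else NULL
  gates <- bind(gate_rows)
  if (!is.null(gates) && config$multiple_testing == "bh_fdr")
    gates$ivw_padj_bh <- stats::p.adjust(gates$ivw_pval, method = "BH")
  report <- structure(list(
    direction = direction, estimates = bind(est_rows),
    sensitivity = bind(sens_rows), gates = gates,
    presso = bind(presso_rows), loo_flags = bind(loo_rows),
    skipped = bind(skip_rows),
    meta = list(seed = config$seed, alpha = config$alpha,
                p_threshold = if (direction == "forward")
                  config$p_forward else config$p_reverse,
                n_traits = length(manifest),
                package_version = as.character(
                  utils::packageVersion("mrmediate")))),
    class = "screen_report")
  if (!is.null(config$out_dir)) write_screen_report(report, config$out_dir)
  report
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report>", x$direction, "direction;",
      x$meta$n_traits, "manifest trait(s)\n")
  if (!is.null(x$gates)) {
    tab <- table(x$gates$category)
    for (nm in names(tab)) cat("  ", nm, ":", tab[[nm]], "\n")
  }
  if (!is.null(x$skipped)) cat("  skipped:", nrow(x$skipped), "\n")
  invisible(x)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

write_screen_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$estimates))
    write_tsv(report$estimates, file.path(out_dir, "screen_estimates.tsv"))
  if (!is.null(report$sensitivity))
    write_tsv(report$sensitivity,
              file.path(out_dir, "screen_sensitivity.tsv"))
  if (!is.null(report$gates))
    write_tsv(report$gates, file.path(out_dir, "screen_gates.tsv"))
  if (!is.null(report$skipped))
    write_tsv(report$skipped, file.path(out_dir, "skipped.tsv"))
  invisible(out_dir)
}

#' Run the mediator screen for one exposure
#'
#' Runs [mediation_screen()] for `top_exposure` against the configured
#' mediator manifest, using the run's thresholds, and writes
#' `mediation.tsv` when an output directory is configured.
#'
#' @param config a [run_config()] with a `mediators` manifest.
#' @param top_exposure trait id present in the exposure manifest.
#' @return The ranked data.frame from [mediation_screen()].
#' @export
run_mediation <- function(config, top_exposure) {
  stopifnot(inherits(config, "run_config"))
  if (!top_exposure %in% names(config$exposures))
    stop("top_exposure '", top_exposure, "' not in the exposure manifest")
  if (is.null(config$mediators) || length(config$mediators) == 0L) {
    warning("no mediators configured; returning empty table")
    return(data.frame(exposure = character(0), mediator = character(0)))
  }
  expo <- load_stats(config$exposures[[top_exposure]], top_exposure)
  outcome <- load_stats(config$outcome, "outcome")
  meds <- lapply(seq_along(config$mediators), function(i)
    load_stats(config$mediators[[i]], names(config$mediators)[i]))
  mc <- mediation_config(p_threshold = config$p_forward,
                         f_min = config$f_min,
                         r2_clump = config$r2_clump,
                         alpha = config$alpha, ld = config$ld)
  out <- mediation_screen(expo, meds, outcome, mc)
  if (nrow(out) == 0L)
    warning("no mediator passed the significance and pleiotropy gates")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(out, file.path(config$out_dir, "mediation.tsv"))
  }
  out
}

#' Recipe for reproducing the published real-data analysis
#'
#' The screening results this package is designed around were obtained
#' on public GWAS summary statistics that are not redistributed here.
#' This function returns a structured description of the inputs and
#' settings needed to re-run the full analysis: the GWAS Catalog
#' accession ranges for the lipidome and metabolite exposure panels, the
#' FinnGen outcome trait, the instrument-selection thresholds, and the
#' processing steps in order.  Note that exact reproduction of published
#' instrument lists additionally requires the original European LD
#' reference panel used for clumping.
#'
#' @return A list of class `reproduction_recipe` with elements `sources`,
#'   `thresholds` and `steps`.
#' @export
reproduction_recipe <- function() {
  structure(list(
    sources = list(
      lipidome = list(
        accessions = "GCST90277238-GCST90277416",
        description = "179 lipid species, 7174 Finnish individuals",
        repository = "GWAS Catalog"),
      metabolites = list(
        accessions = "GCST90199621-GCST90201020",
        description = "1091 metabolites and 309 metabolite ratios, 8299 participants",
        repository = "GWAS Catalog"),
      outcome = list(
        trait_id = "finn-b-M13_INTERVERTEB",
        description = paste("intervertebral disc degeneration, 184683",
                            "subjects (20001 cases, 164682 controls),",
                            "16380337 SNPs"),
        repository = "FinnGen")),
    thresholds = list(p_forward = 1e-5, p_reverse = 5e-8,
                      r2_clump = 0.001, f_min = 10, alpha = 0.05),
    steps = c(
      "download the exposure, mediator and outcome summary statistics from the repositories above",
      "read each file with read_summary_stats() using the gwas_catalog or finngen dialect",
      "obtain a European-ancestry LD reference and supply pairwise r2 via ld_lookup()",
      "run_screen(config, 'forward') for the lipid and metabolite panels against the outcome",
      "run_screen(config, 'reverse') for the disease trait against each lipid",
      "keep exposures that are IVW-significant and clear the pleiotropy gate",
      "run_mediation(config, top_exposure) with the metabolite manifest as mediators")),
    class = "reproduction_recipe")
}

#' @export
print.reproduction_recipe <- function(x, ...) {
  cat("Reproduction recipe (requires downloading the original data):\n")
  for (nm in names(x$sources)) {
    s <- x$sources[[nm]]
    cat(sprintf("  %s [%s]: %s (%s)\n", nm, s$repository,
                if (!is.null(s$accessions)) s$accessions else s$trait_id,
                s$description))
  }
  cat("  thresholds:",
      paste(names(x$thresholds), unlist(x$thresholds), sep = "=",
            collapse = ", "), "\n")
  cat("  steps:\n")
  for (s in x$steps) cat("   -", s, "\n")
  invisible(x)
}
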