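# Reading, validating and writing GWAS summary-statistic tables.
#
# Everything downstream consumes one internal representation: a
# `summary_stats` object holding per-variant associations with a single
# trait.  Source files differ only in column naming, which is absorbed by
# a dialect column map at read time.

#' Canonical per-variant columns
#'
#' The internal representation of one SNP's association with one trait.
#' All readers map onto these columns; all writers emit them.
#'
#' @format A character vector of column names:
#' \describe{
#'   \item{snp_id}{rsID string, unique within one trait.}
#'   \item{chrom}{chromosome label.}
#'   \item{pos}{1-based base-pair position.}
#'   \item{effect_allele, other_allele}{non-empty uppercase strings over
#'     A/C/G/T (single- or multi-base); must differ.}
#'   \item{eaf}{effect-allele frequency, strictly inside (0, 1); may be
#'     missing (NA) when the source lacks it, in which case palindromic
#'     variants are always dropped at harmonization.}
#'   \item{beta}{per-allele effect on the trait (log-odds for binary
#'     traits).}
#'   \item{se}{standard error of beta, > 0.}
#'   \item{pval}{association p-value in (0, 1]; exact zeros are clamped
#'     to the smallest positive double with a warning.}
#'   \item{n}{sample size, >= 1.}
#' }
#' @keywords internal
#' @name variant_columns
NULL

.variant_cols <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pval", "n")

# Built-in column dialects.  Values name the file columns; NA marks a field
# the dialect does not carry.
.dialects <- list(
  canonical = c(snp_id = "snp_id", chrom = "chrom", pos = "pos",
                effect_allele = "effect_allele", other_allele = "other_allele",
                eaf = "eaf", beta = "beta", se = "se", pval = "pval", n = "n"),
  gwas_catalog = c(snp_id = "variant_id", chrom = "chromosome",
                   pos = "base_pair_location",
                   effect_allele = "effect_allele",
                   other_allele = "other_allele",
                   eaf = "effect_allele_frequency", beta = "beta",
                   se = "standard_error", pval = "p_value", n = "n"),
  finngen = c(snp_id = "rsids", chrom = "#chrom", pos = "pos",
              effect_allele = "alt", other_allele = "ref",
              eaf = "af_alt", beta = "beta", se = "sebeta", pval = "pval",
              n = NA)
)

#' Construct a summary_stats object
#'
#' @param variants data.frame with the canonical per-variant columns
#'   (see [variant_columns]); rows violating the type invariants are
#'   dropped with a message.
#' @param trait_id identifier of the trait (e.g. a GWAS accession).
#' @param trait_label free-text description.
#' @param validate drop invalid rows (default TRUE).
#' @return An object of class `summary_stats`: a list with `trait_id`,
#'   `trait_label` and `variants`.
#' @export
summary_stats <- function(variants, trait_id, trait_label = trait_id,
                          validate = TRUE) {
  stopifnot(is.data.frame(variants), is.character(trait_id),
            length(trait_id) == 1L)
  missing_cols <- setdiff(setdiff(.variant_cols, c("eaf", "n")),
                          names(variants))
  if (length(missing_cols))
    stop("missing required variant columns: ",
         paste(missing_cols, collapse = ", "))
  if (!"eaf" %in% names(variants)) variants$eaf <- NA_real_
  if (!"n" %in% names(variants)) variants$n <- NA_real_
  variants <- variants[.variant_cols]
  if (validate) variants <- validate_variants(variants)
  if (anyDuplicated(variants$snp_id))
    stop("duplicated snp_id within one summary_stats: ",
         variants$snp_id[duplicated(variants$snp_id)][1L])
  structure(list(trait_id = trait_id, trait_label = trait_label,
                 variants = variants),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat("<summary_stats> trait:", x$trait_id,
      sprintf("(%s)", x$trait_label), "\n")
  cat("  ", nrow(x$variants), "variants\n")
  invisible(x)
}

#' Number of variants in a summary_stats object
#' @param x a `summary_stats` object.
#' @export
n_variants <- function(x) nrow(x$variants)

# Enforce the VariantAssociation invariants, dropping offending rows.
# Zero p-values are clamped (not dropped) so that -log transforms stay
# finite downstream.
validate_variants <- function(v) {
  v$snp_id <- as.character(v$snp_id)
  v$effect_allele <- toupper(as.character(v$effect_allele))
  v$other_allele <- toupper(as.character(v$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n"))
    v[[col]] <- suppressWarnings(as.numeric(v[[col]]))

  zero_p <- !is.na(v$pval) & v$pval == 0
  if (any(zero_p)) {
    warning(sum(zero_p), " p-value(s) of exactly 0 clamped to ",
            format(.Machine$double.xmin), call. = FALSE)
    v$pval[zero_p] <- .Machine$double.xmin
  }

  allele_ok <- function(a) !is.na(a) & nzchar(a) & grepl("^[ACGT]+$", a)
  ok <- !is.na(v$snp_id) & nzchar(v$snp_id) &
    allele_ok(v$effect_allele) & allele_ok(v$other_allele) &
    v$effect_allele != v$other_allele &
    (is.na(v$eaf) | (v$eaf > 0 & v$eaf < 1)) &
    !is.na(v$se) & v$se > 0 &
    !is.na(v$beta) &
    !is.na(v$pval) & v$pval > 0 & v$pval <= 1 &
    (is.na(v$n) | v$n >= 1)
  n_bad <- sum(!ok)
  if (n_bad > 0)
    message(n_bad, " row(s) dropped for violating variant invariants")
  out <- v[ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

resolve_column_map <- function(column_map) {
  if (is.character(column_map) && length(column_map) == 1L &&
      is.null(names(column_map))) {
    if (!column_map %in% names(.dialects))
      stop("unknown dialect '", column_map, "'; available: ",
           paste(names(.dialects), collapse = ", "))
    return(.dialects[[column_map]])
  }
  if (is.null(names(column_map)) || !all(nzchar(names(column_map))))
    stop("a user column map must be a named character vector ",
         "(canonical field -> file column)")
  unknown <- setdiff(names(column_map), .variant_cols)
  if (length(unknown))
    stop("unknown canonical field(s) in column map: ",
         paste(unknown, collapse = ", "))
  map <- stats::setNames(rep(NA_character_, length(.variant_cols)),
                         .variant_cols)
  map[names(column_map)] <- column_map
  map
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab-separated file (gzip-compressed input is accepted) and maps
#' its columns onto the canonical per-variant representation.  Rows that
#' violate the variant invariants are dropped and counted in a message.
#'
#' @param path path to a TSV file with header.
#' @param column_map either the name of a built-in dialect
#'   (`"canonical"`, `"gwas_catalog"`, `"finngen"`) or a named character
#'   vector mapping canonical fields to file columns.  Fields mapped to
#'   `NA` (or omitted) are treated as absent from the source.
#' @param trait_id trait identifier stored on the result.
#' @param trait_label free-text label (defaults to `trait_id`).
#' @param n sample size used to fill the `n` field when the dialect does
#'   not carry one (e.g. FinnGen release files).
#' @return A [summary_stats] object.
#' @export
read_summary_stats <- function(path, column_map = "canonical", trait_id,
                               trait_label = trait_id, n = NA_real_) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  map <- resolve_column_map(column_map)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "", quote = "")
  required <- c("snp_id", "effect_allele", "other_allele", "beta", "se",
                "pval")
  for (field in required) {
    if (is.na(map[[field]]) || !map[[field]] %in% names(raw))
      stop("schema error: required column for field '", field,
           "' (", map[[field]], ") not found in ", path)
  }
  cols <- lapply(.variant_cols, function(field) {
    src <- map[[field]]
    if (!is.na(src) && src %in% names(raw)) raw[[src]] else rep(NA, nrow(raw))
  })
  v <- stats::setNames(as.data.frame(cols, stringsAsFactors = FALSE,
                                     optional = TRUE), .variant_cols)
  if (nrow(v) > 0L && all(is.na(v$n))) v$n <- n
  summary_stats(v, trait_id = trait_id, trait_label = trait_label)
}

#' Write a summary_stats object to a tab-separated file
#'
#' Numeric fields are written at full double precision (15 significant
#' digits) so that `read_summary_stats()` of the written file reproduces
#' the object field-for-field.  The trait id and label travel with the
#' table as extra columns, which the canonical dialect ignores on read.
#'
#' @param stats a [summary_stats] object.
#' @param path output path.
#' @export
write_summary_stats <- function(stats, path) {
  stopifnot(inherits(stats, "summary_stats"))
  v <- stats$variants
  out <- v
  for (col in c("eaf", "beta", "se", "pval"))
    out[[col]] <- vapply(v[[col]], function(x)
      if (is.na(x)) "NA" else format(x, digits = 15, scientific = TRUE),
      character(1))
  out$trait_id <- rep(stats$trait_id, nrow(v))
  out$trait_label <- rep(stats$trait_label, nrow(v))
  tryCatch(
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE),
    error = function(e) stop("cannot write file: ", path, " (",
                             conditionMessage(e), ")", call. = FALSE))
  invisible(path)
}
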