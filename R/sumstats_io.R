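# Canonical internal column set for a summary-statistics table
.SUMSTATS_COLS <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                    "eaf", "beta", "se", "pval", "n", "n_cases", "trait_type")

#' Default column mapping for summary-statistics tables
#'
#' Maps the short config keys used throughout the package to column names in
#' an input file. Override any entry via the `column_map` argument of
#' [read_gwas_table()].
#'
#' @return Named character vector: keys are `snp, chr, pos, ea, oa, eaf, beta,
#'   se, p, n, ncase`, values the column names expected in the file.
#' @export
default_column_map <- function() {
  c(snp = "snp", chr = "chr", pos = "pos", ea = "ea", oa = "oa", eaf = "eaf",
    beta = "beta", se = "se", p = "p", n = "n", ncase = "ncase")
}

.complement <- function(a) chartr("ACGT", "TGCA", a)

.is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "G" & oa == "C") | (ea == "C" & oa == "G")
}

#' Assemble and validate a variant-association table
#'
#' Builds the canonical per-variant summary-statistics data frame used by all
#' downstream operations. One row is one variant's marginal association with
#' one trait: effect allele, other allele, effect-allele frequency, per-allele
#' effect (log-odds for case-control traits), its standard error, p-value and
#' sample sizes.
#'
#' Rows violating hard invariants (non-finite or non-positive `se`, non-finite
#' `beta`, identical alleles, `eaf` outside (0,1), `pval` outside (0,1]) are
#' dropped; the number of dropped rows is recorded in the `"n_dropped"`
#' attribute. A p-value merely inconsistent with `|beta/se|` triggers a
#' warning, never a drop: reported p-values legitimately come from
#' non-Wald tests.
#'
#' @param df Data frame with (a subset of) the canonical columns
#'   `variant_id, chrom, pos, effect_allele, other_allele, eaf, beta, se,
#'   pval, n, n_cases`.
#' @param trait_type `"quantitative"` or `"case_control"`.
#' @param check_pval Warn when `|z from p| - |beta/se|` exceeds 0.5.
#' @return Data frame of class `variant_assoc`, sorted by (chrom, pos), with
#'   attribute `n_dropped`.
#' @export
variant_assoc <- function(df, trait_type = c("quantitative", "case_control"),
                          check_pval = TRUE) {
  trait_type <- match.arg(trait_type)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("eaf", "n", "n_cases", "pval")) {
    if (is.null(df[[col]])) df[[col]] <- NA_real_
  }
  if (is.null(df$chrom)) df$chrom <- NA_character_
  if (is.null(df$pos)) df$pos <- NA_real_
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  df$chrom <- as.character(df$chrom)
  for (col in c("pos", "eaf", "beta", "se", "pval", "n", "n_cases")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df$variant_id <- as.character(df$variant_id)

  ok <- is.finite(df$beta) & is.finite(df$se) & df$se > 0 &
    df$effect_allele != df$other_allele &
    (is.na(df$eaf) | (df$eaf > 0 & df$eaf < 1)) &
    (is.na(df$pval) | (df$pval > 0 & df$pval <= 1))
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message(n_dropped, " row(s) dropped during validation")
  }
  df <- df[ok, , drop = FALSE]
  if (nrow(df) == 0) stop("no valid rows after validation", call. = FALSE)
  if (anyDuplicated(df$variant_id)) {
    stop("duplicated variant_id in summary statistics: ",
         df$variant_id[duplicated(df$variant_id)][1], call. = FALSE)
  }
  if (is.na(df$pval[1]) || any(is.na(df$pval))) {
    miss <- is.na(df$pval)
    df$pval[miss] <- 2 * stats::pnorm(-abs(df$beta[miss] / df$se[miss]))
  }
  if (check_pval) {
    z_p <- stats::qnorm(pmax(df$pval, .Machine$double.xmin) / 2, lower.tail = FALSE)
    dev <- abs(z_p - abs(df$beta / df$se))
    if (any(is.finite(dev) & dev > 0.5)) {
      warning(sum(dev > 0.5, na.rm = TRUE),
              " variant(s) with p-value inconsistent with beta/se (|dz| > 0.5)",
              call. = FALSE)
    }
  }
  df$trait_type <- trait_type
  df <- df[order(df$chrom, df$pos, df$variant_id), .SUMSTATS_COLS, drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_dropped") <- n_dropped
  class(df) <- c("variant_assoc", "data.frame")
  df
}

#' Read a GWAS/QTL summary-statistics table from disk
#'
#' Reads a whitespace/tab-delimited text file with a header and maps its
#' columns onto the canonical variant-association schema. Alleles are
#' upper-cased; rows with unparseable or invalid beta/se are dropped and
#' counted.
#'
#' @param path File path.
#' @param column_map Named character vector or list overriding entries of
#'   [default_column_map()] (keys `snp, chr, pos, ea, oa, eaf, beta, se, p, n,
#'   ncase`).
#' @param trait_type `"quantitative"` or `"case_control"`.
#' @return A `variant_assoc` data frame (see [variant_assoc()]).
#' @export
read_gwas_table <- function(path, column_map = default_column_map(),
                            trait_type = c("quantitative", "case_control")) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cmap <- default_column_map()
  cmap[names(column_map)] <- unlist(column_map)
  raw <- utils::read.table(path, header = TRUE, sep = "", quote = "",
                           comment.char = "", stringsAsFactors = FALSE,
                           check.names = FALSE)
  mandatory <- c("snp", "ea", "oa", "beta", "se")
  for (key in mandatory) {
    if (!cmap[[key]] %in% names(raw)) {
      stop("mandatory column '", cmap[[key]], "' (", key, ") missing from ",
           path, call. = FALSE)
    }
  }
  pick <- function(key) if (cmap[[key]] %in% names(raw)) raw[[cmap[[key]]]] else NA
  df <- data.frame(variant_id = pick("snp"), chrom = pick("chr"),
                   pos = pick("pos"), effect_allele = pick("ea"),
                   other_allele = pick("oa"), eaf = pick("eaf"),
                   beta = pick("beta"), se = pick("se"), pval = pick("p"),
                   n = pick("n"), n_cases = pick("ncase"),
                   stringsAsFactors = FALSE)
  variant_assoc(df, trait_type = trait_type)
}

#' Write a summary-statistics or harmonized table as TSV
#'
#' @param x Data frame (e.g. `variant_assoc` or the output of [harmonize()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Harmonize exposure and outcome summary statistics to a shared effect allele
#'
#' Restricts both tables to their shared variant IDs and re-orients outcome
#' effects so that `beta_exp` and `beta_out` refer to the same effect allele.
#' Outcome rows whose alleles are swapped relative to the exposure have
#' `beta_out` negated and `eaf` reflected (`action = "flipped"`); strand flips
#' (complement alleles) are resolved silently. Strand-ambiguous palindromic
#' variants (A/T, G/C) cannot be oriented from allele letters: when both
#' tables carry an informative frequency (`min(eaf, 1-eaf) <= 0.5 -
#' palindromic_eaf_window`) the orientation is inferred from frequency
#' concordance; otherwise the variant is dropped. Allele sets matching neither
#' directly, after swap, nor after strand flip are dropped as mismatches.
#'
#' Dropped variants never appear in the output; per-action counts (including
#' `dropped_palindromic` and `dropped_mismatch`) are in the `"action_counts"`
#' attribute.
#'
#' @param exposure,outcome `variant_assoc` data frames.
#' @param palindromic_eaf_window Half-width of the frequency exclusion zone
#'   around 0.5 (default 0.08: palindromic variants with
#'   `min(eaf, 1-eaf) > 0.42` in either table are dropped).
#' @return Data frame of class `harmonized` with columns `variant_id, chrom,
#'   pos, effect_allele, other_allele, eaf, beta_exp, se_exp, pval_exp, n_exp,
#'   beta_out, se_out, pval_out, n_out, n_cases_out, outcome_trait_type,
#'   harmonize_action`, sorted by (chrom, pos).
#' @export
harmonize <- function(exposure, outcome, palindromic_eaf_window = 0.08) {
  stopifnot(palindromic_eaf_window >= 0, palindromic_eaf_window < 0.5)
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  if (length(shared) == 0) stop("no shared variants between exposure and outcome",
                                call. = FALSE)
  ex <- exposure[match(shared, exposure$variant_id), , drop = FALSE]
  ou <- outcome[match(shared, outcome$variant_id), , drop = FALSE]

  k <- length(shared)
  action <- character(k)
  beta_out <- ou$beta
  eaf_out <- ou$eaf

  pal_x <- .is_palindromic(ex$effect_allele, ex$other_allele)
  pal_y <- .is_palindromic(ou$effect_allele, ou$other_allele)
  informative <- function(f) !is.na(f) & pmin(f, 1 - f) <= 0.5 - palindromic_eaf_window

  for (i in seq_len(k)) {
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ou$effect_allele[i]; oa_y <- ou$other_allele[i]
    if (pal_x[i] || pal_y[i]) {
      same_set <- setequal(c(ea_x, oa_x), c(ea_y, oa_y))
      if (!same_set || !(pal_x[i] && pal_y[i])) {
        action[i] <- "dropped_mismatch"
      } else if (!informative(ex$eaf[i]) || !informative(ou$eaf[i])) {
        action[i] <- "dropped_palindromic"
      } else if ((ex$eaf[i] - 0.5) * (ou$eaf[i] - 0.5) > 0) {
        action[i] <- "kept"          # frequencies concordant: same orientation
      } else {
        action[i] <- "flipped"
        beta_out[i] <- -beta_out[i]
        eaf_out[i] <- 1 - eaf_out[i]
      }
    } else if (ea_y == ea_x && oa_y == oa_x) {
      action[i] <- "kept"
    } else if (ea_y == oa_x && oa_y == ea_x) {
      action[i] <- "flipped"
      beta_out[i] <- -beta_out[i]
      eaf_out[i] <- if (is.na(eaf_out[i])) NA_real_ else 1 - eaf_out[i]
    } else if (.complement(ea_y) == ea_x && .complement(oa_y) == oa_x) {
      action[i] <- "kept"            # strand flip only
    } else if (.complement(ea_y) == oa_x && .complement(oa_y) == ea_x) {
      action[i] <- "flipped"         # strand flip + swap
      beta_out[i] <- -beta_out[i]
      eaf_out[i] <- if (is.na(eaf_out[i])) NA_real_ else 1 - eaf_out[i]
    } else {
      action[i] <- "dropped_mismatch"
    }
  }

  res <- data.frame(variant_id = ex$variant_id, chrom = ex$chrom, pos = ex$pos,
                    effect_allele = ex$effect_allele,
                    other_allele = ex$other_allele, eaf = ex$eaf,
                    beta_exp = ex$beta, se_exp = ex$se, pval_exp = ex$pval,
                    n_exp = ex$n, beta_out = beta_out, se_out = ou$se,
                    pval_out = ou$pval, n_out = ou$n,
                    n_cases_out = ou$n_cases,
                    outcome_trait_type = ou$trait_type,
                    harmonize_action = action, stringsAsFactors = FALSE)
  counts <- table(factor(action, levels = c("kept", "flipped",
                                            "dropped_palindromic",
                                            "dropped_mismatch")))
  res <- res[!startsWith(action, "dropped"), , drop = FALSE]
  res <- res[order(res$chrom, res$pos, res$variant_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "action_counts") <- counts
  class(res) <- c("harmonized", "data.frame")
  res
}
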