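#' Compare a locus-specific mediator effect against the genome-wide expectation
#'
#' Tests whether the effect of a mediator (e.g. blood pressure) on the
#' outcome, proxied by a single index variant in a candidate locus, is
#' consistent with the mediator's genome-wide effect on the outcome estimated
#' after excluding that locus. Under full mediation the two estimates target
#' the same quantity; a locus-specific Wald estimate far above the
#' genome-wide IVW expectation rejects full mediation.
#'
#' @param index_variant rsID of the locus index variant.
#' @param mediator,outcome `variant_assoc` tables containing the index
#'   variant (mediator and outcome GWAS).
#' @param genomewide_instruments An `instrument_set` (or harmonized data
#'   frame) of genome-wide mediator instruments harmonized against the
#'   outcome.
#' @param exclusion_window_bp Instruments within this distance of the index
#'   variant (same chromosome) are removed before the genome-wide IVW
#'   (default 1 Mb).
#' @return List of class `mediation_report`: `observed_wald` and
#'   `expected_if_mediated` (`mr_result`s), `ratio` (observed/expected beta),
#'   `consistent` (95% CI overlap), and `diff_p` (z-test on the difference).
#' @export
mediation_consistency <- function(index_variant, mediator, outcome,
                                  genomewide_instruments,
                                  exclusion_window_bp = 1e6) {
  med_row <- mediator[mediator$variant_id == index_variant, , drop = FALSE]
  out_row <- outcome[outcome$variant_id == index_variant, , drop = FALSE]
  if (nrow(med_row) == 0 || nrow(out_row) == 0) {
    stop("index variant ", index_variant,
         " missing from mediator or outcome table", call. = FALSE)
  }
  pair <- harmonize(med_row, out_row, palindromic_eaf_window = 0)
  if (nrow(pair) == 0) stop("index variant could not be harmonized", call. = FALSE)
  observed <- wald_ratio(pair)

  gi <- .instruments_df(genomewide_instruments)
  near <- !is.na(gi$chrom) & gi$chrom == med_row$chrom[1] &
    abs(gi$pos - med_row$pos[1]) <= exclusion_window_bp
  gi <- gi[!near, , drop = FALSE]
  if (nrow(gi) < 2) {
    stop("fewer than 2 genome-wide instruments remain after excluding the locus",
         call. = FALSE)
  }
  expected <- ivw(gi)
  overlap <- observed$ci_low <= expected$ci_high &
    expected$ci_low <= observed$ci_high
  z <- (observed$beta - expected$beta) / sqrt(observed$se^2 + expected$se^2)
  structure(list(index_variant = index_variant, observed_wald = observed,
                 expected_if_mediated = expected,
                 ratio = observed$beta / expected$beta,
                 consistent = overlap,
                 diff_p = 2 * stats::pnorm(-abs(z)),
                 n_excluded = sum(near)),
            class = "mediation_report")
}

#' @export
print.mediation_report <- function(x, ...) {
  cat(sprintf("Mediation benchmark at %s\n  observed  %.3g [%.3g, %.3g]\n  expected  %.3g [%.3g, %.3g]\n  consistent (CI overlap): %s  (diff p=%.3g)\n",
              x$index_variant, x$observed_wald$beta, x$observed_wald$ci_low,
              x$observed_wald$ci_high, x$expected_if_mediated$beta,
              x$expected_if_mediated$ci_low, x$expected_if_mediated$ci_high,
              x$consistent, x$diff_p))
  invisible(x)
}

#' Condition outcome summary statistics on a mediator
#'
#' Removes the mediator-transmitted component from each outcome effect with
#' the linear adjustment `beta_cond = beta_out - theta * beta_med` and SE
#' propagation `se_cond = sqrt(se_out^2 + theta^2 se_med^2 +
#' beta_med^2 se_theta^2)` (the uncertainty in the mediator-to-outcome effect
#' `theta` is carried through). Variants absent from the mediator table pass
#' through unchanged with `conditioned = FALSE`. Note `se_cond` can be
#' smaller than `se_out` only when `theta = 0` and `se_theta = 0`; in general
#' it grows, and no ordering with the original SE is guaranteed or required.
#' Conditioning with `theta = 0` is the identity.
#'
#' @param outcome,mediator `variant_assoc` tables matched on `variant_id`
#'   (assumed already harmonized to a shared effect allele).
#' @param theta Mediator-to-outcome causal effect.
#' @param se_theta Its standard error (default 0).
#' @return The outcome table with `beta`/`se` replaced by the conditioned
#'   values, plus columns `beta_raw`, `se_raw`, `conditioned`.
#' @export
condition_on_mediator <- function(outcome, mediator, theta, se_theta = 0) {
  stopifnot(is.finite(theta), is.finite(se_theta), se_theta >= 0)
  out <- as.data.frame(outcome)
  idx <- match(out$variant_id, mediator$variant_id)
  has <- !is.na(idx)
  bm <- mediator$beta[idx[has]]
  sm <- mediator$se[idx[has]]
  out$beta_raw <- out$beta
  out$se_raw <- out$se
  out$beta[has] <- out$beta[has] - theta * bm
  out$se[has] <- sqrt(out$se[has]^2 + theta^2 * sm^2 + bm^2 * se_theta^2)
  out$pval <- pmax(2 * stats::pnorm(-abs(out$beta / out$se)),
                   .Machine$double.xmin)
  out$conditioned <- has
  class(out) <- c("variant_assoc", "data.frame")
  out
}

#' Rank gene-level causal effects on an outcome across a batch
#'
#' Runs the gated primary estimator (IVW when at least two instruments, Wald
#' ratio for single-instrument sets) for every gene-tissue instrument set in
#' a batch (e.g. all genes associated with blood pressure in an exome-wide
#' screen) and ranks them by absolute effect size. Ties in `|beta|` fall back
#' to lexicographic exposure ID, so the ranking is reproducible.
#'
#' @param gene_instrument_sets List of `instrument_set`s, each already
#'   harmonized against the outcome.
#' @param filter Optional character vector of exposure IDs to keep (e.g. the
#'   blood-pressure-associated gene set); an empty intersection is an error.
#' @return Data frame sorted by decreasing `|beta|`: `exposure_id, tier,
#'   method, n_snps, beta, se, ci_low, ci_high, pval, rank`.
#' @export
benchmark_exomewide <- function(gene_instrument_sets, filter = NULL) {
  ids <- vapply(gene_instrument_sets, function(s) s$exposure_id, character(1))
  if (!is.null(filter)) {
    keep <- ids %in% filter
    if (!any(keep)) stop("no instrument set matches the filter gene set",
                         call. = FALSE)
    gene_instrument_sets <- gene_instrument_sets[keep]
  }
  rows <- lapply(gene_instrument_sets, function(s) {
    if (s$n_independent == 0) return(NULL)
    fit <- if (s$n_independent >= 2) ivw(s) else wald_ratio(s)
    cbind(data.frame(exposure_id = s$exposure_id, tier = s$tier,
                     stringsAsFactors = FALSE),
          as.data.frame(fit))
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) == 0) stop("no analyzable instrument sets",
                                           call. = FALSE)
  tab <- tab[order(-abs(tab$beta), tab$exposure_id), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}
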