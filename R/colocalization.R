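.logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Select the variants in a window around a reference variant
#'
#' Keeps variants on the reference's chromosome whose position lies within
#' `half_width_bp` of the reference position, bounds inclusive.
#'
#' @param assocs `variant_assoc` data frame with chrom/pos.
#' @param reference rsID of the anchoring variant (typically the variant with
#'   the smallest exposure p-value).
#' @param half_width_bp Window half-width in base pairs (default 100 kb).
#' @return The subset of `assocs` inside the window.
#' @export
window_select <- function(assocs, reference, half_width_bp = 100000) {
  i <- match(reference, assocs$variant_id)
  if (is.na(i)) stop("reference variant ", reference, " not found", call. = FALSE)
  keep <- assocs$chrom == assocs$chrom[i] &
    abs(assocs$pos - assocs$pos[i]) <= half_width_bp
  out <- assocs[keep & !is.na(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Wakefield log approximate Bayes factor for one variant
#'
#' With sampling variance `V = se^2`, prior effect variance
#' `W = prior_sd^2` and shrinkage `r = W/(V+W)`, the log-ABF comparing an
#' effect to the null is `0.5*log(1-r) + (z^2/2)*r`.
#'
#' @param z Association z-score (`beta/se`).
#' @param se Standard error (> 0).
#' @param prior_sd Prior standard deviation of the true effect.
#' @return Finite log approximate Bayes factor.
#' @export
wakefield_labf <- function(z, se, prior_sd) {
  stopifnot(all(se > 0), prior_sd > 0)
  V <- se^2
  W <- prior_sd^2
  r <- W / (V + W)
  0.5 * log1p(-r) + (z^2 / 2) * r
}

.trait_prior_sd <- function(assocs, default_quant = 0.15, default_cc = 0.2) {
  tt <- assocs$trait_type[1]
  if (!is.null(tt) && identical(tt, "case_control")) default_cc else default_quant
}

#' Bayesian colocalization of two association signals (single-variant ABF)
#'
#' Enumerates the single-causal-variant configurations for two traits over
#' the shared variants of a locus window, scoring each variant by its
#' Wakefield log-ABF and combining them with per-hypothesis priors: H0 no
#' association, H1/H2 one trait only, H3 two distinct causal variants, H4
#' one shared causal variant. Posteriors are normalized with log-sum-exp;
#' evidence for colocalization is declared when PP4 exceeds the threshold.
#'
#' @param trait1,trait2 Windowed `variant_assoc` data frames (see
#'   [window_select()]); intersected on `variant_id`.
#' @param priors Length-3 vector `(p1, p2, p12)`: per-variant prior
#'   probabilities of association with trait 1 only, trait 2 only, and both.
#'   A `p12 > min(p1, p2)` warns.
#' @param prior_sd1,prior_sd2 Prior effect SDs; default 0.15 for quantitative
#'   and 0.2 for case-control traits.
#' @param pp4_threshold Shared-variant posterior required for a positive
#'   decision (default 0.7).
#' @param reference_variant Optional rsID recorded as the window anchor.
#' @return List of class `coloc_result`: `pp` (named PP0..PP4),
#'   `n_snps_window`, `reference_variant`, `priors`, `decision`.
#' @export
coloc_abf <- function(trait1, trait2, priors = c(1e-4, 1e-4, 1e-5),
                      prior_sd1 = NULL, prior_sd2 = NULL, pp4_threshold = 0.7,
                      reference_variant = NA_character_) {
  stopifnot(length(priors) == 3, all(priors > 0))
  p1 <- priors[1]; p2 <- priors[2]; p12 <- priors[3]
  if (p12 > min(p1, p2)) warning("p12 exceeds min(p1, p2)", call. = FALSE)
  shared <- intersect(trait1$variant_id, trait2$variant_id)
  if (length(shared) == 0) stop("no shared variants in window", call. = FALSE)
  t1 <- trait1[match(shared, trait1$variant_id), , drop = FALSE]
  t2 <- trait2[match(shared, trait2$variant_id), , drop = FALSE]
  if (is.null(prior_sd1)) prior_sd1 <- .trait_prior_sd(t1)
  if (is.null(prior_sd2)) prior_sd2 <- .trait_prior_sd(t2)

  z1 <- t1$beta / t1$se
  z2 <- t2$beta / t2$se
  ok <- is.finite(z1) & is.finite(z2)
  if (!all(ok)) {
    message(sum(!ok), " variant(s) with non-finite z skipped")
    t1 <- t1[ok, , drop = FALSE]; t2 <- t2[ok, , drop = FALSE]
    z1 <- z1[ok]; z2 <- z2[ok]
    if (length(z1) == 0) stop("no usable variants in window", call. = FALSE)
  }
  l1 <- wakefield_labf(z1, t1$se, prior_sd1)
  l2 <- wakefield_labf(z2, t2$se, prior_sd2)

  s1 <- .logsumexp(l1)                 # log sum_i ABF1_i
  s2 <- .logsumexp(l2)
  s12 <- .logsumexp(l1 + l2)           # log sum_i ABF1_i * ABF2_i
  # log( sum_{i != j} ABF1_i ABF2_j ) = log( e^{s1+s2} - e^{s12} )
  s3 <- if (length(z1) == 1 || s12 >= s1 + s2) -Inf
        else s1 + s2 + log1p(-exp(s12 - s1 - s2))

  lh <- c(H0 = 0,
          H1 = log(p1) + s1,
          H2 = log(p2) + s2,
          H3 = log(p1) + log(p2) + s3,
          H4 = log(p12) + s12)
  denom <- .logsumexp(lh)
  pp <- exp(lh - denom)
  names(pp) <- paste0("PP", 0:4)
  structure(list(pp = pp, n_snps_window = length(z1),
                 reference_variant = reference_variant,
                 priors = c(p1 = p1, p2 = p2, p12 = p12),
                 prior_sd = c(trait1 = prior_sd1, trait2 = prior_sd2),
                 pp4_threshold = pp4_threshold,
                 decision = unname(pp["PP4"] > pp4_threshold)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("Colocalization over", x$n_snps_window, "variants",
      if (!is.na(x$reference_variant)) paste0("(ref ", x$reference_variant, ")"),
      "\n")
  print(round(x$pp, 4))
  cat("shared-variant decision (PP4 >", x$pp4_threshold, "):", x$decision, "\n")
  invisible(x)
}
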