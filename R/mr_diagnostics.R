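#' Cochran's Q heterogeneity test across instruments
#'
#' Q over per-variant Wald ratios `r_j` with inverse-variance weights
#' `beta_exp_j^2 / se_out_j^2`, centred at the fixed-effect IVW estimate;
#' algebraically `sum((beta_out - beta_ivw * beta_exp)^2 / se_out^2)`.
#' Referred to a chi-squared distribution with k - 1 degrees of freedom.
#'
#' @param iset An `instrument_set` (or harmonized data frame) with >= 2
#'   variants.
#' @return List with elements `Q`, `df`, `p`.
#' @export
cochran_q <- function(iset) {
  v <- .instruments_df(iset)
  k <- nrow(v)
  if (k < 2) stop("Cochran's Q needs >= 2 instruments", call. = FALSE)
  fit <- ivw(v, model = "fixed")
  Q <- fit$Q
  list(Q = Q, df = k - 1L, p = stats::pchisq(Q, k - 1, lower.tail = FALSE))
}

# Leave-one-out fixed-effect IVW slopes, vectorized.
.loo_ivw <- function(bx, by, w) {
  s1 <- sum(w * bx * by)
  s2 <- sum(w * bx^2)
  (s1 - w * bx * by) / (s2 - w * bx^2)
}

#' MR-PRESSO-style pleiotropy residual sum and outlier test
#'
#' Simulation-based detection of pleiotropic instruments. (i) Global test:
#' the observed weighted residual sum of squares, with each instrument's
#' residual taken against the leave-one-out IVW slope, is compared with
#' `n_sim` RSS values simulated under the no-pleiotropy model
#' `beta_out_j* ~ N(beta_ivw(-j) * beta_exp_j, se_out_j)`. (ii) Outlier test:
#' each instrument's observed squared residual against its own simulated
#' distribution, Bonferroni-corrected across k. (iii) Distortion test: the
#' difference between the all-instrument and outlier-removed IVW estimates is
#' compared with the differences obtained by removing 1000 random
#' same-size subsets of non-outlier instruments.
#'
#' Fewer than 4 instruments returns a not-run marker (`run = FALSE`); absence
#' of a PRESSO estimate never disqualifies a target downstream.
#'
#' @param iset An `instrument_set`.
#' @param n_sim Simulated null RSS draws (default 5000; values below 1000
#'   warn about coarse p-values).
#' @param alpha Significance level for global and outlier flags.
#' @param seed Mandatory RNG seed.
#' @return List of class `presso_result`: `run`, `global_rss`, `global_p`,
#'   `outlier_indices`, `outlier_p` (Bonferroni-adjusted), `distortion_p`,
#'   `raw` and `corrected` `mr_result`s (`corrected` NULL without outliers).
#' @export
mr_presso <- function(iset, n_sim = 5000, alpha = 0.05, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  v <- .instruments_df(iset)
  k <- nrow(v)
  if (k < 4) {
    return(structure(list(run = FALSE, reason = "needs >= 4 independent instruments"),
                     class = "presso_result"))
  }
  if (n_sim < 1000) warning("n_sim < 1000: simulation p-values are coarse",
                            call. = FALSE)
  set.seed(seed)
  bx <- v$beta_exp; by <- v$beta_out; so <- v$se_out
  w <- 1 / so^2
  b_loo <- .loo_ivw(bx, by, w)
  res2_obs <- w * (by - b_loo * bx)^2
  rss_obs <- sum(res2_obs)

  # simulate k x n_sim outcome effects under the per-instrument LOO null
  by_sim <- matrix(stats::rnorm(k * n_sim, mean = b_loo * bx, sd = so), nrow = k)
  s1_sim <- as.vector(crossprod(by_sim, w * bx))            # per-sim sum(w bx by*)
  s2 <- sum(w * bx^2)
  b_loo_sim <- (matrix(s1_sim, k, n_sim, byrow = TRUE) - (w * bx) * by_sim) /
    (s2 - w * bx^2)
  res2_sim <- w * (by_sim - b_loo_sim * bx)^2
  rss_sim <- colSums(res2_sim)
  global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)

  outlier_p <- rep(1, k)
  outliers <- integer(0)
  if (global_p <= alpha) {
    p_raw <- (1 + rowSums(res2_sim >= res2_obs)) / (n_sim + 1)
    outlier_p <- pmin(p_raw * k, 1)                          # Bonferroni
    outliers <- which(outlier_p < alpha)
  }

  raw <- ivw(v, model = "fixed")
  corrected <- NULL
  distortion_p <- NA_real_
  if (length(outliers) > 0 && k - length(outliers) >= 2) {
    keep <- setdiff(seq_len(k), outliers)
    corrected <- ivw(v[keep, , drop = FALSE],
                     model = if (length(keep) >= 3) "multiplicative_random" else "fixed")
    d_obs <- raw$beta - corrected$beta
    n_perm <- 1000
    d_perm <- vapply(seq_len(n_perm), function(i) {
      drop_i <- sample(keep, length(outliers))
      sub <- setdiff(seq_len(k), drop_i)
      b_sub <- sum(w[sub] * bx[sub] * by[sub]) / sum(w[sub] * bx[sub]^2)
      raw$beta - b_sub
    }, numeric(1))
    distortion_p <- (1 + sum(abs(d_perm) >= abs(d_obs))) / (n_perm + 1)
  }
  structure(list(run = TRUE, global_rss = rss_obs, global_p = global_p,
                 outlier_indices = outliers, outlier_p = outlier_p,
                 distortion_p = distortion_p, raw = raw, corrected = corrected,
                 n_sim = n_sim, alpha = alpha),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  if (!x$run) {
    cat("MR-PRESSO not run:", x$reason, "\n")
  } else {
    cat(sprintf("MR-PRESSO: global RSS=%.4g p=%.3g; %d outlier(s)\n",
                x$global_rss, x$global_p, length(x$outlier_indices)))
  }
  invisible(x)
}

#' Steiger directionality test
#'
#' Compares the variance the instruments explain in the exposure against the
#' variance they explain in the outcome, using the t-approximation
#' `r^2 = t^2 / (t^2 + n - 2)` with `t = beta/se` per variant. A causal
#' exposure -> outcome orientation should explain more variance in the
#' exposure. Binary outcomes are handled on the observed log-odds scale (no
#' liability conversion; conservative, needs no prevalence input). The
#' p-value is a two-sided z-test on the difference of Fisher-transformed
#' multiple correlations.
#'
#' @param iset An `instrument_set` (or harmonized data frame) carrying
#'   `n_exp` and `n_out`.
#' @return List of class `steiger_result`: `r2_exposure`, `r2_outcome`,
#'   `direction_ok`, `steiger_p`; or `NULL` (with a message) when sample
#'   sizes are missing.
#' @export
steiger_test <- function(iset) {
  v <- .instruments_df(iset)
  if (any(is.na(v$n_exp)) || any(is.na(v$n_out))) {
    message("Steiger test skipped: missing sample size(s)")
    return(NULL)
  }
  r2_one <- function(beta, se, n) {
    t2 <- (beta / se)^2
    sum(t2 / (t2 + n - 2))
  }
  r2_exp <- min(r2_one(v$beta_exp, v$se_exp, v$n_exp), 1 - 1e-12)
  r2_out <- min(r2_one(v$beta_out, v$se_out, v$n_out), 1 - 1e-12)
  n_exp <- mean(v$n_exp); n_out <- mean(v$n_out)
  z_exp <- atanh(sqrt(r2_exp)); z_out <- atanh(sqrt(r2_out))
  z <- (z_exp - z_out) / sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  structure(list(r2_exposure = r2_exp, r2_outcome = r2_out,
                 direction_ok = r2_exp > r2_out,
                 steiger_p = 2 * stats::pnorm(-abs(z))),
            class = "steiger_result")
}

#' @export
print.steiger_result <- function(x, ...) {
  cat(sprintf("Steiger: r2_exp=%.4g r2_out=%.4g direction_ok=%s p=%.3g\n",
              x$r2_exposure, x$r2_outcome, x$direction_ok, x$steiger_p))
  invisible(x)
}
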