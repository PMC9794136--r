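# Extract the harmonized variants data frame from an instrument_set or
# accept a harmonized data frame directly.
.instruments_df <- function(x) {
  if (inherits(x, "instrument_set")) x$variants else as.data.frame(x)
}

.mr_result <- function(method, beta, se, n_snps, df = Inf, extra = list()) {
  if (is.finite(df) && df > 0) {
    q <- stats::qt(0.975, df)
    pval <- if (se > 0) 2 * stats::pt(-abs(beta / se), df) else as.numeric(beta == 0)
  } else {
    q <- stats::qnorm(0.975)
    pval <- if (se > 0) 2 * stats::pnorm(-abs(beta / se)) else as.numeric(beta == 0)
  }
  res <- c(list(method = method, beta = beta, se = se,
                ci_low = beta - q * se, ci_high = beta + q * se,
                pval = max(pval, .Machine$double.xmin), n_snps = n_snps,
                or = exp(beta), or_ci_low = exp(beta - q * se),
                or_ci_high = exp(beta + q * se)),
           extra)
  class(res) <- "mr_result"
  res
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR %s (k=%d): beta=%.4g se=%.4g [%.4g, %.4g] p=%.3g\n",
              x$method, x$n_snps, x$beta, x$se, x$ci_low, x$ci_high, x$pval))
  if (!is.null(x$egger_intercept)) {
    cat(sprintf("  Egger intercept=%.4g se=%.4g p=%.3g\n",
                x$egger_intercept, x$intercept_se, x$intercept_p))
  }
  invisible(x)
}

#' Coerce an MR result to a one-row data frame
#' @param x An `mr_result`.
#' @param ... Unused.
#' @export
as.data.frame.mr_result <- function(x, ...) {
  data.frame(method = x$method, n_snps = x$n_snps, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
             or = x$or, or_ci_low = x$or_ci_low, or_ci_high = x$or_ci_high,
             stringsAsFactors = FALSE)
}

# Per-variant Wald ratios and their first-order delta-method SEs.
.wald_ratios <- function(v) {
  list(ratio = v$beta_out / v$beta_exp, se = v$se_out / abs(v$beta_exp))
}

#' Wald ratio causal estimate from a single instrument
#'
#' The per-variant causal estimate: outcome effect divided by exposure effect,
#' with the first-order delta-method standard error `se_out / |beta_exp|` and
#' a two-sided normal p-value.
#'
#' @param v A one-row harmonized data frame, or an `instrument_set` with
#'   exactly one variant.
#' @return An `mr_result` with `method = "wald"`.
#' @export
wald_ratio <- function(v) {
  v <- .instruments_df(v)
  stopifnot(nrow(v) == 1)
  if (v$beta_exp == 0) stop("degenerate instrument: beta_exp = 0", call. = FALSE)
  .mr_result("wald", v$beta_out / v$beta_exp, v$se_out / abs(v$beta_exp), 1L)
}

#' Inverse-variance-weighted causal estimate
#'
#' Weighted zero-intercept regression of outcome effects on exposure effects
#' with weights `1/se_out^2`; algebraically the precision-weighted mean of
#' per-variant Wald ratios. Under the multiplicative random-effects model the
#' fixed-effect SE is inflated by `max(1, sqrt(Q/(k-1)))`, never deflated.
#'
#' @param iset An `instrument_set` (or harmonized data frame) with at least 2
#'   variants.
#' @param model `"auto"` (random effects when k >= 3, fixed for k = 2),
#'   `"fixed"`, or `"multiplicative_random"`.
#' @return An `mr_result` with `method = "ivw"` and extra fields `Q`, `Q_df`,
#'   `Q_pval`, `model`.
#' @export
ivw <- function(iset, model = c("auto", "fixed", "multiplicative_random")) {
  model <- match.arg(model)
  v <- .instruments_df(iset)
  k <- nrow(v)
  if (k < 2) stop("IVW needs >= 2 independent instruments; use wald_ratio()",
                  call. = FALSE)
  w <- 1 / v$se_out^2
  beta <- sum(w * v$beta_exp * v$beta_out) / sum(w * v$beta_exp^2)
  se_fixed <- 1 / sqrt(sum(w * v$beta_exp^2))
  Q <- sum(w * (v$beta_out - beta * v$beta_exp)^2)
  if (model == "auto") model <- if (k >= 3) "multiplicative_random" else "fixed"
  se <- if (model == "multiplicative_random") {
    se_fixed * max(1, sqrt(Q / (k - 1)))
  } else se_fixed
  .mr_result("ivw", beta, se, as.integer(k),
             extra = list(Q = Q, Q_df = k - 1L,
                          Q_pval = stats::pchisq(Q, k - 1, lower.tail = FALSE),
                          model = model))
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome on exposure effects with a free
#' intercept (weights `1/se_out^2`), after orienting every instrument so that
#' `beta_exp >= 0`. The slope is the causal estimate; a non-zero intercept is
#' the directional-pleiotropy diagnostic. SEs use the multiplicative
#' random-effects convention (model SE divided by `min(1, sigma)`) with
#' t-inference on k - 2 degrees of freedom.
#'
#' @param iset An `instrument_set` (or harmonized data frame) with >= 3
#'   variants.
#' @return An `mr_result` with `method = "egger"` and extra fields
#'   `egger_intercept`, `intercept_se`, `intercept_p`, `intercept_ci_low`,
#'   `intercept_ci_high`.
#' @export
mr_egger <- function(iset) {
  v <- .instruments_df(iset)
  k <- nrow(v)
  if (k < 3) stop("MR-Egger needs >= 3 independent instruments", call. = FALSE)
  flip <- sign(v$beta_exp)
  flip[flip == 0] <- 1
  bx <- v$beta_exp * flip
  by <- v$beta_out * flip
  w <- 1 / v$se_out^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  adj <- min(1, sm$sigma)          # floor residual SD at 1: never below fixed-effect
  slope <- sm$coefficients["bx", "Estimate"]
  slope_se <- sm$coefficients["bx", "Std. Error"] / adj
  int <- sm$coefficients["(Intercept)", "Estimate"]
  int_se <- sm$coefficients["(Intercept)", "Std. Error"] / adj
  qt975 <- stats::qt(0.975, k - 2)
  .mr_result("egger", slope, slope_se, as.integer(k), df = k - 2,
             extra = list(egger_intercept = int, intercept_se = int_se,
                          intercept_p = 2 * stats::pt(-abs(int / int_se), k - 2),
                          intercept_ci_low = int - qt975 * int_se,
                          intercept_ci_high = int + qt975 * int_se))
}

# Weighted-median point estimate: interpolate ordered ratios at cumulative
# weight 0.5 (weights centred at w_i/2, the standard convention).
.weighted_median_point <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  cw <- cumsum(w) - w / 2
  idx <- which(cw < 0.5)
  if (length(idx) == 0) return(r[1])
  below <- max(idx)
  if (below == length(r)) return(r[length(r)])
  r[below] + (r[below + 1] - r[below]) * (0.5 - cw[below]) / (cw[below + 1] - cw[below])
}

.boot_se <- function(v, point_fun, n_boot, seed) {
  set.seed(seed)
  est <- vapply(seq_len(n_boot), function(i) {
    bx <- stats::rnorm(nrow(v), v$beta_exp, v$se_exp)
    by <- stats::rnorm(nrow(v), v$beta_out, v$se_out)
    point_fun(by / bx, bx, by)
  }, numeric(1))
  stats::sd(est)
}

#' Weighted-median causal estimate
#'
#' Orders per-variant Wald ratios and takes the value at cumulative weight
#' 0.5 (weights `beta_exp^2 / se_out^2`, normalized), linearly interpolating
#' between adjacent ratios. Consistent when at least half the weight comes
#' from valid instruments. The SE comes from a seeded parametric bootstrap
#' resampling `beta_exp` and `beta_out` from their marginal normals.
#'
#' @param iset An `instrument_set` (or harmonized data frame) with >= 3
#'   variants.
#' @param n_boot Bootstrap replicates (default 1000; < 100 warns).
#' @param seed Mandatory RNG seed for the bootstrap.
#' @return An `mr_result` with `method = "weighted_median"`.
#' @export
weighted_median <- function(iset, n_boot = 1000, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (n_boot < 100) warning("n_boot < 100: bootstrap SE unreliable", call. = FALSE)
  v <- .instruments_df(iset)
  if (nrow(v) < 3) stop("weighted median needs >= 3 instruments", call. = FALSE)
  rr <- .wald_ratios(v)
  ok <- is.finite(rr$ratio)
  if (!all(ok)) {
    message(sum(!ok), " instrument(s) with non-finite ratio excluded")
    v <- v[ok, , drop = FALSE]
  }
  weights <- v$beta_exp^2 / v$se_out^2
  beta <- .weighted_median_point(v$beta_out / v$beta_exp, weights)
  se <- .boot_se(v, function(r, bx, by) .weighted_median_point(r, bx^2 / v$se_out^2),
                 n_boot, seed)
  .mr_result("weighted_median", beta, se, as.integer(nrow(v)))
}

# Weighted kernel-density argmax over a fixed grid.
.mode_point <- function(ratios, weights, bandwidth_factor, n_grid = 512) {
  w <- weights / sum(weights)
  n <- length(ratios)
  spread <- stats::sd(ratios)
  if (!is.finite(spread) || spread == 0) return(ratios[1])   # identical ratios
  m <- stats::mad(ratios)
  if (m == 0) m <- spread            # majority-identical ratios: fall back to sd
  h <- bandwidth_factor * 0.9 * min(spread, m) * n^(-1 / 5)
  grid <- seq(min(ratios) - 3 * h, max(ratios) + 3 * h, length.out = n_grid)
  dens <- vapply(grid, function(x) sum(w * stats::dnorm((x - ratios) / h)), numeric(1))
  grid[which.max(dens)]
}

#' Mode-based causal estimate (weighted or simple)
#'
#' Smooths the per-variant Wald ratios with a normal kernel (bandwidth =
#' `bandwidth_factor` times the modified Silverman rule
#' `0.9 * min(sd, mad) * k^(-1/5)`) and takes the argmax of the smoothed
#' density on a 512-point grid spanning the ratios plus/minus 3 bandwidths.
#' Weights are inverse-variance (`beta_exp^2 / se_out^2`) when
#' `weighted = TRUE`, uniform otherwise. Consistent when the largest
#' homogeneous cluster of instruments is valid. SE by seeded parametric
#' bootstrap. Identical ratios (zero bandwidth) return the common ratio with
#' SE 0.
#'
#' @param iset An `instrument_set` (or harmonized data frame) with >= 3
#'   variants.
#' @param weighted Use inverse-variance weights (weighted mode) or uniform
#'   (simple mode).
#' @param bandwidth_factor Multiplier on the Silverman bandwidth (default 1).
#' @param n_boot Bootstrap replicates.
#' @param seed Mandatory RNG seed.
#' @return An `mr_result` with `method` `"weighted_mode"` or `"simple_mode"`.
#' @export
mode_estimate <- function(iset, weighted = TRUE, bandwidth_factor = 1,
                          n_boot = 1000, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  v <- .instruments_df(iset)
  if (nrow(v) < 3) stop("mode estimator needs >= 3 instruments", call. = FALSE)
  ratios <- v$beta_out / v$beta_exp
  weights <- if (weighted) v$beta_exp^2 / v$se_out^2 else rep(1, nrow(v))
  beta <- .mode_point(ratios, weights, bandwidth_factor)
  if (stats::sd(ratios) == 0) {
    return(.mr_result(if (weighted) "weighted_mode" else "simple_mode",
                      beta, 0, as.integer(nrow(v))))
  }
  se <- .boot_se(v, function(r, bx, by) {
    wts <- if (weighted) bx^2 / v$se_out^2 else rep(1, length(r))
    .mode_point(r, wts, bandwidth_factor)
  }, n_boot, seed)
  .mr_result(if (weighted) "weighted_mode" else "simple_mode",
             beta, se, as.integer(nrow(v)))
}

#' Run every estimator the instrument count permits
#'
#' One instrument yields the Wald ratio only; two add IVW; three or more add
#' MR-Egger, weighted median, and both mode estimators.
#'
#' @param iset An `instrument_set`.
#' @param seed RNG seed for bootstrap-based estimators.
#' @param n_boot Bootstrap replicates for median/mode SEs.
#' @return Named list of `mr_result` objects (empty when not analyzable).
#' @export
mr_all <- function(iset, seed, n_boot = 1000) {
  k <- iset$n_independent
  out <- list()
  if (k == 0) return(out)
  if (k == 1) {
    out$wald <- wald_ratio(iset)
    return(out)
  }
  out$ivw <- ivw(iset)
  if (k >= 3) {
    out$egger <- mr_egger(iset)
    out$weighted_median <- weighted_median(iset, n_boot = n_boot, seed = seed)
    out$weighted_mode <- mode_estimate(iset, weighted = TRUE, n_boot = n_boot,
                                       seed = seed + 1)
    out$simple_mode <- mode_estimate(iset, weighted = FALSE, n_boot = n_boot,
                                     seed = seed + 2)
  }
  out
}
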