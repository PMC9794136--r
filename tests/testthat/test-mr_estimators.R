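test_that("Wald ratio is the delta-method outcome/exposure ratio", {
  h <- make_h(bx = 0.15, by = 0.30, sey = 0.10, sex = 0.01)
  w <- wald_ratio(h)
  expect_equal(w$beta, 2.0)
  expect_equal(w$se, 0.10 / 0.15)
  expect_equal(w$or, exp(2.0))

  null <- wald_ratio(make_h(bx = 0.15, by = 0, sey = 0.10, sex = 0.01))
  expect_equal(null$beta, 0)
  expect_equal(null$pval, 1)

  flip <- wald_ratio(make_h(bx = -0.15, by = 0.30, sey = 0.10, sex = 0.01))
  expect_equal(flip$beta, -2.0)
  expect_equal(flip$se, w$se)

  expect_error(wald_ratio(make_h(bx = 0, by = 0.1, sey = 0.1, sex = 0.01)),
               "degenerate")
})

test_that("IVW matches its closed form and weight algebra", {
  h <- make_h(bx = c(1, 2), by = c(2, 2), sey = c(1, 1), sex = 0.01)
  f <- ivw(h, model = "fixed")
  expect_equal(f$beta, 1.2)
  expect_equal(f$se, sqrt(1 / 5))

  # all instruments sharing one Wald ratio recover it exactly
  hr <- make_h(bx = c(0.2, 0.5, 0.8), by = 1.7 * c(0.2, 0.5, 0.8),
               sey = c(0.1, 0.2, 0.3), sex = 0.01)
  expect_equal(ivw(hr)$beta, 1.7)

  # duplicating every instrument keeps beta, shrinks fixed se by sqrt(2)
  h2 <- rbind(h, h)
  h2$variant_id <- sprintf("rs%03d", 1:4)
  f2 <- ivw(h2, model = "fixed")
  expect_equal(f2$beta, f$beta)
  expect_equal(f2$se, f$se / sqrt(2))

  expect_error(ivw(h[1, ]), "wald_ratio")
})

test_that("IVW and Egger agree with the weighted least-squares oracle on random sets", {
  set.seed(101)
  for (i in 1:100) {
    k <- sample(3:30, 1)
    bx <- runif(k, 0.1, 1) * sample(c(-1, 1), k, TRUE)
    by <- 0.4 * bx + rnorm(k, 0, 0.1)
    sey <- runif(k, 0.02, 0.3)
    h <- make_h(bx, by, sey, sex = 0.01)
    w <- 1 / sey^2
    expect_equal(ivw(h, model = "fixed")$beta, wls_origin(bx, by, w),
                 tolerance = 1e-10)
    expect_equal(ivw(h, model = "fixed")$se, 1 / sqrt(sum(w * bx^2)),
                 tolerance = 1e-10)
    # Egger fits on exposure-positive orientation
    flip <- ifelse(bx < 0, -1, 1)
    ora <- wls_free(bx * flip, by * flip, w)
    e <- mr_egger(h)
    expect_equal(e$egger_intercept, ora[1], tolerance = 1e-10)
    expect_equal(e$beta, ora[2], tolerance = 1e-10)
  }
})

test_that("IVW equals the precision-weighted mean of Wald ratios", {
  set.seed(7)
  k <- 15
  h <- make_h(runif(k, 0.2, 0.9), rnorm(k, 0.2, 0.2), runif(k, 0.05, 0.2),
              sex = 0.01)
  ratios <- h$beta_out / h$beta_exp
  wts <- h$beta_exp^2 / h$se_out^2
  expect_equal(ivw(h, model = "fixed")$beta, sum(wts * ratios) / sum(wts),
               tolerance = 1e-12)
})

test_that("MR-Egger recovers an exact pleiotropic line and needs 3 instruments", {
  bx <- c(0.2, 0.5, 0.8)
  h <- make_h(bx, 0.1 + 2 * bx, sey = 0.1, sex = 0.01)
  e <- mr_egger(h)
  expect_equal(e$beta, 2.0, tolerance = 1e-10)
  expect_equal(e$egger_intercept, 0.1, tolerance = 1e-10)
  # exact proportionality: zero intercept
  e0 <- mr_egger(make_h(bx, 2 * bx, sey = 0.1, sex = 0.01))
  expect_equal(e0$egger_intercept, 0, tolerance = 1e-10)
  expect_error(mr_egger(h[1:2, ]), "3")
})

test_that("Egger detects planted directional pleiotropy affecting all instruments", {
  s <- synthetic_scenario(n_snps = 50, ld_rho = 0, theta = 0.3,
                          pleiotropy = list(type = "directional", mean = 0.05,
                                            sd = 0.01, prop = 1), seed = 21)
  d <- simulate_qtl_outcome_pair(s)
  e <- mr_egger(harmonize(d$exposure, d$outcome))
  expect_true(e$intercept_ci_low > 0 || e$intercept_ci_high < 0)
  expect_lt(e$intercept_p, 0.05)
})

test_that("weighted median interpolates the ratio at cumulative weight 0.5", {
  # equal weights on {1, 2, 3}: the middle ratio
  h <- make_h(bx = c(1, 1, 1), by = c(1, 2, 3), sey = 1, sex = 0.01)
  expect_equal(weighted_median(h, n_boot = 200, seed = 1)$beta, 2.0)
  # half the weight at 1, half at 3: interpolation gives 2
  h2 <- make_h(bx = c(1, 1, 1, 1), by = c(1, 1, 3, 3), sey = 1, sex = 0.01)
  expect_equal(weighted_median(h2, n_boot = 200, seed = 1)$beta, 2.0)
  # agreement with the brute-force cumulative-weight walk on random sets
  set.seed(33)
  for (i in 1:50) {
    k <- sample(3:25, 1)
    hh <- make_h(runif(k, 0.1, 1), rnorm(k, 0.3, 0.3), runif(k, 0.05, 0.4),
                 sex = 0.01)
    expect_equal(weighted_median(hh, n_boot = 100, seed = i)$beta,
                 median_walk(hh$beta_out / hh$beta_exp,
                             hh$beta_exp^2 / hh$se_out^2),
                 tolerance = 1e-12)
  }
})

test_that("weighted median resists a low-weight outlier", {
  set.seed(5)
  k <- 20
  bx <- runif(k, 0.3, 0.8)
  h <- make_h(bx, 1.5 * bx + rnorm(k, 0, 0.02), sey = 0.05, sex = 0.01)
  clean <- weighted_median(h, n_boot = 200, seed = 2)$beta
  h_out <- h
  h_out$beta_out[1] <- 50 * h_out$beta_exp[1]
  h_out$se_out[1] <- 2                      # tiny weight
  dirty <- weighted_median(h_out, n_boot = 200, seed = 2)$beta
  expect_lt(abs(dirty - clean), 0.05)
})

test_that("mode estimators find the dominant ratio cluster", {
  # majority mode among {2, 2, 2, 7}
  h <- make_h(bx = rep(1, 4), by = c(2, 2, 2, 7), sey = 1, sex = 0.01)
  m <- mode_estimate(h, weighted = FALSE, n_boot = 100, seed = 1)
  expect_equal(m$beta, 2, tolerance = 0.15)
  # identical ratios collapse to that ratio with zero SE
  # (power-of-two effects keep the ratios exactly representable)
  h0 <- make_h(bx = c(0.25, 0.5, 1), by = 3 * c(0.25, 0.5, 1), sey = 1,
               sex = 0.01)
  m0 <- mode_estimate(h0, n_boot = 100, seed = 1)
  expect_equal(m0$beta, 3)
  expect_equal(m0$se, 0)
  # bimodal {1 x6, 3 x4}, uniform weights: the heavier cluster wins and the
  # point estimate matches a fine-grid argmax oracle at the same bandwidth
  hb <- make_h(bx = rep(1, 10), by = c(rep(1, 6), rep(3, 4)), sey = 1,
               sex = 0.01)
  mb <- mode_estimate(hb, weighted = FALSE, n_boot = 100, seed = 1)
  ratios <- hb$beta_out / hb$beta_exp
  bw <- 0.9 * sd(ratios) * 10^(-1 / 5)     # mad = 0 falls back to sd
  oracle <- grid_mode(ratios, rep(1, 10), bw)
  expect_equal(mb$beta, oracle, tolerance = 0.02)
  expect_lt(abs(mb$beta - 1), 0.25)
})

test_that("estimators are equivariant to exposure rescaling and allele flips", {
  set.seed(9)
  k <- 12
  h <- make_h(runif(k, 0.2, 0.8), rnorm(k, 0.3, 0.1), runif(k, 0.05, 0.2),
              sex = 0.01)
  scale_h <- function(h, c) { h$beta_exp <- h$beta_exp * c; h$se_exp <- h$se_exp * abs(c); h }
  flip_h <- function(h, i) {
    h$beta_exp[i] <- -h$beta_exp[i]; h$beta_out[i] <- -h$beta_out[i]; h
  }
  for (fit in list(function(x) ivw(x)$beta,
                   function(x) mr_egger(x)$beta,
                   function(x) weighted_median(x, n_boot = 100, seed = 4)$beta,
                   function(x) mode_estimate(x, n_boot = 100, seed = 4)$beta)) {
    expect_equal(fit(scale_h(h, 2)), fit(h) / 2, tolerance = 1e-6)
    expect_equal(fit(flip_h(h, c(2, 5))), fit(h), tolerance = 1e-6)
  }
})
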