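test_that("conditioning on a mediator follows the linear adjustment exactly", {
  ou <- make_assoc(c("rs1", "rs2"), c(0.40, 0.25), c(0.05, 0.04))
  me <- make_assoc("rs1", 0.50, 0.02)
  # theta = 0 is the identity
  id <- condition_on_mediator(ou, me, theta = 0)
  expect_equal(id$beta, ou$beta)
  expect_equal(id$se, ou$se)
  # hand algebra: 0.40 - 0.6*0.50 = 0.10; SE propagation with se_theta = 0
  cond <- condition_on_mediator(ou, me, theta = 0.6, se_theta = 0)
  expect_equal(cond$beta[cond$variant_id == "rs1"], 0.10)
  expect_equal(cond$se[cond$variant_id == "rs1"],
               sqrt(0.05^2 + 0.36 * 0.02^2))
  # theta uncertainty propagates through the mediator effect
  cond2 <- condition_on_mediator(ou, me, theta = 0.6, se_theta = 0.1)
  expect_equal(cond2$se[cond2$variant_id == "rs1"],
               sqrt(0.05^2 + 0.36 * 0.02^2 + 0.50^2 * 0.01))
  # variants absent from the mediator pass through unchanged, flagged
  expect_false(cond$conditioned[cond$variant_id == "rs2"])
  expect_equal(cond$beta[cond$variant_id == "rs2"], 0.25)
})

test_that("a noise-free fully mediated locus cancels exactly under conditioning", {
  m <- simulate_mediation_scenario(synthetic_scenario(mediation_fraction = 1,
                                                      noise_scale = 0, seed = 2))
  loc <- m$outcome[m$outcome$chrom == "10", ]
  cond <- condition_on_mediator(loc, m$mediator, theta = m$truth$theta_med)
  expect_equal(max(abs(cond$beta)), 0, tolerance = 1e-12)
})

test_that("conditioning shrinks mediator-routed effects and spares direct ones", {
  raw_vs_cond <- function(mf) {
    m <- simulate_mediation_scenario(synthetic_scenario(mediation_fraction = mf,
                                                        noise_scale = 0,
                                                        seed = 3))
    cond_out <- condition_on_mediator(m$outcome, m$mediator,
                                      theta = m$truth$theta_med)
    idx <- m$index_variant
    raw <- m$outcome$beta[m$outcome$variant_id == idx] /
      m$exposure$beta[m$exposure$variant_id == idx]
    cnd <- cond_out$beta[cond_out$variant_id == idx] /
      m$exposure$beta[m$exposure$variant_id == idx]
    c(raw = raw, cond = cnd)
  }
  full <- raw_vs_cond(1)
  expect_lt(abs(full["cond"] / full["raw"]), 0.2)    # mediator-only: wiped out
  partial <- raw_vs_cond(0.1)
  expect_gt(partial["cond"] / partial["raw"], 0.7)   # mostly direct: retained
})

test_that("the locus-vs-genome-wide benchmark detects broken mediation", {
  m <- simulate_mediation_scenario(synthetic_scenario(mediation_fraction = 0.1,
                                                      seed = 5))
  rep <- mediation_consistency(m$index_variant, m$mediator, m$outcome,
                               m$gw_instruments)
  expect_false(rep$consistent)
  expect_gt(rep$observed_wald$ci_low, rep$expected_if_mediated$ci_high)
  expect_gt(rep$ratio, 3)
  expect_lt(rep$diff_p, 0.05)

  full <- simulate_mediation_scenario(synthetic_scenario(mediation_fraction = 1,
                                                         seed = 5))
  rep2 <- mediation_consistency(full$index_variant, full$mediator,
                                full$outcome, full$gw_instruments)
  expect_true(rep2$consistent)
})

test_that("benchmark CI structure mirrors an observed 5.98 vs expected 0.58 contrast", {
  # index variant engineered to a Wald effect of 5.98 (95% CI 3.94-8.01);
  # genome-wide instruments engineered to an IVW of 0.58 (0.41-0.75)
  se_obs <- (8.01 - 5.98) / qnorm(0.975)
  med <- make_assoc(c("rsIdx", "rsG1", "rsG2"), c(1, 1, 1), c(0.01, 0.1, 0.1),
                    chrom = c("10", "2", "3"), pos = c(1e6, 1e6, 1e6))
  out <- make_assoc(c("rsIdx", "rsG1", "rsG2"), c(5.98, 0.58, 0.58),
                    c(se_obs, 0.1, 0.1), chrom = c("10", "2", "3"),
                    pos = c(1e6, 1e6, 1e6))
  gw <- harmonize(med[med$variant_id != "rsIdx", ],
                  out[out$variant_id != "rsIdx", ])
  gw$se_out <- (0.75 - 0.58) / qnorm(0.975) * sqrt(2)  # combined IVW CI 0.41-0.75
  rep <- mediation_consistency("rsIdx", med, out, gw)
  expect_equal(rep$observed_wald$beta, 5.98, tolerance = 1e-9)
  expect_equal(rep$observed_wald$ci_high, 8.01, tolerance = 0.02)
  expect_equal(rep$expected_if_mediated$beta, 0.58, tolerance = 1e-9)
  expect_equal(rep$expected_if_mediated$ci_low, 0.41, tolerance = 0.02)
  expect_false(rep$consistent)   # full mediation rejected
})

test_that("locus exclusion behaves at its boundaries", {
  m <- simulate_mediation_scenario(synthetic_scenario(seed = 6))
  # excluding nothing reproduces plain IVW of the genome-wide set
  rep <- mediation_consistency(m$index_variant, m$mediator, m$outcome,
                               m$gw_instruments, exclusion_window_bp = 0)
  expect_equal(rep$expected_if_mediated$beta, ivw(m$gw_instruments)$beta)
  expect_equal(rep$n_excluded, 0)
  # a window that swallows every instrument is an analysis error
  gw_same_chrom <- m$gw_instruments
  gw_same_chrom$chrom <- "10"
  gw_same_chrom$pos <- 1e6
  expect_error(mediation_consistency(m$index_variant, m$mediator, m$outcome,
                                     gw_same_chrom,
                                     exclusion_window_bp = 1e6),
               "fewer than 2")
  expect_error(mediation_consistency("rsNope", m$mediator, m$outcome,
                                     m$gw_instruments), "missing")
})

test_that("the exome-wide batch ranks a planted strong gene first", {
  set.seed(91)
  mk_gene <- function(id, effect) {
    bx <- runif(4, 0.3, 0.7)
    h <- make_h(bx, effect * bx + rnorm(4, 0, 0.01), sey = 0.05, sex = 0.01,
                ids = sprintf("%s_%d", id, 1:4))
    make_iset(h, exposure_id = id)
  }
  sets <- c(lapply(sprintf("GENE%02d", 1:9),
                   function(g) mk_gene(g, 0.2)),
            list(mk_gene("CAND", 1.0)))
  tab <- benchmark_exomewide(sets)
  expect_equal(tab$exposure_id[1], "CAND")
  expect_equal(tab$rank, seq_len(nrow(tab)))
  # filter excluding the top gene promotes the next one
  tab2 <- benchmark_exomewide(sets, filter = sprintf("GENE%02d", 1:9))
  expect_false("CAND" %in% tab2$exposure_id)
  expect_equal(tab2$exposure_id[1], tab$exposure_id[2])
  expect_error(benchmark_exomewide(sets, filter = "NOPE"), "filter")
})

test_that("identical effects rank lexicographically by exposure id", {
  bx <- c(0.5, 0.6, 0.7)
  mk <- function(id) make_iset(make_h(bx, 0.3 * bx, sey = 0.05, sex = 0.01,
                                      ids = paste0(id, "_", 1:3)),
                               exposure_id = id)
  tab <- benchmark_exomewide(list(mk("B"), mk("A"), mk("C")))
  expect_equal(tab$exposure_id, c("A", "B", "C"))
})
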