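# Standard GWAS approximations for the SE of a marginal per-allele effect:
# quantitative traits 1/sqrt(2 maf (1-maf) n); case-control (log-odds scale)
# 1/sqrt(2 maf (1-maf) n phi (1-phi)) with case fraction phi.
.se_quant <- function(maf, n) 1 / sqrt(2 * maf * (1 - maf) * n)
.se_cc <- function(maf, n, phi) 1 / sqrt(2 * maf * (1 - maf) * n * phi * (1 - phi))

# Draw noise with covariance D R D (D = diag(se)) so neighbouring marginal
# effects share sampling error the way LD makes them in a real GWAS.
.ld_noise <- function(R, se) {
  as.vector(se * (t(chol(R)) %*% stats::rnorm(nrow(R))))
}

.make_assoc <- function(ids, chrom, pos, maf, beta, se, n, trait_type,
                        n_cases = NA_real_) {
  variant_assoc(data.frame(variant_id = ids, chrom = chrom, pos = pos,
                           effect_allele = "A", other_allele = "G", eaf = maf,
                           beta = beta, se = se,
                           pval = pmax(2 * stats::pnorm(-abs(beta / se)),
                                       .Machine$double.xmin),
                           n = n, n_cases = n_cases, stringsAsFactors = FALSE),
                trait_type = trait_type, check_pval = FALSE)
}

#' Define a synthetic summary-statistics scenario
#'
#' Bundles the ground-truth parameters shared by the generators. Defaults
#' emulate the scale of the real screen: strong cis-QTL effect sizes
#' (|b| in 0.2-0.8 exposure SD per allele), an exposure GWAS of n = 1e5, a
#' case-control outcome GWAS of 79 429 with 7 495 cases (log-odds scale), a
#' very large quantitative mediator GWAS (blood-pressure size), AR-1 locus
#' LD with rho = 0.9, and a genome-wide mediator-to-outcome effect of 0.58
#' with a locus contrast an order of magnitude larger when mediation is
#' partial.
#'
#' @param n_snps Variants per locus / instruments per set.
#' @param ld_rho AR-1 LD parameter in (-1, 1).
#' @param n_exp,n_out,n_med GWAS sample sizes (exposure, outcome, mediator).
#' @param case_fraction_out Outcome case fraction (outcome is case-control).
#' @param maf_range Minor-allele-frequency range, within (0, 0.5].
#' @param beta_exp_range Magnitude range of true causal exposure effects.
#' @param n_causal Causal variants per locus; `NA` means every variant (a
#'   panel of LD-independent instruments rather than one locus).
#' @param theta True exposure-to-outcome causal effect (log-odds per
#'   exposure unit).
#' @param pleiotropy List: `type` (`"none"`, `"balanced"`, `"directional"`),
#'   `mean` (directional only), `sd`, and `prop`, the fraction of instruments
#'   carrying a direct outcome effect.
#' @param coloc_mode `"H0" ... "H4"`: planted locus configuration.
#' @param coloc_z Causal-variant |z| for colocalization scenarios.
#' @param mediation_fraction Share of the exposure's outcome effect
#'   transmitted through the mediator, in [0, 1].
#' @param theta_med Mediator-to-outcome causal effect (genome-wide truth).
#' @param tau Total exposure-to-outcome effect at the mediation locus.
#' @param n_gw Genome-wide mediator instruments outside the locus.
#' @param noise_scale Multiplier on all sampling noise (0 = noise-free limit).
#' @param seed RNG seed; every generator is deterministic given it.
#' @return List of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_snps = 50, ld_rho = 0.9, n_exp = 1e5,
                               n_out = 79429, n_med = 750000,
                               case_fraction_out = 7495 / 79429,
                               maf_range = c(0.05, 0.5),
                               beta_exp_range = c(0.2, 0.8), n_causal = NA,
                               theta = 0,
                               pleiotropy = list(type = "none", mean = 0,
                                                 sd = 0, prop = 1),
                               coloc_mode = "H4", coloc_z = 8,
                               mediation_fraction = 1, theta_med = 0.58,
                               tau = log(3.02), n_gw = 100, noise_scale = 1,
                               seed = 1) {
  stopifnot(n_snps >= 1, abs(ld_rho) < 1,
            mediation_fraction >= 0, mediation_fraction <= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            coloc_mode %in% paste0("H", 0:4), noise_scale >= 0)
  if (is.null(pleiotropy$prop)) pleiotropy$prop <- 1
  structure(as.list(environment()), class = "synthetic_scenario")
}

#' Read a synthetic scenario from a YAML config
#'
#' Field names and defaults are those of [synthetic_scenario()]; unknown
#' fields are an error. Requires the `yaml` package.
#'
#' @param path YAML file path.
#' @return A `synthetic_scenario`.
#' @export
read_scenario_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read scenario configs", call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(formals(synthetic_scenario)))
  if (length(unknown) > 0) stop("unknown scenario field(s): ",
                                paste(unknown, collapse = ", "), call. = FALSE)
  do.call(synthetic_scenario, cfg)
}

#' Simulate an AR-1 LD matrix
#'
#' `r[i, j] = rho^|i - j|`: symmetric, positive definite, unit diagonal.
#' Block-diagonal composition of several loci is available through
#' `Matrix::bdiag`-style assembly by the caller; each locus here is one
#' AR-1 block.
#'
#' @param n_snps Number of variants.
#' @param rho AR-1 parameter, |rho| < 1.
#' @param variant_ids Optional IDs (default `snp1..snpN`).
#' @return An [ld_matrix()].
#' @export
simulate_ld_matrix <- function(n_snps, rho, variant_ids = paste0("snp", seq_len(n_snps))) {
  stopifnot(n_snps >= 1, abs(rho) < 1)
  idx <- seq_len(n_snps)
  r <- rho^abs(outer(idx, idx, "-"))
  ld_matrix(r, variant_ids)
}

#' Simulate an exposure/outcome summary-statistics pair with known truth
#'
#' Draws sparse true per-variant exposure effects `b` (uniform magnitudes in
#' `beta_exp_range`, random signs, `n_causal` non-zero entries), propagates
#' them through the LD matrix to noise-free marginal effects `R b`, and adds
#' LD-correlated sampling noise at the SE implied by MAF and sample size.
#' Outcome marginal effects are `theta * R b` plus an optional per-variant
#' pleiotropy term (also propagated through LD) plus case-control-scale
#' noise, so exposure and outcome sampling errors are independent, as in a
#' two-sample design.
#'
#' @param s A [synthetic_scenario()].
#' @return List: `exposure` and `outcome` (`variant_assoc` tables), `ld`
#'   (`ld_matrix`), `truth` (true `b`, `theta`, pleiotropy indices/values,
#'   causal indices, seed; round-trips through JSON).
#' @export
simulate_qtl_outcome_pair <- function(s) {
  stopifnot(inherits(s, "synthetic_scenario"))
  set.seed(s$seed)
  n <- s$n_snps
  ids <- sprintf("rs%05d", seq_len(n))
  R <- simulate_ld_matrix(n, s$ld_rho, ids)
  maf <- stats::runif(n, s$maf_range[1], s$maf_range[2])

  n_causal <- if (is.na(s$n_causal)) n else min(s$n_causal, n)
  causal <- sort(sample.int(n, n_causal))
  b <- numeric(n)
  b[causal] <- stats::runif(n_causal, s$beta_exp_range[1], s$beta_exp_range[2]) *
    sample(c(-1, 1), n_causal, replace = TRUE)

  mu_x <- as.vector(R %*% b)
  se_x <- .se_quant(maf, s$n_exp)
  beta_x <- mu_x + s$noise_scale * .ld_noise(R, se_x)

  alpha <- numeric(n)
  pleio_idx <- integer(0)
  if (s$pleiotropy$type != "none") {
    k_p <- max(1, round(s$pleiotropy$prop * n))
    pleio_idx <- sort(sample.int(n, k_p))
    alpha[pleio_idx] <- stats::rnorm(k_p,
                                     if (s$pleiotropy$type == "directional")
                                       s$pleiotropy$mean else 0,
                                     s$pleiotropy$sd)
  }
  phi <- s$case_fraction_out
  se_y <- .se_cc(maf, s$n_out, phi)
  # directional pleiotropy attaches to the exposure-increasing allele: its
  # sign must survive the exposure-positive orientation the estimators use
  align <- ifelse(mu_x >= 0, 1, -1)
  mu_y <- as.vector(s$theta * mu_x + R %*% (align * alpha))
  beta_y <- mu_y + s$noise_scale * .ld_noise(R, se_y)

  pos <- 1e6 + (seq_len(n) - 1) * 5000
  list(exposure = .make_assoc(ids, "1", pos, maf, beta_x, se_x, s$n_exp,
                              "quantitative"),
       outcome = .make_assoc(ids, "1", pos, maf, beta_y, se_y, s$n_out,
                             "case_control", n_cases = round(phi * s$n_out)),
       ld = R,
       truth = list(b = b, theta = s$theta, causal_idx = causal,
                    pleio_idx = pleio_idx, pleio_effects = alpha[pleio_idx],
                    seed = s$seed))
}

#' Simulate a colocalization locus under a chosen hypothesis
#'
#' Plants causal variants per `coloc_mode`: H4 one shared causal variant; H3
#' two distinct causal variants chosen so their LD satisfies r^2 < 0.1;
#' H1/H2 a causal variant in one trait only; H0 none. Marginal z-scores are
#' drawn as `MVN(R u, R)` where `u` carries `coloc_z` at the causal index,
#' then converted to betas at the MAF/sample-size-implied SE. Trait 1 is
#' quantitative (QTL-like), trait 2 case-control (disease GWAS).
#'
#' @param s A [synthetic_scenario()].
#' @return List: `trait1`, `trait2` (windowed `variant_assoc` tables over a
#'   shared 100 kb-scale region), `ld`, `truth` (mode and causal indices).
#' @export
simulate_coloc_scenario <- function(s) {
  stopifnot(inherits(s, "synthetic_scenario"))
  set.seed(s$seed)
  n <- s$n_snps
  ids <- sprintf("rs%05d", seq_len(n))
  R <- simulate_ld_matrix(n, s$ld_rho, ids)
  maf <- stats::runif(n, s$maf_range[1], s$maf_range[2])

  c1 <- max(1L, n %/% 4)
  c2 <- min(n, (3L * n) %/% 4 + 1L)
  while (c2 > c1 && R[c1, c2]^2 >= 0.1) c2 <- min(n, c2 + 1L)
  causal1 <- causal2 <- integer(0)
  if (s$coloc_mode %in% c("H1", "H3", "H4")) causal1 <- c1
  if (s$coloc_mode == "H2") causal2 <- c1
  if (s$coloc_mode == "H3") causal2 <- c2
  if (s$coloc_mode == "H4") causal2 <- c1

  draw_z <- function(causal) {
    u <- numeric(n)
    u[causal] <- s$coloc_z
    as.vector(R %*% u) + s$noise_scale * as.vector(t(chol(R)) %*% stats::rnorm(n))
  }
  z1 <- draw_z(causal1)
  z2 <- draw_z(causal2)
  se1 <- .se_quant(maf, s$n_exp)
  phi <- s$case_fraction_out
  se2 <- .se_cc(maf, s$n_out, phi)
  pos <- 1e6 + (seq_len(n) - 1) * 2000
  list(trait1 = .make_assoc(ids, "1", pos, maf, z1 * se1, se1, s$n_exp,
                            "quantitative"),
       trait2 = .make_assoc(ids, "1", pos, maf, z2 * se2, se2, s$n_out,
                            "case_control", n_cases = round(phi * s$n_out)),
       ld = R,
       truth = list(mode = s$coloc_mode, causal1 = causal1, causal2 = causal2,
                    seed = s$seed))
}

#' Simulate a mediation scenario (locus + genome-wide mediator instruments)
#'
#' The locus carries a causal exposure variant whose effect reaches the
#' outcome along two paths: through the mediator (share `mediation_fraction`
#' of the total effect `tau`) and directly (the remainder). The mediator's
#' locus effects are `kappa * (R b)` with `kappa = mediation_fraction * tau /
#' theta_med`, so the outcome locus effects are `tau * (R b)` regardless of
#' the split, while the index-variant Wald estimate of the mediator-outcome
#' effect equals `theta_med + (1 - mediation_fraction) * tau / kappa` —
#' reproducing the locus-vs-genome-wide contrast of the blood-pressure
#' benchmark. Genome-wide mediator instruments live on another chromosome
#' with outcome effects `theta_med * beta_med` plus noise.
#'
#' @param s A [synthetic_scenario()].
#' @return List: `exposure` (locus QTL table), `mediator` and `outcome`
#'   (locus + genome-wide tables), `gw_instruments` (harmonized
#'   mediator-to-outcome data frame of the genome-wide instruments), `ld`,
#'   `index_variant`, `truth`.
#' @export
simulate_mediation_scenario <- function(s) {
  stopifnot(inherits(s, "synthetic_scenario"))
  set.seed(s$seed)
  n <- s$n_snps
  mf <- s$mediation_fraction
  kappa <- if (mf > 0) mf * s$tau / s$theta_med else 0
  d <- (1 - mf) * s$tau

  ids <- sprintf("rsL%04d", seq_len(n))
  R <- simulate_ld_matrix(n, s$ld_rho, ids)
  maf <- stats::runif(n, s$maf_range[1], s$maf_range[2])
  causal <- (n + 1L) %/% 2L
  b <- numeric(n)
  b[causal] <- mean(s$beta_exp_range)
  mu_x <- as.vector(R %*% b)

  se_x <- .se_quant(maf, s$n_exp)
  se_m <- .se_quant(maf, s$n_med)
  phi <- s$case_fraction_out
  se_y <- .se_cc(maf, s$n_out, phi)
  beta_x <- mu_x + s$noise_scale * .ld_noise(R, se_x)
  beta_m <- kappa * mu_x + s$noise_scale * .ld_noise(R, se_m)
  # outcome = theta_med * (mediated part) + direct part = tau * mu_x
  beta_y <- as.vector(s$theta_med * kappa * mu_x + d * mu_x) +
    s$noise_scale * .ld_noise(R, se_y)
  pos <- 1e6 + (seq_len(n) - 1) * 5000

  gw_ids <- sprintf("rsG%04d", seq_len(s$n_gw))
  gw_maf <- stats::runif(s$n_gw, s$maf_range[1], s$maf_range[2])
  gw_bm_true <- stats::runif(s$n_gw, 0.02, 0.08) *
    sample(c(-1, 1), s$n_gw, replace = TRUE)
  gw_se_m <- .se_quant(gw_maf, s$n_med)
  gw_se_y <- .se_cc(gw_maf, s$n_out, phi)
  gw_bm <- gw_bm_true + s$noise_scale * stats::rnorm(s$n_gw, 0, gw_se_m)
  gw_by <- s$theta_med * gw_bm_true + s$noise_scale * stats::rnorm(s$n_gw, 0, gw_se_y)
  gw_pos <- 1e6 + (seq_len(s$n_gw) - 1) * 1e6

  mediator <- .make_assoc(c(ids, gw_ids), c(rep("10", n), rep("2", s$n_gw)),
                          c(pos, gw_pos), c(maf, gw_maf), c(beta_m, gw_bm),
                          c(se_m, gw_se_m), s$n_med, "quantitative")
  outcome <- .make_assoc(c(ids, gw_ids), c(rep("10", n), rep("2", s$n_gw)),
                         c(pos, gw_pos), c(maf, gw_maf), c(beta_y, gw_by),
                         c(se_y, gw_se_y), s$n_out, "case_control",
                         n_cases = round(phi * s$n_out))
  gw_h <- harmonize(mediator[mediator$variant_id %in% gw_ids, , drop = FALSE],
                    outcome[outcome$variant_id %in% gw_ids, , drop = FALSE])
  list(exposure = .make_assoc(ids, "10", pos, maf, beta_x, se_x, s$n_exp,
                              "quantitative"),
       mediator = mediator, outcome = outcome, gw_instruments = gw_h,
       ld = R, index_variant = ids[causal],
       truth = list(mediation_fraction = mf, theta_med = s$theta_med,
                    tau = s$tau, kappa = kappa, direct = d,
                    causal_idx = causal, seed = s$seed))
}

#' Simulate a multi-gene drug-target screen with one planted signal
#'
#' Builds the inputs for [run_screen()]: `n_null + 1` gene-tissue exposures,
#' each a 50-variant AR-1 locus with two LD-independent causal eQTL
#' variants; one planted gene whose locus outcome effects are
#' `theta * (R b)` with the causal variants shared between exposure and
#' outcome (colocalizing), and null genes whose outcome effects are pure
#' noise. A small drug-gene edge table links a CMap knockdown/positive edge
#' to the planted gene and interaction-only edges to two null genes.
#'
#' @param n_null Number of null genes (default 20).
#' @param theta Planted causal effect (default `log(3.02)`, the screen's
#'   headline odds-ratio scale).
#' @param n_exp Exposure (eQTL) sample size; default 584, arterial-tissue
#'   scale.
#' @param seed RNG seed.
#' @return A config list for [run_screen()] with a `truth` element naming
#'   the planted gene.
#' @export
simulate_drug_target_screen <- function(n_null = 20, theta = log(3.02),
                                        n_exp = 584, seed = 7) {
  genes <- sprintf("GENE%02d", seq_len(n_null + 1))
  planted <- genes[1]
  exposures <- list()
  outcome_rows <- list()
  for (g in seq_along(genes)) {
    s <- synthetic_scenario(n_snps = 50, ld_rho = 0.9, n_exp = n_exp,
                            coloc_z = 8, seed = seed * 1000 + g)
    set.seed(s$seed)
    n <- s$n_snps
    ids <- sprintf("rs%02d_%04d", g, seq_len(n))
    R <- simulate_ld_matrix(n, s$ld_rho, ids)
    maf <- stats::runif(n, s$maf_range[1], s$maf_range[2])
    c1 <- n %/% 4; c2 <- (3L * n) %/% 4 + 1L
    b <- numeric(n)
    b[c(c1, c2)] <- c(0.55, 0.45)
    mu_x <- as.vector(R %*% b)
    se_x <- .se_quant(maf, s$n_exp)
    beta_x <- mu_x + .ld_noise(R, se_x)
    phi <- s$case_fraction_out
    se_y <- .se_cc(maf, s$n_out, phi)
    mu_y <- if (genes[g] == planted) theta * mu_x else numeric(n)
    beta_y <- mu_y + .ld_noise(R, se_y)
    pos <- 1e6 + (seq_len(n) - 1) * 2000
    exposures[[genes[g]]] <- list(
      sumstats = .make_assoc(ids, as.character(g), pos, maf, beta_x, se_x,
                             s$n_exp, "quantitative"),
      tissue = "tibial_artery", ld = R)
    outcome_rows[[g]] <- as.data.frame(
      .make_assoc(ids, as.character(g), pos, maf, beta_y, se_y, s$n_out,
                  "case_control", n_cases = round(phi * s$n_out)))
  }
  outcome <- variant_assoc(do.call(rbind, outcome_rows),
                           trait_type = "case_control", check_pval = FALSE)
  edges <- build_target_map(data.frame(
    drug = c("drugA", "drugA", "drugB", "drugC"),
    gene = c(planted, genes[2], planted, genes[3]),
    source = c("cmap", "dgidb", "cmap", "dgidb"),
    perturbation = c("knockdown", "", "overexpression", ""),
    similarity = c("0.9", "", "-0.8", ""), stringsAsFactors = FALSE))
  list(exposures = exposures, outcomes = list(ia_combined = outcome),
       tiers = 5e-5, clump_r2 = 0.1, ivw_alpha = 0.05, pp4_threshold = 0.7,
       coloc_half_width_bp = 1e5, drug_edges = edges, seed = seed,
       truth = list(planted_gene = planted, theta = theta))
}
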