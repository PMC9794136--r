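toy_table <- function() {
  data.frame(snp = c("rs3", "rs1", "rs2"), chr = c("2", "1", "1"),
             pos = c(500, 100, 300), ea = c("A", "C", "a"),
             oa = c("G", "T", "g"), eaf = c(0.2, 0.4, 0.1),
             beta = c(0.1, -0.2, 0.05), se = c(0.05, 0.04, 0.02),
             p = c(0.0455, 5.7e-7, 0.0124), n = 1000,
             stringsAsFactors = FALSE)
}

test_that("reading a GWAS table sorts by position and normalizes alleles", {
  path <- write_toy_gwas(toy_table())
  tab <- read_gwas_table(path)
  expect_s3_class(tab, "variant_assoc")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$variant_id, c("rs1", "rs2", "rs3"))  # (chrom, pos) order
  expect_equal(tab$effect_allele[tab$variant_id == "rs2"], "A")
  expect_equal(tab$other_allele[tab$variant_id == "rs2"], "G")
  expect_equal(attr(tab, "n_dropped"), 0)
})

test_that("invalid rows are dropped and counted, not fatal", {
  df <- toy_table()
  df$se[2] <- 0
  path <- write_toy_gwas(df)
  expect_message(tab <- read_gwas_table(path), "1 row")
  expect_equal(nrow(tab), 2)
  expect_equal(attr(tab, "n_dropped"), 1)
  expect_false("rs1" %in% tab$variant_id)
})

test_that("missing mandatory columns and empty tables are errors naming the cause", {
  df <- toy_table()
  names(df)[names(df) == "se"] <- "stderr"
  expect_error(read_gwas_table(write_toy_gwas(df)), "se")
  df2 <- toy_table()
  df2$se <- -1
  expect_error(suppressMessages(read_gwas_table(write_toy_gwas(df2))),
               "no valid rows")
  # remapping the column fixes it
  tab <- read_gwas_table(write_toy_gwas(df), column_map = c(se = "stderr"))
  expect_equal(nrow(tab), 3)
})

test_that("p-values inconsistent with beta/se warn but are not altered", {
  df <- toy_table()
  df$p[1] <- 0.9
  expect_warning(tab <- read_gwas_table(write_toy_gwas(df)), "inconsistent")
  expect_equal(tab$pval[tab$variant_id == "rs3"], 0.9)
})

test_that("harmonization flips swapped outcome alleles and negates beta", {
  ex <- make_assoc("rs1", 0.10, 0.02, ea = "A", oa = "G")
  ou <- make_assoc("rs1", 0.20, 0.05, ea = "G", oa = "A", eaf = 0.7)
  h <- harmonize(ex, ou)
  expect_equal(h$harmonize_action, "flipped")
  expect_equal(h$beta_out, -0.20)
  expect_equal(h$beta_exp, 0.10)
  # strand-flipped coding (complement alleles) resolves without sign change
  ou2 <- make_assoc("rs1", 0.20, 0.05, ea = "T", oa = "C")
  h2 <- harmonize(ex, ou2)
  expect_equal(h2$beta_out, 0.20)
  expect_equal(h2$harmonize_action, "kept")
})

test_that("ambiguous palindromic variants are dropped, informative ones oriented by eaf", {
  ex <- make_assoc(c("rs1", "rs2", "rs3"), c(0.1, 0.1, 0.1), 0.02,
                   ea = "A", oa = "T", eaf = c(0.50, 0.10, 0.10))
  ou <- make_assoc(c("rs1", "rs2", "rs3"), c(0.2, 0.2, 0.2), 0.05,
                   ea = "A", oa = "T", eaf = c(0.50, 0.12, 0.88))
  h <- harmonize(ex, ou, palindromic_eaf_window = 0.08)
  counts <- attr(h, "action_counts")
  expect_equal(unname(counts["dropped_palindromic"]), 1)   # eaf at 0.5
  expect_false("rs1" %in% h$variant_id)
  # concordant frequencies: kept as-is; discordant: flipped
  expect_equal(h$harmonize_action[h$variant_id == "rs2"], "kept")
  expect_equal(h$harmonize_action[h$variant_id == "rs3"], "flipped")
  expect_equal(h$beta_out[h$variant_id == "rs3"], -0.2)
})

test_that("incompatible allele sets are dropped as mismatches", {
  ex <- make_assoc("rs1", 0.1, 0.02, ea = "A", oa = "G")
  ou <- make_assoc("rs1", 0.2, 0.05, ea = "A", oa = "C")
  expect_equal(nrow(suppressMessages(harmonize(ex, ou))), 0)
  expect_error(harmonize(ex, make_assoc("rs9", 0.1, 0.1)), "no shared")
})

test_that("harmonization is invariant to outcome allele coding and idempotent", {
  set.seed(11)
  n <- 20
  ids <- sprintf("rs%02d", 1:n)
  ex <- make_assoc(ids, rnorm(n, 0, 0.3), 0.05, ea = "A", oa = "G",
                   eaf = runif(n, 0.1, 0.9))
  ou <- make_assoc(ids, rnorm(n, 0, 0.1), 0.03, ea = "A", oa = "G",
                   eaf = runif(n, 0.1, 0.9))
  h1 <- harmonize(ex, ou)
  # recode outcome: swap alleles, negate beta, reflect eaf -> same result
  ou2 <- ou
  ou2$effect_allele <- "G"; ou2$other_allele <- "A"
  ou2$beta <- -ou2$beta; ou2$eaf <- 1 - ou2$eaf
  h2 <- harmonize(ex, ou2)
  expect_equal(h1$beta_out, h2$beta_out)
  expect_equal(h1$beta_exp, h2$beta_exp)
  # idempotence: feeding the harmonized outcome back reproduces the pairs
  ou3 <- make_assoc(h1$variant_id, h1$beta_out, h1$se_out,
                    ea = "A", oa = "G", eaf = h1$eaf)
  h3 <- harmonize(ex, ou3)
  expect_equal(h3$beta_out, h1$beta_out)
  expect_equal(h3$beta_exp, h1$beta_exp)
  expect_true(all(h3$harmonize_action == "kept"))
  # no dropped_* action ever appears in output
  expect_true(all(!startsWith(h1$harmonize_action, "dropped")))
})
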