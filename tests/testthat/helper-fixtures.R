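# Build a harmonized instrument table directly from effect vectors.
make_h <- function(bx, by, sey, sex = rep(0.05, length(bx)),
                   ids = sprintf("rs%03d", seq_along(bx)),
                   n_exp = 1e4, n_out = 1e5, chrom = "1") {
  data.frame(variant_id = ids, chrom = chrom,
             pos = 1e6 + seq_along(bx) * 1e4,
             effect_allele = "A", other_allele = "G", eaf = 0.3,
             beta_exp = bx, se_exp = sex,
             pval_exp = pmax(2 * pnorm(-abs(bx / sex)), .Machine$double.xmin),
             n_exp = n_exp, beta_out = by, se_out = sey,
             pval_out = pmax(2 * pnorm(-abs(by / sey)), .Machine$double.xmin),
             n_out = n_out, n_cases_out = NA_real_,
             outcome_trait_type = "case_control",
             harmonize_action = "kept", stringsAsFactors = FALSE)
}

# Wrap a harmonized table in an instrument_set via identity-LD clumping.
make_iset <- function(h, exposure_id = "toy") {
  ld <- ld_matrix(diag(nrow(h)), h$variant_id)
  select_instruments(h, ld, p_threshold = 1 - 1e-12, clump_r2 = 0.99,
                     exposure_id = exposure_id)
}

# Minimal variant_assoc builder for IO / coloc / mediation tests.
make_assoc <- function(ids, beta, se, chrom = "1",
                       pos = 1e6 + seq_along(ids) * 1000,
                       ea = "A", oa = "G", eaf = 0.3, n = 1e4,
                       trait_type = "quantitative") {
  variant_assoc(data.frame(variant_id = ids, chrom = chrom, pos = pos,
                           effect_allele = ea, other_allele = oa, eaf = eaf,
                           beta = beta, se = se,
                           pval = pmax(2 * pnorm(-abs(beta / se)),
                                       .Machine$double.xmin),
                           n = n, stringsAsFactors = FALSE),
                trait_type = trait_type, check_pval = FALSE)
}

# Write a small GWAS table to a temp TSV and return the path.
write_toy_gwas <- function(df, ...) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
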