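.config_hash <- function(config) {
  keep <- config[setdiff(names(config), "truth")]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(keep, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

.pick_reference <- function(assocs) {
  z <- abs(assocs$beta / assocs$se)
  ord <- order(assocs$pval, -z, assocs$variant_id)
  assocs$variant_id[ord[1]]
}

#' Colocalization selection gate
#'
#' A target advances to colocalization when its primary MR estimate (IVW, or
#' the Wald ratio for single-instrument sets) has p below `alpha` and, if an
#' MR-PRESSO estimate exists, that estimate's p is not above `alpha`. An
#' absent MR-PRESSO estimate (too few instruments) never disqualifies.
#'
#' @param primary_p Primary MR p-value.
#' @param presso_run Did MR-PRESSO run?
#' @param presso_p MR-PRESSO estimate p-value (corrected when outliers were
#'   removed, else raw); ignored when `presso_run` is `FALSE`.
#' @param alpha Significance level (default 0.05).
#' @return Logical.
#' @export
selection_gate <- function(primary_p, presso_run, presso_p = NA_real_,
                           alpha = 0.05) {
  primary_p < alpha && !(isTRUE(presso_run) && presso_p > alpha)
}

#' Run the full drug-target MR screen
#'
#' For every exposure x tier x outcome combination: harmonize, select
#' LD-independent instruments, run every eligible estimator, attach
#' heterogeneity/pleiotropy/directionality diagnostics, and apply the
#' selection gate — primary MR p below `ivw_alpha` and, when MR-PRESSO ran,
#' a PRESSO estimate p not above `ivw_alpha` (an absent PRESSO estimate
#' never disqualifies). Gated targets proceed to colocalization in a window
#' around the most-significant exposure variant; coloc-positive targets with
#' CMap edges receive drug direction calls. Per-target failures are
#' quarantined into an errors table and the run continues. Nominal p-values
#' are accompanied by Bonferroni adjustment across the exposures tested per
#' tier (the most conservative choice for "correcting for the number of
#' genes and proteins tested"; the procedure is configurable via
#' `p_adjust_method`).
#'
#' @param config List with elements `exposures` (named list of
#'   `list(sumstats, tissue, ld)`), `outcomes` (named list of
#'   `variant_assoc`), `tiers` (p-value thresholds, default 5e-5),
#'   `clump_r2`, `ivw_alpha`, `pp4_threshold`, `coloc_half_width_bp`,
#'   `coloc_priors`, `presso_n_sim`, `drug_edges` (optional
#'   `drug_gene_edges`), `p_adjust_method`, `seed`.
#' @return List of class `screen_report`: data frames `mr_results`,
#'   `diagnostics`, `coloc`, `direction`, `errors`, plus `manifest`.
#' @export
run_screen <- function(config) {
  stopifnot(length(config$exposures) >= 1, length(config$outcomes) >= 1)
  tiers <- if (is.null(config$tiers)) 5e-5 else config$tiers
  clump_r2 <- if (is.null(config$clump_r2)) 0.1 else config$clump_r2
  ivw_alpha <- if (is.null(config$ivw_alpha)) 0.05 else config$ivw_alpha
  pp4_thr <- if (is.null(config$pp4_threshold)) 0.7 else config$pp4_threshold
  half_w <- if (is.null(config$coloc_half_width_bp)) 1e5 else config$coloc_half_width_bp
  priors <- if (is.null(config$coloc_priors)) c(1e-4, 1e-4, 1e-5) else config$coloc_priors
  n_sim <- if (is.null(config$presso_n_sim)) 5000 else config$presso_n_sim
  padj <- if (is.null(config$p_adjust_method)) "bonferroni" else config$p_adjust_method
  seed <- if (is.null(config$seed)) 1 else config$seed
  stopifnot(ivw_alpha > 0, ivw_alpha < 1, pp4_thr > 0, pp4_thr < 1)

  mr_rows <- list(); diag_rows <- list(); coloc_rows <- list()
  err_rows <- list(); gated_mr <- list(); inst_hash <- list()

  for (ex_name in names(config$exposures)) {
    ex <- config$exposures[[ex_name]]
    for (tier in tiers) {
      for (out_name in names(config$outcomes)) {
        target <- paste(ex_name, format(tier, scientific = TRUE), out_name,
                        sep = "|")
        res <- tryCatch({
          h <- harmonize(ex$sumstats, config$outcomes[[out_name]])
          iset <- select_instruments(h, ex$ld, p_threshold = tier,
                                     clump_r2 = clump_r2,
                                     exposure_id = ex_name, tier = tier)
          inst_hash[[target]] <- paste(sort(iset$variants$variant_id),
                                       collapse = ",")
          if (iset$not_analyzable) {
            err_rows[[target]] <- data.frame(target = target,
                                             stage = "instruments",
                                             error = "not_analyzable")
            NULL
          } else {
            ests <- mr_all(iset, seed = seed)
            primary <- if (iset$n_independent >= 2) ests$ivw else ests$wald
            q <- if (iset$n_independent >= 2) cochran_q(iset) else NULL
            pr <- mr_presso(iset, n_sim = n_sim, seed = seed)
            st <- steiger_test(iset)
            presso_p <- if (pr$run) {
              if (!is.null(pr$corrected)) pr$corrected$pval else pr$raw$pval
            } else NA_real_
            gate <- selection_gate(primary$pval, pr$run, presso_p, ivw_alpha)

            mr_rows[[target]] <- do.call(rbind, lapply(ests, function(e) {
              cbind(data.frame(exposure_id = ex_name, tissue = ex$tissue,
                               tier = tier, outcome = out_name,
                               stringsAsFactors = FALSE),
                    as.data.frame(e))
            }))
            diag_rows[[target]] <- data.frame(
              exposure_id = ex_name, tissue = ex$tissue, tier = tier,
              outcome = out_name, n_snps = iset$n_independent,
              gate = iset$estimator_gate,
              Q = if (is.null(q)) NA_real_ else q$Q,
              Q_p = if (is.null(q)) NA_real_ else q$p,
              presso_run = pr$run,
              presso_global_p = if (pr$run) pr$global_p else NA_real_,
              presso_outliers = if (pr$run) length(pr$outlier_indices) else NA_integer_,
              presso_p = presso_p,
              steiger_dir = if (is.null(st)) NA else st$direction_ok,
              steiger_p = if (is.null(st)) NA_real_ else st$steiger_p,
              gate_pass = gate, stringsAsFactors = FALSE)

            if (gate) {
              ref <- .pick_reference(
                ex$sumstats[ex$sumstats$variant_id %in% iset$variants$variant_id, ,
                            drop = FALSE])
              t1w <- window_select(ex$sumstats, ref, half_w)
              out_tab <- config$outcomes[[out_name]]
              t2w <- out_tab[out_tab$variant_id %in% t1w$variant_id, , drop = FALSE]
              cl <- coloc_abf(t1w, t2w, priors = priors,
                              pp4_threshold = pp4_thr, reference_variant = ref)
              coloc_rows[[target]] <- data.frame(
                exposure_id = ex_name, tissue = ex$tissue, tier = tier,
                outcome = out_name, reference_variant = ref,
                n_snps = cl$n_snps_window, PP0 = cl$pp[["PP0"]],
                PP1 = cl$pp[["PP1"]], PP2 = cl$pp[["PP2"]],
                PP3 = cl$pp[["PP3"]], PP4 = cl$pp[["PP4"]],
                decision = cl$decision, stringsAsFactors = FALSE)
              if (cl$decision) gated_mr[[ex_name]] <- primary
            }
            TRUE
          }
        }, error = function(e) {
          err_rows[[target]] <<- data.frame(target = target, stage = "run",
                                            error = conditionMessage(e))
          NULL
        })
      }
    }
  }

  empty_df <- function(...) {
    d <- data.frame(...)
    d[0, , drop = FALSE]
  }
  mr_results <- if (length(mr_rows)) do.call(rbind, mr_rows) else
    empty_df(exposure_id = "", tissue = "", tier = 0, outcome = "",
             method = "", n_snps = 0L, beta = 0, se = 0, ci_low = 0,
             ci_high = 0, pval = 0, or = 0, or_ci_low = 0, or_ci_high = 0)
  if (nrow(mr_results) > 0) {
    # correct across the exposures tested per tier, not across methods
    mr_results$pval_adjusted <- NA_real_
    for (tr in unique(mr_results$tier)) {
      sel <- mr_results$tier == tr
      m <- length(unique(mr_results$exposure_id[sel]))
      mr_results$pval_adjusted[sel] <- if (padj == "bonferroni") {
        pmin(mr_results$pval[sel] * m, 1)
      } else {
        stats::p.adjust(mr_results$pval[sel], method = padj)
      }
    }
  }
  rownames(mr_results) <- NULL

  diagnostics <- if (length(diag_rows)) do.call(rbind, diag_rows) else
    empty_df(exposure_id = "", tissue = "", tier = 0, outcome = "",
             n_snps = 0L, gate = "", Q = 0, Q_p = 0, presso_run = FALSE,
             presso_global_p = 0, presso_outliers = 0L, presso_p = 0,
             steiger_dir = NA, steiger_p = 0, gate_pass = FALSE)
  rownames(diagnostics) <- NULL
  coloc <- if (length(coloc_rows)) do.call(rbind, coloc_rows) else
    empty_df(exposure_id = "", tissue = "", tier = 0, outcome = "",
             reference_variant = "", n_snps = 0L, PP0 = 0, PP1 = 0, PP2 = 0,
             PP3 = 0, PP4 = 0, decision = FALSE)
  rownames(coloc) <- NULL
  errors <- if (length(err_rows)) do.call(rbind, err_rows) else
    empty_df(target = "", stage = "", error = "")
  rownames(errors) <- NULL

  direction <- if (!is.null(config$drug_edges) && length(gated_mr) > 0) {
    direction_calls(config$drug_edges, gated_mr)
  } else {
    empty_df(drug = "", gene = "", mr_direction = "",
             expected_drug_effect_on_gene = "",
             expected_drug_effect_on_risk = "", conflict = FALSE)
  }

  structure(list(mr_results = mr_results, diagnostics = diagnostics,
                 coloc = coloc, direction = direction, errors = errors,
                 instrument_hashes = inst_hash,
                 manifest = list(package = "targetmr",
                                 version = as.character(utils::packageVersion("targetmr")),
                                 r_version = paste(R.version$major,
                                                   R.version$minor, sep = "."),
                                 seed = seed, config_hash = .config_hash(config),
                                 tiers = tiers, ivw_alpha = ivw_alpha,
                                 pp4_threshold = pp4_thr)),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Drug-target MR screen:",
      length(unique(x$diagnostics$exposure_id)), "exposures,",
      sum(x$diagnostics$gate_pass), "passed the MR gate,",
      sum(x$coloc$decision), "coloc-positive\n")
  invisible(x)
}

#' Write the screen report to disk
#'
#' Emits four TSV tables — per-method MR estimates, colocalization
#' posteriors, the per-outcome comparison of primary estimates, and drug
#' direction calls — plus a machine-readable JSON manifest (package version,
#' seed, config hash). Re-running the same config and seed reproduces a
#' byte-identical manifest.
#'
#' @param report A `screen_report`.
#' @param dir Output directory (created if absent; unwritable is an error
#'   before anything is computed or discarded).
#' @return Character vector of paths written, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "screen_report"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory ", dir, call. = FALSE)
  }
  if (file.access(dir, 2) != 0) stop("output directory not writable: ", dir,
                                     call. = FALSE)
  paths <- c(mr = file.path(dir, "mr_results.tsv"),
             coloc = file.path(dir, "coloc.tsv"),
             outcomes = file.path(dir, "outcome_comparison.tsv"),
             direction = file.path(dir, "direction_calls.tsv"),
             manifest = file.path(dir, "manifest.json"))
  utils::write.table(report$mr_results, paths["mr"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$coloc, paths["coloc"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  primary <- report$mr_results[report$mr_results$method %in% c("ivw", "wald"), ,
                               drop = FALSE]
  utils::write.table(primary, paths["outcomes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(report$direction, paths["direction"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report$manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
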