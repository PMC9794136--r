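#' Construct and validate an LD matrix
#'
#' LD is always consumed, never computed: the matrix of pairwise correlations
#' `r` (signed, unit diagonal) comes from an external reference panel.
#'
#' @param r Square numeric matrix of correlations.
#' @param variant_ids Variant IDs in matrix order; defaults to `rownames(r)`.
#' @return Matrix of class `ld_matrix` with dimnames set to `variant_ids`.
#' @export
ld_matrix <- function(r, variant_ids = rownames(r)) {
  r <- as.matrix(r)
  if (is.null(variant_ids)) stop("LD matrix needs variant IDs", call. = FALSE)
  stopifnot(nrow(r) == ncol(r), length(variant_ids) == nrow(r))
  if (max(abs(r - t(r))) > 1e-8) stop("LD matrix not symmetric", call. = FALSE)
  if (max(abs(diag(r) - 1)) > 1e-8) stop("LD matrix diagonal must be 1", call. = FALSE)
  if (max(abs(r)) > 1 + 1e-8) stop("|r| must be <= 1", call. = FALSE)
  dimnames(r) <- list(variant_ids, variant_ids)
  class(r) <- c("ld_matrix", "matrix")
  r
}

#' Read an LD matrix from a TSV file
#'
#' Accepts either a square table (header row and first column of variant IDs)
#' or a long-format three-column table `(id1, id2, r)`; the long format is
#' symmetrized and missing off-diagonal pairs default to r = 0.
#'
#' @param path File path.
#' @return An `ld_matrix`.
#' @export
read_ld_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = "", quote = "",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) == 3 && !is.numeric(tab[[2]])) {
    ids <- unique(c(tab[[1]], tab[[2]]))
    r <- diag(length(ids))
    dimnames(r) <- list(ids, ids)
    for (i in seq_len(nrow(tab))) {
      r[tab[[1]][i], tab[[2]][i]] <- tab[[3]][i]
      r[tab[[2]][i], tab[[1]][i]] <- tab[[3]][i]
    }
    ld_matrix(r, ids)
  } else {
    ids <- as.character(tab[[1]])
    r <- as.matrix(tab[, -1, drop = FALSE])
    ld_matrix(r, ids)
  }
}

#' Instrument set constructor
#' @keywords internal
.instrument_set <- function(variants, exposure_id, tier, not_analyzable = FALSE) {
  n <- if (is.null(variants)) 0L else nrow(variants)
  gate <- if (n >= 4) "presso_eligible" else if (n >= 2) "ivw_eligible"
          else if (n == 1) "wald_only" else "not_analyzable"
  structure(list(exposure_id = exposure_id, tier = tier, variants = variants,
                 n_independent = n, estimator_gate = gate,
                 not_analyzable = not_analyzable || n == 0),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("Instrument set:", x$exposure_id, " tier", format(x$tier, scientific = TRUE),
      "\n  independent variants:", x$n_independent,
      " gate:", x$estimator_gate, "\n")
  invisible(x)
}

#' Select LD-independent instruments for one exposure
#'
#' Filters harmonized variants at a significance tier and greedily clumps them
#' against a locus LD matrix: the remaining variant with the smallest exposure
#' p-value is kept and every other remaining variant with `r^2 >= clump_r2`
#' against it is removed, until none remain. Ties on p-value are broken by
#' larger `|beta_exp|`, then lexicographic variant ID, so the result is
#' independent of input row order.
#'
#' The `estimator_gate` reflects the standard eligibility rules for
#' summary-statistics MR: one instrument permits only a Wald ratio, two permit
#' IVW, and four (IVW's minimum plus two) permit MR-PRESSO.
#'
#' @param assocs `harmonized` data frame (output of [harmonize()]).
#' @param ld An [ld_matrix()] covering every candidate variant.
#' @param p_threshold Exposure p-value tier (conventionally `5e-5` or `5e-8`).
#' @param clump_r2 Squared-correlation threshold above which the weaker
#'   variant is removed (default 0.1).
#' @param exposure_id Label carried into results (gene/protein + tissue).
#' @param tier Label for the tier; defaults to `p_threshold`.
#' @return An object of class `instrument_set`. When no variant passes the
#'   tier the set is empty and flagged `not_analyzable` rather than an error.
#' @export
select_instruments <- function(assocs, ld, p_threshold = 5e-5, clump_r2 = 0.1,
                               exposure_id = "exposure", tier = p_threshold) {
  stopifnot(clump_r2 > 0, clump_r2 < 1)
  cand <- as.data.frame(assocs)[assocs$pval_exp < p_threshold, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(.instrument_set(cand, exposure_id, tier, not_analyzable = TRUE))
  }
  missing <- setdiff(cand$variant_id, rownames(ld))
  if (length(missing) > 0) {
    stop("variant(s) absent from LD matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ord <- order(cand$pval_exp, -abs(cand$beta_exp), cand$variant_id)
  cand <- cand[ord, , drop = FALSE]
  keep <- character(0)
  remaining <- cand$variant_id
  while (length(remaining) > 0) {
    top <- remaining[1]
    keep <- c(keep, top)
    r2 <- ld[top, remaining]^2
    remaining <- remaining[r2 < clump_r2 & remaining != top]
  }
  sel <- cand[match(keep, cand$variant_id), , drop = FALSE]
  rownames(sel) <- NULL
  .instrument_set(sel, exposure_id, tier)
}

#' MR-PRESSO eligibility gate
#'
#' MR-PRESSO's leave-one-out construction needs two independent variants
#' beyond IVW's minimum of two; a `FALSE` gate marks the diagnostic as
#' not-run and never disqualifies the target downstream.
#'
#' @param iset An `instrument_set`.
#' @return `TRUE` iff the set holds at least 4 independent instruments.
#' @export
presso_gate <- function(iset) {
  stopifnot(inherits(iset, "instrument_set"))
  iset$n_independent >= 4
}
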