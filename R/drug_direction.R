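#' Build a deduplicated drug-to-gene target map
#'
#' Consumes an already-extracted drug/gene edge table (DGIdb/CMap style).
#' Interaction databases contribute `interaction_only` edges (no perturbation
#' direction); perturbation-similarity resources contribute `knockdown` or
#' `overexpression` edges with a signed similarity. Malformed rows are
#' skipped with a message; unknown sources are rejected.
#'
#' @param edges Path to a TSV with columns `drug, gene, source, perturbation,
#'   similarity`, or a data frame with those columns. `similarity` may be a
#'   sign (`"+"`/`"-"`), a number (its sign is used), or missing.
#' @param min_abs_similarity Optional threshold on `|similarity|` below which
#'   a numeric similarity is treated as missing (default 0: sign only).
#' @return Data frame of class `drug_gene_edges` with columns `drug, gene,
#'   source, perturbation, similarity_sign`.
#' @export
build_target_map <- function(edges, min_abs_similarity = 0) {
  tab <- if (is.character(edges)) {
    if (!file.exists(edges)) stop("file not found: ", edges, call. = FALSE)
    utils::read.table(edges, header = TRUE, sep = "\t", quote = "",
                      stringsAsFactors = FALSE)
  } else as.data.frame(edges, stringsAsFactors = FALSE)
  need <- c("drug", "gene", "source", "perturbation", "similarity")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) stop("edge table missing column(s): ",
                             paste(miss, collapse = ", "), call. = FALSE)
  tab$source <- tolower(tab$source)
  bad_source <- !tab$source %in% c("dgidb", "cmap")
  bad_drug <- is.na(tab$drug) | tab$drug == "" | is.na(tab$gene) | tab$gene == ""
  bad <- bad_source | bad_drug
  if (any(bad)) message(sum(bad), " malformed edge row(s) skipped")
  tab <- tab[!bad, , drop = FALSE]
  if (nrow(tab) == 0) stop("no valid drug-gene edges", call. = FALSE)

  sim_sign <- function(s) {
    if (is.na(s) || s == "") return("missing")
    if (s %in% c("+", "-")) return(s)
    x <- suppressWarnings(as.numeric(s))
    if (is.na(x) || abs(x) <= min_abs_similarity) return("missing")
    if (x > 0) "+" else "-"
  }
  tab$similarity_sign <- vapply(as.character(tab$similarity), sim_sign,
                                character(1), USE.NAMES = FALSE)
  tab$perturbation <- ifelse(tab$source == "dgidb", "interaction_only",
                             tolower(tab$perturbation))
  ok_pert <- tab$perturbation %in% c("knockdown", "overexpression",
                                     "interaction_only")
  if (any(!ok_pert)) {
    message(sum(!ok_pert), " edge(s) with unknown perturbation skipped")
    tab <- tab[ok_pert, , drop = FALSE]
  }
  tab <- tab[, c("drug", "gene", "source", "perturbation", "similarity_sign")]
  tab <- unique(tab)
  if (nrow(tab) == 0) stop("no valid drug-gene edges", call. = FALSE)
  rownames(tab) <- NULL
  class(tab) <- c("drug_gene_edges", "data.frame")
  tab
}

.compose_sign <- function(gene_dir, mr_dir) {
  if (gene_dir == "indeterminate") return("indeterminate")
  # drug lowers a risk-increasing gene => risk decreases, etc.
  if ((gene_dir == "decrease") == (mr_dir == "risk_increasing")) "decrease" else "increase"
}

#' Infer the expected direction of a drug's effect on disease risk
#'
#' Sign composition of perturbation similarity and MR direction: a drug whose
#' expression signature resembles a gene's knockdown (positive similarity) is
#' expected to lower that gene's level; if MR says higher gene level raises
#' risk, the drug is expected to lower risk. `interaction_only` edges and
#' missing similarity signs yield `indeterminate`, never an error.
#'
#' @param edge One-row `drug_gene_edges` entry (or equivalent list/row).
#' @param mr An `mr_result` for the gene's effect on the outcome (finite
#'   beta).
#' @return One-row data frame of class `direction_call`: `drug, gene,
#'   mr_direction, expected_drug_effect_on_gene, expected_drug_effect_on_risk`.
#' @export
infer_drug_direction <- function(edge, mr) {
  edge <- as.list(as.data.frame(edge, stringsAsFactors = FALSE))
  stopifnot(is.finite(mr$beta))
  mr_dir <- if (mr$beta >= 0) "risk_increasing" else "risk_decreasing"
  gene_dir <- if (edge$perturbation == "interaction_only" ||
                  edge$similarity_sign == "missing") {
    "indeterminate"
  } else if (edge$perturbation == "knockdown") {
    if (edge$similarity_sign == "+") "decrease" else "increase"
  } else {                                        # overexpression
    if (edge$similarity_sign == "+") "increase" else "decrease"
  }
  out <- data.frame(drug = edge$drug, gene = edge$gene, mr_direction = mr_dir,
                    expected_drug_effect_on_gene = gene_dir,
                    expected_drug_effect_on_risk = .compose_sign(gene_dir, mr_dir),
                    stringsAsFactors = FALSE)
  class(out) <- c("direction_call", "data.frame")
  out
}

#' Direction calls for every drug-gene edge of a screen
#'
#' Applies [infer_drug_direction()] to each edge whose gene has an MR result,
#' flagging drugs with conflicting calls for the same gene (the edge list is
#' never aggregated: all calls are emitted).
#'
#' @param edges `drug_gene_edges` table.
#' @param mr_results Named list of `mr_result`s keyed by gene symbol.
#' @return `direction_call` data frame with an extra `conflict` flag.
#' @export
direction_calls <- function(edges, mr_results) {
  edges <- edges[edges$gene %in% names(mr_results), , drop = FALSE]
  if (nrow(edges) == 0) {
    return(data.frame(drug = character(0), gene = character(0),
                      mr_direction = character(0),
                      expected_drug_effect_on_gene = character(0),
                      expected_drug_effect_on_risk = character(0),
                      conflict = logical(0)))
  }
  calls <- do.call(rbind, lapply(seq_len(nrow(edges)), function(i) {
    infer_drug_direction(edges[i, ], mr_results[[edges$gene[i]]])
  }))
  key <- paste(calls$drug, calls$gene)
  determinate <- calls$expected_drug_effect_on_risk != "indeterminate"
  n_dir <- tapply(calls$expected_drug_effect_on_risk[determinate],
                  key[determinate], function(x) length(unique(x)))
  calls$conflict <- !is.na(n_dir[key]) & n_dir[key] > 1
  rownames(calls) <- NULL
  calls
}
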