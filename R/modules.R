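# Gene-module extraction from factor matrices: within each factor row the
# gene weights are z-scored and genes with z above the threshold form the
# module; only modules with enough members are reported downstream.

new_gene_module <- function(source, module_index, z_scores, member_genes,
                            reported, z_threshold, min_genes) {
  structure(list(source = source, module_index = module_index,
                 z_scores = z_scores, member_genes = member_genes,
                 reported = reported, z_threshold = z_threshold,
                 min_genes = min_genes),
            class = "gene_module")
}

#' @export
print.gene_module <- function(x, ...) {
  cat(sprintf("gene_module %s_M%d: %d member genes (z > %g)%s\n",
              x$source, x$module_index, length(x$member_genes),
              x$z_threshold, if (x$reported) "" else " [not reported]"))
  invisible(x)
}

module_label <- function(module) sprintf("%s_M%d", module$source, module$module_index)

#' Extract gene modules from a factor matrix
#'
#' For each row of an `m x g` gene-factor matrix the per-gene z-scores are
#' computed across the `g` genes using the population (divide-by-`g`)
#' standard deviation; genes with `z > z_threshold` are the module members.
#' A constant row (zero standard deviation) yields an empty module. Modules
#' are flagged `reported` when they have at least `min_genes` members.
#' Applied to `W` this yields shared modules; applied to a `V_i`,
#' dataset-specific (cell-type-specific) modules.
#'
#' @param factor_matrix Non-negative `m x g` matrix (rows = factors).
#' @param gene_names Character vector of `g` gene names (defaults to the
#'   matrix column names).
#' @param z_threshold Membership threshold on the z-score; default 1.
#' @param min_genes Minimum members for a module to be reported; default 20.
#' @param source Label for the matrix of origin: `"shared"` for `W` or a
#'   dataset id for a `V_i`.
#' @return List of `gene_module` objects (class `gene_module_list`), one per
#'   row, each with `z_scores`, `member_genes`, `reported`.
#' @export
extract_gene_modules <- function(factor_matrix, gene_names = colnames(factor_matrix),
                                 z_threshold = 1, min_genes = 20L,
                                 source = "shared") {
  factor_matrix <- as.matrix(factor_matrix)
  g <- ncol(factor_matrix)
  if (g < 2L) stopf("need at least 2 genes to compute z-scores, got %d", g)
  if (is.null(gene_names)) stopf("gene_names required when matrix has no column names")
  if (length(gene_names) != g) stopf("gene_names length %d != %d columns",
                                     length(gene_names), g)
  if (min(factor_matrix) < 0) stopf("factor matrix must be non-negative")
  modules <- lapply(seq_len(nrow(factor_matrix)), function(r) {
    w <- factor_matrix[r, ]
    mu <- mean(w)
    sdev <- sqrt(mean((w - mu)^2))
    if (sdev == 0) {
      z <- stats::setNames(rep(0, g), gene_names)
      members <- character(0)
    } else {
      z <- stats::setNames((w - mu) / sdev, gene_names)
      members <- gene_names[z > z_threshold]
    }
    new_gene_module(source, r, z, members,
                    reported = length(members) >= min_genes,
                    z_threshold = z_threshold, min_genes = min_genes)
  })
  structure(modules, class = "gene_module_list")
}

#' Extract all modules of a factorization
#'
#' Convenience wrapper running [extract_gene_modules()] on `W` (source
#' `"shared"`) and on each `V_i` (source = dataset id).
#'
#' @param result An `irnmf_result`.
#' @inheritParams extract_gene_modules
#' @return A single `gene_module_list` concatenating all sources.
#' @export
gene_modules <- function(result, z_threshold = 1, min_genes = 20L) {
  out <- extract_gene_modules(result$W, z_threshold = z_threshold,
                              min_genes = min_genes, source = "shared")
  for (id in names(result$V)) {
    out <- c(out, extract_gene_modules(result$V[[id]],
                                       z_threshold = z_threshold,
                                       min_genes = min_genes, source = id))
  }
  structure(out, class = "gene_module_list")
}

#' @export
print.gene_module_list <- function(x, ...) {
  rep_n <- sum(vapply(x, `[[`, logical(1L), "reported"))
  cat(sprintf("gene_module_list: %d modules, %d reported\n", length(x), rep_n))
  invisible(x)
}

#' Top genes of a module by z-score
#'
#' Members ranked by z-score descending, ties broken lexicographically by
#' gene name so reports regenerate identically. Genes present in an optional
#' risk set are flagged (the figures' boldface).
#'
#' @param module A `gene_module` with at least one member.
#' @param n Number of genes to return (default 3); fewer are returned when
#'   the module is smaller.
#' @param risk_genes Optional character vector of risk genes.
#' @return Data frame with columns `gene`, `z`, and `risk` (if `risk_genes`
#'   given).
#' @export
module_top_genes <- function(module, n = 3L, risk_genes = NULL) {
  if (n < 1L) stopf("n must be >= 1")
  if (!length(module$member_genes)) stopf("module has no member genes")
  z <- module$z_scores[module$member_genes]
  ord <- order(-z, names(z))
  top <- utils::head(ord, n)
  out <- data.frame(gene = names(z)[top], z = unname(z[top]),
                    stringsAsFactors = FALSE)
  if (!is.null(risk_genes)) out$risk <- out$gene %in% risk_genes
  out
}
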