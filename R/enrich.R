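# Enrichment statistics: one-sided hypergeometric tests of gene modules
# against a risk-gene set (Bonferroni-corrected) and against functional
# gene-set collections (BH/FDR-corrected), plus the term-specificity logic
# that classifies enriched terms as common, module-specific, or
# cell-type-specific.

#' One-sided hypergeometric upper-tail probability
#'
#' `P(X >= x)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes (a
#' module) from a universe of `N` containing `K` marked genes, the
#' probability of at least `x` marked genes in the draw. Evaluated through
#' the stable log-space tail of [stats::phyper()].
#'
#' @param N Universe size.
#' @param K Marked genes in the universe (e.g. risk genes or a term's genes).
#' @param n Module size.
#' @param x Observed overlap.
#' @return Probability in `(0, 1]`; `x = 0` gives exactly 1.
#' @examples
#' hypergeometric_test(20, 4, 5, 3)  # 496/15504
#' @export
hypergeometric_test <- function(N, K, n, x) {
  if (any(c(N, K, n, x) < 0) || K > N || n > N || x > min(K, n))
    stopf("inconsistent hypergeometric counts (N=%g, K=%g, n=%g, x=%g)",
          N, K, n, x)
  if (x == 0) return(1)
  exp(stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Flag modules enriched for a risk-gene set
#'
#' Tests every *reported* module for over-representation of risk genes with
#' [hypergeometric_test()], using as universe the gene vocabulary of the
#' analyzed matrix; the risk set is intersected with the universe first.
#' Bonferroni correction is applied within each test family: by default each
#' source matrix (`W`, or one `V_i`) is its own family, mirroring per-cell-
#' type reporting; `family = "global"` pools all reported modules into one
#' family. Modules with adjusted p below `alpha` are flagged associated.
#'
#' @param modules A `gene_module_list` (see [extract_gene_modules()],
#'   [gene_modules()]).
#' @param risk_genes Character vector of risk-gene symbols.
#' @param universe Character vector: the genes of the analyzed expression
#'   matrix.
#' @param alpha Significance threshold on the Bonferroni-adjusted p; default
#'   0.1.
#' @param family `"per_source"` (default) or `"global"`.
#' @return Data frame sorted by adjusted p with columns `module`, `source`,
#'   `module_index`, `universe_size`, `risk_in_universe`, `module_size`,
#'   `overlap`, `raw_p`, `adjusted_p`, `associated`.
#' @export
flag_associated_modules <- function(modules, risk_genes, universe,
                                    alpha = 0.1,
                                    family = c("per_source", "global")) {
  family <- match.arg(family)
  risk <- intersect(unique(risk_genes), universe)
  if (!length(risk)) stopf("no risk genes present in the universe")
  reported <- Filter(function(m) m$reported, modules)
  if (!length(reported)) stopf("no reported modules to test")
  N <- length(universe)
  K <- length(risk)
  rows <- lapply(reported, function(mod) {
    members <- intersect(mod$member_genes, universe)
    x <- length(intersect(members, risk))
    data.frame(module = module_label(mod), source = mod$source,
               module_index = mod$module_index, universe_size = N,
               risk_in_universe = K, module_size = length(members),
               overlap = x,
               raw_p = hypergeometric_test(N, K, length(members), x),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  fam <- if (family == "global") rep("all", nrow(tab)) else tab$source
  n_tests <- stats::ave(tab$raw_p, fam, FUN = length)
  tab$adjusted_p <- pmin(1, tab$raw_p * n_tests)
  tab$associated <- tab$adjusted_p < alpha
  tab[order(tab$adjusted_p, tab$raw_p, tab$module), ]
}

#' Over-representation analysis of one module
#'
#' Hypergeometric upper-tail test of the module against every term of a
#' gene-set collection, with `N` = universe size, `K` = term size after
#' universe intersection, `n` = module size, `x` = overlap. P-values are
#' BH-adjusted across all terms tested for this module. A term is flagged
#' significant when `q < q_threshold` *and* its universe-intersected size is
#' at least `min_term_size`.
#'
#' @param module A `gene_module`.
#' @param sets A [gene_sets] collection.
#' @param universe Character vector of background genes (the analyzed
#'   matrix's vocabulary).
#' @param q_threshold FDR threshold; default 0.1.
#' @param min_term_size Minimum universe-intersected term size; default 10.
#' @return Data frame (one row per term overlapping the universe) with
#'   columns `module`, `term_id`, `term_name`, `term_size`, `module_size`,
#'   `overlap`, `raw_p`, `q`, `significant`, sorted by `q` then `raw_p` then
#'   `term_id`. Empty (with a warning) when no term overlaps the universe.
#' @export
overrepresentation_analysis <- function(module, sets, universe,
                                        q_threshold = 0.1,
                                        min_term_size = 10L) {
  stopifnot(inherits(sets, "gene_sets"))
  members <- intersect(module$member_genes, universe)
  N <- length(universe)
  term_genes <- lapply(sets$sets, function(s) intersect(s$genes, universe))
  keep <- lengths(term_genes) > 0L
  if (!any(keep)) {
    warning("no gene set overlaps the universe", call. = FALSE)
    return(data.frame(module = character(0), term_id = character(0),
                      term_name = character(0), term_size = integer(0),
                      module_size = integer(0), overlap = integer(0),
                      raw_p = numeric(0), q = numeric(0),
                      significant = logical(0)))
  }
  ids <- names(sets$sets)[keep]
  tg <- term_genes[keep]
  K <- lengths(tg)
  x <- vapply(tg, function(gset) length(intersect(gset, members)), integer(1L))
  raw_p <- vapply(seq_along(ids), function(i)
    hypergeometric_test(N, K[i], length(members), x[i]), numeric(1L))
  q <- stats::p.adjust(raw_p, method = "BH")
  tab <- data.frame(module = module_label(module), term_id = ids,
                    term_name = vapply(sets$sets[keep], `[[`, character(1L),
                                       "term_name"),
                    term_size = unname(K), module_size = length(members),
                    overlap = unname(x), raw_p = raw_p, q = q,
                    significant = q < q_threshold & K >= min_term_size,
                    stringsAsFactors = FALSE, row.names = NULL)
  tab[order(tab$q, tab$raw_p, tab$term_id), ]
}

#' Run over-representation analysis for every reported module
#'
#' @param modules A `gene_module_list`.
#' @inheritParams overrepresentation_analysis
#' @return Named list of [overrepresentation_analysis()] tables, one per
#'   reported module, keyed by module label (e.g. `shared_M3`).
#' @export
ora_all_modules <- function(modules, sets, universe, q_threshold = 0.1,
                            min_term_size = 10L) {
  reported <- Filter(function(m) m$reported, modules)
  tabs <- lapply(reported, overrepresentation_analysis, sets = sets,
                 universe = universe, q_threshold = q_threshold,
                 min_term_size = min_term_size)
  names(tabs) <- vapply(reported, module_label, character(1L))
  tabs
}

significant_terms <- function(tab) tab$term_id[tab$significant]

#' Rank terms by how many modules they are significant in
#'
#' @param tables Named list of per-module enrichment tables (as from
#'   [ora_all_modules()]); names label the modules in scope.
#' @return Data frame with columns `term_id`, `n_modules`,
#'   `n_total_modules`, descending by count with lexicographic tie-break;
#'   terms significant nowhere are excluded.
#' @export
rank_common_terms <- function(tables) {
  if (!length(tables)) stopf("need at least one table")
  per_mod <- lapply(tables, significant_terms)
  counts <- table(unlist(per_mod, use.names = FALSE))
  if (!length(counts)) {
    return(data.frame(term_id = character(0), n_modules = integer(0),
                      n_total_modules = integer(0)))
  }
  out <- data.frame(term_id = names(counts), n_modules = as.integer(counts),
                    n_total_modules = length(tables),
                    stringsAsFactors = FALSE)
  out[order(-out$n_modules, out$term_id), , drop = FALSE]
}

#' Module-specific significant terms within one scope
#'
#' Removes terms significant in more than one module of the scope (the
#' shared modules, or one cell type's modules), keeping per module only the
#' terms significant in exactly that module and nowhere else. Modules left
#' with at least one term are the "modules with module-specific terms". The
#' operation is idempotent.
#'
#' @param tables Named list of per-module enrichment tables within one scope.
#' @return Named list of tables restricted to each module's specific
#'   significant terms (possibly zero-row).
#' @export
module_specific_terms <- function(tables) {
  per_mod <- lapply(tables, significant_terms)
  counts <- table(unlist(per_mod, use.names = FALSE))
  unique_terms <- names(counts)[counts == 1L]
  lapply(tables, function(tab)
    tab[tab$significant & tab$term_id %in% unique_terms, , drop = FALSE])
}

#' Cell-type- and module-specific terms across cell types
#'
#' Keeps terms significant in exactly one module of exactly one cell type:
#' a term found in two modules anywhere, or in modules of two cell types, is
#' removed everywhere.
#'
#' @param tables_by_celltype Named list (cell type) of named lists (module)
#'   of enrichment tables.
#' @return Structure parallel to the input with each table restricted to
#'   the globally unique significant terms.
#' @export
cell_type_specific_terms <- function(tables_by_celltype) {
  all_terms <- unlist(lapply(tables_by_celltype, function(tabs)
    unlist(lapply(tabs, significant_terms), use.names = FALSE)),
    use.names = FALSE)
  counts <- table(all_terms)
  unique_terms <- names(counts)[counts == 1L]
  lapply(tables_by_celltype, function(tabs)
    lapply(tabs, function(tab)
      tab[tab$significant & tab$term_id %in% unique_terms, , drop = FALSE]))
}
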