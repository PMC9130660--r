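#' Construct an expression dataset
#'
#' An `expression_dataset` holds one non-negative expression matrix \eqn{X_i}
#' oriented samples x genes, together with unique sample and gene identifiers
#' and a dataset label (typically a cell type or study name).
#'
#' @param values Numeric matrix, `n` samples x `g` genes. All entries must be
#'   finite and non-negative.
#' @param sample_ids Character vector of `n` unique sample identifiers.
#' @param gene_names Character vector of `g` unique gene names.
#' @param dataset_id Single string labelling the dataset.
#' @return An object of class `expression_dataset` with elements `values`,
#'   `sample_ids`, `gene_names`, `dataset_id`.
#' @examples
#' x <- matrix(1:6, 2, 3)
#' ds <- expression_dataset(x, c("s1", "s2"), c("gA", "gB", "gC"), "demo")
#' dim(ds$values)
#' @export
expression_dataset <- function(values, sample_ids, gene_names, dataset_id) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.character(sample_ids)) sample_ids <- as.character(sample_ids)
  if (!is.character(gene_names)) gene_names <- as.character(gene_names)
  if (length(dataset_id) != 1L || !nzchar(dataset_id))
    stopf("dataset_id must be a single non-empty string")
  if (nrow(values) != length(sample_ids))
    stopf("dataset '%s': %d rows but %d sample ids", dataset_id,
          nrow(values), length(sample_ids))
  if (ncol(values) != length(gene_names))
    stopf("dataset '%s': %d columns but %d gene names", dataset_id,
          ncol(values), length(gene_names))
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stopf("dataset '%s': duplicate sample ids: %s", dataset_id,
          paste(utils::head(dup, 5L), collapse = ", "))
  dup <- unique(gene_names[duplicated(gene_names)])
  if (length(dup))
    stopf("dataset '%s': duplicate gene names: %s", dataset_id,
          paste(utils::head(dup, 5L), collapse = ", "))
  check_nonnegative_finite(values, sample_ids, gene_names, dataset_id)
  dimnames(values) <- list(sample_ids, gene_names)
  structure(list(values = values, sample_ids = sample_ids,
                 gene_names = gene_names, dataset_id = dataset_id),
            class = "expression_dataset")
}

check_nonnegative_finite <- function(values, sample_ids, gene_names, dataset_id) {
  bad <- which(!is.finite(values) | values < 0)
  if (length(bad)) {
    idx <- arrayInd(bad[seq_len(min(5L, length(bad)))], dim(values))
    where <- apply(idx, 1L, function(rc)
      sprintf("[%s, %s] = %g", sample_ids[rc[1L]], gene_names[rc[2L]],
              values[rc[1L], rc[2L]]))
    stopf("dataset '%s': %d negative or non-finite entries, e.g. %s",
          dataset_id, length(bad), paste(where, collapse = "; "))
  }
  invisible(TRUE)
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset '%s': %d samples x %d genes\n",
              x$dataset_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Construct an expression collection
#'
#' Bundles `k >= 2` [expression_dataset] objects that share one gene
#' vocabulary in one order. Use [harmonize_collection()] to align datasets
#' whose gene vocabularies differ in order or content.
#'
#' @param datasets List of [expression_dataset] objects with identical
#'   `gene_names` (same genes, same order) and unique `dataset_id`s.
#' @return Object of class `expression_collection` with elements `datasets`
#'   (named by dataset id) and `gene_names`.
#' @export
expression_collection <- function(datasets) {
  if (!is.list(datasets) || length(datasets) < 2L)
    stopf("a collection needs at least 2 datasets, got %d", length(datasets))
  ok <- vapply(datasets, inherits, logical(1L), "expression_dataset")
  if (!all(ok)) stopf("all elements must be expression_dataset objects")
  ids <- vapply(datasets, `[[`, character(1L), "dataset_id")
  if (anyDuplicated(ids))
    stopf("duplicate dataset ids: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  genes <- datasets[[1L]]$gene_names
  for (d in datasets[-1L]) {
    if (!identical(d$gene_names, genes))
      stopf("dataset '%s' gene vocabulary differs from '%s'; harmonize first",
            d$dataset_id, datasets[[1L]]$dataset_id)
  }
  names(datasets) <- ids
  structure(list(datasets = datasets, gene_names = genes),
            class = "expression_collection")
}

#' @export
print.expression_collection <- function(x, ...) {
  n <- vapply(x$datasets, function(d) nrow(d$values), integer(1L))
  cat(sprintf("expression_collection: %d datasets (%s), %d common genes\n",
              length(x$datasets),
              paste(sprintf("%s: %d", names(n), n), collapse = ", "),
              length(x$gene_names)))
  invisible(x)
}

n_datasets <- function(collection) length(collection$datasets)

dataset_sizes <- function(collection)
  vapply(collection$datasets, function(d) nrow(d$values), integer(1L))

#' Construct a gene set collection
#'
#' @param sets Named list, one element per term id; each element is a list
#'   with `term_name` (string) and `genes` (character vector, deduplicated
#'   on construction, must be non-empty).
#' @return Object of class `gene_sets`.
#' @seealso [load_gmt()]
#' @export
gene_sets <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stopf("sets must be a named list keyed by term id")
  if (anyDuplicated(names(sets)))
    stopf("duplicate term ids: %s",
          paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets <- lapply(sets, function(s) {
    genes <- unique(as.character(s$genes))
    if (!length(genes)) stopf("gene sets must be non-empty")
    list(term_name = as.character(s$term_name %||% ""), genes = genes)
  })
  structure(list(sets = sets), class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  sizes <- vapply(x$sets, function(s) length(s$genes), integer(1L))
  cat(sprintf("gene_sets: %d terms, set sizes %d-%d\n",
              length(sizes), min(sizes), max(sizes)))
  invisible(x)
}
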