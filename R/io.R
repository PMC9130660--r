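#' Load an expression dataset from disk
#'
#' Reads either a dense delimited matrix (TSV or CSV, sniffed from the header
#' line) with a gene-name header row and a sample-id first column, or a
#' Matrix Market triplet accompanied by plain-text gene and sample name files
#' (one name per line).
#'
#' Matrices are stored samples x genes; pass `transposed = TRUE` when the file
#' holds genes x samples (the common layout of 10x-style triplets).
#'
#' @param path Path to the dense matrix file, or to the `.mtx` file when
#'   `format = "mtx_triplet"`.
#' @param format `"dense"` or `"mtx_triplet"`.
#' @param dataset_id Label for the resulting dataset.
#' @param genes_file,samples_file Name files for the triplet format.
#' @param transposed Set `TRUE` if the stored matrix is genes x samples.
#' @param uppercase_genes Opt-in normalization of gene symbols to upper case;
#'   matching elsewhere in the package is exact and case-sensitive.
#' @return An [expression_dataset].
#' @export
load_dataset <- function(path, format = c("dense", "mtx_triplet"),
                         dataset_id = basename(path),
                         genes_file = NULL, samples_file = NULL,
                         transposed = FALSE, uppercase_genes = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  ds <- if (format == "dense") {
    read_dense_matrix(path, dataset_id, transposed)
  } else {
    if (is.null(genes_file) || is.null(samples_file))
      stopf("mtx_triplet format needs genes_file and samples_file")
    read_mtx_triplet(path, genes_file, samples_file, dataset_id, transposed)
  }
  if (uppercase_genes) {
    ds <- expression_dataset(ds$values, ds$sample_ids,
                             toupper(ds$gene_names), ds$dataset_id)
  }
  ds
}

read_dense_matrix <- function(path, dataset_id, transposed) {
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stopf("dense matrix '%s' has no data columns", path)
  ids <- as.character(df[[1L]])
  values <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(values)) stopf("non-numeric entries in '%s'", path)
  genes <- colnames(df)[-1L]
  if (transposed) {
    values <- t(values)
    expression_dataset(values, genes, ids, dataset_id)
  } else {
    expression_dataset(values, ids, genes, dataset_id)
  }
}

read_mtx_triplet <- function(mtx, genes_file, samples_file, dataset_id,
                             transposed) {
  m <- as.matrix(Matrix::readMM(mtx))
  genes <- read_name_file(genes_file)
  samples <- read_name_file(samples_file)
  if (transposed) m <- t(m)
  if (nrow(m) != length(samples) || ncol(m) != length(genes))
    stopf("mtx is %d x %d but %d samples / %d genes were supplied%s",
          nrow(m), ncol(m), length(samples), length(genes),
          if (!transposed) " (is the matrix transposed?)" else "")
  expression_dataset(m, samples, genes, dataset_id)
}

read_name_file <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  x <- readLines(path)
  # tolerate annotated name files (e.g. ensembl_id TAB symbol): first field
  vapply(strsplit(x, "\t", fixed = TRUE), `[[`, character(1L), 1L)
}

#' Harmonize datasets onto one gene vocabulary
#'
#' @param datasets List of [expression_dataset] objects (`k >= 2`).
#' @param policy `"intersect"` subsets and reorders every dataset to the
#'   sorted intersection of gene vocabularies; `"strict"` requires identical
#'   vocabularies as sets and aligns all datasets to the first dataset's
#'   gene order.
#' @return An [expression_collection].
#' @examples
#' d1 <- expression_dataset(matrix(1, 2, 3), c("a", "b"), c("g1", "g2", "g3"), "x")
#' d2 <- expression_dataset(matrix(1, 2, 3), c("c", "d"), c("g3", "g2", "g4"), "y")
#' coll <- harmonize_collection(list(d1, d2), policy = "intersect")
#' coll$gene_names  # "g2" "g3"
#' @export
harmonize_collection <- function(datasets, policy = c("intersect", "strict")) {
  policy <- match.arg(policy)
  if (length(datasets) < 2L)
    stopf("harmonization needs at least 2 datasets, got %d", length(datasets))
  vocabs <- lapply(datasets, `[[`, "gene_names")
  if (policy == "strict") {
    ref <- vocabs[[1L]]
    for (i in seq_along(vocabs)[-1L]) {
      if (!setequal(vocabs[[i]], ref))
        stopf("strict policy: dataset '%s' gene set differs (e.g. %s)",
              datasets[[i]]$dataset_id,
              paste(utils::head(c(setdiff(ref, vocabs[[i]]),
                                  setdiff(vocabs[[i]], ref)), 3L),
                    collapse = ", "))
    }
    common <- ref
  } else {
    common <- sort(Reduce(intersect, vocabs))
    if (!length(common)) stopf("empty gene intersection across datasets")
  }
  aligned <- lapply(datasets, function(d) {
    expression_dataset(d$values[, match(common, d$gene_names), drop = FALSE],
                       d$sample_ids, common, d$dataset_id)
  })
  expression_collection(aligned)
}

#' Load a plain-text gene list
#'
#' One symbol per line; blank lines and lines starting with `#` are skipped;
#' duplicates are collapsed.
#'
#' @param path Path to the file.
#' @param universe Optional character vector; when supplied the returned set
#'   is also intersected with it and the raw set kept in attribute `"raw"`.
#' @return Character vector of unique gene symbols.
#' @export
load_gene_list <- function(path, universe = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  x <- unique(x)
  if (!length(x)) stopf("gene list '%s' is empty", path)
  if (!is.null(universe)) {
    raw <- x
    x <- intersect(x, universe)
    attr(x, "raw") <- raw
  }
  x
}

#' Load gene sets from a GMT file
#'
#' Standard GMT: `term_id TAB description TAB gene1 TAB gene2 ...`, one set
#' per line; duplicate genes within a line are collapsed.
#'
#' @param path Path to the GMT file.
#' @return A [gene_sets] collection.
#' @export
load_gmt <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("GMT file '%s' is empty", path)
  parsed <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parsed) < 3L)
  if (length(short))
    stopf("GMT line %d has %d fields; need term, description, >=1 gene",
          short[1L], lengths(parsed)[short[1L]])
  sets <- lapply(parsed, function(f)
    list(term_name = f[2L], genes = unique(f[-(1:2)])))
  names(sets) <- vapply(parsed, `[[`, character(1L), 1L)
  gene_sets(sets)
}

# ---- factorization result persistence ------------------------------------

write_matrix_txt <- function(m, path) {
  chr <- matrix(sprintf("%.17g", m), nrow(m), dimnames = dimnames(m))
  utils::write.table(chr, path, sep = "\t", quote = FALSE,
                     col.names = NA, row.names = TRUE)
}

read_matrix_txt <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  as.matrix(df)
}

#' Write and read a factorization result
#'
#' `write_factorization()` stores `W`, each `V_i` and each `H_i` as labelled
#' tab-delimited matrices at full double precision plus a JSON manifest with
#' the fit configuration and objective trace; `read_factorization()` rebuilds
#' the [fit_irnmf()] result, checking dimensions against the manifest.
#'
#' @param result An `irnmf_result` from [fit_irnmf()].
#' @param dir Directory to write into (created if needed).
#' @return `write_factorization()` returns the manifest path invisibly;
#'   `read_factorization()` returns the `irnmf_result`.
#' @export
write_factorization <- function(result, dir) {
  stopifnot(inherits(result, "irnmf_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_txt(result$W, file.path(dir, "W.tsv"))
  ids <- names(result$V)
  for (id in ids) {
    write_matrix_txt(result$V[[id]], file.path(dir, paste0("V_", id, ".tsv")))
    write_matrix_txt(result$H[[id]], file.path(dir, paste0("H_", id, ".tsv")))
  }
  manifest <- list(
    dataset_ids = ids,
    config = unclass(result$config),
    objective_trace = result$objective_trace,
    converged = result$converged,
    n_sweeps = result$n_sweeps,
    dims = list(m = nrow(result$W), g = ncol(result$W),
                n = vapply(result$H, nrow, integer(1L)))
  )
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' @rdname write_factorization
#' @export
read_factorization <- function(dir) {
  mp <- file.path(dir, "manifest.json")
  if (!file.exists(mp)) stopf("no manifest.json in '%s'", dir)
  manifest <- tryCatch(jsonlite::fromJSON(mp, simplifyVector = TRUE),
                       error = function(e)
                         stopf("corrupted manifest in '%s': %s", dir,
                               conditionMessage(e)))
  ids <- manifest$dataset_ids
  W <- read_matrix_txt(file.path(dir, "W.tsv"))
  V <- lapply(ids, function(id) read_matrix_txt(file.path(dir, paste0("V_", id, ".tsv"))))
  H <- lapply(ids, function(id) read_matrix_txt(file.path(dir, paste0("H_", id, ".tsv"))))
  names(V) <- names(H) <- ids
  m <- manifest$dims$m
  g <- manifest$dims$g
  if (nrow(W) != m || ncol(W) != g)
    stopf("W is %d x %d but manifest says %d x %d", nrow(W), ncol(W), m, g)
  for (i in seq_along(ids)) {
    if (nrow(V[[i]]) != m || ncol(V[[i]]) != g)
      stopf("V_%s dimensions disagree with manifest", ids[i])
    if (nrow(H[[i]]) != manifest$dims$n[[i]] || ncol(H[[i]]) != m)
      stopf("H_%s dimensions disagree with manifest", ids[i])
  }
  new_irnmf_result(W = W, V = V, H = H,
                   objective_trace = as.numeric(manifest$objective_trace),
                   config = manifest$config,
                   converged = isTRUE(manifest$converged),
                   n_sweeps = as.integer(manifest$n_sweeps))
}
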