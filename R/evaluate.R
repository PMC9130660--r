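# Evaluation metrics: how faithfully the factorization reconstructs each
# dataset (entrywise, per cell, per gene), how well it preserves structure
# (sample-sample distances, gene-gene correlations), how separable the
# datasets are in the joint loading space, and how functionally distinct the
# modules are.

safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Reconstruction correlation
#'
#' Pearson correlation between one dataset `X_i` and its reconstruction
#' `H_i (W + V_i)`. Mode `"flattened"` correlates all `n_i * g` paired
#' entries; `"per_cell"` returns one correlation per sample (row);
#' `"per_gene"` one per gene (column). Zero-variance vectors give an
#' undefined correlation, returned as `NA` (excluded from summaries, with
#' the count in attribute `"n_undefined"`), never imputed.
#'
#' @param collection An [expression_collection].
#' @param result An `irnmf_result`.
#' @param i Dataset index or id.
#' @param mode `"flattened"`, `"per_cell"` or `"per_gene"`.
#' @return Scalar (flattened) or numeric vector with attribute
#'   `"n_undefined"`.
#' @export
reconstruction_correlation <- function(collection, result, i,
                                       mode = c("flattened", "per_cell",
                                                "per_gene")) {
  mode <- match.arg(mode)
  check_result_dims(collection, result)
  X <- collection$datasets[[i]]$values
  Xhat <- reconstruct(result, i)
  if (mode == "flattened") return(safe_cor(as.vector(X), as.vector(Xhat)))
  vals <- if (mode == "per_cell") {
    vapply(seq_len(nrow(X)), function(r) safe_cor(X[r, ], Xhat[r, ]),
           numeric(1L))
  } else {
    vapply(seq_len(ncol(X)), function(cc) safe_cor(X[, cc], Xhat[, cc]),
           numeric(1L))
  }
  attr(vals, "n_undefined") <- sum(is.na(vals))
  vals
}

#' Structure-preservation correlation
#'
#' `"sample_distance"`: Euclidean sample-sample distance matrices are built
#' from `X_i` and its reconstruction and correlated over their strict upper
#' triangles. `"gene_correlation_recon"`: gene-gene Pearson matrices from
#' `X_i` and the reconstruction, correlated the same way.
#' `"gene_correlation_lowdim"`: the gene-gene matrix of `X_i` against
#' correlations of the `m`-dimensional gene columns of `W + V_i`. Pairs
#' undefined because of constant genes are dropped (count in attribute
#' `"n_undefined"`); fully degenerate input is an error.
#'
#' @inheritParams reconstruction_correlation
#' @param structure Which structural summary to compare.
#' @return Scalar Pearson correlation.
#' @export
structure_correlation <- function(collection, result, i,
                                  structure = c("sample_distance",
                                                "gene_correlation_recon",
                                                "gene_correlation_lowdim")) {
  structure <- match.arg(structure)
  check_result_dims(collection, result)
  X <- collection$datasets[[i]]$values
  if (nrow(X) < 3L || ncol(X) < 3L) stopf("need at least 3 samples and 3 genes")
  if (structure == "sample_distance") {
    d1 <- as.vector(stats::dist(X))
    d2 <- as.vector(stats::dist(reconstruct(result, i)))
    if (stats::sd(d1) == 0 || stats::sd(d2) == 0)
      stopf("degenerate distance matrix (all pairwise distances equal)")
    return(stats::cor(d1, d2))
  }
  c1 <- upper_tri_vec(suppressWarnings(stats::cor(X)))
  other <- if (structure == "gene_correlation_recon") reconstruct(result, i)
           else result$W + result$V[[i]]
  c2 <- upper_tri_vec(suppressWarnings(stats::cor(other)))
  ok <- is.finite(c1) & is.finite(c2)
  if (!any(ok)) stopf("all gene-gene correlation pairs are undefined")
  out <- stats::cor(c1[ok], c2[ok])
  attr(out, "n_undefined") <- sum(!ok)
  out
}

#' Clustering evaluation of the joint loading space
#'
#' Runs seeded K-means (`nstart = 10`) on the row-concatenated loadings `H`
#' and scores the clusters against the true labels (by default each sample's
#' dataset of origin) with ARI, the Fowlkes-Mallows index, the Jaccard
#' coefficient, NMI (square-root normalization), purity, and the mean
#' silhouette width of the clustering.
#'
#' @param result An `irnmf_result`.
#' @param true_labels Optional label per row of the concatenated `H`;
#'   defaults to dataset membership.
#' @param n_clusters Number of K-means clusters; defaults to the number of
#'   datasets.
#' @param seed RNG seed for K-means.
#' @return Named numeric vector `ARI`, `FMI`, `JC`, `NMI`, `PUR`, `SC`
#'   with attribute `"cluster"` holding the K-means assignment.
#' @export
clustering_evaluation <- function(result, true_labels = NULL,
                                  n_clusters = length(result$H), seed = 1L) {
  H <- do.call(rbind, result$H)
  N <- nrow(H)
  if (n_clusters > N) stopf("n_clusters (%d) exceeds %d samples", n_clusters, N)
  if (is.null(true_labels)) {
    true_labels <- rep(names(result$H),
                       vapply(result$H, nrow, integer(1L)))
  }
  if (length(true_labels) != N)
    stopf("true_labels length %d != %d samples", length(true_labels), N)
  km <- with_seed(seed, stats::kmeans(H, centers = n_clusters, nstart = 10L))
  idx <- pair_counting_indices(km$cluster, true_labels)
  sc <- if (n_clusters < 2L) NA_real_ else
    mean(cluster::silhouette(km$cluster, stats::dist(H))[, 3L])
  out <- c(idx, SC = sc)
  attr(out, "cluster") <- km$cluster
  out
}

# External clustering indices from the contingency table.
pair_counting_indices <- function(cluster, labels) {
  tab <- table(cluster, labels)
  N <- sum(tab)
  sum_nij <- sum(choose(tab, 2))
  sum_ai <- sum(choose(rowSums(tab), 2))
  sum_bj <- sum(choose(colSums(tab), 2))
  n_pairs <- choose(N, 2)
  expected <- sum_ai * sum_bj / n_pairs
  denom <- (sum_ai + sum_bj) / 2 - expected
  ari <- if (denom == 0) 1 else (sum_nij - expected) / denom
  fmi <- if (sum_ai > 0 && sum_bj > 0) sum_nij / sqrt(sum_ai * sum_bj) else 0
  pair_union <- sum_ai + sum_bj - sum_nij
  jc <- if (pair_union > 0) sum_nij / pair_union else 1
  p_ij <- tab / N
  p_i <- rowSums(p_ij)
  p_j <- colSums(p_ij)
  mi_terms <- p_ij * log(p_ij / outer(p_i, p_j))
  mi <- sum(mi_terms[p_ij > 0])
  h_i <- -sum(p_i[p_i > 0] * log(p_i[p_i > 0]))
  h_j <- -sum(p_j[p_j > 0] * log(p_j[p_j > 0]))
  nmi <- if (h_i > 0 && h_j > 0) mi / sqrt(h_i * h_j) else 0
  pur <- sum(apply(tab, 1L, max)) / N
  c(ARI = ari, FMI = fmi, JC = jc, NMI = nmi, PUR = pur)
}

#' Average number of uniquely enriched terms per module
#'
#' For each module in scope, its `top_n` significant terms (ranked by `q`,
#' then raw p, then term id) are collected; a term is unique when it occurs
#' in the top list of at most one module. Returns the mean, over modules, of
#' the number of unique terms in the module's top list — high values mean
#' the modules capture functionally distinct biology.
#'
#' @param tables Named list of per-module enrichment tables (one scope).
#' @param top_n Number of top significant terms per module; default 5.
#' @return Scalar in `[0, top_n]`.
#' @export
unique_term_rate <- function(tables, top_n = 5L) {
  top_lists <- lapply(tables, function(tab) {
    sig <- tab[tab$significant, , drop = FALSE]
    sig <- sig[order(sig$q, sig$raw_p, sig$term_id), , drop = FALSE]
    utils::head(sig$term_id, top_n)
  })
  counts <- table(unlist(top_lists, use.names = FALSE))
  unique_terms <- names(counts)[counts <= 1L]
  mean(vapply(top_lists, function(terms) sum(terms %in% unique_terms),
              numeric(1L)))
}

#' Full evaluation report for a factorization
#'
#' Bundles the reconstruction, structure, and clustering metrics for every
#' dataset into one list (per-cell and per-gene correlations summarised by
#' their mean with undefined values excluded and counted).
#'
#' @inheritParams reconstruction_correlation
#' @param seed Seed for the K-means step.
#' @return List of class `irnmf_evaluation`.
#' @export
evaluate_factorization <- function(collection, result, seed = 1L) {
  ids <- names(collection$datasets)
  per_dataset <- lapply(ids, function(id) {
    pc <- reconstruction_correlation(collection, result, id, "per_cell")
    pg <- reconstruction_correlation(collection, result, id, "per_gene")
    list(
      flattened = reconstruction_correlation(collection, result, id, "flattened"),
      per_cell_mean = mean(pc, na.rm = TRUE),
      per_cell_undefined = attr(pc, "n_undefined"),
      per_gene_mean = mean(pg, na.rm = TRUE),
      per_gene_undefined = attr(pg, "n_undefined"),
      sample_distance = structure_correlation(collection, result, id,
                                              "sample_distance"),
      gene_correlation_recon = as.numeric(
        structure_correlation(collection, result, id, "gene_correlation_recon")),
      gene_correlation_lowdim = as.numeric(
        structure_correlation(collection, result, id, "gene_correlation_lowdim"))
    )
  })
  names(per_dataset) <- ids
  structure(list(per_dataset = per_dataset,
                 clustering = clustering_evaluation(result, seed = seed),
                 mse = reconstruction_mse(collection, result)),
            class = "irnmf_evaluation")
}

#' @export
print.irnmf_evaluation <- function(x, ...) {
  cat("irnmf evaluation\n")
  for (id in names(x$per_dataset)) {
    d <- x$per_dataset[[id]]
    cat(sprintf("  %s: flattened r = %.4f, distance r = %.4f, gene-gene r = %.4f\n",
                id, d$flattened, d$sample_distance, d$gene_correlation_recon))
  }
  cl <- x$clustering
  cat(sprintf("  clustering: ARI %.3f, NMI %.3f, purity %.3f, silhouette %.3f\n",
              cl[["ARI"]], cl[["NMI"]], cl[["PUR"]], cl[["SC"]]))
  cat(sprintf("  summed per-dataset MSE: %.6g\n", x$mse))
  invisible(x)
}
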