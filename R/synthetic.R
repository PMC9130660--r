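# Planted-factor synthetic collections: every factor is either shared
# (present in W for all datasets) or specific to one dataset (present in its
# V_i), with two-level gene weights so planted module membership is
# unambiguous, block-structured loadings, optional noise, and risk genes
# planted into chosen modules for enrichment power testing.

#' Configuration of the planted-factor generator
#'
#' The defaults describe a desk-scale collection that runs in seconds:
#' 3 datasets of 100 samples over 200 genes with 8 factors (2 shared plus 2
#' specific per dataset), disjoint 25-gene modules (two-level weights, high
#' 1 / low 0), samples split evenly into groups loading U(0.5, 1.5) on one
#' active factor each, and clipped-Gaussian noise of sd 0.1 on expression
#' values of order 1. Risk genes are planted as 75% of the genes of one
#' shared and one specific module, plus a 5% background rate among all other
#' genes (roughly the share of catalogued risk genes among protein-coding
#' genes).
#'
#' @param k Number of datasets.
#' @param n_per_dataset Samples per dataset (recycled to length `k`).
#' @param g Number of genes.
#' @param m Total factors; must equal
#'   `n_shared_factors + k * n_specific_factors`.
#' @param n_shared_factors,n_specific_factors Shared factors, and specific
#'   factors per dataset.
#' @param shared_module_size,specific_module_size Genes at high weight per
#'   factor; module gene blocks are disjoint and must fit in `g`.
#' @param weight_high,weight_low Factor gene weights; `weight_high >
#'   weight_low >= 0`.
#' @param loading_range Range of the uniform loading of a sample group on
#'   its factor.
#' @param noise `"none"`, `"gaussian_clipped"` (add N(0, sigma), clip at 0)
#'   or `"poisson"` (draw Poisson with the noise-free entry as mean).
#' @param sigma Noise sd for `"gaussian_clipped"`.
#' @param risk_modules Indices of factors whose modules receive planted risk
#'   genes; default one shared factor and the first specific factor.
#' @param risk_gene_fraction Fraction of each planted module's genes marked
#'   as risk genes.
#' @param background_risk_fraction Fraction of the remaining genes marked as
#'   risk genes.
#' @param seed RNG seed; the whole collection is reproducible from the
#'   config.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(k = 3L, n_per_dataset = 100L, g = 200L, m = 8L,
                             n_shared_factors = 2L, n_specific_factors = 2L,
                             shared_module_size = 25L,
                             specific_module_size = 25L,
                             weight_high = 1, weight_low = 0,
                             loading_range = c(0.5, 1.5),
                             noise = c("gaussian_clipped", "none", "poisson"),
                             sigma = 0.1,
                             risk_modules = NULL,
                             risk_gene_fraction = 0.75,
                             background_risk_fraction = 0.05,
                             seed = 1L) {
  noise <- match.arg(noise)
  k <- as.integer(k)
  n_per_dataset <- rep_len(as.integer(n_per_dataset), k)
  if (k < 2L) stopf("need k >= 2 datasets")
  if (any(c(n_per_dataset, g, m, n_shared_factors, n_specific_factors,
            shared_module_size, specific_module_size) < 1))
    stopf("all sizes must be positive")
  if (m != n_shared_factors + k * n_specific_factors)
    stopf("m = %d but n_shared + k * n_specific = %d", m,
          n_shared_factors + k * n_specific_factors)
  need <- n_shared_factors * shared_module_size +
    k * n_specific_factors * specific_module_size
  if (need > g)
    stopf("module gene blocks need %d genes but g = %d", need, g)
  if (!(weight_high > weight_low && weight_low >= 0))
    stopf("need weight_high > weight_low >= 0")
  if (is.null(risk_modules))
    risk_modules <- c(1L, n_shared_factors + 1L)
  if (any(risk_modules < 1L | risk_modules > m))
    stopf("risk_modules out of 1..%d", m)
  structure(list(k = k, n_per_dataset = n_per_dataset, g = as.integer(g),
                 m = as.integer(m),
                 n_shared_factors = as.integer(n_shared_factors),
                 n_specific_factors = as.integer(n_specific_factors),
                 shared_module_size = as.integer(shared_module_size),
                 specific_module_size = as.integer(specific_module_size),
                 weight_high = weight_high, weight_low = weight_low,
                 loading_range = loading_range, noise = noise, sigma = sigma,
                 risk_modules = as.integer(risk_modules),
                 risk_gene_fraction = risk_gene_fraction,
                 background_risk_fraction = background_risk_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a planted-factor expression collection
#'
#' Builds true factor matrices per [synthetic_config()], block-structured
#' loadings, and datasets `X_i = H_i (W + V_i)` with the configured noise;
#' plants risk genes into the chosen modules. Fully reproducible from the
#' config's seed.
#'
#' @param config A [synthetic_config()].
#' @return List with `collection` (an [expression_collection]) and `truth`
#'   (class `synthetic_truth`: true `W`, `V`, `H`, `factor_type` data frame,
#'   `planted_modules` list of gene sets per factor, `risk_genes`,
#'   `gene_names`, and the `config`).
#' @export
generate_planted_collection <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  genes <- sprintf("gene%03d", seq_len(cfg$g))
  ids <- sprintf("ds%d", seq_len(cfg$k))
  s <- cfg$n_shared_factors
  factor_owner <- c(rep(0L, s),
                    rep(seq_len(cfg$k), each = cfg$n_specific_factors))
  owner_id <- rep(NA_character_, cfg$m)
  owner_id[factor_owner > 0L] <- ids[factor_owner[factor_owner > 0L]]
  factor_type <- data.frame(
    factor = seq_len(cfg$m),
    type = ifelse(factor_owner == 0L, "shared", "specific"),
    dataset = owner_id,
    stringsAsFactors = FALSE)

  # disjoint gene blocks, one per factor, laid out sequentially
  sizes <- ifelse(factor_owner == 0L, cfg$shared_module_size,
                  cfg$specific_module_size)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  planted <- lapply(seq_len(cfg$m), function(f) genes[starts[f]:ends[f]])

  W <- matrix(cfg$weight_low, cfg$m, cfg$g, dimnames = list(
    paste0("M", seq_len(cfg$m)), genes))
  V <- lapply(seq_len(cfg$k), function(i) W)
  for (f in seq_len(cfg$m)) {
    cols <- starts[f]:ends[f]
    if (factor_owner[f] == 0L) W[f, cols] <- cfg$weight_high
    else V[[factor_owner[f]]][f, cols] <- cfg$weight_high
  }
  names(V) <- ids

  out <- with_seed(cfg$seed, {
    H <- vector("list", cfg$k)
    X <- vector("list", cfg$k)
    for (i in seq_len(cfg$k)) {
      n <- cfg$n_per_dataset[i]
      active <- which(factor_owner %in% c(0L, i))
      grp <- rep_len(seq_along(active), n)
      Hi <- matrix(0, n, cfg$m,
                   dimnames = list(sprintf("%s_s%03d", ids[i], seq_len(n)),
                                   paste0("M", seq_len(cfg$m))))
      for (a in seq_along(active)) {
        rows <- which(grp == a)
        Hi[rows, active[a]] <- stats::runif(length(rows),
                                            cfg$loading_range[1L],
                                            cfg$loading_range[2L])
      }
      H[[i]] <- Hi
      clean <- Hi %*% (W + V[[i]])
      X[[i]] <- switch(cfg$noise,
        none = clean,
        gaussian_clipped = pmax(clean + matrix(
          stats::rnorm(length(clean), 0, cfg$sigma), nrow(clean)), 0),
        poisson = matrix(stats::rpois(length(clean), clean), nrow(clean)))
      dimnames(X[[i]]) <- dimnames(clean)
    }
    names(H) <- ids
    # planted risk genes: a fraction of each chosen module, plus background
    risk <- unlist(lapply(cfg$risk_modules, function(f) {
      gs <- planted[[f]]
      sample(gs, round(cfg$risk_gene_fraction * length(gs)))
    }), use.names = FALSE)
    rest <- setdiff(genes, unlist(planted[cfg$risk_modules]))
    risk <- c(risk, sample(rest, round(cfg$background_risk_fraction *
                                         length(rest))))
    list(H = H, X = X, risk = sort(unique(risk)))
  })

  datasets <- lapply(seq_len(cfg$k), function(i)
    expression_dataset(out$X[[i]], rownames(out$H[[i]]), genes, ids[i]))
  collection <- expression_collection(datasets)
  truth <- structure(list(W = W, V = V, H = out$H, factor_type = factor_type,
                          planted_modules = planted, risk_genes = out$risk,
                          gene_names = genes, config = cfg),
                     class = "synthetic_truth")
  list(collection = collection, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "synthetic_truth: %d factors (%d shared), %d genes, %d risk genes\n",
    nrow(x$W), sum(x$factor_type$type == "shared"), length(x$gene_names),
    length(x$risk_genes)))
  invisible(x)
}

# Exact minimal-cost assignment (Hungarian algorithm with potentials,
# O(n^3)).  Returns, for each row, the assigned column.
hungarian_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)    # p[j + 1] = row currently assigned to column j
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L]] <- u[p[j + 1L]] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) assignment[p[j + 1L]] <- j
  assignment
}

true_gene_vector <- function(truth, f) {
  ft <- truth$factor_type
  if (ft$type[f] == "shared") truth$W[f, ] else truth$V[[ft$dataset[f]]][f, ]
}

est_gene_vector <- function(estimated, truth, f_true, j_est) {
  ft <- truth$factor_type
  if (ft$type[f_true] == "shared") return(estimated$W[j_est, ])
  v <- estimated$V[[ft$dataset[f_true]]]
  if (is.null(v)) stopf("estimate has no V block named '%s'", ft$dataset[f_true])
  v[j_est, ]
}

#' Match estimated factors to planted truth
#'
#' True shared factors are matched one-to-one against the rows of the
#' estimated `W`; each dataset's true specific factors are matched
#' one-to-one against the rows of that dataset's estimated `V_i`. Each
#' matching maximizes total cosine similarity and is solved exactly
#' (Hungarian algorithm). The matchings are per matrix because a factor
#' slot whose `W` row is empty carries no shared identity: different
#' datasets may legitimately park unrelated specific patterns in the same
#' slot of their respective `V_i`. Zero rows have cosine 0 by convention;
#' surplus estimated factors are left unmatched.
#'
#' @param estimated An `irnmf_result`.
#' @param truth A `synthetic_truth`.
#' @return List with `assignment` (per true factor, the matched row index of
#'   its comparison matrix) and `cosine` (per true factor).
#' @export
match_factors <- function(estimated, truth) {
  m_true <- nrow(truth$W)
  m_est <- nrow(estimated$W)
  if (m_est < m_true)
    stopf("estimate has %d factors but truth has %d", m_est, m_true)
  ft <- truth$factor_type
  assignment <- integer(m_true)
  cosine <- numeric(m_true)
  groups <- split(seq_len(m_true),
                  ifelse(ft$type == "shared", "shared", ft$dataset))
  for (fs in groups) {
    S <- matrix(0, length(fs), m_est)
    for (a in seq_along(fs)) {
      tv <- true_gene_vector(truth, fs[a])
      for (j in seq_len(m_est)) {
        S[a, j] <- cosine_sim(tv, est_gene_vector(estimated, truth, fs[a], j))
      }
    }
    # pad with zero-similarity dummy rows to square the cost matrix
    cost <- rbind(max(S) - S, matrix(0, m_est - length(fs), m_est))
    asg <- hungarian_assignment(cost)[seq_along(fs)]
    assignment[fs] <- asg
    cosine[fs] <- S[cbind(seq_along(fs), asg)]
  }
  list(assignment = assignment, cosine = cosine)
}

#' Recovery report against planted truth
#'
#' Aggregates the matched-factor cosines for gene factors (overall and split
#' by shared/specific) and for the loading columns, the Jaccard overlap of
#' z-score-extracted modules with the planted modules, the summed relative
#' reconstruction error, and — when the collection is supplied — whether the
#' planted risk modules (and no others) come out flagged by
#' [flag_associated_modules()].
#'
#' @param estimated An `irnmf_result`.
#' @param truth A `synthetic_truth`.
#' @param z_threshold,min_genes Passed to [extract_gene_modules()] for the
#'   Jaccard scoring.
#' @param enrichment_family Family convention for the enrichment check; see
#'   [flag_associated_modules()].
#' @return List of class `recovery_report` with elements
#'   `mean_cosine_gene`, `mean_cosine_shared`, `mean_cosine_specific`,
#'   `mean_cosine_loadings`, `module_jaccard`, `relative_reconstruction_error`,
#'   `planted_flagged`, `false_flags`, and the `match`.
#' @export
recovery_report <- function(estimated, truth, z_threshold = 1,
                            min_genes = 20L,
                            enrichment_family = c("global", "per_source")) {
  enrichment_family <- match.arg(enrichment_family)
  cfg <- truth$config
  match <- match_factors(estimated, truth)
  ft <- truth$factor_type
  shared <- ft$type == "shared"

  # loadings: shared factors compared on the concatenated H, specific
  # factors only on the owning dataset's H (slot reuse makes other
  # datasets' loadings on that slot uninformative)
  h_cos <- vapply(seq_len(nrow(truth$W)), function(f) {
    j <- match$assignment[f]
    if (shared[f]) {
      cosine_sim(unlist(lapply(truth$H, function(h) h[, f])),
                 unlist(lapply(estimated$H, function(h) h[, j])))
    } else {
      id <- ft$dataset[f]
      cosine_sim(truth$H[[id]][, f], estimated$H[[id]][, j])
    }
  }, numeric(1L))

  jac <- vapply(seq_len(nrow(truth$W)), function(f) {
    j <- match$assignment[f]
    mat <- if (shared[f]) estimated$W else estimated$V[[ft$dataset[f]]]
    mods <- extract_gene_modules(mat, truth$gene_names,
                                 z_threshold = z_threshold,
                                 min_genes = min_genes,
                                 source = if (shared[f]) "shared" else ft$dataset[f])
    est_genes <- mods[[j]]$member_genes
    planted <- truth$planted_modules[[f]]
    length(intersect(est_genes, planted)) / length(union(est_genes, planted))
  }, numeric(1L))

  # relative reconstruction error needs the data; rebuild noise-free X from
  # truth when no collection is attached to the estimate
  num <- den <- 0
  for (i in seq_along(truth$H)) {
    X <- truth$H[[i]] %*% (truth$W + truth$V[[i]])
    num <- num + sq_frob(X - reconstruct(estimated, i))
    den <- den + sq_frob(X)
  }

  est_named <- estimated
  if (is.null(colnames(est_named$W))) {
    colnames(est_named$W) <- truth$gene_names
    est_named$V <- lapply(est_named$V, `colnames<-`, truth$gene_names)
  }
  mods <- gene_modules(est_named, z_threshold = z_threshold,
                       min_genes = min_genes)
  enr <- tryCatch(
    flag_associated_modules(mods, truth$risk_genes, truth$gene_names,
                            family = enrichment_family),
    error = function(e) NULL)
  planted_flagged <- false_flags <- NA
  if (!is.null(enr)) {
    planted_labels <- vapply(cfg$risk_modules, function(f) {
      j <- match$assignment[f]
      sprintf("%s_M%d", if (shared[f]) "shared" else ft$dataset[f], j)
    }, character(1L))
    flagged <- enr$module[enr$associated]
    planted_flagged <- all(planted_labels %in% flagged)
    false_flags <- length(setdiff(flagged, planted_labels))
  }

  structure(list(
    mean_cosine_gene = mean(match$cosine),
    mean_cosine_shared = mean(match$cosine[shared]),
    mean_cosine_specific = mean(match$cosine[!shared]),
    mean_cosine_loadings = mean(h_cos),
    module_jaccard = mean(jac),
    relative_reconstruction_error = num / den,
    planted_flagged = planted_flagged,
    false_flags = false_flags,
    match = match), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(paste0(
    "recovery_report: gene-factor cosine %.3f (shared %.3f, specific %.3f)\n",
    "  loading cosine %.3f, module Jaccard %.3f, rel. recon. error %.3g\n"),
    x$mean_cosine_gene, x$mean_cosine_shared, x$mean_cosine_specific,
    x$mean_cosine_loadings, x$module_jaccard,
    x$relative_reconstruction_error))
  if (!is.na(x$planted_flagged))
    cat(sprintf("  planted risk modules flagged: %s; false flags: %d\n",
                x$planted_flagged, x$false_flags))
  invisible(x)
}
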