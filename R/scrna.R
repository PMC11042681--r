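#' Quality-control filter for single cells
#'
#' Keeps cells with library size and detected-gene count at or above the
#' thresholds and mitochondrial count fraction at or below the limit
#' (boundaries inclusive), then drops genes whose total count across the
#' surviving cells is zero.
#'
#' @param counts matrix (genes x cells).
#' @param mito_genes character vector of mitochondrial gene ids.
#' @param min_libsize,min_genes,max_mito QC thresholds (defaults 2000,
#'   1000, 0.10).
#' @return List with `qc` (per-cell tibble: `cell_id`, `libsize`,
#'   `n_genes`, `mito_fraction`, `pass`) and `filtered` (surviving
#'   matrix).
#' @export
qc_filter <- function(counts, mito_genes = character(0), min_libsize = 2000,
                      min_genes = 1000, max_mito = 0.10) {
  if (!all(mito_genes %in% rownames(counts))) {
    abort("mito_genes must be a subset of the matrix gene ids")
  }
  lib <- colSums(counts)
  ngene <- colSums(counts > 0)
  mito <- if (length(mito_genes) > 0) {
    colSums(counts[mito_genes, , drop = FALSE]) / pmax(lib, 1)
  } else {
    rep(0, ncol(counts))
  }
  pass <- lib >= min_libsize & ngene >= min_genes & mito <= max_mito
  filtered <- counts[, pass, drop = FALSE]
  if (ncol(filtered) == 0) abort("no cell passes QC")
  filtered <- filtered[rowSums(filtered) > 0, , drop = FALSE]
  list(
    qc = tibble(cell_id = colnames(counts), libsize = unname(lib),
                n_genes = unname(ngene), mito_fraction = unname(mito),
                pass = unname(pass)),
    filtered = filtered
  )
}

#' Cluster-wise median-ratio size factors and log normalization
#'
#' Two-level normalization in the spirit of pooling deconvolution: cells
#' are grouped by k-means on a PCA of logCPM values; within each cluster a
#' cell's factor is the median ratio of its counts to the cluster
#' pseudo-cell (gene-wise mean) over genes positive in the pseudo-cell;
#' factors are then rescaled across clusters by the pseudo-cell library
#' sums so they are comparable, and finally normalized to mean 1.
#'
#' @param counts matrix (genes x cells), QC-filtered.
#' @param n_clusters number of k-means clusters (default 4).
#' @param n_pcs PCs used for clustering (default 10, reduced to fit).
#' @param seed RNG seed for k-means.
#' @return List with `size_factors` (named per-cell), `cluster` (named
#'   integer vector) and `log_norm` (matrix of
#'   `log2(count / size_factor + 1)`).
#' @export
cluster_normalize <- function(counts, n_clusters = 4, n_pcs = 10,
                              seed = 1L) {
  n_cells <- ncol(counts)
  if (n_cells < 10 * n_clusters) n_clusters <- max(1L, n_cells %/% 10L)
  lc <- log_cpm(counts, prior = 1)
  keep <- apply(lc, 1, sd) > 0
  n_pcs <- min(n_pcs, sum(keep) - 1, n_cells - 1)
  cl <- if (n_clusters == 1L) {
    rep(1L, n_cells)
  } else {
    pc <- prcomp(t(lc[keep, , drop = FALSE]), rank. = n_pcs)
    withr_seed(seed, kmeans(pc$x, centers = n_clusters, nstart = 10,
                            iter.max = 50))$cluster
  }
  sf <- numeric(n_cells)
  scale_c <- numeric(n_clusters)
  for (c0 in seq_len(n_clusters)) {
    idx <- which(cl == c0)
    pseudo <- rowMeans(counts[, idx, drop = FALSE])
    pos <- pseudo > 0
    if (!any(pos)) abort("cluster pseudo-cell has no positive gene")
    for (i in idx) {
      sf[i] <- median(counts[pos, i] / pseudo[pos])
    }
    scale_c[c0] <- sum(pseudo)
  }
  sf <- sf * scale_c[cl] / mean(scale_c)
  if (any(sf <= 0)) {
    warn("non-positive size factor(s) floored to the smallest positive one")
    sf[sf <= 0] <- min(sf[sf > 0])
  }
  sf <- sf / mean(sf)
  names(sf) <- colnames(counts)
  log_norm <- log2(sweep(counts, 2, sf, "/") + 1)
  list(size_factors = sf, cluster = setNames(cl, colnames(counts)),
       log_norm = log_norm)
}

# evaluate expr under a local, restored RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Select highly variable genes against Poisson technical noise
#'
#' The technical variance of each gene's log-normalized expression is the
#' delta-method variance implied by Poisson counting noise at the gene's
#' mean and the cell size factors; the biological variance is total minus
#' technical, and the top `n` genes by biological variance are returned.
#'
#' @param log_norm matrix from [cluster_normalize()]
#'   (`log2(count/sf + 1)`).
#' @param size_factors per-cell size factors used to build `log_norm`.
#' @param n number of genes to select (default 1000).
#' @return Tibble ranked by `bio_var`: `gene_id`, `mean`, `total_var`,
#'   `tech_var`, `bio_var`, `selected`.
#' @export
hvg_select <- function(log_norm, size_factors, n = 1000) {
  if (n > nrow(log_norm)) abort("n exceeds the number of genes")
  mu <- rowMeans(2^log_norm - 1) # mean normalized count
  total <- apply(log_norm, 1, var)
  ln2sq <- log(2)^2
  # delta method: var log2(x/s + 1) ~ (mu/s) / (ln2 (mu+1))^2 per cell
  tech <- vapply(seq_len(nrow(log_norm)), function(g) {
    mean(mu[g] / (size_factors * ln2sq * (mu[g] + 1)^2))
  }, numeric(1))
  out <- tibble(
    gene_id = rownames(log_norm), mean = unname(mu),
    total_var = unname(total), tech_var = unname(tech),
    bio_var = unname(total - tech)
  ) |>
    arrange(desc(.data$bio_var)) |>
    mutate(selected = row_number() <= n)
  out
}

#' Gaussian-mixture beta-cell call from insulin expression
#'
#' Fits a K-component univariate Gaussian mixture (unequal variances) to
#' per-cell insulin log-expression, ranks components by mean, assigns each
#' cell by maximum posterior, and labels cells in the top two components
#' (the 3rd and 4th insulin modes when K = 4) as beta cells.
#'
#' @param insulin numeric vector of per-cell insulin log-expression,
#'   optionally named by cell id.
#' @param K number of mixture components (default 4, must be >= 2).
#' @param seed RNG seed for the mixture fit.
#' @return Tibble: `cell_id`, `insulin`, `component` (1..K ranked by
#'   increasing mean), `posterior` (of the assigned component),
#'   `is_beta`.
#' @export
gmm_beta_call <- function(insulin, K = 4, seed = 1L) {
  if (K < 2) abort("beta-cell calling needs at least 2 mixture components")
  if (length(insulin) < 4 * K) abort("too few cells for the mixture fit")
  # Mclust() evaluates mclustBIC() in the caller frame, which fails when
  # mclust is imported but not attached; make it visible locally
  mclustBIC <- mclust::mclustBIC
  fit <- withr_seed(seed, mclust::Mclust(insulin, G = K, modelNames = "V",
                                         verbose = FALSE))
  if (is.null(fit)) abort("mixture fit failed")
  rank_by_mean <- rank(fit$parameters$mean, ties.method = "first")
  comp <- rank_by_mean[fit$classification]
  post <- fit$z[cbind(seq_along(insulin), fit$classification)]
  tibble(
    cell_id = names(insulin) %||% as.character(seq_along(insulin)),
    insulin = as.numeric(insulin),
    component = as.integer(comp),
    posterior = as.numeric(post),
    is_beta = comp >= K - 1L
  )
}

#' Differential expression within beta cells
#'
#' Restricts to called beta cells, drops genes expressed (count > 0) in
#' fewer than `min_cells` of them, and applies the moderated t-test to the
#' log-normalized values between conditions.
#'
#' @param counts matrix (genes x cells), QC-filtered.
#' @param log_norm matched log-normalized matrix.
#' @param calls tibble from [gmm_beta_call()].
#' @param design tibble with `cell_id` and `condition` (`CTRL`/`CASE`).
#' @param min_cells minimum expressing beta cells per gene (default 10).
#' @return Tibble as [moderated_t()].
#' @export
beta_de <- function(counts, log_norm, calls, design, min_cells = 10) {
  beta_cells <- calls$cell_id[calls$is_beta]
  des <- as_tibble(design)
  des <- des[des$cell_id %in% beta_cells, ]
  if (length(unique(des$condition)) < 2) {
    abort("both conditions need called beta cells")
  }
  sub <- counts[, des$cell_id, drop = FALSE]
  keep <- rowSums(sub > 0) >= min_cells
  lm_mat <- log_norm[keep, des$cell_id, drop = FALSE]
  moderated_t(lm_mat, tibble(sample_id = des$cell_id,
                             condition = des$condition))
}
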