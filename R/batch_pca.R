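#' Remove nuisance effects before PCA
#'
#' Residualizes each feature on nuisance covariates (subject, clone, batch,
#' gender, age, BMI, ...) by least squares while preserving the retained
#' design effects and the grand mean.  A thin wrapper around
#' \code{limma::removeBatchEffect}, which implements exactly this
#' projection.
#'
#' @param log_matrix numeric matrix (features x samples) on a log-like scale.
#' @param design sample design tibble aligned to the columns.
#' @param nuisance character vector of design columns to remove; character
#'   or factor columns are treated as batches, numeric ones as covariates.
#' @param retained character vector of design columns whose effects must be
#'   preserved (e.g. `"condition"`).
#' @return Residualized matrix of the same shape.
#' @export
remove_batch_for_pca <- function(log_matrix, design, nuisance,
                                 retained = "condition") {
  des <- as_tibble(design)
  des <- des[match(colnames(log_matrix), des$sample_id), ]
  keep <- stats::model.matrix(stats::reformulate(retained), data = des)
  is_num <- vapply(nuisance, function(v) is.numeric(des[[v]]), logical(1))
  batches <- nuisance[!is_num]
  covars <- nuisance[is_num]
  args <- list(x = log_matrix, design = keep)
  if (length(batches) >= 1) args$batch <- factor(des[[batches[1]]])
  if (length(batches) >= 2) args$batch2 <- factor(des[[batches[2]]])
  if (length(batches) > 2) {
    abort("at most two factor-valued nuisance variables are supported")
  }
  if (length(covars) > 0) {
    args$covariates <- as.matrix(des[, covars, drop = FALSE])
  }
  comb <- cbind(keep, do.call(cbind, lapply(nuisance, function(v) {
    if (is.numeric(des[[v]])) des[[v]] else as.numeric(factor(des[[v]]))
  })))
  if (qr(comb)$rank < ncol(comb)) {
    abort("retained and nuisance design columns are confounded")
  }
  do.call(limma::removeBatchEffect, args)
}

#' Sample-level principal components
#'
#' Column-centred SVD of the feature matrix; samples are observations.
#'
#' @param log_matrix numeric matrix (features x samples).
#' @param n_components number of components to return.
#' @param design optional design tibble joined onto the scores.
#' @return List with `scores` (tibble: `sample_id`, `PC1..PCk`, design
#'   columns) and `explained` (tibble of per-component variance fractions).
#' @export
pca_samples <- function(log_matrix, n_components = 2, design = NULL) {
  if (n_components > min(dim(log_matrix))) {
    abort("n_components exceeds matrix dimensions")
  }
  if (all(apply(log_matrix, 1, sd) == 0)) abort("constant matrix has no PCs")
  pc <- prcomp(t(log_matrix), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- as_tibble(pc$x[, seq_len(k), drop = FALSE])
  scores <- mutate(scores, sample_id = colnames(log_matrix), .before = 1)
  if (!is.null(design)) {
    scores <- left_join(scores, as_tibble(design), by = "sample_id")
  }
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(
    scores = scores,
    explained = tibble(component = paste0("PC", seq_along(expl)),
                       variance_fraction = expl)[seq_len(k), ]
  )
}
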