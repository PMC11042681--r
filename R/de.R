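#' Filter genes on counts per million
#'
#' Keeps genes with CPM above `min_cpm` in at least `min_samples` samples.
#' The study's two presets ship as `cpm_presets`: `nod-beta` (CPM > 1 in
#' >= 3 samples) and `oas-oe` (CPM > 0.49 in >= 4 samples).
#'
#' @param counts matrix (genes x samples) of raw counts.
#' @param min_cpm CPM threshold (exclusive).
#' @param min_samples minimum number of samples exceeding it.
#' @return Character vector of kept gene ids.
#' @export
cpm_filter <- function(counts, min_cpm = 1, min_samples = 3) {
  if (min_samples > ncol(counts)) {
    abort("min_samples exceeds the number of samples")
  }
  lib <- colSums(counts)
  if (any(lib <= 0)) abort("library sizes must be positive")
  cpm <- sweep(counts, 2, lib, "/") * 1e6
  rownames(counts)[rowSums(cpm > min_cpm) >= min_samples]
}

#' @rdname cpm_filter
#' @export
cpm_presets <- list(
  `nod-beta` = list(min_cpm = 1, min_samples = 3),
  `oas-oe` = list(min_cpm = 0.49, min_samples = 4)
)

#' Trimmed mean of M-values normalization factors
#'
#' Weighted TMM factors against a reference sample (the one whose
#' upper-quartile CPM is closest to the mean upper quartile).  M-values are
#' doubly trimmed (30% on M, 5% on A by default) and averaged with inverse
#' delta-method variance weights; factors are rescaled to geometric mean 1.
#'
#' @param counts matrix (genes x samples).
#' @param logratio_trim,abs_trim two-sided trim fractions on M and A.
#' @return Named vector of per-sample factors.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, abs_trim = 0.05) {
  lib <- colSums(counts)
  uq <- apply(counts, 2, function(x) quantile(x / sum(x), 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(s) {
    if (s == ref) return(1)
    tmm_pair(counts[, s], counts[, ref], lib[s], lib[ref],
             logratio_trim, abs_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, abs_trim) {
  pos <- obs > 0 & ref > 0
  if (!any(pos)) abort("sample shares no positive genes with the reference")
  obs <- obs[pos]; ref <- ref[pos]
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(m) & is.finite(a) & w > 0
  m <- m[fin]; a <- a[fin]; w <- w[fin]
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * abs_trim) + 1
  hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m & rank(a) >= lo_a & rank(a) <= hi_a
  if (!any(keep)) return(1)
  2^(sum(m[keep] / w[keep]) / sum(1 / w[keep]))
}

#' Log counts per million
#'
#' `log2((count + prior) / (effective library size + 2 * prior) * 1e6)`
#' with effective library size `libsize * factor`.
#'
#' @param counts matrix (genes x samples).
#' @param factors normalization factors (default 1).
#' @param prior prior count (default 0.5).
#' @return Matrix of logCPM values.
#' @export
log_cpm <- function(counts, factors = NULL, prior = 0.5) {
  lib <- colSums(counts)
  eff <- lib * (factors %||% rep(1, ncol(counts)))
  log2(sweep(counts + prior, 2, eff + 2 * prior, "/") * 1e6)
}

#' Moderated t-test differential expression
#'
#' Per-gene linear model on logCPM values with empirical-Bayes variance
#' moderation: residual variances are shrunk toward a common prior
#' `s0^2` with prior degrees of freedom `d0`, both estimated by moment
#' matching of the log residual variances against a scaled F distribution;
#' the moderated t is referred to `d0 + df_residual` degrees of freedom.
#'
#' @param logcpm matrix (genes x samples).
#' @param design design tibble with `sample_id` and `condition`
#'   (`CTRL`/`CASE`), or a numeric design matrix whose last column is the
#'   tested coefficient.
#' @param d0 override for the prior degrees of freedom: `0` gives the
#'   ordinary t-test, `Inf` full shrinkage to `s0^2`; `NULL` (default)
#'   estimates it from the data.
#' @return Tibble: `gene_id`, `log_fc`, `ave_expr`, `t`, `df_total`,
#'   `pvalue`, `qvalue`, `s2_post`.
#' @export
moderated_t <- function(logcpm, design, d0 = NULL) {
  if (is.matrix(design)) {
    X <- design
  } else {
    des <- as_tibble(design)
    des <- des[match(colnames(logcpm), des$sample_id), ]
    des$condition <- factor(des$condition, levels = c("CTRL", "CASE"))
    X <- stats::model.matrix(~condition, data = des)
  }
  n <- nrow(X); p <- ncol(X)
  df_res <- n - p
  if (df_res < 1) abort("at least one residual degree of freedom required")
  qrX <- qr(X)
  B <- t(qr.coef(qrX, t(logcpm)))            # genes x p
  fit <- t(qr.fitted(qrX, t(logcpm)))
  res <- logcpm - fit
  s2 <- rowSums(res^2) / df_res
  xtxi <- chol2inv(qr.R(qrX))
  v_coef <- xtxi[p, p]

  est <- fit_f_dist(s2, df_res)
  if (is.null(d0)) d0 <- est$df_prior
  s0_2 <- est$s2_prior
  if (is.infinite(d0)) {
    s2_post <- rep(s0_2, length(s2))
  } else {
    s2_post <- (d0 * s0_2 + df_res * s2) / (d0 + df_res)
  }
  # total df capped at the summed residual df over all genes
  df_total <- rep(min(d0 + df_res, length(s2) * df_res), length(s2))
  tval <- B[, p] / sqrt(s2_post * v_coef)
  pval <- 2 * pt(-abs(tval), df = df_total)
  tibble(
    gene_id = rownames(logcpm),
    log_fc = unname(B[, p]),
    ave_expr = rowMeans(logcpm),
    t = unname(tval),
    df_total = unname(df_total),
    pvalue = unname(pval),
    qvalue = bh_adjust(unname(pval)),
    s2_post = unname(s2_post)
  )
}

# Moment-matching fit of log s^2 to a scaled F: returns the prior variance
# s2_prior and prior degrees of freedom df_prior (Inf when the spread of
# log s^2 is no larger than expected from the residual chi-square alone).
fit_f_dist <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  z <- log(s2[ok])
  if (length(z) < 2) return(list(df_prior = 0, s2_prior = mean(s2[ok])))
  e <- z - digamma(df / 2) + log(df / 2)
  ev <- mean((e - mean(e))^2) * length(e) / (length(e) - 1) - trigamma(df / 2)
  if (is.na(ev) || ev <= 0) {
    df_prior <- Inf
    s2_prior <- mean(s2[ok])
  } else {
    df_prior <- 2 * trigamma_inverse(ev)
    s2_prior <- exp(mean(e) + digamma(df_prior / 2) - log(df_prior / 2))
  }
  list(df_prior = df_prior, s2_prior = s2_prior)
}

trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Gene-level NB differential expression with covariates
#'
#' Runs the negative-binomial Wald engine on raw gene counts (input
#' libraries) with median-of-ratios size factors as offsets, adjusting for
#' covariates such as sequencing batch, gender and age.
#'
#' @param counts matrix (genes x samples) of raw counts.
#' @param design design tibble with `sample_id`, `condition` and covariate
#'   columns.
#' @param covariates character vector of covariate column names (may be
#'   empty).
#' @return Tibble as [nb_wald_test()], with `qvalue` added.
#' @export
nb_de <- function(counts, design, covariates = character(0)) {
  sf <- estimate_size_factors(counts)
  res <- nb_wald_test(counts, design, mode = "covariate",
                      covariates = covariates, size_factors = sf)
  res$qvalue <- bh_adjust(res$pvalue)
  res
}

#' Intersect differentially expressed and methylated genes
#'
#' Classifies genes by methylation direction (hyper/hypo regions at
#' `dm_q`) against expression direction (up/down at `de_q`).  A gene with
#' regions in both directions contributes to each matching cell and is
#' flagged.
#'
#' @param de DE tibble with `gene_id`, `log_fc` (or `log2fc`), `qvalue`.
#' @param dm region tibble with `gene_id`, `direction`, `fdr`.
#' @param de_q,dm_q FDR thresholds (defaults 0.05).
#' @return List with `table` (2x2 tibble of counts), `genes` (per-gene
#'   classification) and `both_directions` (flagged gene ids).
#' @export
intersect_deg_dmg <- function(de, dm, de_q = 0.05, dm_q = 0.05) {
  lfc <- de$log_fc %||% de$log2fc
  deg <- tibble(gene_id = de$gene_id,
                de_dir = ifelse(lfc >= 0, "up", "down"))[
                  !is.na(de$qvalue) & de$qvalue < de_q, ]
  dmg <- dm[!is.na(dm$fdr) & dm$fdr < dm_q, c("gene_id", "direction")] |>
    distinct()
  joint <- dplyr::inner_join(dmg, deg, by = "gene_id")
  cells <- tidyr::expand_grid(direction = c("hyper", "hypo"),
                              de_dir = c("up", "down"))
  tab <- joint |>
    count(.data$direction, .data$de_dir) |>
    dplyr::right_join(cells, by = c("direction", "de_dir")) |>
    mutate(n = tidyr::replace_na(.data$n, 0L)) |>
    arrange(.data$direction, .data$de_dir)
  dup <- joint |>
    distinct(.data$gene_id, .data$direction) |>
    count(.data$gene_id) |>
    filter(.data$n > 1) |>
    pull(.data$gene_id)
  list(table = tab, genes = joint, both_directions = dup)
}
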