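#' Negative-binomial Wald test per bin
#'
#' Fits each bin's rounded, adjusted IP counts with a log-link
#' negative-binomial GLM and tests the condition coefficient with a Wald
#' z-test.  In `paired` mode the design is `~ subject + condition`, so each
#' treated sample is compared against its own baseline; in `covariate` mode
#' it is `~ covariates + condition`.  The per-bin dispersion is the
#' Cox-Reid-adjusted profile MLE, shrunk on the log scale toward a lowess
#' mean-dispersion trend before the final fit (see `shrink`).
#'
#' @param counts matrix (features x samples) of non-negative counts;
#'   fractional values are rounded half-even with a message.
#' @param design tibble with `sample_id`, `condition` (`CTRL`/`CASE`) and,
#'   depending on the mode, `subject` or the covariate columns.
#' @param mode `"paired"` or `"covariate"`.
#' @param covariates character vector of design columns to adjust for in
#'   covariate mode.
#' @param size_factors optional per-sample factors whose logs enter the GLM
#'   as offsets; use when `counts` are raw (not pre-normalized).
#' @param shrink `"eb"` (default) weights the lowess trend against each
#'   bin's dispersion MLE by their estimated precisions (the trend
#'   dominates when bins share a common dispersion, the MLE when bins are
#'   truly heterogeneous); a numeric value in `[0, 1]` fixes the trend
#'   weight instead (0 = per-bin MLE only).
#' @param alpha_range search bounds for the dispersion MLE.
#' @return Tibble with one row per feature: `bin_id`, `gene_id`, `ordinal`
#'   (parsed from `gene:ordinal` ids when possible), `base_mean`, `log2fc`,
#'   `lfc_se`, `stat`, `pvalue`, `dispersion`, `converged`.
#' @export
nb_wald_test <- function(counts, design, mode = c("paired", "covariate"),
                         covariates = NULL, size_factors = NULL,
                         shrink = "eb", alpha_range = c(1e-8, 10)) {
  mode <- match.arg(mode)
  des <- as_tibble(design)
  des <- des[match(colnames(counts), des$sample_id), ]
  if (anyNA(des$sample_id)) abort("design is missing some count columns")
  des$condition <- factor(des$condition, levels = c("CTRL", "CASE"))

  X <- if (mode == "paired") {
    stats::model.matrix(~ subject + condition, data = des)
  } else {
    if (is.null(covariates) || length(covariates) == 0) {
      stats::model.matrix(~condition, data = des)
    } else {
      fml <- stats::reformulate(c(covariates, "condition"))
      stats::model.matrix(fml, data = des)
    }
  }
  if (qr(X)$rank < ncol(X)) abort("design matrix is not full rank")
  if (nrow(X) - ncol(X) < 1) abort("no residual degrees of freedom")
  coef_idx <- which(colnames(X) == "conditionCASE")

  if (any(counts != round(counts))) {
    inform("fractional counts rounded (half-even) before GLM fitting")
    counts <- round(counts)
  }
  storage.mode(counts) <- "double"
  off <- if (is.null(size_factors)) {
    rep(0, ncol(counts))
  } else {
    log(size_factors[colnames(counts)])
  }

  alpha_hat <- nb_alpha_mle(counts, X, off, alpha_range[1], alpha_range[2])
  base_mean <- if (is.null(size_factors)) {
    rowMeans(counts)
  } else {
    rowMeans(sweep(counts, 2, size_factors[colnames(counts)], "/"))
  }

  alpha_final <- shrink_dispersion(alpha_hat, base_mean, shrink, alpha_range,
                                   X = X, off = off)
  fit <- nb_wald_fit(counts, X, off, alpha_final, coef_idx)

  n_bad <- sum(!fit$converged & !is.na(fit$beta))
  if (n_bad > 0) inform(sprintf("%d feature fit(s) did not converge", n_bad))
  z <- fit$beta / fit$se
  pval <- pmax(2 * pnorm(-abs(z)), .Machine$double.xmin)
  pval[!fit$converged] <- NA_real_
  ids <- rownames(counts)
  has_ord <- grepl("^.+:[0-9]+$", ids)
  tibble(
    bin_id = ids,
    gene_id = ifelse(has_ord, sub(":[0-9]+$", "", ids), ids),
    ordinal = ifelse(has_ord, as.integer(sub("^.+:", "", ids)), NA_integer_),
    base_mean = unname(base_mean),
    log2fc = fit$beta / log(2),
    lfc_se = fit$se / log(2),
    stat = z,
    pvalue = pval,
    dispersion = as.numeric(alpha_final),
    converged = fit$converged & !is.na(fit$beta)
  )
}

# Log-scale shrinkage of per-feature dispersion MLEs toward a lowess
# mean-dispersion trend.  Only "interior" MLEs (away from the search
# bounds) inform the trend, which is rescaled by the mean MLE/trend ratio
# so it is unbiased on the natural scale (log-MLEs are left-skewed).
# With `shrink = "eb"` the trend weight is set empirically: the sampling
# variance of a log dispersion MLE under the fitted design is estimated by
# a small parametric bootstrap at the trend dispersion, the excess spread
# of observed MLEs around the trend estimates the true between-feature
# dispersion variance, and the two give the usual precision weighting.  A
# numeric `shrink` fixes the trend weight instead.  Features whose MLE hit
# a bound (or is missing) get the trend value.
shrink_dispersion <- function(alpha_hat, base_mean, shrink, alpha_range,
                              X = NULL, off = NULL) {
  interior <- is.finite(alpha_hat) & is.finite(base_mean) & base_mean > 0 &
    alpha_hat > 2 * alpha_range[1] & alpha_hat < 0.9 * alpha_range[2]
  if (sum(interior) < 5) {
    return(ifelse(is.finite(alpha_hat), alpha_hat, NA_real_))
  }
  la <- log(alpha_hat[interior])
  lo <- lowess(log(base_mean[interior]), la, f = 0.5)
  trend <- approx(lo$x, lo$y, xout = log(pmax(base_mean, 1e-8)), rule = 2,
                  ties = mean)$y
  ratio <- mean(pmin(alpha_hat[interior] / exp(trend[interior]), 20))
  trend <- trend + log(max(ratio, .Machine$double.eps))
  if (identical(shrink, "eb")) {
    var_samp <- if (!is.null(X) && sum(interior) >= 50) {
      boot_log_alpha_var(base_mean[interior], exp(trend[interior]), X, off,
                         alpha_range)
    } else {
      # chi-square approximation when the bootstrap is not worthwhile
      trigamma(max(nrow(X %||% matrix(0, 2, 1)) - ncol(X %||% matrix(0, 2, 1)), 1) / 2)
    }
    resid <- la - trend[interior]
    var_prior <- max(var(resid) - var_samp, 0.02)
    w_trend <- var_samp / (var_samp + var_prior)
  } else {
    w_trend <- shrink
  }
  out <- exp((1 - w_trend) * log(alpha_hat) + w_trend * trend)
  out[!interior] <- exp(trend[!interior])
  pmin(pmax(out, alpha_range[1]), alpha_range[2])
}

# Parametric bootstrap of the log-dispersion MLE sampling variance: NB
# counts are simulated at the trend dispersion for a spread of observed
# mean levels and re-estimated under the same design.  A fixed internal
# seed keeps the whole test path deterministic.
boot_log_alpha_var <- function(means, alphas, X, off, alpha_range,
                               n_boot = 400) {
  idx <- unique(round(seq(1, length(means), length.out = n_boot)))
  o <- order(means)
  idx <- o[idx]
  withr_seed(760L, {
    mu <- outer(means[idx], exp(off %||% rep(0, nrow(X))))
    y <- matrix(rnbinom(length(mu), size = rep(1 / alphas[idx], ncol(mu)),
                        mu = mu), nrow = nrow(mu))
    a <- nb_alpha_mle(y, X, off %||% rep(0, nrow(X)),
                      alpha_range[1], alpha_range[2])
    la <- log(a) - log(alphas[idx])
    ok <- is.finite(la) & a > 2 * alpha_range[1] & a < 0.9 * alpha_range[2]
    if (sum(ok) < 20) return(trigamma(max(nrow(X) - ncol(X), 1) / 2))
    var(la[ok])
  })
}
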