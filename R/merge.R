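#' Combine p-values with Fisher's method
#'
#' `X = -2 * sum(log p)` referred to a chi-square distribution with `2k`
#' degrees of freedom.  Zero p-values are clamped to the smallest positive
#' double with a warning.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return Single combined p-value.
#' @export
fisher_combine <- function(p) {
  if (any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warn("zero p-value clamped to smallest positive double")
    p <- pmax(p, .Machine$double.xmin)
  }
  pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (a thin wrapper over [stats::p.adjust()]);
#' input order is preserved.
#'
#' @param p numeric vector of p-values.
#' @return Vector of q-values, monotone in `p` and capped at 1.
#' @export
bh_adjust <- function(p) p.adjust(p, method = "BH")

#' Merge adjacent significant bins into candidate regions
#'
#' Maximal runs of bins that are individually significant (`p <
#' bin_p_threshold`), lie in the same gene on consecutive ordinals and
#' (optionally) share the fold-change sign become one region; the region
#' p-value is the Fisher combination of its member bins.
#'
#' @param results bin-level test tibble from [nb_wald_test()].
#' @param bin_p_threshold raw p-value cut for a "significant bin"
#'   (default 0.05).
#' @param same_sign require a common fold-change direction within a region
#'   (default TRUE, so every region has a direction).
#' @return Tibble with one row per region: `gene_id`, `bin_start`,
#'   `bin_end` (ordinals, inclusive), `n_bins`, `direction`
#'   (`hyper`/`hypo`), `mean_log2fc`, `p_combined` and the member p-values
#'   as a list column.
#' @export
merge_adjacent_significant <- function(results, bin_p_threshold = 0.05,
                                       same_sign = TRUE) {
  r <- results |>
    filter(!is.na(.data$pvalue), .data$pvalue < bin_p_threshold) |>
    arrange(.data$gene_id, .data$ordinal)
  if (nrow(r) == 0) {
    return(tibble(gene_id = character(), bin_start = integer(),
                  bin_end = integer(), n_bins = integer(),
                  direction = character(), mean_log2fc = numeric(),
                  p_combined = numeric(), p_bins = list()))
  }
  sgn <- sign(r$log2fc)
  new_run <- c(TRUE, r$gene_id[-1] != r$gene_id[-nrow(r)] |
                 r$ordinal[-1] != r$ordinal[-nrow(r)] + 1L)
  if (same_sign) new_run <- new_run | c(TRUE, sgn[-1] != sgn[-nrow(r)])
  r$run <- cumsum(new_run)
  r |>
    group_by(.data$run) |>
    summarise(
      gene_id = .data$gene_id[1],
      bin_start = min(.data$ordinal),
      bin_end = max(.data$ordinal),
      n_bins = dplyr::n(),
      mean_log2fc = mean(.data$log2fc),
      direction = ifelse(mean(.data$log2fc) >= 0, "hyper", "hypo"),
      p_combined = fisher_combine(.data$pvalue),
      p_bins = list(.data$pvalue),
      .groups = "drop"
    ) |>
    select(-"run")
}

#' Call differentially methylated regions with FDR control
#'
#' Merges significant bins ([merge_adjacent_significant()]) and applies
#' Benjamini-Hochberg adjustment to the region-level Fisher p-values.  The
#' BH family is the full set of tested sites: the merged regions together
#' with every non-significant bin (each standing as its own candidate), so
#' the multiplicity of the original bin-level scan is retained rather than
#' conditioning on the significant subset.
#'
#' @inheritParams merge_adjacent_significant
#' @param bins optional bin table; when supplied, regions gain transcript
#'   coordinates (`tx_start`, `tx_end`).
#' @return Region tibble with an added `fdr` column, sorted by `fdr`.
#' @export
call_dm_regions <- function(results, bins = NULL, bin_p_threshold = 0.05,
                            same_sign = TRUE) {
  regions <- merge_adjacent_significant(results, bin_p_threshold, same_sign)
  p_ns <- results$pvalue[!is.na(results$pvalue) &
                           results$pvalue >= bin_p_threshold]
  q_all <- bh_adjust(c(regions$p_combined, p_ns))
  regions$fdr <- utils::head(q_all, nrow(regions))
  if (!is.null(bins) && nrow(regions) > 0) {
    b0 <- bins[match(paste0(regions$gene_id, ":", regions$bin_start),
                     bins$bin_id), ]
    b1 <- bins[match(paste0(regions$gene_id, ":", regions$bin_end),
                     bins$bin_id), ]
    regions$tx_start <- b0$tx_start
    regions$tx_end <- b1$tx_end
  }
  arrange(regions, .data$fdr, .data$p_combined)
}

#' Summarize differentially methylated regions
#'
#' Counts regions ("sites") and unique genes passing an FDR cutoff, split
#' by direction.
#'
#' @param regions region tibble from [call_dm_regions()].
#' @param q_cutoff FDR threshold (default 0.05).
#' @return One-row tibble: `n_sites`, `n_genes`, `n_hyper`, `n_hypo`,
#'   `q_cutoff`.
#' @export
summarize_dm <- function(regions, q_cutoff = 0.05) {
  sig <- regions[!is.na(regions$fdr) & regions$fdr < q_cutoff, ]
  tibble(
    n_sites = nrow(sig),
    n_genes = length(unique(sig$gene_id)),
    n_hyper = sum(sig$direction == "hyper"),
    n_hypo = sum(sig$direction == "hypo"),
    q_cutoff = q_cutoff
  )
}
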