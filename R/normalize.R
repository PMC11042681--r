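#' Median-of-ratios library size factors
#'
#' For each sample, the factor is the median across features (positive in
#' every sample) of the ratio of its count to the feature's geometric mean;
#' factors are rescaled to geometric mean 1.  If no feature is positive in
#' all samples, falls back to total-count ratios with a warning.
#'
#' @param counts matrix (features x samples).
#' @return Named positive numeric vector, one factor per sample.
#' @export
estimate_size_factors <- function(counts) {
  log_gm <- rowMeans(log(counts))
  ok <- is.finite(log_gm)
  if (!any(ok)) {
    warn("no feature positive in all samples; falling back to total-count ratios")
    f <- colSums(counts)
  } else {
    f <- apply(counts[ok, , drop = FALSE], 2,
               function(x) exp(median(log(x) - log_gm[ok])))
  }
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

#' Adjust IP bin counts for expression level
#'
#' Divides each library-size-normalized IP bin count by the matched input
#' library's relative gene expression: the subject's normalized gene-level
#' input count (plus a pseudo-count) over the cross-sample mean of the same
#' quantity.  This cancels expression changes so that remaining IP signal
#' differences reflect methylation.
#'
#' @param ip_bins matrix (bins x IP samples) of raw IP bin counts.
#' @param input_genes matrix (genes x input samples) of gene-level input
#'   counts.
#' @param bins bin table mapping bin rows to genes.
#' @param design sample design tibble with `sample_id`, `subject`,
#'   `condition`, `assay` so each IP column can be matched to the input
#'   library of the same subject and condition.
#' @param ip_factors,input_factors size factors for the two library sets
#'   (estimated with [estimate_size_factors()] when `NULL`).
#' @param pseudo pseudo-count guarding zero input genes (default 1).
#' @return Fractional matrix of adjusted IP counts (bins x IP samples).
#' @export
adjust_ip_by_input <- function(ip_bins, input_genes, bins, design,
                               ip_factors = NULL, input_factors = NULL,
                               pseudo = 1) {
  ip_factors <- ip_factors %||% estimate_size_factors(ip_bins)
  input_factors <- input_factors %||% estimate_size_factors(input_genes)
  des <- as_tibble(design)
  ip_des <- des[des$assay == "IP", ]
  in_des <- des[des$assay == "INPUT", ]
  match_input <- function(sid) {
    r <- ip_des[ip_des$sample_id == sid, ]
    m <- in_des$sample_id[in_des$subject == r$subject &
                            in_des$condition == r$condition]
    if (length(m) != 1L) {
      abort(sprintf("no unique input library for subject %s (%s)",
                    r$subject, r$condition))
    }
    m
  }
  ip_samples <- colnames(ip_bins)
  input_of <- vapply(ip_samples, match_input, character(1))

  norm_input <- sweep(input_genes, 2, input_factors[colnames(input_genes)], "/") + pseudo
  rel_expr <- norm_input / rowMeans(norm_input) # genes x input samples
  gene_of_bin <- bins$gene_id[match(rownames(ip_bins), bins$bin_id)]

  adj <- sweep(ip_bins, 2, ip_factors[ip_samples], "/")
  adj / rel_expr[gene_of_bin, input_of, drop = FALSE]
}

#' Filter bins on abundance and IP enrichment
#'
#' Removes bins whose mean adjusted IP count is below `min_mean` in both
#' the CTRL and CASE groups, then bins whose per-base IP signal over
#' per-base input gene signal falls below `enrich_ratio` in both groups.
#'
#' @param adjusted_ip adjusted IP matrix (bins x IP samples).
#' @param input_genes gene-level input count matrix.
#' @param bins bin table.
#' @param design sample design tibble.
#' @param min_mean low-count threshold on group mean adjusted counts
#'   (default 10).
#' @param enrich_ratio minimum IP/input per-base signal ratio (default 1).
#' @param input_factors,ip_factors size factors used for the enrichment
#'   comparison (estimated when `NULL`).
#' @return List with `kept` (filtered matrix) and `flags`, a tibble of
#'   per-bin status in `{kept, low_count, not_enriched}`.
#' @export
filter_bins <- function(adjusted_ip, input_genes, bins, design,
                        min_mean = 10, enrich_ratio = 1,
                        ip_factors = NULL, input_factors = NULL) {
  if (min_mean < 0) abort("min_mean must be >= 0")
  des <- as_tibble(design)
  ip_des <- des[des$assay == "IP", ]
  grp <- setNames(ip_des$condition, ip_des$sample_id)[colnames(adjusted_ip)]
  if (!all(c("CTRL", "CASE") %in% grp)) abort("both CTRL and CASE IP samples required")

  mean_by_group <- function(m) {
    cbind(CTRL = rowMeans(m[, grp == "CTRL", drop = FALSE]),
          CASE = rowMeans(m[, grp == "CASE", drop = FALSE]))
  }
  gm <- mean_by_group(adjusted_ip)
  low <- gm[, "CTRL"] < min_mean & gm[, "CASE"] < min_mean

  # per-base enrichment: adjusted IP bin signal per base vs normalized
  # input gene signal per base of the same gene
  input_factors <- input_factors %||% estimate_size_factors(input_genes)
  bidx <- match(rownames(adjusted_ip), bins$bin_id)
  bw <- bins$width[bidx]
  gene_of_bin <- bins$gene_id[bidx]
  lens <- bins |>
    group_by(.data$gene_id) |>
    summarise(tx_length = max(.data$tx_end), .groups = "drop")
  glen <- setNames(lens$tx_length, lens$gene_id)[gene_of_bin]

  in_des <- des[des$assay == "INPUT", ]
  grp_in <- setNames(in_des$condition, in_des$sample_id)[colnames(input_genes)]
  norm_input <- sweep(input_genes, 2, input_factors[colnames(input_genes)], "/")
  gin <- cbind(
    CTRL = rowMeans(norm_input[, grp_in == "CTRL", drop = FALSE]),
    CASE = rowMeans(norm_input[, grp_in == "CASE", drop = FALSE])
  )[gene_of_bin, , drop = FALSE]
  ip_per_base <- gm / bw
  input_per_base <- gin / glen
  enr <- ip_per_base / pmax(input_per_base, .Machine$double.eps)
  not_enr <- !low & enr[, "CTRL"] < enrich_ratio & enr[, "CASE"] < enrich_ratio

  flag <- unname(ifelse(low, "low_count",
                        ifelse(not_enr, "not_enriched", "kept")))
  list(
    kept = adjusted_ip[flag == "kept", , drop = FALSE],
    flags = tibble(bin_id = rownames(adjusted_ip), flag = flag,
                   mean_ctrl = unname(gm[, "CTRL"]),
                   mean_case = unname(gm[, "CASE"]))
  )
}
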