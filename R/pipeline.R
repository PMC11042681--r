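#' Run the full differential-methylation pipeline on simulated data
#'
#' Wires simulation, normalization, input adjustment, filtering, the NB
#' Wald test, region merging/FDR, metagene and motif annotation, and
#' input-library differential expression into one deterministic run.  A
#' manifest records parameters, seeds, warning tallies and (when writing)
#' output file digests; re-running with the same seed reproduces
#' byte-identical tables.
#'
#' @param config simulation/analysis configuration from [sim_config()];
#'   unknown keys are rejected there.
#' @param seed root seed for every stochastic stage.
#' @param outdir optional directory for TSV/BED outputs.
#' @param bin_p,fdr bin-level significance and region FDR thresholds.
#' @param min_mean,enrich_ratio bin filter parameters.
#' @param plant_rate GGACU plant rate for sequences of genes carrying a
#'   planted DM region.
#' @return A `merip_result` list: `regions`, `bin_results`, `summary`,
#'   `de`, `metagene`, `motifs`, `truth`, `design`, `manifest`.
#' @export
run_merip_pipeline <- function(config = sim_config(), seed = 1L,
                               outdir = NULL, bin_p = 0.05, fdr = 0.05,
                               min_mean = 10, enrich_ratio = 1,
                               plant_rate = 0.8) {
  sim_genes <- simulate_gene_models(config$n_genes, seed = seed,
                                    len_range = config$gene_len_range,
                                    plant_rate = plant_rate)
  sim <- simulate_merip_counts(sim_genes$models, config, seed = seed)

  ip_sf <- estimate_size_factors(sim$ip_counts)
  in_sf <- estimate_size_factors(sim$input_counts)
  adj <- adjust_ip_by_input(sim$ip_counts, sim$input_counts, sim$bins,
                            sim$design, ip_factors = ip_sf,
                            input_factors = in_sf)
  filt <- filter_bins(adj, sim$input_counts, sim$bins, sim$design,
                      min_mean = min_mean, enrich_ratio = enrich_ratio,
                      ip_factors = ip_sf, input_factors = in_sf)
  mode <- if (config$paired) "paired" else "covariate"
  covs <- if (mode == "covariate") c("batch", "gender", "age", "bmi") else NULL
  bin_res <- nb_wald_test(filt$kept, sim$design, mode = mode,
                          covariates = covs)
  regions <- call_dm_regions(bin_res, bins = sim$bins,
                             bin_p_threshold = bin_p)
  summary <- summarize_dm(regions, q_cutoff = fdr)

  sig <- regions[!is.na(regions$fdr) & regions$fdr < fdr, ]
  metagene <- if (nrow(sig) > 0) {
    metagene_profile(sig, sim_genes$models)
  } else {
    NULL
  }
  motifs <- annotate_regions_motifs(sig, sim_genes, seed = seed)

  de <- nb_de(sim$input_counts, sim$design,
              covariates = if (mode == "covariate") c("batch", "gender", "age") else character(0))
  de$log_fc <- de$log2fc
  intersect <- intersect_deg_dmg(de, regions, de_q = fdr, dm_q = fdr)

  manifest <- list(
    seed = seed, config = config,
    parameters = list(bin_p = bin_p, fdr = fdr, min_mean = min_mean,
                      enrich_ratio = enrich_ratio, plant_rate = plant_rate),
    n_bins_tested = sum(!is.na(bin_res$pvalue)),
    n_nonconverged = sum(!bin_res$converged),
    n_filtered = sum(filt$flags$flag != "kept")
  )
  out <- list(regions = regions, bin_results = bin_res, summary = summary,
              de = de, intersect = intersect, metagene = metagene,
              motifs = motifs, truth = sim$truth, design = sim$design,
              models = sim_genes$models, manifest = manifest)
  class(out) <- "merip_result"

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    reg_out <- regions
    reg_out$p_bins <- vapply(reg_out$p_bins, function(p)
      paste(signif(p, 10), collapse = ","), character(1))
    write.table(as.data.frame(reg_out), file.path(outdir, "regions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(de), file.path(outdir, "de.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(sig) > 0 && all(c("tx_start", "tx_end") %in% names(sig))) {
      write_regions(sig, sim_genes$models,
                    bed_path = file.path(outdir, "regions.bed"))
    }
    manifest$output_md5 <- tools::md5sum(
      list.files(outdir, full.names = TRUE, pattern = "\\.(tsv|bed)$"))
    out$manifest <- manifest
  }
  out
}

# motif enrichment of significant-region sequences against windows drawn
# from genes without a planted/called region
annotate_regions_motifs <- function(sig, sim_genes, seed = 1L,
                                    window = 100) {
  if (nrow(sig) == 0) return(NULL)
  seqs <- sim_genes$seqs
  peak_seq <- character(0)
  for (i in seq_len(nrow(sig))) {
    s <- seqs[[sig$gene_id[i]]]
    mid <- floor((sig$tx_start[i] + sig$tx_end[i]) / 2)
    a <- max(1, mid - window / 2)
    b <- min(nchar(s), a + window - 1)
    peak_seq <- c(peak_seq, substr(s, a, b))
  }
  bg_genes <- setdiff(names(seqs), sig$gene_id)
  if (length(bg_genes) < 5) return(NULL)
  bg_seq <- withr_seed(split_seed(seed, "motif_bg"), {
    vapply(bg_genes, function(g) {
      s <- seqs[[g]]
      a <- sample.int(max(1, nchar(s) - window), 1)
      substr(s, a, a + window - 1)
    }, character(1))
  })
  motif_enrichment(peak_seq, bg_seq)
}

#' @export
#' @method print merip_result
print.merip_result <- function(x, ...) {
  cat("MeRIP-seq differential methylation result\n")
  cat(sprintf("  preset: %s, seed %d\n", x$manifest$config$preset,
              x$manifest$seed))
  cat(sprintf("  bins tested: %d (non-converged: %d)\n",
              x$manifest$n_bins_tested, x$manifest$n_nonconverged))
  s <- x$summary
  cat(sprintf("  DM sites at FDR < %g: %d (%d hyper / %d hypo) in %d genes\n",
              s$q_cutoff, s$n_sites, s$n_hyper, s$n_hypo, s$n_genes))
  invisible(x)
}

#' @export
tidy.merip_result <- function(x, ...) {
  r <- x$regions
  r$p_bins <- NULL
  r
}

#' @export
glance.merip_result <- function(x, ...) {
  dplyr::bind_cols(
    x$summary,
    tibble(n_bins_tested = x$manifest$n_bins_tested,
           n_nonconverged = x$manifest$n_nonconverged,
           n_de_genes = sum(!is.na(x$de$qvalue) & x$de$qvalue < 0.05))
  )
}

#' Score called regions against planted truth
#'
#' A truth region is detected if any called region passing the FDR cutoff
#' overlaps its bin span in the same gene; a called region is false if it
#' overlaps no truth region.
#'
#' @param regions called region tibble with `fdr`.
#' @param truth planted `dm_regions` tibble.
#' @param fdr FDR cutoff for calling (default 0.05).
#' @return One-row tibble: `n_called`, `n_true`, `sensitivity`,
#'   `false_discovery_rate`, `sign_accuracy` (direction agreement among
#'   detected truth regions).
#' @export
score_dm_calls <- function(regions, truth, fdr = 0.05) {
  called <- regions[!is.na(regions$fdr) & regions$fdr < fdr, ]
  overlaps <- function(a1, a2, b1, b2) a1 <= b2 & b1 <= a2
  detected <- logical(nrow(truth))
  sign_ok <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    hit <- called$gene_id == truth$gene_id[i] &
      overlaps(called$bin_start, called$bin_end,
               truth$bin_start[i], truth$bin_end[i])
    detected[i] <- any(hit)
    sign_ok[i] <- any(hit & called$direction == truth$direction[i])
  }
  false_call <- vapply(seq_len(nrow(called)), function(j) {
    !any(truth$gene_id == called$gene_id[j] &
           overlaps(truth$bin_start, truth$bin_end,
                    called$bin_start[j], called$bin_end[j]))
  }, logical(1))
  tibble(
    n_called = nrow(called),
    n_true = nrow(truth),
    sensitivity = if (nrow(truth) > 0) mean(detected) else NA_real_,
    false_discovery_rate = if (nrow(called) > 0) mean(false_call) else 0,
    sign_accuracy = if (any(detected)) mean(sign_ok[detected]) else NA_real_
  )
}
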