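test_that("Fisher combination matches its closed forms", {
  expect_equal(fisher_combine(0.05), 0.05)
  expect_equal(fisher_combine(c(1, 1, 1)), 1)
  # df = 4 closed form: p = exp(-x/2) (1 + x/2)
  x <- -2 * sum(log(c(0.01, 0.04)))
  expect_equal(x, 15.64806, tolerance = 1e-5)
  expect_equal(fisher_combine(c(0.01, 0.04)), exp(-x / 2) * (1 + x / 2),
               tolerance = 1e-12)
  expect_equal(fisher_combine(c(0.01, 0.04)), 3.53e-3, tolerance = 1e-3)
  expect_warning(fisher_combine(c(0, 0.5)), "clamped")
  expect_error(fisher_combine(c(-0.1, 0.5)), "p-values")
})

test_that("BH adjustment equals the definition-based oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  set.seed(77)
  for (i in 1:20) {
    p <- runif(sample(1:200, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("adjacent significant bins merge by gene, ordinal and sign", {
  res <- tibble::tibble(
    bin_id = paste0("g:", 0:3), gene_id = "g", ordinal = 0:3,
    pvalue = c(0.01, 0.02, 0.8, 0.03), log2fc = c(1, 1, 1, 1)
  )
  r <- merge_adjacent_significant(res)
  expect_equal(nrow(r), 2)
  expect_equal(r$bin_start, c(0, 3))
  expect_equal(r$bin_end, c(1, 3))
  # opposite signs split a run
  res$pvalue <- c(0.01, 0.02, 0.03, 0.8)
  res$log2fc <- c(1, -1, -1, 1)
  r2 <- merge_adjacent_significant(res)
  expect_equal(nrow(r2), 2)
  expect_equal(r2$direction, c("hyper", "hypo"))
  # ignoring sign keeps one run
  expect_equal(nrow(merge_adjacent_significant(res, same_sign = FALSE)), 1)
})

test_that("merging matches the run-length oracle on random inputs", {
  set.seed(99)
  for (rep in 1:30) {
    n <- 100
    res <- tibble::tibble(
      gene_id = sort(sample(paste0("g", 1:8), n, replace = TRUE)),
      pvalue = runif(n)^2,
      log2fc = rnorm(n)
    )
    res <- dplyr::mutate(dplyr::group_by(res, gene_id),
                         ordinal = dplyr::row_number() - 1L)
    res <- dplyr::ungroup(res)
    res$bin_id <- paste0(res$gene_id, ":", res$ordinal)
    got <- merge_adjacent_significant(res)
    want <- oracle_merge(res$gene_id, res$ordinal, res$pvalue,
                         sign(res$log2fc))
    expect_equal(nrow(got), length(want))
    if (length(want) > 0) {
      want_df <- dplyr::arrange(
        tibble::tibble(gene_id = vapply(want, `[[`, "", "gene"),
                       bin_start = vapply(want, function(w) as.integer(w$start), 1L),
                       bin_end = vapply(want, function(w) as.integer(w$end), 1L)),
        gene_id, bin_start)
      got_df <- dplyr::arrange(got[, c("gene_id", "bin_start", "bin_end")],
                               gene_id, bin_start)
      expect_equal(as.data.frame(got_df), as.data.frame(want_df))
      # combined p invariant to bin order within a region
      for (w in want[lengths(lapply(want, `[[`, "p")) > 1]) {
        expect_equal(fisher_combine(w$p), fisher_combine(rev(w$p)))
      }
    }
  }
})

test_that("region FDR keeps the full bin-level multiplicity", {
  set.seed(13)
  res <- tibble::tibble(
    gene_id = rep("g", 100), ordinal = 0:99,
    bin_id = paste0("g:", 0:99),
    pvalue = runif(100), log2fc = rnorm(100)
  )
  reg <- call_dm_regions(res)
  # oracle: BH over the family of region p-values plus every
  # non-significant bin standing as its own candidate site
  raw <- merge_adjacent_significant(res)
  p_ns <- res$pvalue[res$pvalue >= 0.05]
  q_oracle <- oracle_bh(c(raw$p_combined, p_ns))[seq_len(nrow(raw))]
  want <- q_oracle[order(raw$p_combined)]
  expect_equal(reg$fdr[order(reg$p_combined)], want, tolerance = 1e-12)
  expect_true(all(diff(reg$fdr[order(reg$p_combined)]) >= -1e-12))
})

test_that("summaries count sites, genes and directions", {
  reg <- tibble::tibble(
    gene_id = c("a", "a", "b"), direction = c("hyper", "hypo", "hyper"),
    fdr = c(0.01, 0.2, 0.001)
  )
  s <- summarize_dm(reg)
  expect_equal(s$n_sites, 2)
  expect_equal(s$n_genes, 2)
  expect_equal(s$n_hyper, 2)
  expect_equal(s$n_hypo, 0)
  empty <- summarize_dm(reg[0, ])
  expect_equal(empty$n_sites, 0)
  expect_equal(empty$n_genes, 0)
})
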