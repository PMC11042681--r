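test_that("all generators are deterministic in the seed", {
  a <- simulate_gene_models(10, seed = 3, plant_rate = 0.5)
  b <- simulate_gene_models(10, seed = 3, plant_rate = 0.5)
  expect_identical(a, b)
  cfg <- sim_config(n_genes = 10, n_subjects = 3)
  s1 <- simulate_merip_counts(a$models, cfg, seed = 4)
  s2 <- simulate_merip_counts(a$models, cfg, seed = 4)
  expect_identical(s1$ip_counts, s2$ip_counts)
  expect_identical(s1$input_counts, s2$input_counts)
  c1 <- simulate_scrna(n_cells = 50, n_genes = 200, seed = 5)
  c2 <- simulate_scrna(n_cells = 50, n_genes = 200, seed = 5)
  expect_identical(c1$counts, c2$counts)
  t1 <- simulate_assay_tables(seed = 6)
  t2 <- simulate_assay_tables(seed = 6)
  expect_identical(t1, t2)
  # different seeds give different draws
  expect_false(identical(s1$ip_counts,
                         simulate_merip_counts(a$models, cfg, seed = 5)$ip_counts))
})

test_that("peak planting guarantees GGACU and background stays uniform", {
  sim <- simulate_gene_models(50, seed = 8, plant_rate = 1)
  expect_true(all(sim$peaks$planted))
  for (i in seq_len(10)) {
    pk <- sim$peaks[i, ]
    s <- substr(sim$seqs[[pk$gene_id]], pk$tx_start + 1, pk$tx_end)
    expect_true(grepl("GGACT", s))
  }
  # background GGACU frequency ~ 4^-5 within 3 binomial SD over >= 1e5 bases
  bg <- simulate_gene_models(100, seed = 9, plant_rate = 0)
  all_seq <- paste(bg$seqs, collapse = "")
  n <- nchar(all_seq) - 4
  expect_gt(n, 1e5)
  n_ggact <- length(gregexpr("GGACT", all_seq, fixed = TRUE)[[1]])
  p0 <- 4^-5
  expect_lt(abs(n_ggact - n * p0), 3 * sqrt(n * p0 * (1 - p0)))
})

test_that("planted methylation shifts the adjusted IP ratio by the stated effect", {
  # Monte-Carlo over replicates: CASE/CTRL mean adjusted-IP ratio on truth
  # bins approaches 2^dm_lfc
  ratios <- c()
  for (r in 1:20) {
    gm <- simulate_gene_models(40, seed = 100 + r, len_range = c(300, 500))
    cfg <- sim_config(n_genes = 40, n_subjects = 6, fraction_dm = 0.5,
                      dm_lfc = 1, prop_hyper = 1, fraction_de = 0)
    sim <- simulate_merip_counts(gm$models, cfg, seed = 100 + r)
    adj <- adjust_ip_by_input(sim$ip_counts, sim$input_counts, sim$bins,
                              sim$design)
    tr <- sim$truth$dm_regions
    tb <- unlist(mapply(function(g, a, b) paste0(g, ":", a:b),
                        tr$gene_id, tr$bin_start, tr$bin_end))
    des <- sim$design[sim$design$assay == "IP", ]
    case <- des$sample_id[des$condition == "CASE"]
    ctrl <- des$sample_id[des$condition == "CTRL"]
    ratios <- c(ratios, rowMeans(adj[tb, case]) / rowMeans(adj[tb, ctrl]))
  }
  expect_equal(median(ratios), 2, tolerance = 0.1)
})

test_that("simulated NB counts have the stated mean-variance relation", {
  cfg <- sim_config(n_genes = 60, n_subjects = 8, fraction_dm = 0,
                    fraction_de = 0, subject_sd = 0, dispersion = 0.15,
                    lib_range_input = c(1, 1), gene_mean_sd = 0)
  gm <- simulate_gene_models(60, seed = 11, len_range = c(600, 600))
  sim <- simulate_merip_counts(gm$models, cfg, seed = 11)
  x <- as.vector(sim$input_counts) # all genes share mu = 1000, alpha = 0.15
  n <- length(x)
  expect_gt(n, 500)
  mu <- mean(x)
  v <- var(x)
  v_expect <- mu + 0.15 * mu^2
  # variance of the sample variance for NB, rough 3-SE band via moments
  se <- v_expect * sqrt(2 / n) * 2
  expect_lt(abs(v - v_expect), 3 * se + abs(mu - 1000) * 0.3 * mu)
})

test_that("truth tables line up with emitted features and honour fractions", {
  gm <- simulate_gene_models(30, seed = 12)
  cfg0 <- sim_config(n_genes = 30, n_subjects = 3, fraction_dm = 0)
  s0 <- simulate_merip_counts(gm$models, cfg0, seed = 12)
  expect_equal(nrow(s0$truth$dm_regions), 0)
  cfg1 <- sim_config(n_genes = 30, n_subjects = 3, fraction_dm = 0.3,
                     fraction_de = 0.2)
  s1 <- simulate_merip_counts(gm$models, cfg1, seed = 12)
  expect_equal(nrow(s1$truth$dm_regions), 9)
  expect_equal(nrow(s1$truth$de_genes), 6)
  expect_true(all(s1$truth$dm_regions$gene_id %in% rownames(s1$input_counts)))
  expect_true(all(s1$truth$de_genes$gene_id %in% rownames(s1$input_counts)))
  # planted regions are runs of 1-3 bins inside their gene
  len <- s1$truth$dm_regions$bin_end - s1$truth$dm_regions$bin_start + 1
  expect_true(all(len >= 1 & len <= 3))
})

test_that("scRNA simulation plants QC failures and insulin modes as configured", {
  sim <- simulate_scrna(n_cells = 1000, n_genes = 1500, seed = 13,
                        mito_high = 0.1, low_depth = 0.05)
  mito_frac <- colSums(sim$counts[sim$mito_genes, ]) / colSums(sim$counts)
  # ~10% of cells planted high-mito; binomial 3-SD band
  p <- mean(sim$truth$mito_high)
  expect_lt(abs(p - 0.1), 3 * sqrt(0.1 * 0.9 / 1000))
  expect_true(all(mito_frac[sim$truth$mito_high] > 0.10))
  expect_equal(mean(sim$truth$is_beta), 0.5, tolerance = 0.06)
  expect_error(simulate_scrna(mode_means = c(0, 2, 2, 6)), "increasing")
})

test_that("assay simulators honour their noiseless limits", {
  sim <- simulate_assay_tables(seed = 14, ct_noise_sd = 0, fold_truth = 2,
                               decay_noise_cv = 0, decay_half_life = 4)
  out <- delta_delta_ct(sim$ct, "GAPDH", "CTRL")
  expect_equal(out$fold_changes$fold[out$fold_changes$group == "CASE"], 2)
  # noiseless decay with half-life 4 h at t = 0, 4, 8
  expect_equal(sim$decay$abundance, c(1, 0.5, 0.25))
  expect_error(simulate_assay_tables(decay_half_life = -1), "positive")
})
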