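test_that("CPM filter applies its threshold rule exactly", {
  m <- rbind(g1 = c(2000, 0, 0), g2 = c(12, 12, 8), g3 = c(50, 50, 50))
  colnames(m) <- paste0("s", 1:3)
  m <- rbind(m, filler = 1e7 - colSums(m)) # library sizes 1e7
  # a 2000-read gene in a 1e7 library has CPM 200
  expect_equal(unname(m["g1", 1] / colSums(m)[1] * 1e6), 200)
  # g2 has CPM (1.2, 1.2, 0.8): fails CPM > 1 in >= 3 samples
  kept <- cpm_filter(m, min_cpm = 1, min_samples = 3)
  expect_false("g2" %in% kept)
  expect_true("g3" %in% kept)
  expect_error(cpm_filter(m, min_samples = 10), "min_samples")
  # definition-based oracle on random matrices
  set.seed(1)
  r <- matrix(rpois(200, 3), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  for (preset in cpm_presets) {
    cpm <- sweep(r, 2, colSums(r), "/") * 1e6
    want <- rownames(r)[rowSums(cpm > preset$min_cpm) >= preset$min_samples]
    expect_equal(cpm_filter(r, preset$min_cpm, preset$min_samples), want)
  }
})

test_that("TMM factors have the expected identities and robustness", {
  set.seed(2)
  base <- rnbinom(2000, size = 3, mu = 100) + 1
  same <- cbind(s1 = base, s2 = base, s3 = base)
  rownames(same) <- paste0("g", seq_along(base))
  expect_equal(unname(tmm_factors(same)), rep(1, 3), tolerance = 1e-12)
  # pure scaling is absorbed by library size: factor stays 1
  scaled <- cbind(s1 = base, s2 = base * 2L)
  rownames(scaled) <- paste0("g", seq_along(base))
  expect_equal(unname(tmm_factors(scaled)), c(1, 1), tolerance = 1e-9)
  # a 5% contamination of hugely-up genes is trimmed away
  contam <- cbind(s1 = base, s2 = base)
  contam[1:100, 2] <- contam[1:100, 2] * 50L
  rownames(contam) <- paste0("g", seq_along(base))
  f <- tmm_factors(contam)
  expect_lt(abs(f[["s2"]] / f[["s1"]] - 1), 0.1)
})

test_that("TMM agrees with edgeR on random count matrices", {
  skip_if_not_installed("edgeR")
  set.seed(3)
  m <- matrix(rnbinom(4000, size = 2, mu = 60), 500, 8,
              dimnames = list(paste0("g", 1:500), paste0("s", 1:8)))
  ours <- tmm_factors(m)
  theirs <- edgeR::calcNormFactors(m, method = "TMM")
  theirs <- theirs / exp(mean(log(theirs)))
  expect_equal(unname(ours), unname(theirs), tolerance = 0.02)
})

test_that("logCPM matches its defining formula", {
  m <- matrix(c(0, 10, 100, 1e6 - 110), 4, 1,
              dimnames = list(paste0("g", 1:4), "s1"))
  lc <- log_cpm(m)
  expect_equal(lc["g1", 1], log2(0.5 / (1e6 + 1) * 1e6), tolerance = 1e-10)
  expect_equal(lc["g1", 1], -1, tolerance = 1e-5)
  # monotone in count, ~ +1 per doubling at large counts
  expect_true(all(diff(lc[1:3, 1]) > 0))
  big <- matrix(c(4e5, 8e5), 2, 1, dimnames = list(c("a", "b"), "s"))
  lcb <- log_cpm(big)
  expect_equal(lcb["b", 1] - lcb["a", 1], 1, tolerance = 1e-3)
})

test_that("moderated t reduces to the ordinary t at d0 = 0 and pools at d0 = Inf", {
  set.seed(4)
  x <- matrix(rnorm(20 * 8), 20, 8,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:8)))
  design <- tibble::tibble(sample_id = colnames(x),
                           condition = rep(c("CTRL", "CASE"), each = 4))
  plain <- moderated_t(x, design, d0 = 0)
  ref_t <- apply(x, 1, function(r)
    stats::t.test(r[5:8], r[1:4], var.equal = TRUE)$statistic)
  expect_equal(plain$t, unname(ref_t), tolerance = 1e-10)
  pooled <- moderated_t(x, design, d0 = Inf)
  expect_equal(length(unique(round(pooled$s2_post, 12))), 1)
})

test_that("moderated t agrees with limma on a fixture", {
  skip_if_not_installed("limma")
  set.seed(5)
  x <- matrix(rnorm(200 * 6), 200, 6,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:6)))
  design <- tibble::tibble(sample_id = colnames(x),
                           condition = rep(c("CTRL", "CASE"), each = 3))
  ours <- moderated_t(x, design)
  X <- stats::model.matrix(~ rep(c(0, 1), each = 3))
  fit <- limma::eBayes(limma::lmFit(x, X))
  expect_equal(ours$t, unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(ours$pvalue, unname(fit$p.value[, 2]), tolerance = 1e-6)
})

test_that("moderated t is calibrated under the global null", {
  set.seed(6)
  x <- matrix(rnorm(2000 * 10), 2000, 10,
              dimnames = list(paste0("g", 1:2000), paste0("s", 1:10)))
  design <- tibble::tibble(sample_id = colnames(x),
                           condition = rep(c("CTRL", "CASE"), each = 5))
  res <- moderated_t(x, design)
  expect_gt(mean(res$pvalue < 0.05), 0.035)
  expect_lt(mean(res$pvalue < 0.05), 0.065)
})

test_that("DEG x DMG intersection matches set algebra", {
  de <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                       log_fc = c(1, -2, 0.5, 1),
                       qvalue = c(0.01, 0.01, 0.2, 0.04))
  dm <- tibble::tibble(gene_id = c("a", "b", "b", "e"),
                       direction = c("hyper", "hypo", "hyper", "hyper"),
                       fdr = c(0.001, 0.01, 0.01, 0.001))
  out <- intersect_deg_dmg(de, dm)
  tab <- out$table
  get <- function(d1, d2) tab$n[tab$direction == d1 & tab$de_dir == d2]
  expect_equal(get("hyper", "up"), 1)    # a
  expect_equal(get("hypo", "down"), 1)   # b
  expect_equal(get("hyper", "down"), 1)  # b both-direction flag
  expect_equal(get("hypo", "up"), 0)
  expect_equal(out$both_directions, "b")
  # disjoint sets give all-zero cells
  none <- intersect_deg_dmg(de[de$gene_id == "c", ], dm)
  expect_true(all(none$table$n == 0))
})
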