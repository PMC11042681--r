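test_that("median-of-ratios factors match the hand-computed toy example", {
  m <- matrix(c(100, 50, 200, 100), 2, dimnames = list(c("f1", "f2"),
                                                       c("s1", "s2")))
  f <- estimate_size_factors(m)
  expect_equal(unname(f), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-10)
  # identical columns -> unit factors
  same <- cbind(s1 = c(5, 9, 2), s2 = c(5, 9, 2))
  rownames(same) <- letters[1:3]
  expect_equal(unname(estimate_size_factors(same)), c(1, 1))
})

test_that("size factors recover simulated library scalings", {
  set.seed(21)
  truth <- c(0.6, 1, 1.4, 2)
  base <- rnbinom(500, size = 5, mu = 200)
  m <- sapply(truth, function(f) rpois(500, base * f))
  rownames(m) <- paste0("g", 1:500); colnames(m) <- paste0("s", 1:4)
  f <- estimate_size_factors(m)
  rel <- f / f[2]
  expect_true(all(abs(rel - truth / truth[2]) / (truth / truth[2]) < 0.05))
  # scale equivariance: multiplying one library rescales its factor
  m2 <- m; m2[, 1] <- m2[, 1] * 3
  f2 <- estimate_size_factors(m2)
  expect_equal(unname(f2[1] / f2[2]), unname(3 * f[1] / f[2]),
               tolerance = 1e-6)
})

test_that("input adjustment is the identity when gene expression is balanced", {
  sim <- simulate_gene_models(4, seed = 2, len_range = c(150, 250))
  bins <- partition_bins(sim$models)
  design <- tibble::tibble(
    sample_id = c("a_CTRL_IP", "a_CTRL_INPUT", "b_CASE_IP", "b_CASE_INPUT"),
    subject = c("a", "a", "b", "b"),
    condition = c("CTRL", "CTRL", "CASE", "CASE"),
    assay = c("IP", "INPUT", "IP", "INPUT")
  )
  ip <- matrix(50, nrow(bins), 2,
               dimnames = list(bins$bin_id, c("a_CTRL_IP", "b_CASE_IP")))
  input <- matrix(400, 4, 2, dimnames = list(unique(bins$gene_id),
                                             c("a_CTRL_INPUT", "b_CASE_INPUT")))
  adj <- adjust_ip_by_input(ip, input, bins, design)
  expect_equal(unname(adj), unname(ip), tolerance = 1e-12)
})

test_that("a subject with doubled input expression has its IP signal halved", {
  sim <- simulate_gene_models(1, seed = 2, len_range = c(150, 150))
  bins <- partition_bins(sim$models)
  design <- tibble::tibble(
    sample_id = c("a_CTRL_IP", "a_CTRL_INPUT", "b_CASE_IP", "b_CASE_INPUT"),
    subject = c("a", "a", "b", "b"),
    condition = c("CTRL", "CTRL", "CASE", "CASE"),
    assay = c("IP", "INPUT", "IP", "INPUT")
  )
  ip <- matrix(60, nrow(bins), 2,
               dimnames = list(bins$bin_id, c("a_CTRL_IP", "b_CASE_IP")))
  input <- matrix(c(1000, 2000), 1,
                  dimnames = list(unique(bins$gene_id),
                                  c("a_CTRL_INPUT", "b_CASE_INPUT")))
  # supply unit factors so only the relative-expression divisor acts
  f_ip <- c(a_CTRL_IP = 1, b_CASE_IP = 1)
  f_in <- c(a_CTRL_INPUT = 1, b_CASE_INPUT = 1)
  adj <- adjust_ip_by_input(ip, input, bins, design, f_ip, f_in, pseudo = 0)
  # subject b expression is 2000 vs mean 1500 -> divisor 4/3; a -> 2/3
  expect_equal(unname(adj[1, ]), c(60 / (1000 / 1500), 60 / (2000 / 1500)))
  expect_equal(unname(adj[1, "b_CASE_IP"] / adj[1, "a_CTRL_IP"]), 0.5)
})

test_that("bin filters apply the low-count and enrichment rules exactly", {
  # toy: one gene of 6 bins, 2 CTRL + 2 CASE IP samples
  g <- gene_model("g", "chr1", "+", cbind(0, 300))
  bins <- partition_bins(g)
  design <- tibble::tibble(
    sample_id = c("c1_IP", "c2_IP", "t1_IP", "t2_IP",
                  "c1_IN", "c2_IN", "t1_IN", "t2_IN"),
    subject = rep(c("c1", "c2", "t1", "t2"), 2),
    condition = rep(c("CTRL", "CTRL", "CASE", "CASE"), 2),
    assay = rep(c("IP", "INPUT"), each = 4)
  )
  # group means per bin: (9,9) low in both; (9,11) kept; rest large
  adj <- rbind(
    c(9, 9, 9, 9), c(9, 9, 11, 11), c(50, 50, 50, 50),
    c(100, 100, 100, 100), c(2, 2, 2, 2), c(40, 40, 40, 40)
  )
  dimnames(adj) <- list(bins$bin_id, c("c1_IP", "c2_IP", "t1_IP", "t2_IP"))
  input <- matrix(600, 1, 4, dimnames = list("g", c("c1_IN", "c2_IN",
                                                    "t1_IN", "t2_IN")))
  f1 <- setNames(rep(1, 4), colnames(adj))
  f2 <- setNames(rep(1, 4), colnames(input))
  res <- filter_bins(adj, input, bins, design, ip_factors = f1,
                     input_factors = f2)
  # per-base input = 600/300 = 2/base; bin per-base = mean/50
  # enrichment >= 1 requires bin mean >= 100 here
  oracle <- function(ctrl, case) {
    if (ctrl < 10 && case < 10) return("low_count")
    if (ctrl / 50 / 2 < 1 && case / 50 / 2 < 1) return("not_enriched")
    "kept"
  }
  means <- cbind(rowMeans(adj[, 1:2]), rowMeans(adj[, 3:4]))
  expect_equal(res$flags$flag, mapply(oracle, means[, 1], means[, 2],
                                      USE.NAMES = FALSE))
  expect_equal(rownames(res$kept),
               bins$bin_id[res$flags$flag == "kept"])
  expect_error(filter_bins(adj, input, bins, design, min_mean = -1), "min_mean")
})
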