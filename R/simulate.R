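#' Deterministic child seeds
#'
#' Splits a root seed into independent per-generator seeds by hashing the
#' generator label into the root (polynomial string hash modulo a prime
#' below 2^31), so each simulator can be re-run independently of the
#' others.
#'
#' @param seed root integer seed.
#' @param label generator name.
#' @return Integer seed in `[1, 2^31)`.
#' @export
split_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483629
  as.integer((as.numeric(seed) * 1000003 + h) %% 2147483629 + 1)
}

#' Simulation configuration
#'
#' Bundles the knobs of the MeRIP-seq simulator with defaults emulating
#' the study designs: a paired cytokine-treatment design with 15 subjects
#' per group, or a covariate-adjusted case/control design with 20 controls
#' and 7 cases (batch, gender, age, BMI).  Counts are negative binomial
#' with dispersion `dispersion`; gene-specific subject effects are
#' Normal(0, 0.2^2) on the log scale so that pairing is informative.
#'
#' @param preset `"cytokine-paired"` or `"t1d-covariate"`.
#' @param ... overrides for any config entry.
#' @return Named list of simulation parameters.
#' @export
sim_config <- function(preset = c("cytokine-paired", "t1d-covariate"), ...) {
  preset <- match.arg(preset)
  base <- list(
    preset = preset,
    n_genes = 200,
    gene_len_range = c(600, 3000),
    paired = TRUE,
    n_subjects = 15,       # per group when unpaired; total pairs when paired
    n_ctrl = 15, n_case = 15,
    dispersion = 0.1,
    lib_range_input = c(0.7, 1.3),
    lib_range_ip = c(0.7, 1.3),
    gene_mean = 1000, gene_mean_sd = 0.7,
    subject_sd = 0.2,
    enrich_mean = 2, enrich_shape = 5,
    fraction_dm = 0.1, dm_lfc = 1.0, dm_len_range = c(1L, 3L),
    prop_hyper = 0.5,
    fraction_de = 0.1, de_lfc = 1.0,
    covariates = NULL
  )
  if (preset == "t1d-covariate") {
    base$paired <- FALSE
    base$n_ctrl <- 20
    base$n_case <- 7
    base$covariates <- list(batch_levels = 2, batch_sd = 0.3,
                            gender_sd = 0.1, age_slope_sd = 0.005,
                            bmi_slope_sd = 0.005)
  }
  over <- list(...)
  stopifnot(all(names(over) %in% names(base)))
  base[names(over)] <- over
  stopifnot(base$fraction_dm >= 0, base$fraction_dm <= 1,
            base$fraction_de >= 0, base$fraction_de <= 1,
            base$dispersion > 0)
  base
}

#' Simulate gene models and transcript sequences
#'
#' Random single-exon genes (lengths 600-3000 nt by default) partitioned
#' into 5'UTR/CDS/3'UTR, with uniform-random transcript sequences.  One
#' peak window per gene is designated; with probability `plant_rate` a
#' GGACU occurrence is written into it, so planted peaks carry the
#' canonical motif while the background occurrence rate stays at the
#' uniform expectation 4^-5.
#'
#' @param n_genes number of genes.
#' @param seed RNG seed.
#' @param len_range transcript length range.
#' @param plant_rate probability a peak window receives a planted GGACU.
#' @param peak_width width of the designated peak window (default 100).
#' @return List: `models` (gene_models), `seqs` (named character vector of
#'   transcript sequences, DNA alphabet), `peaks` tibble (`gene_id`,
#'   `tx_start`, `tx_end`, `planted`).
#' @export
simulate_gene_models <- function(n_genes, seed = 1L,
                                 len_range = c(600, 3000),
                                 plant_rate = 0, peak_width = 100) {
  stopifnot(n_genes >= 1)
  withr_seed(split_seed(seed, "gene_models"), {
    lens <- len_range[1] +
      sample.int(len_range[2] - len_range[1] + 1, n_genes, replace = TRUE) - 1L
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)
    gap <- 1000
    models <- vector("list", n_genes)
    seqs <- character(n_genes)
    peaks <- vector("list", n_genes)
    pos <- 0
    for (i in seq_len(n_genes)) {
      g <- sprintf("g%04d", i)
      L <- lens[i]
      u5 <- round(L * runif(1, 0.05, 0.15))
      u3 <- round(L * runif(1, 0.2, 0.4))
      start <- pos
      models[[i]] <- gene_model(g, "chr1", strands[i],
                                cbind(start, start + L),
                                cds = if (strands[i] == "+") {
                                  c(start + u5, start + L - u3)
                                } else {
                                  c(start + u3, start + L - u5)
                                })
      s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      pk_width <- min(peak_width, L - 10)
      pk_start <- sample.int(L - pk_width, 1)
      planted <- runif(1) < plant_rate
      if (planted) {
        off <- sample.int(pk_width - 5, 1)
        s[(pk_start + off):(pk_start + off + 4)] <- c("G", "G", "A", "C", "T")
      }
      seqs[i] <- paste(s, collapse = "")
      names(seqs)[i] <- g
      peaks[[i]] <- tibble(gene_id = g, tx_start = pk_start,
                           tx_end = pk_start + pk_width, planted = planted)
      pos <- start + L + gap
    }
    list(models = new_gene_models(bind_rows(models)), seqs = seqs,
         peaks = bind_rows(peaks))
  })
}

#' Write transcript sequences as FASTA
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Simulate a paired MeRIP-seq experiment with planted truth
#'
#' Input gene counts are NB with gene-specific subject effects and
#' optional planted expression changes; IP bin counts are NB with mean
#' `pi_b * (input gene mean) * f_ip * exp(beta_b I[CASE])`, where the
#' per-bin IP rate `pi_b` scales the gene's expression into the bin and
#' `beta_b = dm_lfc * ln 2` on planted hypermethylated bins (negated for
#' hypomethylated).  Differentially methylated regions are planted as runs
#' of 1-3 adjacent bins.
#'
#' @param models a `gene_models` tibble (e.g. from
#'   [simulate_gene_models()]).
#' @param config list from [sim_config()].
#' @param seed RNG seed.
#' @return List: `ip_counts` (bins x IP samples), `input_counts` (genes x
#'   input samples), `bins`, `design`, and `truth` (list with
#'   `dm_regions`, `de_genes`).
#' @export
simulate_merip_counts <- function(models, config, seed = 1L) {
  cfg <- config
  bins <- partition_bins(models)
  lens <- gene_lengths(models)
  genes <- lens$gene_id
  ng <- length(genes)
  if (cfg$paired) {
    n_sub <- cfg$n_subjects
    subjects <- sprintf("sub%02d", seq_len(n_sub))
    des <- tidyr::expand_grid(subject = subjects,
                              condition = c("CTRL", "CASE"),
                              assay = c("INPUT", "IP"))
  } else {
    subjects <- sprintf("sub%02d", seq_len(cfg$n_ctrl + cfg$n_case))
    des <- tibble(subject = rep(subjects, each = 2),
                  condition = rep(c(rep("CTRL", cfg$n_ctrl),
                                    rep("CASE", cfg$n_case)), each = 2),
                  assay = rep(c("INPUT", "IP"), times = length(subjects)))
  }
  des$sample_id <- paste(des$subject, des$condition, des$assay, sep = "_")
  if (length(unique(des$sample_id)) != nrow(des)) abort("degenerate design")
  if (nrow(des) == 0) abort("config yields zero subjects")

  withr_seed(split_seed(seed, "merip_counts"), {
    q_g <- cfg$gene_mean * exp(rnorm(ng, 0, cfg$gene_mean_sd))
    n_bins_g <- table(factor(bins$gene_id, levels = genes))
    # per-bin IP rate: per-base share times a gamma-distributed enrichment
    e_b <- rgamma(nrow(bins), shape = cfg$enrich_shape,
                  rate = cfg$enrich_shape) * cfg$enrich_mean
    pi_b <- (bins$width / lens$tx_length[match(bins$gene_id, lens$gene_id)]) * e_b

    # gene x subject effects, shared by both conditions of a subject
    u <- matrix(rnorm(ng * length(subjects), 0, cfg$subject_sd),
                nrow = ng, dimnames = list(genes, subjects))

    # planted DE genes
    n_de <- round(cfg$fraction_de * ng)
    de_idx <- if (n_de > 0) sample.int(ng, n_de) else integer(0)
    de_sign <- sample(c(1, -1), n_de, replace = TRUE)
    de_genes <- tibble(gene_id = genes[de_idx],
                       lfc = de_sign * cfg$de_lfc)
    de_beta <- setNames(rep(0, ng), genes)
    de_beta[de_idx] <- de_sign * cfg$de_lfc * log(2)

    # planted DM regions (never on DE genes, to keep truths separable)
    n_dm <- round(cfg$fraction_dm * ng)
    dm_pool <- setdiff(seq_len(ng), de_idx)
    dm_idx <- if (n_dm > 0) sample(dm_pool, min(n_dm, length(dm_pool))) else integer(0)
    beta_b <- setNames(rep(0, nrow(bins)), bins$bin_id)
    dm_regions <- list()
    for (gi in dm_idx) {
      g <- genes[gi]
      nb <- as.integer(n_bins_g[[g]])
      len <- sample(seq(cfg$dm_len_range[1], cfg$dm_len_range[2]), 1)
      len <- min(len, nb)
      start <- sample.int(nb - len + 1L, 1) - 1L
      dir <- if (runif(1) < cfg$prop_hyper) 1 else -1
      ords <- start:(start + len - 1L)
      beta_b[paste0(g, ":", ords)] <- dir * cfg$dm_lfc * log(2)
      dm_regions[[g]] <- tibble(gene_id = g, bin_start = start,
                                bin_end = start + len - 1L,
                                direction = if (dir > 0) "hyper" else "hypo",
                                lfc = dir * cfg$dm_lfc)
    }
    dm_regions <- if (length(dm_regions)) bind_rows(dm_regions) else
      tibble(gene_id = character(), bin_start = integer(),
             bin_end = integer(), direction = character(), lfc = numeric())

    f <- runif(nrow(des), 0, 1)
    f[des$assay == "INPUT"] <- runif(sum(des$assay == "INPUT"),
                                     cfg$lib_range_input[1], cfg$lib_range_input[2])
    f[des$assay == "IP"] <- runif(sum(des$assay == "IP"),
                                  cfg$lib_range_ip[1], cfg$lib_range_ip[2])
    names(f) <- des$sample_id

    # covariates (unpaired design)
    cov_tab <- NULL
    cov_eff <- matrix(0, nrow = ng, ncol = nrow(des))
    if (!is.null(cfg$covariates)) {
      cv <- cfg$covariates
      batch <- sample(seq_len(cv$batch_levels), length(subjects), replace = TRUE)
      gender <- sample(c("F", "M"), length(subjects), replace = TRUE)
      age <- round(runif(length(subjects), 25, 70))
      bmi <- round(runif(length(subjects), 19, 35), 1)
      cov_tab <- tibble(subject = subjects, batch = factor(batch),
                        gender = gender, age = age, bmi = bmi)
      b_g <- matrix(rnorm(ng * cv$batch_levels, 0, cv$batch_sd), nrow = ng)
      b_g[, 1] <- 0
      g_g <- rnorm(ng, 0, cv$gender_sd)
      a_g <- rnorm(ng, 0, cv$age_slope_sd)
      m_g <- rnorm(ng, 0, cv$bmi_slope_sd)
      si <- match(des$subject, subjects)
      cov_eff <- b_g[, batch[si], drop = FALSE] +
        outer(g_g, as.numeric(gender[si] == "M")) +
        outer(a_g, age[si] - mean(age)) +
        outer(m_g, bmi[si] - mean(bmi))
    }

    size <- 1 / cfg$dispersion
    input_cols <- which(des$assay == "INPUT")
    ip_cols <- which(des$assay == "IP")
    input_counts <- matrix(0, nrow = ng, ncol = length(input_cols),
                           dimnames = list(genes, des$sample_id[input_cols]))
    ip_counts <- matrix(0, nrow = nrow(bins), ncol = length(ip_cols),
                        dimnames = list(bins$bin_id, des$sample_id[ip_cols]))
    gene_of_bin <- match(bins$gene_id, genes)
    for (k in seq_along(input_cols)) {
      j <- input_cols[k]
      sub <- des$subject[j]
      is_case <- des$condition[j] == "CASE"
      mu_g <- q_g * exp(u[, sub] + (if (is_case) de_beta else 0) + cov_eff[, j])
      input_counts[, k] <- rnbinom(ng, size = size, mu = mu_g * f[j])
    }
    for (k in seq_along(ip_cols)) {
      j <- ip_cols[k]
      sub <- des$subject[j]
      is_case <- des$condition[j] == "CASE"
      mu_g <- q_g * exp(u[, sub] + (if (is_case) de_beta else 0) + cov_eff[, j])
      mu_b <- pi_b * mu_g[gene_of_bin] * f[j] *
        exp(if (is_case) beta_b else 0)
      ip_counts[, k] <- rnbinom(nrow(bins), size = size, mu = mu_b)
    }
    design <- des[, c("sample_id", "subject", "condition", "assay")]
    if (!is.null(cov_tab)) design <- left_join(design, cov_tab, by = "subject")
    list(ip_counts = ip_counts, input_counts = input_counts, bins = bins,
         design = design,
         truth = list(dm_regions = dm_regions, de_genes = de_genes,
                      lib_factors = f))
  })
}

#' Simulate a single-cell count matrix with four insulin modes
#'
#' Per-cell insulin log2-expression is drawn from a 4-component Gaussian
#' mixture; cells from the two highest-mean components are beta cells in
#' truth.  Other genes get lognormal base means with Poisson counting
#' noise; mitochondrial genes carry a configurable share of counts, with a
#' `mito_high` fraction of cells elevated past the QC limit and a
#' `low_depth` fraction scaled down past the library-size/detected-gene
#' thresholds.
#'
#' @param n_cells,n_genes matrix dimensions (insulin and 10 mito genes are
#'   included in `n_genes`).
#' @param mode_means increasing vector of 4 insulin log2 mode means.
#' @param mode_sd within-mode standard deviation.
#' @param weights mixture weights (default equal).
#' @param seed RNG seed.
#' @param mito_high,low_depth fractions of cells planted to fail QC.
#' @param n_de,de_lfc beta-cell-specific differentially expressed genes
#'   between the two conditions.
#' @param insulin_scale expected insulin count at log2-expression 0.
#' @return List: `counts` (genes x cells), `design` (`cell_id`,
#'   `condition`), `mito_genes`, `insulin_gene`, and `truth` (`component`,
#'   `is_beta`, `mito_high`, `low_depth`, `de_genes`).
#' @export
simulate_scrna <- function(n_cells = 500, n_genes = 2000,
                           mode_means = c(0, 2, 4, 6), mode_sd = 0.3,
                           weights = rep(0.25, 4), seed = 1L,
                           mito_high = 0.1, low_depth = 0.05,
                           n_de = 20, de_lfc = 1, insulin_scale = 20) {
  if (any(diff(mode_means) <= 0)) abort("mode means must be increasing")
  withr_seed(split_seed(seed, "scrna"), {
    mito_genes <- sprintf("MT-%02d", 1:10)
    other <- sprintf("gene%04d", seq_len(n_genes - 11))
    genes <- c("INS", mito_genes, other)
    cells <- sprintf("cell%04d", seq_len(n_cells))

    comp <- sample.int(4, n_cells, replace = TRUE, prob = weights)
    ins_log2 <- rnorm(n_cells, mode_means[comp], mode_sd)
    condition <- sample(rep(c("CTRL", "CASE"), length.out = n_cells))

    lam <- exp(rnorm(length(other), log(2), 1))  # base means, arbitrary units
    de_genes <- sample(other, n_de)
    de_sign <- sample(c(1, -1), n_de, replace = TRUE)
    lfc_vec <- setNames(rep(0, length(other)), other)
    lfc_vec[de_genes] <- de_sign * de_lfc

    depth <- exp(rnorm(n_cells, 0, 0.25))
    low_cells <- runif(n_cells) < low_depth
    depth[low_cells] <- depth[low_cells] * 0.15
    mito_cells <- !low_cells & runif(n_cells) < mito_high
    mito_share <- ifelse(mito_cells, 0.18, 0.04)

    counts <- matrix(0L, nrow = length(genes), ncol = n_cells,
                     dimnames = list(genes, cells))
    lam_sum <- sum(lam)
    for (c0 in seq_len(n_cells)) {
      lam_c <- lam * exp(if (condition[c0] == "CASE" && comp[c0] >= 3)
        lfc_vec * log(2) else 0)
      # scale non-mito genes to a target depth, then add the mito share
      base_total <- 6000 * depth[c0]
      mu_other <- lam_c / sum(lam_c) * base_total * (1 - mito_share[c0])
      mu_mito <- rep(base_total * mito_share[c0] / 10, 10)
      mu_ins <- insulin_scale * 2^ins_log2[c0] * depth[c0]
      counts[, c0] <- rpois(length(genes), c(mu_ins, mu_mito, mu_other))
    }
    list(
      counts = counts,
      design = tibble(cell_id = cells, condition = condition),
      mito_genes = mito_genes, insulin_gene = "INS",
      truth = tibble(cell_id = cells, component = comp,
                     is_beta = comp >= 3, mito_high = mito_cells,
                     low_depth = low_cells) |>
        structure(de_genes = tibble(gene_id = de_genes,
                                    lfc = de_sign * de_lfc))
    )
  })
}

#' Simulate bench assay tables with known truth
#'
#' Emits a qPCR Ct table (`Ct = c0 - log2(expression) + noise`, reference
#' gene included), an actinomycin-D decay series
#' (`abundance = exp(-k t) * (1 + eps)`) and a colorimetric OD table
#' linear in analyte concentration.
#'
#' @param seed RNG seed.
#' @param n_replicates replicates per group.
#' @param fold_truth true expression fold (CASE over CTRL) for the qPCR
#'   gene.
#' @param ct_noise_sd Ct measurement noise in cycles.
#' @param decay_half_life true half-life in hours.
#' @param decay_times chase time points (h).
#' @param decay_noise_cv multiplicative noise CV on abundances.
#' @return List of tibbles `ct`, `decay`, `od`, and `truth`.
#' @export
simulate_assay_tables <- function(seed = 1L, n_replicates = 4,
                                  fold_truth = 2, ct_noise_sd = 0.1,
                                  decay_half_life = 4,
                                  decay_times = c(0, 4, 8),
                                  decay_noise_cv = 0.05) {
  if (decay_half_life <= 0) abort("half-life must be positive")
  withr_seed(split_seed(seed, "assays"), {
    groups <- rep(c("CTRL", "CASE"), each = n_replicates)
    samples <- paste0(groups, "_", rep(seq_len(n_replicates), 2))
    expr <- ifelse(groups == "CASE", fold_truth, 1)
    ct <- bind_rows(
      tibble(sample = samples, group = groups, gene = "TARGET",
             ct = 25 - log2(expr) + rnorm(length(samples), 0, ct_noise_sd)),
      tibble(sample = samples, group = groups, gene = "GAPDH",
             ct = 20 + rnorm(length(samples), 0, ct_noise_sd))
    )
    k <- log(2) / decay_half_life
    decay <- tibble(
      time = decay_times,
      abundance = exp(-k * decay_times) *
        (1 + rnorm(length(decay_times), 0, decay_noise_cv))
    )
    decay$abundance <- decay$abundance / decay$abundance[1]
    conc <- c(0, 2, 5, 10, 20)
    od <- tibble(conc = conc,
                 od = 0.05 + 0.08 * conc + rnorm(length(conc), 0, 0.01))
    list(ct = ct, decay = decay, od = od,
         truth = list(fold = fold_truth, k = k,
                      half_life = decay_half_life))
  })
}
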