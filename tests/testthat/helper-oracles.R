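# Independent brute-force oracles and small fixture builders shared by the
# unit tests.  Oracles deliberately re-derive results from definitions and
# never call the implementation paths they check.

# step-up BH from the definition: sort, multiply by m/rank, cumulative min
# from the largest p, cap at 1, restore input order
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# run-length scan for merging: walk bins in order, open a region at any
# significant bin, extend while gene matches, ordinals are consecutive and
# (optionally) signs agree
oracle_merge <- function(gene, ordinal, p, sign, threshold = 0.05,
                         same_sign = TRUE) {
  idx <- order(gene, ordinal)
  gene <- gene[idx]; ordinal <- ordinal[idx]; p <- p[idx]; sign <- sign[idx]
  regions <- list()
  open <- NULL
  for (i in seq_along(p)) {
    if (is.na(p[i]) || p[i] >= threshold) {
      if (!is.null(open)) regions[[length(regions) + 1]] <- open
      open <- NULL
      next
    }
    extend <- !is.null(open) && open$gene == gene[i] &&
      ordinal[i] == open$end + 1 && (!same_sign || sign[i] == open$sign)
    if (extend) {
      open$end <- ordinal[i]
      open$p <- c(open$p, p[i])
    } else {
      if (!is.null(open)) regions[[length(regions) + 1]] <- open
      open <- list(gene = gene[i], start = ordinal[i], end = ordinal[i],
                   sign = sign[i], p = p[i])
    }
  }
  if (!is.null(open)) regions[[length(regions) + 1]] <- open
  regions
}

# base-by-base read assignment: enumerate the read's exonic bases in the
# gene, take min/max transcript positions, apply the midpoint rule over
# candidate bins naively
oracle_assign_bin <- function(models, gene, read_start, read_end, bins) {
  m <- models[models$gene_id == gene, ]
  gpos <- read_start:(read_end - 1)
  exonic <- gpos[vapply(gpos, function(p)
    any(p >= m$gstart & p < m$gend), logical(1))]
  if (length(exonic) == 0) return(NA_character_)
  tpos <- genomic_to_tx(models, gene, exonic)
  mid <- floor((min(tpos) + max(tpos) + 1) / 2)
  b <- bins[bins$gene_id == gene & bins$tx_start <= mid & bins$tx_end > mid, ]
  if (nrow(b) != 1) NA_character_ else b$bin_id
}

# single-gene fixture: plus or minus strand, one or two exons
toy_gene <- function(strand = "+", two_exon = FALSE) {
  if (two_exon) {
    gene_model("toy", "chr1", strand, rbind(c(0, 100), c(200, 300)),
               cds = c(50, 250))
  } else {
    gene_model("toy", "chr1", strand, cbind(0, 300), cds = c(100, 250))
  }
}

# small paired design + NB count matrix with optional per-bin condition
# effect (natural-log scale), used by the NB test checks
toy_paired_counts <- function(n_bins = 50, n_sub = 6, mu = 50, alpha = 0.1,
                              beta = 0, subject_sd = 0.2, seed = 1) {
  set.seed(seed)
  design <- tibble::tibble(
    sample_id = paste0("s", seq_len(2 * n_sub)),
    subject = rep(paste0("sub", seq_len(n_sub)), each = 2),
    condition = rep(c("CTRL", "CASE"), n_sub)
  )
  u <- matrix(rnorm(n_bins * n_sub, 0, subject_sd), n_bins)
  m <- mu * exp(u[, rep(seq_len(n_sub), each = 2)] +
                  outer(rep(beta, n_bins),
                        as.numeric(design$condition == "CASE")))
  y <- matrix(rnbinom(length(m), size = 1 / alpha, mu = m), n_bins,
              dimnames = list(paste0("g:", seq_len(n_bins)),
                              design$sample_id))
  list(counts = y, design = design)
}
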