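#' Metagene profile of region positions
#'
#' Maps each region's transcript midpoint to a fractional position within
#' its segment (5'UTR, CDS or 3'UTR), accumulates the positions on a fixed
#' grid of `cells` per segment, and normalizes the whole profile to sum 1.
#' Genes lacking a segment contribute only to the segments they have.
#'
#' @param regions tibble with `gene_id`, `tx_start`, `tx_end` (transcript
#'   coordinates of each region).
#' @param models the `gene_models` the regions refer to.
#' @param cells grid cells per segment (default 50).
#' @return A `metagene_profile` tibble: `segment`, `cell` (0-based within
#'   segment), `position` (global 0-based across the three segments) and
#'   `density`.
#' @export
metagene_profile <- function(regions, models, cells = 50) {
  lens <- gene_lengths(models)
  segs <- c("utr5", "cds", "utr3")
  counts <- matrix(0, nrow = 3, ncol = cells, dimnames = list(segs, NULL))
  for (i in seq_len(nrow(regions))) {
    g <- regions$gene_id[i]
    L <- lens[lens$gene_id == g, ]
    if (nrow(L) == 0) abort(sprintf("region gene '%s' not in models", g))
    mid <- (regions$tx_start[i] + regions$tx_end[i]) / 2
    if (mid < 0 || mid > L$tx_length) {
      abort(sprintf("region midpoint outside transcript of gene %s", g))
    }
    bounds <- cumsum(c(0, L$utr5_len, L$cds_len, L$utr3_len))
    k <- findInterval(mid, bounds, rightmost.closed = TRUE)
    k <- min(max(k, 1L), 3L)
    seg_len <- c(L$utr5_len, L$cds_len, L$utr3_len)[k]
    if (seg_len == 0) next
    frac <- (mid - bounds[k]) / seg_len
    cell <- min(floor(frac * cells), cells - 1)
    counts[k, cell + 1] <- counts[k, cell + 1] + 1
  }
  total <- sum(counts)
  dens <- if (total > 0) counts / total else counts
  out <- tibble(
    segment = factor(rep(segs, each = cells), levels = segs),
    cell = rep(seq_len(cells) - 1L, times = 3),
    position = seq_len(3 * cells) - 1L,
    density = as.vector(t(dens))
  )
  class(out) <- unique(c("metagene_profile", class(out)))
  out
}

#' k-mer and RRACH motif enrichment under peaks
#'
#' Scores every k-mer (plus the degenerate RRACH class) by sequence-level
#' presence in peak versus background sequences with a hypergeometric
#' upper-tail test, BH-adjusts across motifs, and ranks by fold enrichment
#' (Haldane-corrected when a zero count occurs).  T and U are equivalent;
#' motifs are reported in the RNA alphabet.
#'
#' @param peak_seqs,background_seqs character vectors (or
#'   `Biostrings::DNAStringSet`/`RNAStringSet`) of sequences.
#' @param k motif length (default 5).
#' @return Tibble ranked by fold enrichment: `motif`, `n_peak`, `n_bg`,
#'   `fold`, `pvalue`, `qvalue`; the RRACH class appears as motif
#'   `"RRACH"`.
#' @export
motif_enrichment <- function(peak_seqs, background_seqs, k = 5) {
  to_dna <- function(x) {
    x <- toupper(as.character(x))
    Biostrings::DNAStringSet(chartr("U", "T", x))
  }
  ps <- to_dna(peak_seqs)
  bs <- to_dna(background_seqs)
  if (length(bs) == 0) abort("background set is empty")
  if (min(Biostrings::width(ps), Biostrings::width(bs)) < k) {
    abort("k exceeds the shortest sequence length")
  }
  pres <- function(x) Biostrings::oligonucleotideFrequency(x, width = k) > 0
  pp <- pres(ps)
  bp <- pres(bs)
  # degenerate RRACH class (R = A/G, H = A/C/T), DNA alphabet
  rrach <- as.vector(outer(
    as.vector(outer(c("A", "G"), c("A", "G"), paste0)), c("A", "C", "T"),
    function(rr, h) paste0(rr, "AC", h)
  ))
  a <- colSums(pp)
  b <- colSums(bp)
  if (k == 5) {
    a <- c(a, RRACH = sum(apply(pp[, rrach, drop = FALSE], 1, any)))
    b <- c(b, RRACH = sum(apply(bp[, rrach, drop = FALSE], 1, any)))
  }
  np <- length(ps); nb <- length(bs)
  pval <- phyper(a - 1, a + b, np + nb - (a + b), np, lower.tail = FALSE)
  fold <- ifelse(
    a == 0 | b == 0,
    ((a + 0.5) / (np + 0.5)) / ((b + 0.5) / (nb + 0.5)),
    (a / np) / (b / nb)
  )
  out <- tibble(
    motif = chartr("T", "U", names(a)),
    n_peak = as.integer(a), n_bg = as.integer(b),
    fold = unname(fold), pvalue = unname(pval),
    qvalue = bh_adjust(unname(pval))
  )
  arrange(out, desc(.data$fold), .data$pvalue)
}

#' Count RRACH-class matches in one sequence
#'
#' @param seq a single RNA or DNA sequence.
#' @return Number of positions matching the degenerate RRACH pattern.
#' @export
count_rrach <- function(seq) {
  s <- chartr("U", "T", toupper(as.character(seq)))
  Biostrings::countPattern("RRACH", Biostrings::DNAString(s), fixed = FALSE)
}
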