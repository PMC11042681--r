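#' Partition gene transcripts into consecutive 50-nt bins
#'
#' Bins tile the transcript `[0, tx_length)` exactly; only the final bin of
#' a gene may be narrower than `width`.  Bin ids are `gene:ordinal` with a
#' 0-based ordinal.
#'
#' @param models a `gene_models` tibble.
#' @param width bin width in nucleotides (default 50).
#' @return Tibble with `bin_id`, `gene_id`, `ordinal`, `tx_start`, `tx_end`,
#'   `width`, `partial` (flag for trailing sub-width bins).
#' @export
partition_bins <- function(models, width = 50) {
  if (width < 1) abort("bin width must be >= 1")
  lens <- gene_lengths(models)
  lens |>
    mutate(n_bins = ceiling(.data$tx_length / width)) |>
    select("gene_id", "tx_length", "n_bins") |>
    tidyr::uncount(.data$n_bins, .id = "ord1") |>
    mutate(
      ordinal = .data$ord1 - 1L,
      tx_start = .data$ordinal * width,
      tx_end = pmin(.data$tx_start + width, .data$tx_length),
      width = .data$tx_end - .data$tx_start,
      partial = .data$width < !!width,
      bin_id = paste0(.data$gene_id, ":", .data$ordinal)
    ) |>
    select("bin_id", "gene_id", "ordinal", "tx_start", "tx_end", "width",
           "partial")
}

#' Count reads into transcript bins
#'
#' Each read's genomic span is intersected with a gene's exons and projected
#' to transcript coordinates; within each overlapped gene the read
#' increments exactly one bin — the one containing the midpoint of its
#' projected span.  A read overlapping several genes counts once per gene;
#' reads overlapping no gene are tallied and dropped.
#'
#' @param reads tibble with `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `sample_id`.
#' @param models a `gene_models` tibble.
#' @param bins output of [partition_bins()] over the same models.
#' @param stranded require read strand to match gene strand.
#' @return Count matrix (bins x samples); attribute `dropped` holds the
#'   per-sample tally of unassigned reads.
#' @export
count_reads_in_bins <- function(reads, models, bins, stranded = FALSE) {
  if (any(reads$end <= reads$start)) abort("inverted read interval")
  samples <- unique(reads$sample_id)
  mat <- matrix(0L, nrow = nrow(bins), ncol = length(samples),
                dimnames = list(bins$bin_id, samples))
  dropped <- setNames(numeric(length(samples)), samples)

  by_gene <- split(models, models$gene_id)
  gene_tab <- lapply(by_gene, function(m) {
    list(chrom = m$chrom[1], strand = m$strand[1],
         gstart = m$gstart, gend = m$gend,
         tx_start = m$tx_start, span = c(min(m$gstart), max(m$gend)))
  })
  bin_by_gene <- split(seq_len(nrow(bins)), bins$gene_id)

  for (i in seq_len(nrow(reads))) {
    rs <- reads$start[i]; re <- reads$end[i]; rc <- reads$chrom[i]
    s <- match(reads$sample_id[i], samples)
    assigned <- FALSE
    for (g in names(gene_tab)) {
      gt <- gene_tab[[g]]
      if (gt$chrom != rc || re <= gt$span[1] || rs >= gt$span[2]) next
      if (stranded && gt$strand != reads$strand[i]) next
      # project read onto transcript: union of per-piece overlaps
      tpos <- numeric(0)
      for (k in seq_along(gt$gstart)) {
        a <- max(rs, gt$gstart[k]); b <- min(re, gt$gend[k])
        if (b > a) {
          if (gt$strand == "+") {
            tpos <- c(tpos, gt$tx_start[k] + (a - gt$gstart[k]),
                      gt$tx_start[k] + (b - 1 - gt$gstart[k]))
          } else {
            tpos <- c(tpos, gt$tx_start[k] + (gt$gend[k] - b),
                      gt$tx_start[k] + (gt$gend[k] - 1 - a))
          }
        }
      }
      if (length(tpos) == 0) next
      mid <- floor((min(tpos) + max(tpos) + 1) / 2) # midpoint of [min, max+1)
      idx <- bin_by_gene[[g]]
      j <- idx[bins$tx_start[idx] <= mid & bins$tx_end[idx] > mid]
      if (length(j) == 1L) {
        mat[j, s] <- mat[j, s] + 1L
        assigned <- TRUE
      }
    }
    if (!assigned) dropped[s] <- dropped[s] + 1
  }
  if (sum(dropped) > 0) {
    inform(sprintf("%d read(s) overlapped no gene and were dropped",
                   as.integer(sum(dropped))))
  }
  attr(mat, "dropped") <- dropped
  mat
}

#' Sum bin counts to gene-level counts
#'
#' @param bin_counts matrix (bins x samples) with `gene:ordinal` rownames.
#' @param bins the bin table the matrix rows refer to.
#' @return Matrix (genes x samples); column totals are preserved.
#' @export
gene_input_counts <- function(bin_counts, bins) {
  idx <- match(rownames(bin_counts), bins$bin_id)
  if (anyNA(idx)) {
    abort(sprintf("orphan bin id: %s",
                  rownames(bin_counts)[which(is.na(idx))[1]]))
  }
  g <- factor(bins$gene_id[idx], levels = unique(bins$gene_id[idx]))
  out <- rowsum(bin_counts, g)
  rownames(out) <- levels(g)
  out
}
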