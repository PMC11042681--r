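#' Read a count matrix from TSV or MatrixMarket
#'
#' TSV input carries feature ids in the first column and one header field
#' per sample.  MatrixMarket input is the coordinate (triplet) format with
#' sibling plain-text feature and sample id files; absent cells are zero.
#'
#' @param path count file (`.tsv`/`.txt` or `.mtx`).
#' @param features,samples id files (one id per line), required for MTX.
#' @param allow_fractional permit non-integer values (e.g. adjusted counts).
#' @return A numeric matrix with feature rownames and sample colnames.
#' @export
read_counts <- function(path, features = NULL, samples = NULL,
                        allow_fractional = FALSE) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    m <- as.matrix(Matrix::readMM(path))
    if (is.null(features) || is.null(samples)) {
      abort("MTX input requires feature and sample id files")
    }
    rownames(m) <- readLines(features)
    colnames(m) <- readLines(samples)
  } else {
    d <- read.delim(path, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
    ids <- as.character(d[[1]])
    m <- as.matrix(d[, -1, drop = FALSE])
    if (!is.numeric(m)) abort(sprintf("non-numeric cell in %s", path))
    rownames(m) <- ids
  }
  if (anyDuplicated(rownames(m))) {
    abort(sprintf("duplicate feature id in %s: %s", path,
                  rownames(m)[duplicated(rownames(m))][1]))
  }
  if (anyNA(m)) abort(sprintf("missing value in %s", path))
  if (any(m < 0)) abort(sprintf("negative count in %s", path))
  if (!allow_fractional && any(m != round(m))) {
    abort(sprintf("fractional count in %s (use allow_fractional = TRUE)", path))
  }
  m
}

#' Write a count matrix as TSV
#'
#' @param counts numeric matrix with dimnames.
#' @param path output file.
#' @param id_col header name for the feature id column.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, id_col = "feature_id") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write merged regions as BED and TSV
#'
#' BED rows are genomic, 0-based half-open, spanning the region's mapped
#' transcript interval; score is `-10 log10(FDR)` rounded and capped at
#' 1000; strand comes from the gene model.  The TSV carries the full
#' statistics table.
#'
#' @param regions a region tibble from [call_dm_regions()] with columns
#'   `gene_id`, `tx_start`, `tx_end`, `fdr`.
#' @param models the `gene_models` the regions refer to.
#' @param bed_path,tsv_path output files (either may be `NULL` to skip).
#' @return A tibble of the BED fields, invisibly.
#' @export
write_regions <- function(regions, models, bed_path = NULL, tsv_path = NULL) {
  lens <- gene_lengths(models)
  rows <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    L <- lens$tx_length[lens$gene_id == r$gene_id]
    if (length(L) == 0) abort(sprintf("region gene '%s' not in models", r$gene_id))
    if (r$tx_start < 0 || r$tx_end > L) {
      abort(sprintf("region [%d,%d) outside gene %s span [0,%d)",
                    as.integer(r$tx_start), as.integer(r$tx_end), r$gene_id,
                    as.integer(L)))
    }
    gpos <- tx_to_genomic(models, r$gene_id, c(r$tx_start, r$tx_end - 1))
    m1 <- models[models$gene_id == r$gene_id, ]
    score <- min(1000, round(-10 * log10(max(r$fdr, 1e-100))))
    rows[[i]] <- tibble(
      chrom = m1$chrom[1], start = min(gpos), end = max(gpos) + 1,
      name = sprintf("%s:%d-%d", r$gene_id, as.integer(r$tx_start),
                     as.integer(r$tx_end)),
      score = score, strand = m1$strand[1]
    )
  }
  bed <- bind_rows(rows)
  if (!is.null(bed_path)) {
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path)) {
    write.table(as.data.frame(regions), tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(bed)
}
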