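#' Gene models with transcript-relative coordinates
#'
#' A `gene_models` object is a tibble with one row per contiguous piece of a
#' gene's transcript, carrying both genomic and transcript-relative
#' coordinates.  All intervals are 0-based, half-open.  Transcript
#' coordinates always run 5' to 3': position 0 is the 5' end of the mature
#' transcript regardless of strand, so downstream code never branches on
#' strand.  Pieces are labelled by segment (`utr5`, `cds`, `utr3`); a gene
#' without an annotated CDS is treated as a single unsegmented body labelled
#' `cds`.
#'
#' Columns: `gene_id`, `chrom`, `strand` (`+`/`-`), `segment`,
#' `gstart`/`gend` (genomic), `tx_start`/`tx_end` (transcript).
#'
#' @param gene_id,chrom,strand scalar gene identity.
#' @param exons two-column matrix of genomic exon intervals `[start, end)`,
#'   non-overlapping.
#' @param cds optional genomic `[start, end)` bounds of the coding region;
#'   both ends must fall in exons.
#' @return A `gene_models` tibble (a single gene for `gene_model()`).
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds = NULL) {
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.numeric(exons), ncol = 2)
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (any(exons[, 2] <= exons[, 1])) {
    abort(sprintf("gene %s: empty or inverted exon interval", gene_id))
  }
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2])) {
    abort(sprintf("gene %s: overlapping exons", gene_id))
  }
  # transcript order: ascending genomic for '+', descending for '-'
  ord <- if (strand == "+") seq_len(nrow(exons)) else rev(seq_len(nrow(exons)))
  ex <- exons[ord, , drop = FALSE]
  widths <- ex[, 2] - ex[, 1]
  off <- cumsum(c(0, widths[-length(widths)]))
  tx_len <- sum(widths)

  g2t <- function(pos) { # single genomic base -> transcript position
    i <- which(pos >= ex[, 1] & pos < ex[, 2])
    if (length(i) != 1L) {
      abort(sprintf("gene %s: position %d is not exonic", gene_id, as.integer(pos)))
    }
    if (strand == "+") off[i] + (pos - ex[i, 1]) else off[i] + (ex[i, 2] - 1 - pos)
  }

  if (is.null(cds)) {
    seg_bounds <- c(0, 0, tx_len, tx_len)
  } else {
    cds <- as.numeric(cds)
    if (cds[2] <= cds[1]) abort(sprintf("gene %s: empty CDS", gene_id))
    t1 <- g2t(cds[1])
    t2 <- g2t(cds[2] - 1)
    cs <- min(t1, t2)
    ce <- max(t1, t2) + 1
    seg_bounds <- c(0, cs, ce, tx_len)
  }

  # split [0, tx_len) at segment bounds and exon boundaries
  brk <- sort(unique(c(seg_bounds, off, tx_len)))
  brk <- brk[brk >= 0 & brk <= tx_len]
  starts <- brk[-length(brk)]
  ends <- brk[-1]
  keep <- ends > starts
  starts <- starts[keep]; ends <- ends[keep]
  seg_names <- if (seg_bounds[2] == 0 && seg_bounds[3] == tx_len) {
    rep("cds", length(starts))
  } else {
    c("utr5", "cds", "utr3")[findInterval(starts, c(0, seg_bounds[2], seg_bounds[3]))]
  }
  exon_idx <- findInterval(starts, off)
  gs <- ge <- numeric(length(starts))
  for (k in seq_along(starts)) {
    i <- exon_idx[k]
    a <- starts[k] - off[i]; b <- ends[k] - off[i]
    if (strand == "+") {
      gs[k] <- ex[i, 1] + a; ge[k] <- ex[i, 1] + b
    } else {
      gs[k] <- ex[i, 2] - b; ge[k] <- ex[i, 2] - a
    }
  }
  out <- tibble(
    gene_id = gene_id, chrom = chrom, strand = strand, segment = seg_names,
    gstart = gs, gend = ge, tx_start = starts, tx_end = ends
  )
  new_gene_models(out)
}

new_gene_models <- function(df) {
  class(df) <- unique(c("gene_models", class(tibble())))
  df
}

#' @export
`[.gene_models` <- function(x, ...) new_gene_models(NextMethod())

#' Transcript lengths and segment widths per gene
#'
#' @param models a `gene_models` tibble.
#' @return Tibble with `gene_id`, `chrom`, `strand`, `tx_length` and the
#'   widths of the three segments (zero when absent).
#' @export
gene_lengths <- function(models) {
  models |>
    mutate(w = .data$tx_end - .data$tx_start) |>
    group_by(.data$gene_id, .data$chrom, .data$strand) |>
    summarise(
      tx_length = sum(.data$w),
      utr5_len = sum(.data$w[.data$segment == "utr5"]),
      cds_len = sum(.data$w[.data$segment == "cds"]),
      utr3_len = sum(.data$w[.data$segment == "utr3"]),
      .groups = "drop"
    )
}

validate_gene_models <- function(models) {
  by_gene <- split(models, models$gene_id)
  for (m in by_gene) {
    m <- m[order(m$tx_start), ]
    if (m$tx_start[1] != 0) abort(sprintf("gene %s: transcript does not start at 0", m$gene_id[1]))
    if (nrow(m) > 1 && any(m$tx_start[-1] != m$tx_end[-nrow(m)])) {
      abort(sprintf("gene %s: transcript pieces not contiguous", m$gene_id[1]))
    }
    if (any((m$gend - m$gstart) != (m$tx_end - m$tx_start))) {
      abort(sprintf("gene %s: genomic/transcript widths disagree", m$gene_id[1]))
    }
  }
  invisible(models)
}

#' Map transcript positions of one gene to genomic positions
#'
#' Bijective over exonic bases; minus-strand genes are reflected so that
#' transcript position 0 is the genomic 3'-most base of the gene span.
#'
#' @param models a `gene_models` tibble.
#' @param gene a single gene id present in `models`.
#' @param tx_pos vector of transcript positions (0-based).
#' @return Numeric vector of genomic positions (0-based).
#' @export
tx_to_genomic <- function(models, gene, tx_pos) {
  m <- models[models$gene_id == gene, ]
  if (nrow(m) == 0) abort(sprintf("unknown gene '%s'", gene))
  m <- m[order(m$tx_start), ]
  i <- findInterval(tx_pos, m$tx_start)
  if (any(tx_pos < 0 | tx_pos >= max(m$tx_end))) {
    abort(sprintf("transcript position outside [0, %d) for gene %s",
                  as.integer(max(m$tx_end)), gene))
  }
  d <- tx_pos - m$tx_start[i]
  ifelse(m$strand[i] == "+", m$gstart[i] + d, m$gend[i] - 1 - d)
}

#' Map genomic positions of one gene to transcript positions
#'
#' @inheritParams tx_to_genomic
#' @param gpos vector of genomic positions (0-based); all must be exonic.
#' @return Numeric vector of transcript positions.
#' @export
genomic_to_tx <- function(models, gene, gpos) {
  m <- models[models$gene_id == gene, ]
  if (nrow(m) == 0) abort(sprintf("unknown gene '%s'", gene))
  out <- rep(NA_real_, length(gpos))
  for (k in seq_len(nrow(m))) {
    hit <- gpos >= m$gstart[k] & gpos < m$gend[k]
    out[hit] <- if (m$strand[k] == "+") {
      m$tx_start[k] + (gpos[hit] - m$gstart[k])
    } else {
      m$tx_start[k] + (m$gend[k] - 1 - gpos[hit])
    }
  }
  if (anyNA(out)) abort(sprintf("non-exonic genomic position for gene %s", gene))
  out
}

#' Read gene models from GTF or BED
#'
#' GTF (Ensembl dialect) is parsed with \pkg{rtracklayer}; exons are unioned
#' per gene and the coding region is the span of that gene's CDS features.
#' BED input may be BED6 (whole body treated as CDS), BED8 (thickStart /
#' thickEnd as CDS bounds) or BED12 (blocks as exons).  Duplicate exon lines
#' are deduplicated with a warning.
#'
#' @param path file path; format inferred from the extension unless given.
#' @param format `"auto"`, `"gtf"` or `"bed"`.
#' @return A `gene_models` tibble covering every gene in the file.
#' @export
read_gene_models <- function(path, format = c("auto", "gtf", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gtf"
  }
  if (format == "gtf") read_gene_models_gtf(path) else read_gene_models_bed(path)
}

read_gene_models_gtf <- function(path) {
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 9)) {
    bad <- which(body)[which(nf < 9)[1]]
    abort(sprintf("malformed GTF line %d in %s: fewer than 9 fields", bad, path))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  df <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L, # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    gene_id = gr$gene_id
  )
  out <- list()
  for (g in unique(df$gene_id)) {
    d <- df[df$gene_id == g, ]
    ex <- d[d$type == "exon", c("start", "end")]
    if (nrow(ex) == 0) abort(sprintf("gene %s has no exon features", g))
    if (anyDuplicated(ex)) {
      warn(sprintf("gene %s: duplicate exon lines deduplicated", g))
      ex <- unique(ex)
    }
    ex <- reduce_intervals(as.matrix(ex))
    cds_rows <- d[d$type == "CDS", ]
    cds <- if (nrow(cds_rows) > 0) c(min(cds_rows$start), max(cds_rows$end)) else NULL
    if (!is.null(cds) &&
        (!point_in_intervals(cds[1], ex) || !point_in_intervals(cds[2] - 1, ex))) {
      abort(sprintf("gene %s: CDS bounds outside exons", g))
    }
    out[[g]] <- gene_model(g, d$chrom[1], d$strand[1], ex, cds)
  }
  validate_gene_models(new_gene_models(bind_rows(out)))
}

read_gene_models_bed <- function(path) {
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 6) abort("BED input needs at least 6 columns")
  out <- vector("list", nrow(d))
  for (i in seq_len(nrow(d))) {
    chrom <- d[i, 1]; start <- as.numeric(d[i, 2]); end <- as.numeric(d[i, 3])
    name <- as.character(d[i, 4]); strand <- as.character(d[i, 6])
    if (ncol(d) >= 12 && !is.na(d[i, 10])) {
      nb <- as.integer(d[i, 10])
      sizes <- as.numeric(strsplit(as.character(d[i, 11]), ",")[[1]])[seq_len(nb)]
      offs <- as.numeric(strsplit(as.character(d[i, 12]), ",")[[1]])[seq_len(nb)]
      exons <- cbind(start + offs, start + offs + sizes)
    } else {
      exons <- cbind(start, end)
    }
    cds <- NULL
    if (ncol(d) >= 8 && !is.na(d[i, 7]) && as.numeric(d[i, 8]) > as.numeric(d[i, 7])) {
      cds <- c(as.numeric(d[i, 7]), as.numeric(d[i, 8]))
    }
    out[[i]] <- gene_model(name, chrom, strand, exons, cds)
  }
  validate_gene_models(new_gene_models(bind_rows(out)))
}

reduce_intervals <- function(x) {
  x <- x[order(x[, 1]), , drop = FALSE]
  res <- x[1, , drop = FALSE]
  for (k in seq_len(nrow(x))[-1]) {
    if (x[k, 1] <= res[nrow(res), 2]) {
      res[nrow(res), 2] <- max(res[nrow(res), 2], x[k, 2])
    } else {
      res <- rbind(res, x[k, ])
    }
  }
  res
}

point_in_intervals <- function(p, x) any(p >= x[, 1] & p < x[, 2])

#' Write gene models as GTF
#'
#' Emits one transcript per gene with `exon` and `CDS` features; reading the
#' file back with [read_gene_models()] reproduces the object.
#'
#' @param models a `gene_models` tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  lens <- gene_lengths(models)
  lines <- character(0)
  for (g in lens$gene_id) {
    m <- models[models$gene_id == g, ]
    m <- m[order(m$gstart), ]
    attr_str <- sprintf('gene_id "%s"; transcript_id "%s.t1";', g, g)
    ex <- reduce_intervals(cbind(m$gstart, m$gend))
    for (k in seq_len(nrow(ex))) {
      lines <- c(lines, paste(m$chrom[1], "meripdm", "exon", ex[k, 1] + 1, ex[k, 2],
                              ".", m$strand[1], ".", attr_str, sep = "\t"))
    }
    cdsm <- m[m$segment == "cds", ]
    if (nrow(cdsm) > 0 && any(m$segment != "cds")) {
      for (k in seq_len(nrow(cdsm))) {
        lines <- c(lines, paste(cdsm$chrom[1], "meripdm", "CDS",
                                cdsm$gstart[k] + 1, cdsm$gend[k],
                                ".", cdsm$strand[1], ".", attr_str, sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
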