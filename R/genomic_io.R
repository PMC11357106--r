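# Readers and writers for the genomics formats the pipeline touches.
#
# All internal coordinates are 0-based half-open (BED convention). GFF3 input
# (1-based inclusive) is converted at the boundary, in both directions.

# ---------------------------------------------------------------------------
# Peaks (ENCODE narrowPeak, BED6+4)

#' Construct a peak table
#'
#' Peaks are stored as a plain data.frame in ENCODE narrowPeak column order,
#' with 0-based half-open coordinates. `summit_offset` is the distance in bp
#' from `start` to the peak summit.
#'
#' @param chrom,start,end Interval (0-based half-open).
#' @param name Peak identifiers; defaults to `peak_1..n`.
#' @param score Integer display score (narrowPeak column 5).
#' @param strand One of "+", "-", "." per peak.
#' @param fold_enrichment Fold enrichment at the summit (narrowPeak
#'   signalValue), finite and >= 0.
#' @param neg_log10_p,neg_log10_q -log10 p/q value (narrowPeak columns 8-9).
#' @param summit_offset Summit offset from `start` in bp; must satisfy
#'   `start + summit_offset < end`.
#' @return data.frame with one row per peak.
#' @export
peak_set <- function(chrom, start, end,
                     name = paste0("peak_", seq_along(chrom)),
                     score = 0L, strand = ".",
                     fold_enrichment = 0, neg_log10_p = 0, neg_log10_q = 0,
                     summit_offset = (end - start) %/% 2L) {
  pk <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start), end = as.integer(end),
    name = as.character(name), score = as.integer(score),
    strand = as.character(strand),
    fold_enrichment = as.numeric(fold_enrichment),
    neg_log10_p = as.numeric(neg_log10_p),
    neg_log10_q = as.numeric(neg_log10_q),
    summit_offset = as.integer(summit_offset),
    stringsAsFactors = FALSE
  )
  validate_peaks(pk)
  pk
}

validate_peaks <- function(pk, chrom_lengths = NULL) {
  validate_intervals(pk, chrom_lengths, what = "peak")
  if (any(pk$summit_offset < 0L) ||
      any(pk$start + pk$summit_offset >= pk$end)) {
    stopf("peak summit_offset must satisfy start + summit_offset < end")
  }
  bad <- !is.finite(pk$fold_enrichment) | !is.finite(pk$neg_log10_q) |
    pk$fold_enrichment < 0 | pk$neg_log10_q < 0
  if (any(bad)) stopf("fold_enrichment and neg_log10_q must be finite and >= 0")
  invisible(pk)
}

#' Absolute summit positions of a peak table
#'
#' @param peaks A peak table from [peak_set()] or [read_narrowpeak()].
#' @return Integer vector of 0-based summit positions (`start + summit_offset`).
#' @export
peak_summits <- function(peaks) peaks$start + peaks$summit_offset

#' Read an ENCODE narrowPeak file
#'
#' Expects the 10-column tab-separated narrowPeak dialect as written by
#' MACS2. A summit offset of -1 (summit not called) is replaced by the
#' interval midpoint `floor((end - start) / 2)` so that summit-centric
#' operations stay total.
#'
#' @param path Path to a narrowPeak file.
#' @return Peak table (see [peak_set()]), in file order.
#' @export
read_narrowpeak <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  nf <- utils::count.fields(path, sep = "\t", comment.char = "", quote = "")
  if (length(nf) == 0) {
    return(peak_set(character(), integer(), integer()))
  }
  if (any(nf != 10L)) {
    bad <- which(nf != 10L)[1]
    stopf("%s line %d: expected 10 tab-separated narrowPeak columns, found %d",
          path, bad, nf[bad])
  }
  tb <- utils::read.table(path, sep = "\t", quote = "", comment.char = "",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "integer",
                                         "character", "integer", "character",
                                         "numeric", "numeric", "numeric",
                                         "integer"))
  names(tb) <- c("chrom", "start", "end", "name", "score", "strand",
                 "fold_enrichment", "neg_log10_p", "neg_log10_q",
                 "summit_offset")
  if (any(tb$start >= tb$end)) {
    bad <- which(tb$start >= tb$end)[1]
    stopf("%s line %d: start >= end", path, bad)
  }
  absent <- tb$summit_offset == -1L
  tb$summit_offset[absent] <- (tb$end[absent] - tb$start[absent]) %/% 2L
  validate_peaks(tb)
  tb
}

#' Write a peak table as ENCODE narrowPeak
#'
#' @param peaks Peak table (see [peak_set()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  validate_peaks(peaks)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%s\t%s\t%s\t%d",
                   peaks$chrom, peaks$start, peaks$end, peaks$name,
                   peaks$score, peaks$strand,
                   sprintf("%.17g", peaks$fold_enrichment),
                   sprintf("%.17g", peaks$neg_log10_p),
                   sprintf("%.17g", peaks$neg_log10_q),
                   peaks$summit_offset)
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# SignalTrack (binned coverage) and bedGraph

#' Construct a binned signal track
#'
#' A SignalTrack holds, per chromosome, the mean signal in consecutive
#' fixed-size bins (occupancy or ChIP enrichment, arbitrary units >= 0).
#' Bin `i` covers base pairs `[(i-1) * bin_size, i * bin_size)`.
#'
#' @param values Named list of numeric vectors, one per chromosome; vector
#'   `i` must have length `ceiling(chrom_length / bin_size)`.
#' @param bin_size Bin width in bp.
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @return An object of class `SignalTrack`.
#' @export
signal_track <- function(values, bin_size, chrom_lengths) {
  stopifnot(is.list(values), !is.null(names(values)))
  chrom_lengths <- chrom_lengths[names(values)]
  if (anyNA(chrom_lengths)) stopf("every chromosome needs a declared length")
  for (chr in names(values)) {
    nb <- as.integer(ceiling(chrom_lengths[[chr]] / bin_size))
    v <- values[[chr]]
    if (length(v) != nb) {
      stopf("%s: expected %d bins (%d bp / %d bp bins), got %d",
            chr, nb, chrom_lengths[[chr]], bin_size, length(v))
    }
    if (any(!is.finite(v)) || any(v < 0)) {
      stopf("%s: track values must be finite and >= 0", chr)
    }
  }
  structure(list(values = values, bin_size = as.integer(bin_size),
                 chrom_lengths = chrom_lengths),
            class = "SignalTrack")
}

#' @export
print.SignalTrack <- function(x, ...) {
  cat(sprintf("SignalTrack: %d chromosome(s), bin size %d bp\n",
              length(x$values), x$bin_size))
  for (chr in names(x$values)) {
    cat(sprintf("  %s: %d bp, %d bins, mean %.3f\n", chr,
                x$chrom_lengths[[chr]], length(x$values[[chr]]),
                mean(x$values[[chr]])))
  }
  invisible(x)
}

#' Read a bedGraph file into a binned signal track
#'
#' Each bin's value is the length-weighted mean of overlapping bedGraph
#' records, with uncovered base pairs contributing zero. This makes binning
#' mass-conserving: `sum(bin value) * bin_size` equals
#' `sum(record value * record length)` exactly (up to float round-off).
#'
#' @param path Path to a bedGraph file (0-based half-open records).
#' @param bin_size Bin width in bp.
#' @param chrom_lengths Named vector of chromosome lengths; records must not
#'   exceed their declared chromosome.
#' @return A [signal_track()].
#' @export
read_bedgraph <- function(path, bin_size, chrom_lengths) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  rec <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    value = as.numeric(gr$score),
    stringsAsFactors = FALSE
  )
  validate_intervals(rec, chrom_lengths, what = "bedGraph record")
  bin_records(rec, bin_size, chrom_lengths)
}

# Length-weighted binning of (chrom, start, end, value) records.
bin_records <- function(rec, bin_size, chrom_lengths) {
  bs <- as.integer(bin_size)
  values <- lapply(names(chrom_lengths), function(chr) {
    nb <- as.integer(ceiling(chrom_lengths[[chr]] / bs))
    acc <- numeric(nb)
    r <- rec[rec$chrom == chr, , drop = FALSE]
    if (nrow(r) == 0) return(acc)
    fb <- r$start %/% bs          # first bin (0-based)
    lb <- (r$end - 1L) %/% bs     # last bin (0-based)
    one <- fb == lb
    if (any(one)) {
      add <- rowsum((r$end - r$start)[one] * r$value[one], fb[one])
      idx <- as.integer(rownames(add)) + 1L
      acc[idx] <- acc[idx] + add[, 1]
    }
    for (i in which(!one)) {
      b0 <- fb[i]; b1 <- lb[i]; v <- r$value[i]
      acc[b0 + 1L] <- acc[b0 + 1L] + v * ((b0 + 1L) * bs - r$start[i])
      acc[b1 + 1L] <- acc[b1 + 1L] + v * (r$end[i] - b1 * bs)
      if (b1 - b0 > 1L) {
        mid <- (b0 + 2L):b1
        acc[mid] <- acc[mid] + v * bs
      }
    }
    # divide by each bin's actual extent (the final bin may be truncated at
    # the chromosome end), so mass is conserved exactly
    widths <- rep(bs, nb)
    widths[nb] <- chrom_lengths[[chr]] - (nb - 1L) * bs
    acc / widths
  })
  names(values) <- names(chrom_lengths)
  signal_track(values, bs, chrom_lengths)
}

#' Write a signal track as bedGraph
#'
#' Emits one record per run of equal-valued bins; zero-valued runs are
#' skipped (bedGraph leaves uncovered intervals implicit).
#'
#' @param track A [signal_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  bs <- track$bin_size
  for (chr in names(track$values)) {
    v <- track$values[[chr]]
    L <- track$chrom_lengths[[chr]]
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    s <- starts_bin[keep] * bs
    e <- pmin(ends_bin[keep] * bs, L)
    writeLines(sprintf("%s\t%d\t%d\t%.17g", chr, s, e, r$values[keep]), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Gene models (GFF3, gene features only)

#' Read gene models from a GFF3 file
#'
#' Only `gene` features are used. GFF3 1-based inclusive coordinates are
#' converted to the package's 0-based half-open convention. The TSS is the
#' first transcribed base (`start` on "+", `end - 1` on "-") and the TES the
#' opposite extremity; both therefore lie inside `[start, end)`.
#'
#' @param path Path to a GFF3 file.
#' @return data.frame with columns gene_id, chrom, start, end, strand, tss,
#'   tes.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == "gene"]
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) {
    stopf("%s: gene feature(s) without a strand", path)
  }
  id <- gr$ID
  if (is.null(id) || anyNA(id)) stopf("%s: gene feature(s) without an ID", path)
  gm <- data.frame(
    gene_id = as.character(id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = strand,
    stringsAsFactors = FALSE
  )
  gm$tss <- ifelse(gm$strand == "+", gm$start, gm$end - 1L)
  gm$tes <- ifelse(gm$strand == "+", gm$end - 1L, gm$start)
  validate_intervals(gm, what = "gene")
  gm[order(seq_len(nrow(gm))), ]
}

#' Write gene models as GFF3
#'
#' @param genes Gene model table (see [read_gene_models()]).
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path, source = "chromfate") {
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, source, genes$start + 1L, genes$end,
                     genes$strand, genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Expression matrix (MatrixMarket triplet + TSV sidecars)

#' Construct a cells x genes expression matrix
#'
#' @param counts Matrix-like of non-negative integer counts, cells in rows,
#'   genes in columns. Row and column names are used as cell and gene ids if
#'   `cell_ids`/`gene_ids` are not given.
#' @param clusters Character vector of per-cell cluster labels.
#' @param cluster_levels Declared finite set of labels (defaults to the
#'   labels present, in order of first appearance); unknown labels error.
#' @param cell_ids,gene_ids Identifiers.
#' @return Object of class `ExpressionMatrix`: list with elements `counts`
#'   (sparse dgCMatrix), `cell_ids`, `gene_ids`, `clusters` (factor).
#' @export
expression_matrix <- function(counts, clusters,
                              cluster_levels = NULL,
                              cell_ids = rownames(counts),
                              gene_ids = colnames(counts)) {
  counts <- methods::as(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                                "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(cell_ids)) cell_ids <- sprintf("cell_%04d", seq_len(nrow(counts)))
  if (is.null(gene_ids)) gene_ids <- sprintf("gene_%04d", seq_len(ncol(counts)))
  if (length(clusters) != nrow(counts)) {
    stopf("need one cluster label per cell (%d labels, %d cells)",
          length(clusters), nrow(counts))
  }
  if (any(counts@x < 0)) stopf("counts must be non-negative")
  tot <- Matrix::rowSums(counts)
  if (any(tot == 0)) {
    stopf("cell(s) with zero total counts: %s",
          paste(cell_ids[tot == 0], collapse = ", "))
  }
  cluster_levels <- cluster_levels %||% unique(as.character(clusters))
  unknown <- setdiff(unique(as.character(clusters)), cluster_levels)
  if (length(unknown) > 0) {
    stopf("cluster label(s) outside the declared set: %s",
          paste(unknown, collapse = ", "))
  }
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(list(counts = counts,
                 cell_ids = as.character(cell_ids),
                 gene_ids = as.character(gene_ids),
                 clusters = factor(as.character(clusters),
                                   levels = cluster_levels)),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d cells x %d genes, %d cluster level(s)\n",
              nrow(x$counts), ncol(x$counts), nlevels(x$clusters)))
  print(table(x$clusters))
  invisible(x)
}

#' Read a triplet sparse count matrix with TSV sidecars
#'
#' The matrix file is MatrixMarket coordinate format with cells in rows and
#' genes in columns; `genes_path` is a one-column TSV of gene ids and
#' `cells_path` a two-column TSV of cell id and cluster label (no headers).
#'
#' @param matrix_path,genes_path,cells_path File paths.
#' @param cluster_levels Optional declared label set (see
#'   [expression_matrix()]).
#' @return An [expression_matrix()].
#' @export
read_counts <- function(matrix_path, genes_path, cells_path,
                        cluster_levels = NULL) {
  m <- Matrix::readMM(matrix_path)
  genes <- utils::read.table(genes_path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  cells <- utils::read.table(cells_path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE,
                             col.names = c("cell_id", "cluster"))
  if (nrow(m) != nrow(cells) || ncol(m) != length(genes)) {
    stopf("matrix is %d x %d but sidecars declare %d cells and %d genes",
          nrow(m), ncol(m), nrow(cells), length(genes))
  }
  expression_matrix(m, clusters = cells$cluster,
                    cluster_levels = cluster_levels,
                    cell_ids = cells$cell_id, gene_ids = genes)
}

#' Write an expression matrix as MatrixMarket triplets plus sidecars
#'
#' @param em An [expression_matrix()].
#' @param matrix_path,genes_path,cells_path Output paths.
#' @return `matrix_path`, invisibly.
#' @export
write_counts <- function(em, matrix_path, genes_path, cells_path) {
  Matrix::writeMM(em$counts, matrix_path)
  writeLines(em$gene_ids, genes_path)
  writeLines(sprintf("%s\t%s", em$cell_ids, as.character(em$clusters)),
             cells_path)
  invisible(matrix_path)
}

# ---------------------------------------------------------------------------
# Genome sequence (FASTA)

#' Read a genome FASTA
#'
#' @param path Path to an uncompressed FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) Biostrings::readDNAStringSet(path)

#' Write a genome FASTA
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Chromosome lengths of a genome
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @return Named integer vector of sequence lengths.
#' @export
chrom_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}
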