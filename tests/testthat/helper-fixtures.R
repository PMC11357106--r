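# Shared fixture builders. All fixtures are generated in code under fixed
# seeds; nothing is read from disk except files the tests themselves write.

# Random non-overlapping-ish peak set on the given chromosomes.
rand_peaks <- function(n, chrom_lengths, width = 100, seed = 1) {
  chromfate:::with_seed(seed, {
    chrom <- sample(names(chrom_lengths), n, replace = TRUE)
    start <- vapply(chrom, function(ch) {
      as.integer(floor(runif(1) * (chrom_lengths[[ch]] - width)))
    }, integer(1))
    peak_set(chrom, start, start + width,
             summit_offset = sample.int(width, n, replace = TRUE) - 1L,
             fold_enrichment = round(runif(n, 1, 20), 3),
             neg_log10_p = round(runif(n, 0, 30), 3),
             neg_log10_q = round(runif(n, 0, 20), 3),
             score = sample.int(1000, n, replace = TRUE))
  })
}

# A single-chromosome track from a plain numeric vector.
toy_track <- function(v, bin_size = 10, chrom = "chr1") {
  signal_track(stats::setNames(list(v), chrom), bin_size,
               stats::setNames(length(v) * bin_size, chrom))
}

# Random gene models.
rand_genes <- function(n, chrom_lengths, len = 500, seed = 1) {
  chromfate:::with_seed(seed, {
    chrom <- sample(names(chrom_lengths), n, replace = TRUE)
    start <- vapply(chrom, function(ch) {
      as.integer(floor(runif(1) * (chrom_lengths[[ch]] - len)))
    }, integer(1))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    gm <- data.frame(gene_id = sprintf("g%03d", seq_len(n)), chrom = chrom,
                     start = start, end = start + len, strand = strand,
                     stringsAsFactors = FALSE)
    gm$tss <- ifelse(strand == "+", gm$start, gm$end - 1L)
    gm$tes <- ifelse(strand == "+", gm$end - 1L, gm$start)
    gm
  })
}
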