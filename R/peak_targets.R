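# Integration of ChIP-seq peak sets with gene models and single-cell
# statistics: overlap permutation tests, summit-proximal motif occurrence,
# promoter-window peak-to-gene annotation, and the target-assignment rule
# (expressed in >= 25% of factor-expressing cells, log2 fold change >= 0.223,
# and at least one binding site).

#' Permutation test for the overlap of two peak sets
#'
#' The observed statistic is the number of query peaks overlapping at least
#' one subject peak (any-bp overlap). The null is built by re-placing every
#' subject peak uniformly at random within its own chromosome (widths
#' preserved, no inter-chromosome moves) `n_perm` times. The empirical
#' p-value is `(1 + #{perm >= observed}) / (1 + n_perm)`, so it is never 0.
#'
#' @param query_peaks,subject_peaks Peak tables (see [peak_set()]).
#' @param chrom_lengths Named vector of chromosome lengths; every peak must
#'   fit within its chromosome.
#' @param n_perm Number of permutations.
#' @param seed RNG seed (results are reproducible given the seed).
#' @param mode `"uniform"` re-placement (default) or `"circular"` shift of
#'   all subject peaks on a chromosome by one common random offset.
#' The tie-inclusive `empirical_p` is valid but conservative when many
#' permutations tie with the observed count (the overlap statistic is
#' discrete); `mid_p`, which counts ties half, is the standard quantity
#' for checking the calibration of a discrete permutation test and is
#' reported alongside.
#'
#' @return Object of class `overlap_test`: observed_overlap, null_mean,
#'   null_sd, z_score, empirical_p, mid_p, n_perm, seed, null_counts.
#' @export
permutation_overlap_test <- function(query_peaks, subject_peaks,
                                     chrom_lengths, n_perm = 1000,
                                     seed = NULL,
                                     mode = c("uniform", "circular")) {
  mode <- match.arg(mode)
  if (nrow(query_peaks) == 0 || nrow(subject_peaks) == 0) {
    stopf("both peak sets must be non-empty")
  }
  validate_peaks(query_peaks, chrom_lengths)
  validate_peaks(subject_peaks, chrom_lengths)
  w <- subject_peaks$end - subject_peaks$start
  if (any(w > unname(chrom_lengths[subject_peaks$chrom]))) {
    stopf("subject peak longer than its chromosome")
  }
  observed <- sum(overlaps_any(query_peaks, subject_peaks))

  # Pre-split per chromosome for the permutation loop.
  chroms <- intersect(names(chrom_lengths),
                      union(query_peaks$chrom, subject_peaks$chrom))
  qr <- lapply(chroms, function(chr) {
    i <- query_peaks$chrom == chr
    as_iranges0(query_peaks$start[i], query_peaks$end[i])
  })
  sw <- lapply(chroms, function(chr) w[subject_peaks$chrom == chr])
  names(qr) <- names(sw) <- chroms

  null_counts <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      tot <- 0L
      for (chr in chroms) {
        if (length(sw[[chr]]) == 0 || length(qr[[chr]]) == 0) next
        L <- chrom_lengths[[chr]]
        if (mode == "uniform") {
          ns <- floor(stats::runif(length(sw[[chr]])) *
                        (L - sw[[chr]] + 1))
        } else {
          shift <- floor(stats::runif(1) * L)
          i <- subject_peaks$chrom == chr
          ns <- (subject_peaks$start[i] + shift) %% (L - sw[[chr]] + 1)
        }
        sr <- as_iranges0(ns, ns + sw[[chr]])
        tot <- tot + sum(IRanges::overlapsAny(qr[[chr]], sr))
      }
      tot
    }, integer(1))
  })
  null_sd <- stats::sd(null_counts)
  structure(list(
    observed_overlap = observed,
    null_mean = mean(null_counts),
    null_sd = null_sd,
    z_score = if (isTRUE(null_sd > 0)) (observed - mean(null_counts)) / null_sd
              else NA_real_,
    empirical_p = (1 + sum(null_counts >= observed)) / (1 + n_perm),
    mid_p = (0.5 + sum(null_counts > observed) +
               0.5 * sum(null_counts == observed)) / (1 + n_perm),
    n_perm = as.integer(n_perm),
    seed = seed,
    null_counts = null_counts
  ), class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(paste0("overlap permutation test: observed %d, null %.2f +/- ",
                     "%.2f (z = %.2f), empirical p = %.4g (%d permutations)\n"),
              x$observed_overlap, x$null_mean, x$null_sd, x$z_score,
              x$empirical_p, x$n_perm))
  invisible(x)
}

#' Fraction of peaks with a motif hit near their summits
#'
#' A peak "harbors" the motif if the best log-odds score on either strand,
#' among sites whose midpoint lies within `window` bp of the summit, reaches
#' the hit threshold. The default threshold is calibrated on background
#' sequence via [calibrate_pwm_threshold()] (top `fpr` of the single-site
#' null score distribution). Windows extending past a chromosome end are
#' clipped and flagged.
#'
#' @param peaks Peak table.
#' @param x A [pwm()].
#' @param genome A [Biostrings::DNAStringSet].
#' @param window Half-window around the summit in bp (default 100).
#' @param threshold Hit threshold in bits; if `NULL`, calibrated at `fpr`.
#' @param fpr Single-site false-positive rate used for calibration.
#' @return List with `fraction`, `threshold`, and `hits` (per-peak
#'   data.frame: name, score, offset, strand, hit, clipped).
#' @export
motif_fraction_at_summits <- function(peaks, x, genome, window = 100,
                                      threshold = NULL, fpr = 0.001) {
  if (is.null(threshold)) {
    threshold <- calibrate_pwm_threshold(x, fpr = fpr)$threshold
  }
  summit <- peak_summits(peaks)
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    b <- best_site(x, genome, peaks$chrom[i], summit[i], window = window)
    if (is.null(b)) {
      data.frame(name = peaks$name[i], score = NA_real_, offset = NA_integer_,
                 strand = NA_character_, hit = FALSE, clipped = NA)
    } else {
      data.frame(name = peaks$name[i], score = b$score, offset = b$offset,
                 strand = b$strand, hit = b$score >= threshold,
                 clipped = b$clipped)
    }
  })
  hits <- do.call(rbind, rows)
  if (any(hits$clipped, na.rm = TRUE)) {
    warnf("%d summit window(s) clipped at chromosome ends",
          sum(hits$clipped, na.rm = TRUE))
  }
  list(fraction = mean(hits$hit), threshold = threshold, hits = hits)
}

#' Assign peaks to genes with a promoter-window rule
#'
#' A peak is assigned to a gene if its summit lies within the gene body or
#' within `max_distance` bp upstream of the TSS (strand-aware). Among
#' eligible genes the one with the smallest `|summit - TSS|` wins; ties are
#' broken by the lexicographically smaller gene id.
#'
#' @param peaks Peak table.
#' @param gene_models Gene model table (see [read_gene_models()]).
#' @param max_distance Promoter window upstream of the TSS (default 3000 bp,
#'   the 3-kb cutoff).
#' @return data.frame with one row per peak: name, chrom, summit, gene_id
#'   (NA when unassigned), tss_distance.
#' @export
annotate_peaks_to_genes <- function(peaks, gene_models, max_distance = 3000) {
  validate_intervals(gene_models, what = "gene")
  summit <- peak_summits(peaks)
  out <- data.frame(name = peaks$name, chrom = peaks$chrom, summit = summit,
                    gene_id = NA_character_, tss_distance = NA_integer_,
                    stringsAsFactors = FALSE)
  # Eligible window per gene: body union strand-aware upstream promoter,
  # as 0-based half-open intervals.
  up_start <- ifelse(gene_models$strand == "+",
                     pmax(gene_models$tss - max_distance, 0L),
                     gene_models$start)
  up_end <- ifelse(gene_models$strand == "+",
                   gene_models$end,
                   gene_models$end + max_distance)
  for (chr in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == chr)
    gi <- which(gene_models$chrom == chr)
    if (length(gi) == 0) next
    ov <- IRanges::findOverlaps(
      as_iranges0(summit[pi], summit[pi] + 1L),
      as_iranges0(up_start[gi], up_end[gi])
    )
    if (length(ov) == 0) next
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    d <- abs(summit[pi][qh] - gene_models$tss[gi][sh])
    gid <- gene_models$gene_id[gi][sh]
    ord <- order(qh, d, gid)
    first <- !duplicated(qh[ord])
    sel <- ord[first]
    out$gene_id[pi[qh[sel]]] <- gid[sel]
    out$tss_distance[pi[qh[sel]]] <- d[sel]
  }
  out
}

#' Per-gene expression statistics in factor-expressing cells
#'
#' Splits cells into a factor-expressing group (raw count of `factor_gene`
#' >= `min_factor_count`) and the rest. For every gene, `pct_expressing` is
#' the fraction of factor-expressing cells with gene count >= 1, and
#' `log2fc = log2((m_in + eps)/(m_out + eps))` where `m` is the group mean
#' of depth-normalized counts (counts per 10k) and `eps = 1/10k`.
#'
#' @param em An [expression_matrix()].
#' @param factor_gene Gene id of the transcription factor.
#' @param min_factor_count Raw count defining a factor-expressing cell.
#' @return data.frame: gene_id, pct_expressing, log2fc; attributes
#'   `n_expressing` and `n_rest` give the group sizes.
#' @export
marker_stats <- function(em, factor_gene, min_factor_count = 1) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  fi <- match(factor_gene, em$gene_ids)
  if (is.na(fi)) stopf("factor gene %s not in the matrix", factor_gene)
  fc <- em$counts[, fi]
  grp_in <- fc >= min_factor_count
  if (!any(grp_in)) stopf("no cells express %s", factor_gene)
  depth <- Matrix::rowSums(em$counts)
  cp10k <- em$counts / depth * 1e4
  eps <- 1e-4
  m_in <- Matrix::colMeans(cp10k[grp_in, , drop = FALSE])
  m_out <- if (any(!grp_in)) {
    Matrix::colMeans(cp10k[!grp_in, , drop = FALSE])
  } else rep(0, ncol(em$counts))
  pct <- Matrix::colMeans(em$counts[grp_in, , drop = FALSE] >= 1)
  out <- data.frame(gene_id = em$gene_ids,
                    pct_expressing = as.numeric(pct),
                    log2fc = log2((m_in + eps) / (m_out + eps)),
                    stringsAsFactors = FALSE)
  attr(out, "n_expressing") <- sum(grp_in)
  attr(out, "n_rest") <- sum(!grp_in)
  out
}

#' Assign transcription-factor targets
#'
#' A gene is a target of the factor iff it is expressed in at least
#' `min_pct` of factor-expressing cells AND its log2 fold change is at
#' least `min_log2fc` AND it has at least one binding site (an annotated
#' peak). Both thresholds are inclusive.
#'
#' @param stats Output of [marker_stats()].
#' @param peak_annotations Output of [annotate_peaks_to_genes()]; genes
#'   appearing in its `gene_id` column have a binding site.
#' @param factor Factor name recorded in the output.
#' @param min_pct Minimum fraction of factor-expressing cells (default 0.25).
#' @param min_log2fc Minimum log2 fold change (default 0.223, i.e. a
#'   fold change of about 1.17).
#' @return data.frame: gene_id, factor, pct_expressing, log2fc,
#'   has_binding_site, is_target.
#' @export
assign_targets <- function(stats, peak_annotations, factor = "TF",
                           min_pct = 0.25, min_log2fc = 0.223) {
  bound <- unique(stats::na.omit(peak_annotations$gene_id))
  out <- data.frame(
    gene_id = stats$gene_id,
    factor = factor,
    pct_expressing = stats$pct_expressing,
    log2fc = stats$log2fc,
    has_binding_site = stats$gene_id %in% bound,
    stringsAsFactors = FALSE
  )
  out$is_target <- out$pct_expressing >= min_pct &
    out$log2fc >= min_log2fc & out$has_binding_site
  out
}
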