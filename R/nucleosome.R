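# Nucleosome occupancy analysis: a transparent smoothed-peak caller with a
# Poisson tail score (in place of a full nucleosome-positioning tool),
# nucleosomal/non-nucleosomal peak classification, reference-point and
# scaled gene-body metaprofiles, shared-vs-unique peak signal, and induced
# differential occupancy with median-of-ratios normalization.

# Gaussian smoothing with edge renormalization (kernel truncated at 4 sd).
gaussian_smooth <- function(v, sd_bins) {
  if (sd_bins <= 0) return(v)
  half <- max(1L, ceiling(4 * sd_bins))
  k <- stats::dnorm(seq(-half, half), sd = sd_bins)
  num <- stats::filter(c(rep(0, half), v, rep(0, half)), k, sides = 2)
  den <- stats::filter(c(rep(0, half), rep(1, length(v)), rep(0, half)),
                       k, sides = 2)
  (num / den)[(half + 1):(half + length(v))]
}

#' Call nucleosome-occupied regions from an occupancy track
#'
#' The track is Gaussian-smoothed (`smoothing_bandwidth` is the kernel sd in
#' bp); local maxima whose smoothed value exceeds the per-chromosome
#' background (the median of the smoothed track) by at least
#' `min_prominence` become candidate calls. Each call is a 147-bp interval
#' centered on the maximum, with a q-like score
#' `-log10 P(Poisson(background) >= value)`; calls below `q_min` are
#' dropped, and overlapping calls are resolved greedily by descending
#' occupancy score.
#'
#' @param track A [signal_track()] with bin size <= 20 bp.
#' @param smoothing_bandwidth Gaussian kernel sd in bp (default 30).
#' @param min_prominence Minimum height of a maximum above the background,
#'   in track units (default 5).
#' @param q_min Minimum q-like score (default 0; a stringent preset in the
#'   spirit of a q < 1e-50 cutoff would be `q_min = 50`).
#' @return data.frame with one row per call: chrom, start, end (147-bp,
#'   0-based half-open), center, occupancy_score (smoothed value),
#'   q_like_score, background.
#' @export
call_nucleosomes <- function(track, smoothing_bandwidth = 30,
                             min_prominence = 5, q_min = 0) {
  stopifnot(inherits(track, "SignalTrack"))
  if (track$bin_size > 20) stopf("nucleosome calling needs bin_size <= 20 bp")
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), center = integer(),
                      occupancy_score = numeric(), q_like_score = numeric(),
                      background = numeric(), stringsAsFactors = FALSE)
  if (all(vapply(track$values, function(v) all(v == 0), logical(1)))) {
    warnf("track carries no signal; returning zero nucleosome calls")
    return(empty)
  }
  bs <- track$bin_size
  out <- list()
  for (chr in names(track$values)) {
    v <- track$values[[chr]]
    if (length(v) < 3) next
    sm <- gaussian_smooth(v, smoothing_bandwidth / bs)
    bg <- stats::median(sm)
    lambda <- mean(v)
    n <- length(sm)
    ismax <- c(FALSE, sm[2:(n - 1)] > sm[1:(n - 2)] &
                 sm[2:(n - 1)] >= sm[3:n], FALSE)
    cand <- which(ismax & (sm - bg) >= min_prominence)
    if (length(cand) == 0) next
    q_like <- -stats::ppois(sm[cand], lambda = max(lambda, 1e-12),
                            lower.tail = FALSE, log.p = TRUE) / log(10)
    keep <- q_like >= q_min
    cand <- cand[keep]; q_like <- q_like[keep]
    if (length(cand) == 0) next
    center <- as.integer((cand - 1L) * bs + bs %/% 2L)
    df <- data.frame(chrom = chr, start = center - 73L, end = center + 74L,
                     center = center, occupancy_score = sm[cand],
                     q_like_score = q_like, background = bg,
                     stringsAsFactors = FALSE)
    # Greedy resolution of overlapping calls by descending score.
    df <- df[order(-df$occupancy_score, df$center), ]
    taken <- integer(0)
    keep <- logical(nrow(df))
    for (i in seq_len(nrow(df))) {
      if (all(abs(df$center[i] - taken) >= 147L)) {
        keep[i] <- TRUE
        taken <- c(taken, df$center[i])
      }
    }
    df <- df[keep, ]
    out[[chr]] <- df[order(df$center), ]
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify peaks as nucleosomal or non-nucleosomal
#'
#' A peak is nucleosomal iff its summit +/- `window` bp (default 73, half a
#' nucleosome footprint) overlaps any nucleosome call.
#'
#' @param peaks Peak table.
#' @param nucleosome_calls Output of [call_nucleosomes()] (or any interval
#'   table).
#' @param window Half-window around the summit in bp.
#' @return Character vector, `"nucleosomal"` or `"non-nucleosomal"`, one per
#'   peak.
#' @export
classify_peaks <- function(peaks, nucleosome_calls, window = 73) {
  summit <- peak_summits(peaks)
  q <- data.frame(chrom = peaks$chrom, start = summit - window,
                  end = summit + window + 1L)
  hit <- overlaps_any(q, nucleosome_calls)
  ifelse(hit, "nucleosomal", "non-nucleosomal")
}

# Per-bp track values over [start, end); positions outside the chromosome
# give zero (zero-padding).
track_bp_values <- function(track, chr, start, end) {
  v <- track$values[[chr]]
  if (is.null(v)) stopf("no track data for chromosome %s", chr)
  pos <- seq.int(start, end - 1L)
  idx <- pos %/% track$bin_size + 1L
  ok <- pos >= 0L & pos < track$chrom_lengths[[chr]]
  out <- numeric(length(pos))
  out[ok] <- v[idx[ok]]
  out
}

new_metaprofile <- function(mat, positions, anchor_type, clipped = 0L) {
  dimnames(mat) <- NULL
  structure(list(positions = positions, mean = colMeans(mat), matrix = mat,
                 n_sites = nrow(mat), anchor_type = anchor_type,
                 clipped = clipped),
            class = "Metaprofile")
}

#' @export
print.Metaprofile <- function(x, ...) {
  cat(sprintf("Metaprofile (%s): %d sites x %d bins, mean signal %.3f\n",
              x$anchor_type, x$n_sites, length(x$mean), mean(x$mean)))
  if (x$clipped > 0) cat(sprintf("  %d site(s) zero-padded at edges\n",
                                 x$clipped))
  invisible(x)
}

#' Reference-point signal metaprofile
#'
#' Extracts per-site signal over `[anchor - flank, anchor + flank)`, bins it
#' into `n_bins` equal bins, and averages across sites. Sites on the minus
#' strand (when `anchors$strand` is present) are flipped so that upstream is
#' always left. Out-of-range flanks are zero-padded and flagged.
#'
#' @param track A [signal_track()].
#' @param anchors data.frame with columns chrom, pos (0-based bp) and
#'   optionally strand.
#' @param flank Half-window in bp (default 1000).
#' @param n_bins Number of profile bins (default 100); `2 * flank` must be a
#'   multiple of `n_bins`.
#' @return A `Metaprofile`: bin center positions relative to the anchor,
#'   mean signal per bin, and the per-site matrix (sites x bins).
#' @export
metaprofile_point <- function(track, anchors, flank = 1000, n_bins = 100) {
  if (nrow(anchors) == 0) stopf("need at least one anchor")
  width <- 2L * flank
  if (width %% n_bins != 0) stopf("2 * flank must be a multiple of n_bins")
  bpb <- width %/% n_bins
  clipped <- 0L
  rows <- matrix(0, nrow(anchors), width)
  for (i in seq_len(nrow(anchors))) {
    s <- anchors$pos[i] - flank
    e <- anchors$pos[i] + flank
    if (s < 0 || e > track$chrom_lengths[[anchors$chrom[i]]]) {
      clipped <- clipped + 1L
    }
    v <- track_bp_values(track, anchors$chrom[i], s, e)
    if (!is.null(anchors$strand) && anchors$strand[i] == "-") v <- rev(v)
    rows[i, ] <- v
  }
  grp <- rep(seq_len(n_bins), each = bpb)
  binned <- t(rowsum(t(rows), grp) / bpb)
  if (clipped > 0) warnf("%d anchor window(s) zero-padded at edges", clipped)
  new_metaprofile(binned, positions = seq(-flank + bpb / 2, flank, by = bpb),
                  anchor_type = "point", clipped = clipped)
}

#' Scaled gene-body metaprofile (TSS to TES)
#'
#' Each gene body is linearly rescaled to `body_bins` bins; the two flanks
#' are binned natively (`flank / flank_bins` bp per bin). Genes on the minus
#' strand are oriented so the TSS is on the left. Genes shorter than
#' `body_bins` bp are linearly interpolated and flagged.
#'
#' @param track A [signal_track()].
#' @param gene_models Gene model table (see [read_gene_models()]).
#' @param body_bins Number of bins across the gene body (default 100).
#' @param flank Flank length in bp (default 1000).
#' @param flank_bins Number of bins per flank (default 50).
#' @return A `Metaprofile` with `flank_bins + body_bins + flank_bins` bins;
#'   `positions` are bin indices with the body spanning (0, 1].
#' @export
metaprofile_scaled <- function(track, gene_models, body_bins = 100,
                               flank = 1000, flank_bins = 50) {
  if (nrow(gene_models) == 0) stopf("need at least one gene")
  if (flank %% flank_bins != 0) {
    stopf("flank must be a multiple of flank_bins")
  }
  fb <- flank %/% flank_bins
  interpolated <- 0L
  rows <- matrix(0, nrow(gene_models),
                 2L * flank_bins + body_bins)
  for (i in seq_len(nrow(gene_models))) {
    chr <- gene_models$chrom[i]
    gs <- gene_models$start[i]; ge <- gene_models$end[i]
    left <- track_bp_values(track, chr, gs - flank, gs)
    body <- track_bp_values(track, chr, gs, ge)
    right <- track_bp_values(track, chr, ge, ge + flank)
    bin_native <- function(v, nb) {
      as.numeric(rowsum(v, rep(seq_len(nb), each = length(v) / nb)) /
                   (length(v) / nb))
    }
    len <- length(body)
    if (len >= body_bins) {
      grp <- floor((seq_len(len) - 1) * body_bins / len) + 1L
      bodyb <- as.numeric(rowsum(body, grp) / tabulate(grp, body_bins))
    } else {
      bodyb <- stats::approx(seq_len(len), body, n = body_bins)$y
      interpolated <- interpolated + 1L
    }
    prof <- c(bin_native(left, flank_bins), bodyb,
              bin_native(right, flank_bins))
    if (gene_models$strand[i] == "-") prof <- rev(prof)
    rows[i, ] <- prof
  }
  if (interpolated > 0) {
    warnf("%d gene(s) shorter than body_bins were interpolated", interpolated)
  }
  pos <- c(seq(-flank + fb / 2, 0, by = fb) / flank,      # flank in (-1, 0]
           (seq_len(body_bins) - 0.5) / body_bins,        # body in (0, 1)
           1 + seq(fb / 2, flank, by = fb) / flank)       # flank in (1, 2]
  new_metaprofile(rows, positions = pos, anchor_type = "scaled-body",
                  clipped = interpolated)
}

#' Signal at peaks shared between two factors versus unique peaks
#'
#' Partitions the peaks of factor A into those overlapping any peak of
#' factor B (shared, any-bp overlap) and the rest (unique), and computes a
#' summit-anchored metaprofile of A's signal track for each partition.
#'
#' @param peaks_a,peaks_b Peak tables.
#' @param track_a Signal track of factor A.
#' @param flank,n_bins Passed to [metaprofile_point()].
#' @return List with `shared` and `unique` (Metaprofiles, or NULL with a
#'   warning for an empty partition) and `summary` (data.frame of n and mean
#'   signal per partition plus the shared/unique ratio).
#' @export
shared_unique_signal <- function(peaks_a, peaks_b, track_a, flank = 1000,
                                 n_bins = 100) {
  shared <- overlaps_any(peaks_a, peaks_b)
  mk <- function(idx, label) {
    if (!any(idx)) {
      warnf("no %s peaks; profile omitted", label)
      return(NULL)
    }
    metaprofile_point(track_a,
                      data.frame(chrom = peaks_a$chrom[idx],
                                 pos = peak_summits(peaks_a)[idx]),
                      flank = flank, n_bins = n_bins)
  }
  ps <- mk(shared, "shared")
  pu <- mk(!shared, "unique")
  ms <- if (!is.null(ps)) mean(ps$mean) else NA_real_
  mu <- if (!is.null(pu)) mean(pu$mean) else NA_real_
  list(shared = ps, unique = pu,
       summary = data.frame(n_shared = sum(shared), n_unique = sum(!shared),
                            mean_shared = ms, mean_unique = mu,
                            ratio = ms / mu))
}

# Length-weighted summed signal of a track over regions (pseudo-counts).
region_counts <- function(track, regions) {
  validate_intervals(regions, what = "region")
  vapply(seq_len(nrow(regions)), function(i) {
    sum(track_bp_values(track, regions$chrom[i], regions$start[i],
                        regions$end[i])) / track$bin_size
  }, numeric(1))
}

#' Differential nucleosome occupancy between two conditions
#'
#' Sums each track's signal over the given regions as pseudo-counts,
#' normalizes the two conditions by median-of-ratios size factors (each
#' condition's factor is the median over regions of count / geometric mean
#' across conditions, computed on regions with nonzero counts in both), and
#' reports `log2((treat/sf_t + pseudocount) / (mock/sf_m + pseudocount))`
#' per region. Regions with zero counts in both conditions get log2FC 0 and
#' are flagged. Dispersion shrinkage and per-region significance testing are
#' out of scope; only the normalization + fold-change core is implemented.
#'
#' @param track_treat,track_mock Signal tracks sharing bin size and
#'   chromosomes.
#' @param regions Interval table (chrom, start, end), e.g. nucleosome
#'   footprints or summit windows.
#' @param pseudocount Added after size-factor scaling (default 1).
#' @return Object of class `differential_occupancy`: `table` (per-region
#'   counts, normalized counts, log2fc, both_zero flag) and `size_factors`.
#' @export
differential_occupancy <- function(track_treat, track_mock, regions,
                                   pseudocount = 1) {
  if (nrow(regions) == 0) stopf("regions must be non-empty")
  if (track_treat$bin_size != track_mock$bin_size) {
    stopf("tracks must share a bin size")
  }
  ct <- region_counts(track_treat, regions)
  cm <- region_counts(track_mock, regions)
  sf <- median_of_ratios(cbind(treat = ct, mock = cm))
  nt <- ct / sf[["treat"]]
  nm <- cm / sf[["mock"]]
  both_zero <- ct == 0 & cm == 0
  lfc <- log2((nt + pseudocount) / (nm + pseudocount))
  lfc[both_zero] <- 0
  if (any(both_zero)) {
    warnf("%d region(s) with zero counts in both conditions (log2FC set to 0)",
          sum(both_zero))
  }
  tab <- data.frame(regions, count_treat = ct, count_mock = cm,
                    norm_treat = nt, norm_mock = nm, log2fc = lfc,
                    both_zero = both_zero, stringsAsFactors = FALSE)
  structure(list(table = tab, size_factors = sf,
                 pseudocount = pseudocount),
            class = "differential_occupancy")
}

#' Median-of-ratios size factors
#'
#' Each column's size factor is the median over rows of
#' `count / geometric mean across columns`, using only rows where all
#' counts are positive. By construction, dividing the columns by their
#' factors centers the cross-condition ratios at 1.
#'
#' @param counts Numeric matrix, regions in rows, conditions in columns.
#' @return Named numeric vector of size factors (> 0).
#' @export
median_of_ratios <- function(counts) {
  counts <- as.matrix(counts)
  logc <- log(counts)
  ok <- rowSums(!is.finite(logc)) == 0
  if (!any(ok)) stopf("no region has positive counts in all conditions")
  geo <- exp(rowMeans(logc[ok, , drop = FALSE]))
  apply(counts[ok, , drop = FALSE], 2, function(col) {
    stats::median(col / geo)
  })
}

#' @export
print.differential_occupancy <- function(x, ...) {
  cat(sprintf(paste0("differential occupancy: %d regions, size factors ",
                     "treat=%.3f mock=%.3f, mean log2FC %.3f\n"),
              nrow(x$table), x$size_factors[["treat"]],
              x$size_factors[["mock"]], mean(x$table$log2fc)))
  invisible(x)
}
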