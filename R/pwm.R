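# Position weight matrices: construction from aligned sites, log-odds
# scanning on both strands, null-score calibration, and localization of the
# best-scoring site near a peak center.

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' @param probs L x 4 matrix of per-position base probabilities, columns
#'   A, C, G, T; each row must sum to 1 (tolerance 1e-9).
#' @param background Background base probabilities (default uniform).
#' @param pseudocount Pseudocount recorded for provenance (may be NA when
#'   the matrix was supplied directly).
#' @return Object of class `pwm` with elements `probs`, `background`,
#'   `pseudocount`, and `log_odds` (log2(prob/background), in bits).
#' @export
pwm <- function(probs, background = rep(0.25, 4), pseudocount = NA_real_) {
  probs <- as.matrix(probs)
  colnames(probs) <- DNA_BASES
  if (any(abs(rowSums(probs) - 1) > 1e-9)) {
    stopf("each PWM position's probabilities must sum to 1")
  }
  if (any(probs <= 0)) {
    stopf("PWM probabilities must be strictly positive (use a pseudocount)")
  }
  lo <- log2(sweep(probs, 2, background, "/"))
  structure(list(probs = probs, background = background,
                 pseudocount = pseudocount, log_odds = lo),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm: length %d, consensus %s, max score %.2f bits\n",
              nrow(x$probs), pwm_consensus(x), pwm_max_score(x)))
  invisible(x)
}

#' Build a PWM from aligned binding-site sequences
#'
#' Column probabilities are `(count + pseudocount) / (n + 4 * pseudocount)`.
#' An `N` in a site is distributed to the background: it adds
#' `background[b]` to the count of each base `b` at that position.
#'
#' @param sites Character vector of equal-length sequences over ACGT (and N).
#' @param pseudocount Added per base per column (default 0.25).
#' @param background Background base probabilities.
#' @return A [pwm()].
#' @export
pwm_from_sites <- function(sites, pseudocount = 0.25,
                           background = rep(0.25, 4)) {
  if (length(sites) == 0) stopf("need at least one site sequence")
  sites <- toupper(sites)
  L <- unique(nchar(sites))
  if (length(L) != 1) stopf("all sites must have equal length")
  chars <- matrix(unlist(strsplit(sites, "")), nrow = length(sites),
                  byrow = TRUE)
  if (!all(chars %in% c(DNA_BASES, "N"))) {
    stopf("sites may only contain A, C, G, T, N")
  }
  n <- length(sites)
  counts <- sapply(seq_len(L), function(p) {
    col <- chars[, p]
    ct <- vapply(DNA_BASES, function(b) sum(col == b), numeric(1))
    ct + sum(col == "N") * background
  })
  counts <- t(counts)  # L x 4
  probs <- (counts + pseudocount) / (n + 4 * pseudocount)
  pwm(probs, background = background, pseudocount = pseudocount)
}

#' Consensus sequence of a PWM (plurality base per column)
#'
#' @param x A [pwm()].
#' @return Character scalar.
#' @export
pwm_consensus <- function(x) {
  paste(DNA_BASES[apply(x$probs, 1, which.max)], collapse = "")
}

#' Maximum attainable log-odds score of a PWM
#'
#' @param x A [pwm()].
#' @return Score in bits.
#' @export
pwm_max_score <- function(x) sum(apply(x$log_odds, 1, max))

pwm_length <- function(x) nrow(x$probs)

# Log-odds matrix for scoring the minus strand on forward-sequence indices:
# reverse the positions and complement the columns.
pwm_revcomp_lo <- function(x) {
  lo <- x$log_odds
  lo[rev(seq_len(nrow(lo))), c("T", "G", "C", "A")]
}

# Score every start position of `codes` (integer codes 1..4 for ACGT,
# NA for other bases, which contribute 0) against a log-odds matrix.
score_positions <- function(lo, codes) {
  L <- nrow(lo)
  n <- length(codes) - L + 1L
  if (n < 1) return(numeric(0))
  sc <- numeric(n)
  for (p in seq_len(L)) {
    contrib <- lo[p, codes[p:(p + n - 1L)]]
    contrib[is.na(contrib)] <- 0
    sc <- sc + contrib
  }
  sc
}

seq_to_codes <- function(s) {
  match(strsplit(toupper(as.character(s)), "")[[1]], DNA_BASES)
}

#' Scan a sequence with a PWM on both strands
#'
#' @param x A [pwm()].
#' @param seq Character or DNAString sequence.
#' @return data.frame with columns start (0-based, relative to the sequence),
#'   strand, score (bits); one row per start position and strand.
#' @export
pwm_scan <- function(x, seq) {
  codes <- seq_to_codes(seq)
  fw <- score_positions(x$log_odds, codes)
  rv <- score_positions(pwm_revcomp_lo(x), codes)
  n <- length(fw)
  data.frame(start = rep(seq_len(n) - 1L, 2L),
             strand = rep(c("+", "-"), each = n),
             score = c(fw, rv), stringsAsFactors = FALSE)
}

#' Calibrate a PWM hit threshold on background sequence
#'
#' Samples the null distribution of single-site log-odds scores (random
#' L-mers drawn from the background composition) and returns the score
#' exceeded only by the top `fpr` fraction of the null (default: top 0.1%).
#' Optionally also estimates the window-level false-positive rate: the
#' probability that a background window of the kind scanned by
#' [motif_fraction_at_summits()] (best score over both strands) reaches the
#' threshold by chance.
#'
#' @param x A [pwm()].
#' @param fpr Target single-site false-positive rate (default 0.001).
#' @param n Number of null draws.
#' @param window Optional half-window (bp); when given, the returned
#'   `window_fpr` is estimated from `n_windows` background windows of width
#'   `2 * window + L`.
#' @param n_windows Number of background windows for `window_fpr`.
#' @param seed RNG seed for the calibration draws.
#' @return List with `threshold` (bits), `fpr`, and (if `window` given)
#'   `window_fpr`.
#' @export
calibrate_pwm_threshold <- function(x, fpr = 0.001, n = 100000,
                                    window = NULL, n_windows = 2000,
                                    seed = 1L) {
  L <- pwm_length(x)
  with_seed(seed, {
    draws <- matrix(sample.int(4L, n * L, replace = TRUE,
                               prob = x$background), nrow = L)
    sc <- numeric(n)
    for (p in seq_len(L)) sc <- sc + x$log_odds[p, draws[p, ]]
    threshold <- unname(stats::quantile(sc, 1 - fpr, type = 1))
    out <- list(threshold = threshold, fpr = fpr)
    if (!is.null(window)) {
      wlen <- 2L * window + L
      hits <- vapply(seq_len(n_windows), function(i) {
        codes <- sample.int(4L, wlen, replace = TRUE, prob = x$background)
        max(score_positions(x$log_odds, codes),
            score_positions(pwm_revcomp_lo(x), codes)) >= threshold
      }, logical(1))
      out$window_fpr <- mean(hits)
    }
    out
  })
}

#' Best PWM site near a genomic position
#'
#' Scans every start position whose motif midpoint (`start + floor(L/2)`,
#' identical for both strands) lies within `center +/- window`, on both
#' strands, and returns the maximum log-odds site. Ties are broken by
#' smaller `|offset|`, then plus strand, then leftmost position. Windows
#' extending past the chromosome are clipped (reported via the `clipped`
#' field).
#'
#' @param x A [pwm()].
#' @param genome A [Biostrings::DNAStringSet].
#' @param chrom Chromosome name.
#' @param center 0-based position the scan window is anchored on.
#' @param window Half-window in bp (default 50, i.e. sites within 50 bp of
#'   the peak center).
#' @param threshold Minimum score for a hit; `-Inf` (default) always returns
#'   the best site.
#' @return List with `offset` (midpoint - center, bp), `position` (absolute
#'   0-based midpoint), `strand`, `score`, `clipped`; or `NULL` if the best
#'   score is below `threshold`.
#' @export
best_site <- function(x, genome, chrom, center, window = 50,
                      threshold = -Inf) {
  L <- pwm_length(x)
  mid_off <- L %/% 2L
  clen <- length(genome[[chrom]])
  s_min <- center - window - mid_off
  s_max <- center + window - mid_off
  clipped <- s_min < 0 || (s_max + L) > clen
  s_min <- max(s_min, 0L)
  s_max <- min(s_max, clen - L)
  if (s_max < s_min) return(NULL)
  region <- Biostrings::subseq(genome[[chrom]], start = s_min + 1L,
                               end = s_max + L)
  hits <- pwm_scan(x, region)
  hits$start <- hits$start + s_min            # absolute 0-based site start
  hits$position <- hits$start + mid_off
  hits$offset <- hits$position - center
  ord <- order(-hits$score, abs(hits$offset), hits$strand != "+", hits$offset)
  best <- hits[ord[1], ]
  if (best$score < threshold) return(NULL)
  list(offset = best$offset, position = best$position,
       strand = best$strand, score = best$score, clipped = clipped)
}
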