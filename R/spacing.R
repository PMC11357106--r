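# TF-cofactor binding-site spacing: signed distances between PWM-localized
# sites of two factors at shared peaks, compared with the analytic
# independence null (a triangular distribution) and classified as
# constrained, relaxed, or random.

#' Density of the independence null for signed spacings
#'
#' If two factors' sites are placed independently and uniformly within
#' `+/- W` of a common center, their signed distance `d = pos_B - pos_A`
#' follows the triangular density `f(d) = (2W - |d|) / (2W)^2` on
#' `[-2W, 2W]`. With `min_gap > 0` the null additionally conditions on the
#' two site footprints not overlapping (`|d| >= min_gap`, steric
#' exclusion), which truncates and renormalizes the triangle:
#' `f(d) = (2W - |d|) / (2W - g)^2` on `g <= |d| <= 2W`.
#'
#' @param d Signed distances (bp).
#' @param W Placement half-window (bp).
#' @param min_gap Minimum site separation (bp; 0 = unconstrained).
#' @return Density values.
#' @export
dtri_spacing <- function(d, W, min_gap = 0) {
  g <- min_gap
  ifelse(abs(d) <= 2 * W & abs(d) >= g,
         (2 * W - abs(d)) / (2 * W - g)^2, 0)
}

#' Distribution function of the independence null for signed spacings
#'
#' @param d Signed distances (bp).
#' @param W Placement half-window (bp).
#' @param min_gap Minimum site separation (bp; see [dtri_spacing()]).
#' @return `P(D <= d)` under the (possibly exclusion-truncated) triangular
#'   independence null.
#' @export
ptri_spacing <- function(d, W, min_gap = 0) {
  g <- min_gap
  dd <- pmax(pmin(d, 2 * W), -2 * W)
  ifelse(dd <= -g,
         (dd + 2 * W)^2 / (2 * (2 * W - g)^2),
         ifelse(dd < g, 0.5,
                1 - (2 * W - dd)^2 / (2 * (2 * W - g)^2)))
}

#' Signed spacing distribution of two factors at shared peaks
#'
#' Shared peaks are A/B peak pairs with any-bp interval overlap; each A peak
#' is matched to at most one B peak (nearest summit, one-to-one, greedy by
#' increasing summit distance). For every matched pair both PWMs are
#' localized with [best_site()] within `+/- window` of the pair's common
#' anchor (the midpoint of the two summits), and
#' `d = position_B - position_A` is recorded. Pairs where either factor has
#' no site above its threshold are dropped and counted.
#'
#' @param peaks_a,peaks_b Peak tables.
#' @param pwm_a,pwm_b [pwm()]s of the two factors.
#' @param genome A [Biostrings::DNAStringSet].
#' @param window Half-window for site localization (default 50 bp from the
#'   peak center).
#' @param threshold_a,threshold_b Minimum site scores (default `-Inf`: the
#'   best site always counts).
#' @param factor_a,factor_b Factor names.
#' @return Object of class `spacing_distribution`: `d` (signed bp), factor
#'   names, `n_pairs`, `window`, `n_dropped`.
#' @export
pairwise_spacing <- function(peaks_a, peaks_b, pwm_a, pwm_b, genome,
                             window = 50, threshold_a = -Inf,
                             threshold_b = -Inf,
                             factor_a = "A", factor_b = "B") {
  sa <- peak_summits(peaks_a)
  sb <- peak_summits(peaks_b)
  pairs <- list()
  for (chr in unique(peaks_a$chrom)) {
    ai <- which(peaks_a$chrom == chr)
    bi <- which(peaks_b$chrom == chr)
    if (length(bi) == 0) next
    ov <- IRanges::findOverlaps(
      as_iranges0(peaks_a$start[ai], peaks_a$end[ai]),
      as_iranges0(peaks_b$start[bi], peaks_b$end[bi])
    )
    if (length(ov) == 0) next
    a <- ai[S4Vectors::queryHits(ov)]
    b <- bi[S4Vectors::subjectHits(ov)]
    pairs[[chr]] <- data.frame(a = a, b = b, dist = abs(sa[a] - sb[b]))
  }
  if (length(pairs) == 0) stopf("the two peak sets share no peaks")
  pairs <- do.call(rbind, pairs)
  # One-to-one matching, nearest summits first (deterministic tie order).
  pairs <- pairs[order(pairs$dist, pairs$a, pairs$b), ]
  keep <- !duplicated(pairs$a) & !duplicated(pairs$b)
  pairs <- pairs[keep, ]

  d <- integer(0)
  dropped <- 0L
  for (i in seq_len(nrow(pairs))) {
    ai <- pairs$a[i]; bi <- pairs$b[i]
    anchor <- (sa[ai] + sb[bi]) %/% 2L
    site_a <- best_site(pwm_a, genome, peaks_a$chrom[ai], anchor,
                        window = window, threshold = threshold_a)
    site_b <- best_site(pwm_b, genome, peaks_b$chrom[bi], anchor,
                        window = window, threshold = threshold_b)
    if (is.null(site_a) || is.null(site_b)) {
      dropped <- dropped + 1L
      next
    }
    d <- c(d, site_b$position - site_a$position)
  }
  structure(list(d = d, factor_a = factor_a, factor_b = factor_b,
                 n_pairs = length(d), window = window, n_dropped = dropped),
            class = "spacing_distribution")
}

#' Construct a spacing distribution from raw distances
#'
#' Mostly useful for simulations and for re-analyzing externally computed
#' spacings.
#'
#' @param d Signed distances (bp).
#' @param window Placement half-window (bp).
#' @param factor_a,factor_b Factor names.
#' @param n_dropped Pairs dropped during localization.
#' @return A `spacing_distribution`.
#' @export
spacing_distribution <- function(d, window, factor_a = "A", factor_b = "B",
                                 n_dropped = 0L) {
  structure(list(d = d, factor_a = factor_a, factor_b = factor_b,
                 n_pairs = length(d), window = window,
                 n_dropped = as.integer(n_dropped)),
            class = "spacing_distribution")
}

#' @export
print.spacing_distribution <- function(x, ...) {
  cat(sprintf(paste0("spacing %s-%s: n = %d pairs (%d dropped), window ",
                     "+/- %d bp, mean %.2f, sd %.2f\n"),
              x$factor_a, x$factor_b, x$n_pairs, x$n_dropped, x$window,
              mean(x$d), stats::sd(x$d)))
  invisible(x)
}

#' Kolmogorov-Smirnov comparison of spacing distributions
#'
#' Two-sample KS when both arguments are empirical distributions; one-sample
#' KS against the analytic triangular independence null (half-window
#' `null_W`) when `dist_2` is NULL. P-values use the asymptotic
#' distribution (`exact = FALSE`); distances sit on a 1-bp lattice, so ties
#' are expected and the tie warning is suppressed.
#'
#' @param dist_1 A `spacing_distribution`.
#' @param dist_2 A second `spacing_distribution`, or NULL to test against
#'   the independence null.
#' @param null_W Half-window of the analytic null (defaults to
#'   `dist_1$window`).
#' @param min_gap Steric-exclusion gap of the analytic null (bp; see
#'   [dtri_spacing()]).
#' @return List with `statistic` (D), `p_value`, `method`.
#' @export
spacing_ks <- function(dist_1, dist_2 = NULL, null_W = NULL, min_gap = 0) {
  if (length(dist_1$d) < 8) stopf("need at least 8 spacings per sample")
  if (!is.null(dist_2)) {
    if (length(dist_2$d) < 8) stopf("need at least 8 spacings per sample")
    kt <- suppressWarnings(stats::ks.test(dist_1$d, dist_2$d,
                                          exact = FALSE))
    method <- "two-sample KS"
  } else {
    W <- null_W %||% dist_1$window
    kt <- suppressWarnings(stats::ks.test(
      dist_1$d, function(q) ptri_spacing(q, W, min_gap), exact = FALSE))
    method <- sprintf("one-sample KS vs triangular null (W = %g, gap = %g)",
                      W, min_gap)
  }
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       method = method)
}

#' Classify a spacing distribution as constrained, relaxed, or random
#'
#' The distribution is "random" if a one-sample KS test against the
#' triangular independence null is not rejected at `alpha`. Otherwise a
#' Gaussian kernel density is fitted, and the central peak's half-width at
#' half-maximum decides between "constrained" (`<= constrained_halfwidth`,
#' default 10 bp: the sites keep a fixed spacing) and "relaxed" (a broad
#' but non-flat preference).
#'
#' @param dist A `spacing_distribution` with n >= 30.
#' @param null_W Half-window of the independence null (defaults to
#'   `dist$window`).
#' @param alpha KS significance level (default 0.01).
#' @param constrained_halfwidth Half-width threshold in bp (default 10).
#' @param min_gap Steric-exclusion gap of the independence null (bp).
#' @return List with `class`, `ks` (see [spacing_ks()]), `mode` (bp),
#'   `halfwidth` (bp, NA when random).
#' @export
classify_spacing <- function(dist, null_W = NULL, alpha = 0.01,
                             constrained_halfwidth = 10, min_gap = 0) {
  if (length(dist$d) < 30) stopf("need at least 30 spacings to classify")
  ks <- spacing_ks(dist, null_W = null_W, min_gap = min_gap)
  if (ks$p_value >= alpha) {
    return(list(class = "random", ks = ks, mode = NA_real_,
                halfwidth = NA_real_))
  }
  den <- stats::density(dist$d)
  imode <- which.max(den$y)
  half <- den$y[imode] / 2
  above <- den$y >= half
  # contiguous above-half region containing the mode
  left <- imode
  while (left > 1 && above[left - 1]) left <- left - 1
  right <- imode
  while (right < length(above) && above[right + 1]) right <- right + 1
  hw <- (den$x[right] - den$x[left]) / 2
  cls <- if (hw <= constrained_halfwidth) "constrained" else "relaxed"
  list(class = cls, ks = ks, mode = den$x[imode], halfwidth = hw)
}
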