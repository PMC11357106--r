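# Synthetic-data generators with planted ground truth. Every generator is a
# pure function of its parameters and seed, and emits a machine-readable
# truth table alongside the data, so downstream tests can verify recovery
# against the truth rather than against constants.

#' Generate a random genome
#'
#' I.i.d. uniform ACGT sequence per chromosome.
#'
#' @param chrom_lengths Named integer vector of lengths (>= 10 kb each).
#' @param seed RNG seed.
#' @return A [Biostrings::DNAStringSet].
#' @export
make_genome <- function(chrom_lengths, seed = NULL) {
  if (any(chrom_lengths < 10000)) {
    stopf("simulated chromosomes must be >= 10 kb")
  }
  with_seed(seed, {
    seqs <- vapply(chrom_lengths, function(L) {
      paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
    }, character(1))
    Biostrings::DNAStringSet(stats::setNames(seqs, names(chrom_lengths)))
  })
}

#' Demo PWMs for the simulated factor pair
#'
#' Factor A carries the G-box hexamer CACGTG (the E-box variant bound by
#' many plant bHLHs); factor B carries an unrelated non-palindromic hexamer,
#' standing in for a cofactor with its own sequence preference. Both PWMs
#' are built from 20 identical consensus sites with pseudocount 0.25, giving
#' sharp columns (consensus base probability 0.964).
#'
#' @return List with elements `a` and `b` ([pwm()] objects).
#' @export
demo_pwms <- function() {
  list(a = pwm_from_sites(rep("CACGTG", 20)),
       b = pwm_from_sites(rep("CTTAGC", 20)))
}

# Place n non-overlapping peak slots across chromosomes. Returns a peak
# table; summits sit at the peak center.
place_peaks <- function(chrom_lengths, n_peaks, peak_width, slot_width,
                        prefix = "peak") {
  capacity <- floor(chrom_lengths / slot_width)
  if (sum(capacity) < n_peaks) {
    stopf("genome too small for %d peaks (capacity %d)", n_peaks,
          sum(capacity))
  }
  # proportional allocation, then round-robin the remainder
  alloc <- floor(capacity / sum(capacity) * n_peaks)
  while (sum(alloc) < n_peaks) {
    i <- which.max(capacity - alloc)
    alloc[i] <- alloc[i] + 1L
  }
  rows <- lapply(seq_along(chrom_lengths), function(ci) {
    k <- alloc[ci]
    if (k == 0) return(NULL)
    slots <- sort(sample.int(capacity[ci], k))
    start <- (slots - 1L) * slot_width + (slot_width - peak_width) %/% 2L
    data.frame(chrom = names(chrom_lengths)[ci], start = start,
               end = start + peak_width, stringsAsFactors = FALSE)
  })
  pk <- do.call(rbind, rows)
  peak_set(pk$chrom, pk$start, pk$end,
           name = sprintf("%s_%04d", prefix, seq_len(nrow(pk))),
           fold_enrichment = round(2 + stats::rexp(nrow(pk), 1 / 4), 3),
           neg_log10_q = round(6 + stats::rexp(nrow(pk), 1 / 10), 3),
           summit_offset = peak_width %/% 2L)
}

# Replace chance exact-consensus occurrences (both strands, both factors)
# inside a region with a point mutation, skipping planted footprints.
# Keeps the planted site the unambiguous ground truth of the scan window.
scrub_region <- function(chars, s0, e0, consensi, protected) {
  region <- substr(chars, s0 + 1L, e0)
  pats <- unique(unlist(lapply(consensi, function(cs) {
    c(cs, as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(cs))))
  })))
  for (pass in 1:3) {
    changed <- FALSE
    for (pat in pats) {
      m <- gregexpr(pat, region, fixed = TRUE)[[1]]
      if (m[1] == -1) next
      for (pos in as.integer(m)) {
        abs_start <- s0 + pos - 1L            # 0-based
        if (any(abs_start == protected$start)) next  # the planted site itself
        # mutate a base of the chance match that lies outside every planted
        # footprint, preferring positions near the middle of the match
        L <- nchar(pat)
        ord <- order(abs(seq_len(L) - (L %/% 2L + 1L)))
        for (k in ord) {
          abs_k <- abs_start + k - 1L
          if (any(abs_k >= protected$start & abs_k < protected$end)) next
          old <- substr(region, pos + k - 1L, pos + k - 1L)
          new <- DNA_BASES[match(old, DNA_BASES) %% 4L + 1L]
          substr(region, pos + k - 1L, pos + k - 1L) <- new
          changed <- TRUE
          break
        }
      }
    }
    if (!changed) break
  }
  substr(chars, s0 + 1L, e0) <- region
  chars
}

#' Plant peak sets with motifs at known offsets
#'
#' Writes factor A's consensus motif into the genome near each peak summit
#' and, at shared peaks, factor B's motif at a position that is either
#' constrained (`B = A + delta + round(Normal(0, sigma))`) or independent
#' (uniform within the placement window). Both peak sets use the same
#' intervals (fully shared peaks). Offsets are motif midpoints relative to
#' the summit. Two distinct motifs cannot occupy overlapping footprints in
#' one sequence, so a draw that would collide them is re-drawn (bounded
#' retries; steric exclusion). In independent mode the resulting spacing
#' therefore follows the exclusion-truncated triangular null (see
#' [dtri_spacing()] with `min_gap` as reported in the output). Chance
#' occurrences of either consensus inside the scan windows are disrupted by
#' a point mutation so that the planted site is the unique ground truth.
#'
#' @param genome A [Biostrings::DNAStringSet] (modified copy is returned).
#' @param pwm_a,pwm_b [pwm()]s; consensus sequences are planted.
#' @param n_peaks Number of peaks.
#' @param peak_width Peak interval width (bp).
#' @param mode `"constrained"` or `"independent"` B placement.
#' @param delta Constrained spacing (bp).
#' @param sigma Constrained spacing jitter sd (bp).
#' @param window Scan half-window (bp); placements stay within
#'   `window - 5` bp of the summit so motif footprints fit the window.
#' @param motif_prob_a,motif_prob_b Probability that each factor's motif is
#'   planted at a given peak (1 = every peak).
#' @param max_retries Bounded retries for colliding constrained draws.
#' @param seed RNG seed.
#' @return List: `genome` (with motifs written), `peaks_a`, `peaks_b`,
#'   `truth` (per peak: offsets, absolute midpoints, planted flags, spacing
#'   d), `placement_halfwidth` (bp; the `W` of the matching triangular
#'   null), and `min_gap` (bp; the steric-exclusion gap of that null).
#' @export
plant_peaks <- function(genome, pwm_a, pwm_b = NULL, n_peaks = 500,
                        peak_width = 200,
                        mode = c("constrained", "independent"),
                        delta = 10, sigma = 2, window = 50,
                        motif_prob_a = 1, motif_prob_b = 1,
                        max_retries = 100, seed = NULL) {
  mode <- match.arg(mode)
  lens <- chrom_lengths(genome)
  la <- pwm_length(pwm_a)
  lb <- if (!is.null(pwm_b)) pwm_length(pwm_b) else 0L
  cons_a <- pwm_consensus(pwm_a)
  cons_b <- if (!is.null(pwm_b)) pwm_consensus(pwm_b) else NULL
  half <- window - 5L                       # placement half-width
  slot <- peak_width + 2L * (window + max(la, lb)) + 20L

  with_seed(seed, {
    peaks <- place_peaks(lens, n_peaks, peak_width, slot)
    summit <- peak_summits(peaks)
    n <- nrow(peaks)
    a_planted <- stats::runif(n) < motif_prob_a
    b_planted <- if (is.null(pwm_b)) rep(FALSE, n)
                 else stats::runif(n) < motif_prob_b
    a_off <- rep(NA_integer_, n)
    b_off <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      if (a_planted[i]) {
        if (mode == "constrained" && b_planted[i]) {
          lo <- -half + 10L
          hi <- half - 10L - as.integer(delta)
          a_off[i] <- lo + as.integer(floor(stats::runif(1) * (hi - lo + 1L)))
          ok <- FALSE
          for (r in seq_len(max_retries)) {
            cand <- a_off[i] + as.integer(delta) +
              as.integer(round(stats::rnorm(1, 0, sigma)))
            gap <- abs(cand - a_off[i])
            # coincident placement is fine when the two factors share one
            # consensus (a heterodimer reading a single common motif)
            compatible <- gap >= max(la, lb) ||
              (gap == 0L && identical(cons_a, cons_b))
            if (compatible && abs(cand) <= half) {
              b_off[i] <- cand; ok <- TRUE; break
            }
          }
          if (!ok) stopf("could not place B's motif without collision at peak %d", i)
        } else {
          a_off[i] <- as.integer(floor(stats::runif(1) * (2L * half + 1L))) -
            half
          if (b_planted[i]) {
            for (r in seq_len(max_retries)) {
              cand <- as.integer(floor(stats::runif(1) * (2L * half + 1L))) -
                half
              if (abs(cand - a_off[i]) >= max(la, lb)) {
                b_off[i] <- cand
                break
              }
            }
            if (is.na(b_off[i])) stopf("could not place B's motif at peak %d", i)
          }
        }
      } else if (b_planted[i]) {
        b_off[i] <- as.integer(floor(stats::runif(1) * (2L * half + 1L))) - half
      }
    }

    chars <- as.character(genome)
    a_pos <- summit + a_off                  # motif midpoints (0-based)
    b_pos <- summit + b_off
    a_start <- a_pos - la %/% 2L
    b_start <- b_pos - lb %/% 2L
    for (chr in unique(peaks$chrom)) {
      idx <- which(peaks$chrom == chr)
      for (i in idx) {
        prot <- data.frame(start = integer(0), end = integer(0))
        if (a_planted[i]) {
          substr(chars[[chr]], a_start[i] + 1L, a_start[i] + la) <- cons_a
          prot <- rbind(prot, data.frame(start = a_start[i],
                                         end = a_start[i] + la))
        }
        if (b_planted[i]) {
          substr(chars[[chr]], b_start[i] + 1L, b_start[i] + lb) <- cons_b
          prot <- rbind(prot, data.frame(start = b_start[i],
                                         end = b_start[i] + lb))
        }
        chars[[chr]] <- scrub_region(
          chars[[chr]],
          max(summit[i] - window - max(la, lb), 0L),
          min(summit[i] + window + max(la, lb), lens[[chr]]),
          consensi = c(cons_a, cons_b),
          protected = prot
        )
      }
    }
    truth <- data.frame(name = peaks$name, chrom = peaks$chrom,
                        summit = summit,
                        a_planted = a_planted, b_planted = b_planted,
                        a_off = a_off, b_off = b_off,
                        a_pos = a_pos, b_pos = b_pos,
                        d = b_pos - a_pos, stringsAsFactors = FALSE)
    peaks_b <- peaks
    peaks_b$name <- sub("^peak", "peakB", peaks_b$name)
    list(genome = Biostrings::DNAStringSet(chars),
         peaks_a = peaks, peaks_b = peaks_b, truth = truth,
         placement_halfwidth = half,
         min_gap = if (is.null(pwm_b)) 0L else max(la, lb))
  })
}

# Expected per-bin signal: background plus Gaussian bumps.
bump_lambda <- function(centers, chrom_lengths, bin_size, sigma, background) {
  lam <- lapply(chrom_lengths, function(L) {
    rep(as.numeric(background), ceiling(L / bin_size))
  })
  names(lam) <- names(chrom_lengths)
  reach <- ceiling(4 * sigma / bin_size)
  for (i in seq_len(nrow(centers))) {
    chr <- centers$chrom[i]
    v <- lam[[chr]]
    cb <- centers$center[i] %/% bin_size + 1L
    bins <- max(1L, cb - reach):min(length(v), cb + reach)
    mid <- (bins - 1L) * bin_size + bin_size / 2
    v[bins] <- v[bins] + centers$amplitude[i] *
      exp(-(mid - centers$center[i])^2 / (2 * sigma^2))
    lam[[chr]] <- v
  }
  lam
}

#' Simulate a signal track with Gaussian bumps
#'
#' Each row of `centers` contributes a Gaussian bump (sd `sigma`) of the
#' given peak amplitude on top of a flat background; per-bin values are
#' Poisson draws around the expected signal (or the expectation itself with
#' `noise = "none"`).
#'
#' @param centers data.frame with columns chrom, center (bp), amplitude.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param bin_size Bin width (bp).
#' @param sigma Bump sd in bp (positional fuzziness).
#' @param background Flat background level per bin.
#' @param noise `"poisson"` or `"none"`.
#' @param seed RNG seed.
#' @return A [signal_track()].
#' @export
simulate_signal_track <- function(centers, chrom_lengths, bin_size = 10,
                                  sigma = 20, background = 0,
                                  noise = c("poisson", "none"),
                                  seed = NULL) {
  noise <- match.arg(noise)
  lam <- bump_lambda(centers, chrom_lengths, bin_size, sigma, background)
  values <- with_seed(seed, {
    lapply(lam, function(v) {
      if (noise == "poisson") as.numeric(stats::rpois(length(v), v)) else v
    })
  })
  signal_track(values, bin_size, chrom_lengths)
}

#' Simulate mock and induced nucleosome occupancy tracks
#'
#' Plants regularly spaced nucleosomes (centers jittered, minimum spacing
#' respected) as Gaussian bumps of positional fuzziness `fuzziness` on a
#' flat background, with Poisson per-bin noise. A random `target_fraction`
#' of nucleosomes is designated as remodeling targets: in the induced track
#' the expected occupancy over `+/- depletion_halfwidth` of the target dyad
#' is multiplied by `depletion` (0.5 emulates a 2-fold loss of nucleosome
#' occupancy upon induction of the remodeling factor). Both tracks draw
#' their noise from the same stream, so `depletion = 1` yields
#' byte-identical tracks.
#'
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param n_nucleosomes Number of planted nucleosomes.
#' @param spacing Center-to-center spacing (bp; must be >= 167). The
#'   default keeps adjacent nucleosomes far enough apart that one
#'   nucleosome's depletion window cannot bleed into its neighbor's
#'   analysis region (planted units stay independent).
#' @param jitter Uniform center jitter, +/- bp.
#' @param fuzziness Bump sd (bp).
#' @param amplitude Bump peak amplitude (expected counts per bin at the
#'   dyad).
#' @param background Flat background (expected counts per bin).
#' @param bin_size Track bin width (bp).
#' @param depletion Occupancy multiplier at target sites in the induced
#'   condition (0.5 = 50% depletion).
#' @param depletion_halfwidth Half-width of the depleted window around the
#'   target dyad (bp; default 250, the default analysis window of
#'   [differential_occupancy()] region sets).
#' @param target_fraction Fraction of nucleosomes that are targets.
#' @param noise `"poisson"` or `"none"`.
#' @param seed RNG seed.
#' @return List: `mock`, `induced` ([signal_track()]s), `truth` (data.frame:
#'   name, chrom, center, is_target), and `params`.
#' @export
simulate_occupancy <- function(chrom_lengths = c(chrSim = 800000L),
                               n_nucleosomes = 1000, spacing = 700,
                               jitter = 50, fuzziness = 20, amplitude = 25,
                               background = 5, bin_size = 10,
                               depletion = 0.5, depletion_halfwidth = 250L,
                               target_fraction = 0.1,
                               noise = c("poisson", "none"), seed = NULL) {
  noise <- match.arg(noise)
  if (spacing < 167) stopf("spacing must keep nucleosomes >= 167 bp apart")
  if (spacing - 2 * jitter < 167) {
    stopf("jitter too large for the requested spacing")
  }
  with_seed(seed, {
    capacity <- floor((chrom_lengths - spacing) / spacing)
    if (sum(capacity) < n_nucleosomes) {
      stopf("genome too small for %d nucleosomes", n_nucleosomes)
    }
    rows <- list()
    left <- n_nucleosomes
    for (chr in names(chrom_lengths)) {
      k <- min(left, capacity[[chr]])
      if (k == 0) next
      base <- spacing %/% 2L + (seq_len(k) - 1L) * spacing
      ctr <- base + as.integer(floor(stats::runif(k) * (2L * jitter + 1L))) -
        jitter
      rows[[chr]] <- data.frame(chrom = chr, center = ctr,
                                stringsAsFactors = FALSE)
      left <- left - k
    }
    centers <- do.call(rbind, rows)
    centers$amplitude <- amplitude
    centers$name <- sprintf("nuc_%05d", seq_len(nrow(centers)))
    centers$is_target <- FALSE
    centers$is_target[sample.int(nrow(centers),
                                 round(target_fraction * nrow(centers)))] <- TRUE

    lam_mock <- bump_lambda(centers, chrom_lengths, bin_size, fuzziness,
                            background)
    lam_ind <- lam_mock
    for (i in which(centers$is_target)) {
      chr <- centers$chrom[i]
      b0 <- max(1L, (centers$center[i] - depletion_halfwidth) %/% bin_size + 1L)
      b1 <- min(length(lam_ind[[chr]]),
                (centers$center[i] + depletion_halfwidth) %/% bin_size + 1L)
      lam_ind[[chr]][b0:b1] <- lam_ind[[chr]][b0:b1] * depletion
    }
    draw <- function(lam, sub_seed) {
      values <- with_seed(sub_seed, {
        lapply(lam, function(v) {
          if (noise == "poisson") as.numeric(stats::rpois(length(v), v))
          else v
        })
      })
      signal_track(values, bin_size, chrom_lengths)
    }
    sub_seed <- sample.int(.Machine$integer.max, 1)
    list(mock = draw(lam_mock, sub_seed),
         induced = draw(lam_ind, sub_seed),
         truth = centers[, c("name", "chrom", "center", "is_target")],
         params = list(spacing = spacing, fuzziness = fuzziness,
                       amplitude = amplitude, background = background,
                       bin_size = bin_size, depletion = depletion,
                       depletion_halfwidth = depletion_halfwidth))
  })
}

#' Simulate a clustered single-cell count matrix
#'
#' Per cluster, gene probabilities follow a [two_tier_model()] (or the
#' uniform distribution), optionally modulated so that declared marker genes
#' reach a target fraction of expressing cells and log2 fold change in their
#' expressing cluster. Cells are multinomial draws at the given depth.
#'
#' Marker modulation is by closed-form moment matching under the Poisson
#' approximation to multinomial sampling: a target expressing fraction q at
#' depth N fixes the gene probability via `1 - exp(-N p) = q`, i.e.
#' `p_in = -log(1 - q)/N`, and the fold change fixes the probability outside
#' the expressing cluster as `p_out = p_in / 2^log2fc`.
#'
#' @param clusters Named list; each element is a list with `n_cells` and
#'   either `top_fraction`/`top_share` (two-tier) or nothing (uniform).
#' @param n_genes Genes in the shared universe.
#' @param depth Transcripts per cell.
#' @param markers Optional data.frame with columns gene (index), cluster,
#'   pct, log2fc.
#' @param seed RNG seed.
#' @return List: `em` ([expression_matrix()]), `truth_clusters` (cluster,
#'   n_cells, analytic entropy of the cluster's final gene distribution),
#'   `truth_markers` (intended pct/log2fc and the matched probabilities).
#' @export
simulate_counts <- function(clusters, n_genes = 1000, depth = 20000,
                            markers = NULL, seed = NULL) {
  stopifnot(length(clusters) >= 1, !is.null(names(clusters)))
  if (!is.null(markers)) {
    if (any(markers$pct >= 1 | markers$pct <= 0)) {
      stopf("marker pct targets must be in (0, 1)")
    }
    if (any(!markers$cluster %in% names(clusters))) {
      stopf("marker cluster(s) not among the declared clusters")
    }
  }
  probs <- lapply(clusters, function(cl) {
    if (is.null(cl$top_share)) {
      rep(1 / n_genes, n_genes)
    } else {
      two_tier_probs(two_tier_model(n_genes, cl$top_fraction %||% 0.10,
                                    cl$top_share))
    }
  })
  if (!is.null(markers)) {
    for (i in seq_len(nrow(markers))) {
      g <- markers$gene[i]
      p_in <- -log(1 - markers$pct[i]) / depth
      p_out <- p_in / 2^markers$log2fc[i]
      for (cl in names(clusters)) {
        probs[[cl]][g] <- if (cl == markers$cluster[i]) p_in else p_out
      }
    }
    probs <- lapply(probs, function(p) p / sum(p))
  }
  with_seed(seed, {
    mats <- lapply(names(clusters), function(cl) {
      t(stats::rmultinom(clusters[[cl]]$n_cells, depth, probs[[cl]]))
    })
    counts <- do.call(rbind, mats)
    labels <- rep(names(clusters),
                  vapply(clusters, function(cl) cl$n_cells, numeric(1)))
    em <- expression_matrix(
      counts, clusters = labels, cluster_levels = names(clusters),
      cell_ids = sprintf("cell_%05d", seq_len(nrow(counts))),
      gene_ids = sprintf("gene_%05d", seq_len(n_genes))
    )
    truth_clusters <- data.frame(
      cluster = names(clusters),
      n_cells = vapply(clusters, function(cl) cl$n_cells, numeric(1)),
      analytic_entropy = vapply(probs, function(p) -sum(p * log(p)),
                                numeric(1)),
      stringsAsFactors = FALSE
    )
    truth_markers <- if (is.null(markers)) NULL else {
      data.frame(gene_id = sprintf("gene_%05d", markers$gene),
                 cluster = markers$cluster, pct_target = markers$pct,
                 log2fc_target = markers$log2fc, stringsAsFactors = FALSE)
    }
    list(em = em, truth_clusters = truth_clusters,
         truth_markers = truth_markers)
  })
}
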