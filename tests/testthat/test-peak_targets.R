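# Peak integration: permutation overlap test, motif occurrence at summits,
# promoter-window annotation, marker statistics, target assignment.

test_that("permutation overlap test is seed-deterministic with bounded p", {
  lens <- c(chr1 = 5e4, chr2 = 3e4)
  q <- rand_peaks(40, lens, seed = 1)
  s <- rand_peaks(30, lens, seed = 2)
  a <- permutation_overlap_test(q, s, lens, n_perm = 200, seed = 9)
  b <- permutation_overlap_test(q, s, lens, n_perm = 200, seed = 9)
  expect_identical(a$null_counts, b$null_counts)
  expect_gte(a$empirical_p, 1 / 201)
  expect_lte(a$empirical_p, 1)
  expect_lte(a$observed_overlap, nrow(q))
})

test_that("a peak set maximally overlaps itself", {
  lens <- c(chr1 = 2e5)
  q <- rand_peaks(30, lens, width = 50, seed = 3)
  r <- permutation_overlap_test(q, q, lens, n_perm = 500, seed = 5)
  expect_equal(r$observed_overlap, nrow(q))
  # no permutation should beat a perfect self-overlap on a sparse genome
  expect_lte(r$empirical_p, 0.05)
})

test_that("single-interval case matches the closed-form placement probability", {
  # query [0, 100) on a 1000-bp chromosome: a re-placed 100-bp subject
  # (901 possible starts) overlaps iff start <= 99 -> P(hit) = 100/901.
  # With an overlapping observed placement (observed = 1) the empirical
  # p-value estimates exactly this placement probability.
  lens <- c(chr1 = 1000)
  q <- peak_set("chr1", 0, 100)
  s <- peak_set("chr1", 50, 150)
  r <- permutation_overlap_test(q, s, lens, n_perm = 4000, seed = 11)
  p0 <- 100 / 901
  mc_se <- sqrt(p0 * (1 - p0) / 4000)
  expect_lt(abs(r$empirical_p - p0), 3 * mc_se + 1 / 4001)
  # a disjoint observed placement is never beaten: p = 1
  rd <- permutation_overlap_test(q, peak_set("chr1", 600, 700), lens,
                                 n_perm = 200, seed = 12)
  expect_equal(rd$observed_overlap, 0)
  expect_equal(rd$empirical_p, 1)
  expect_error(
    permutation_overlap_test(q, peak_set("chr1", 0, 1000), c(chr1 = 900)),
    "exceeds"
  )
})

test_that("motif fraction is 1 when the consensus is planted at every summit", {
  g <- make_genome(c(chr1 = 1e5), seed = 7)
  pw <- demo_pwms()
  pp <- plant_peaks(g, pw$a, n_peaks = 40, motif_prob_a = 1, seed = 8)
  for (thr in c(pwm_max_score(pw$a), 5, NULL)) {
    mf <- motif_fraction_at_summits(pp$peaks_a, pw$a, pp$genome,
                                    window = 100, threshold = thr)
    expect_equal(mf$fraction, 1.0)
  }
})

test_that("motif fraction recovers a planted 50% subset", {
  g <- make_genome(c(chr1 = 4e5), seed = 17)
  pw <- demo_pwms()
  pp <- plant_peaks(g, pw$a, n_peaks = 300, motif_prob_a = 0.5, seed = 18)
  # threshold between the best 1-mismatch score and the consensus score:
  # planted consensus sites always hit, scrubbed background never does
  # (the generator scrubs chance consensus within its planting window)
  thr <- pwm_max_score(pw$a) - 0.5
  mf <- motif_fraction_at_summits(pp$peaks_a, pw$a, pp$genome,
                                  window = 50, threshold = thr)
  p_hat <- mean(pp$truth$a_planted)
  expect_equal(mf$fraction, p_hat, tolerance = 1e-12)
  # the planted fraction itself sits in the binomial 95% CI of 0.5
  expect_lt(abs(p_hat - 0.5), 1.96 * sqrt(0.25 / nrow(pp$truth)))
  # per-peak hits agree with the planting truth
  expect_equal(mf$hits$hit, pp$truth$a_planted)
})

test_that("background-only peaks hit at about the calibrated window rate", {
  g <- make_genome(c(chr1 = 6e5), seed = 27)
  lens <- chrom_lengths(g)
  pw <- demo_pwms()$a
  pk <- rand_peaks(400, lens, width = 200, seed = 28)
  cal <- calibrate_pwm_threshold(pw, fpr = 0.005, n = 2e5, window = 100,
                                 n_windows = 2000, seed = 29)
  mf <- motif_fraction_at_summits(pk, pw, g, window = 100,
                                  threshold = cal$threshold)
  # binomial 3-sigma band around the calibrated window-level FPR
  se <- sqrt(cal$window_fpr * (1 - cal$window_fpr) / 400)
  expect_lt(abs(mf$fraction - cal$window_fpr), 3 * se + 0.02)
})

test_that("peak-to-gene annotation honors the promoter-window boundaries", {
  gm <- data.frame(gene_id = "gA", chrom = "chr1", start = 10000L,
                   end = 12000L, strand = "+", tss = 10000L, tes = 11999L)
  mk <- function(summit) peak_set("chr1", summit - 10L, summit + 10L,
                                  summit_offset = 10L)
  # summit exactly at the TSS -> assigned
  expect_equal(annotate_peaks_to_genes(mk(10000L), gm)$gene_id, "gA")
  # 3000 bp upstream -> assigned; 3001 -> not
  expect_equal(annotate_peaks_to_genes(mk(7000L), gm)$gene_id, "gA")
  expect_true(is.na(annotate_peaks_to_genes(mk(6999L), gm)$gene_id))
  # inside the body but downstream of the TSS -> assigned (gene body rule)
  expect_equal(annotate_peaks_to_genes(mk(11500L), gm)$gene_id, "gA")
  # just downstream of the body -> not
  expect_true(is.na(annotate_peaks_to_genes(mk(12001L), gm)$gene_id))
  # minus-strand gene: upstream is to the right of the TSS
  gmm <- data.frame(gene_id = "gB", chrom = "chr1", start = 10000L,
                    end = 12000L, strand = "-", tss = 11999L, tes = 10000L)
  expect_equal(annotate_peaks_to_genes(mk(14999L), gmm)$gene_id, "gB")
  expect_true(is.na(annotate_peaks_to_genes(mk(15000L), gmm)$gene_id))
})

test_that("annotation agrees with an exhaustive all-pairs oracle", {
  lens <- c(chr1 = 6e4, chr2 = 4e4)
  gm <- rand_genes(20, lens, len = 800, seed = 51)
  pk <- rand_peaks(50, lens, width = 120, seed = 52)
  ann <- annotate_peaks_to_genes(pk, gm, max_distance = 3000)
  summit <- peak_summits(pk)
  for (i in seq_len(nrow(pk))) {
    best <- NA_character_
    bestd <- Inf
    for (j in seq_len(nrow(gm))) {
      if (pk$chrom[i] != gm$chrom[j]) next
      s <- summit[i]
      in_body <- s >= gm$start[j] && s < gm$end[j]
      updist <- if (gm$strand[j] == "+") gm$tss[j] - s else s - gm$tss[j]
      in_prom <- updist >= 1 && updist <= 3000
      if (!in_body && !in_prom) next
      d <- abs(s - gm$tss[j])
      if (d < bestd || (d == bestd && gm$gene_id[j] < best)) {
        best <- gm$gene_id[j]
        bestd <- d
      }
    }
    expect_identical(ann$gene_id[i], best)
  }
})

test_that("marker statistics match a brute-force computation", {
  set.seed(61)
  counts <- matrix(rpois(20 * 30, 1.5), 20, 30)
  counts[, 1] <- rbinom(20, 1, 0.5) * rpois(20, 3)
  counts[rowSums(counts) == 0, 2] <- 1
  em <- expression_matrix(counts, clusters = rep("c", 20))
  ms <- marker_stats(em, em$gene_ids[1])
  grp <- counts[, 1] >= 1
  depth <- rowSums(counts)
  cp10k <- counts / depth * 1e4
  for (j in sample(30, 10)) {
    m_in <- mean(cp10k[grp, j])
    m_out <- mean(cp10k[!grp, j])
    expect_equal(ms$log2fc[j], log2((m_in + 1e-4) / (m_out + 1e-4)),
                 tolerance = 1e-12)
    expect_equal(ms$pct_expressing[j], mean(counts[grp, j] >= 1),
                 tolerance = 1e-12)
  }
  # identical group means -> log2fc exactly 0 (gene 3 balances the depth)
  cc <- matrix(2, 10, 3)
  cc[1:5, 1] <- 0
  cc[6:10, 3] <- 0  # both groups have total depth 4
  emc <- expression_matrix(cc, clusters = rep("c", 10))
  msc <- marker_stats(emc, emc$gene_ids[1])
  expect_equal(msc$log2fc[2], 0)
  expect_equal(msc$pct_expressing[2], 1)
  expect_error(marker_stats(emc, "nope"), "not in the matrix")
})

test_that("target assignment applies inclusive thresholds", {
  stats <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    pct_expressing = c(0.25, 0.24, 0.9, 0.9),
    log2fc = c(0.223, 0.5, 0.223 - 1e-9, 0.5)
  )
  ann <- data.frame(name = c("p1", "p2", "p3"),
                    gene_id = c("g1", "g2", "g3"))
  tg <- assign_targets(stats, ann)
  # exactly at both thresholds with a binding site -> target
  expect_true(tg$is_target[tg$gene_id == "g1"])
  # pct below threshold -> not
  expect_false(tg$is_target[tg$gene_id == "g2"])
  # log2fc below threshold -> not
  expect_false(tg$is_target[tg$gene_id == "g3"])
  # no binding site -> not, despite passing stats
  expect_false(tg$is_target[tg$gene_id == "g4"])
})

test_that("target assignment equals a brute-force filter and is monotone", {
  set.seed(71)
  stats <- data.frame(
    gene_id = sprintf("g%03d", 1:200),
    pct_expressing = round(runif(200), 2),
    log2fc = round(rnorm(200, 0.2, 0.5), 3)
  )
  # make boundary cases present
  stats$pct_expressing[1:5] <- 0.25
  stats$log2fc[1:5] <- 0.223
  bound_genes <- sample(stats$gene_id, 120)
  ann <- data.frame(name = sprintf("p%03d", seq_along(bound_genes)),
                    gene_id = bound_genes)
  tg <- assign_targets(stats, ann)
  brute <- character(0)
  for (i in 1:200) {
    if (stats$pct_expressing[i] >= 0.25 && stats$log2fc[i] >= 0.223 &&
        stats$gene_id[i] %in% bound_genes) {
      brute <- c(brute, stats$gene_id[i])
    }
  }
  expect_setequal(tg$gene_id[tg$is_target], brute)
  # raising either threshold never adds a target
  t2 <- assign_targets(stats, ann, min_pct = 0.4)
  t3 <- assign_targets(stats, ann, min_log2fc = 0.5)
  expect_true(all(tg$is_target | !t2$is_target))
  expect_true(all(tg$is_target | !t3$is_target))
})
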