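# The generators themselves: determinism, composition, planted ground
# truth, and validity of emitted files as inputs to the readers.

test_that("genome generation is deterministic with uniform composition", {
  g1 <- make_genome(c(chr1 = 100000), seed = 2)
  g2 <- make_genome(c(chr1 = 100000), seed = 2)
  expect_identical(as.character(g1), as.character(g2))
  comp <- Biostrings::alphabetFrequency(g1[[1]])[c("A", "C", "G", "T")]
  # binomial 4-sigma band around 0.25 at n = 1e5
  expect_true(all(abs(comp / 100000 - 0.25) < 4 * sqrt(0.25 * 0.75 / 1e5)))
  # GC is strand-symmetric
  rc <- Biostrings::reverseComplement(g1[[1]])
  gc <- function(x) sum(Biostrings::alphabetFrequency(x)[c("C", "G")])
  expect_equal(gc(g1[[1]]), gc(rc))
  expect_error(make_genome(c(chr1 = 500)), ">= 10 kb")
})

test_that("planting is deterministic and internally consistent", {
  g <- make_genome(c(chr1 = 150000, chr2 = 100000), seed = 3)
  pw <- demo_pwms()
  p1 <- plant_peaks(g, pw$a, pw$b, n_peaks = 150, seed = 4)
  p2 <- plant_peaks(g, pw$a, pw$b, n_peaks = 150, seed = 4)
  expect_identical(as.character(p1$genome), as.character(p2$genome))
  expect_identical(p1$truth, p2$truth)
  # truth-table identities
  tr <- p1$truth
  expect_equal(tr$a_pos, tr$summit + tr$a_off)
  expect_equal(tr$d, tr$b_pos - tr$a_pos)
  expect_true(all(abs(tr$a_off) <= p1$placement_halfwidth))
  expect_true(all(abs(tr$b_off) <= p1$placement_halfwidth))
  # the planted consensus is really in the sequence
  chars <- as.character(p1$genome)
  for (i in sample(nrow(tr), 10)) {
    s0 <- tr$a_pos[i] - 3L
    expect_equal(substr(chars[[tr$chrom[i]]], s0 + 1, s0 + 6), "CACGTG")
  }
})

test_that("a zero-jitter dimer plants a point mass at delta", {
  g <- make_genome(c(chr1 = 100000), seed = 5)
  pw <- demo_pwms()
  # two factors reading the same motif (heterodimer on one shared site):
  # delta 0, sigma 0 recovers a point mass at 0
  pp <- plant_peaks(g, pw$a, pw$a, n_peaks = 80, mode = "constrained",
                    delta = 0, sigma = 0, seed = 6)
  sp <- pairwise_spacing(pp$peaks_a, pp$peaks_b, pw$a, pw$a, pp$genome)
  expect_true(all(sp$d == 0L))
  # distinct motifs at a fixed spacing are exact as well
  pp <- plant_peaks(g, pw$a, pw$b, n_peaks = 80, mode = "constrained",
                    delta = 20, sigma = 0, seed = 6)
  expect_true(all(pp$truth$d == 20))
})

test_that("constrained spacing is recovered end to end", {
  g <- make_genome(c(chr1 = 200000), seed = 7)
  pw <- demo_pwms()
  pp <- plant_peaks(g, pw$a, pw$b, n_peaks = 200, mode = "constrained",
                    delta = 10, sigma = 2, seed = 8)
  sp <- pairwise_spacing(pp$peaks_a, pp$peaks_b, pw$a, pw$b, pp$genome)
  expect_lt(abs(mean(sp$d) - 10), 0.5)
  expect_lt(abs(sd(sp$d) - 2), 0.7)
  # recovered distances equal the planted ones
  expect_equal(sort(sp$d), sort(pp$truth$d))
})

test_that("independent placement reproduces its exclusion-truncated null", {
  g <- make_genome(c(chr1 = 400000), seed = 9)
  pw <- demo_pwms()
  pp <- plant_peaks(g, pw$a, pw$b, n_peaks = 500, mode = "independent",
                    seed = 10)
  sp <- pairwise_spacing(pp$peaks_a, pp$peaks_b, pw$a, pw$b, pp$genome)
  # no footprint overlaps by construction, and recovery is exact
  expect_true(all(abs(sp$d) >= pp$min_gap))
  expect_equal(sort(sp$d), sort(pp$truth$d))
  ks <- spacing_ks(sp, null_W = pp$placement_halfwidth,
                   min_gap = pp$min_gap)
  expect_lt(ks$statistic, 0.08)
  expect_gt(ks$p_value, 0.01)
})

test_that("occupancy simulation is reproducible and respects depletion = 1", {
  o1 <- simulate_occupancy(c(chrSim = 120000), n_nucleosomes = 160,
                           depletion = 1.0, seed = 11)
  o2 <- simulate_occupancy(c(chrSim = 120000), n_nucleosomes = 160,
                           depletion = 1.0, seed = 11)
  expect_identical(o1$mock$values, o2$mock$values)
  # equal seeds and no depletion: the two conditions are identical
  expect_identical(o1$mock$values, o1$induced$values)
  # with depletion, only target neighborhoods change
  o3 <- simulate_occupancy(c(chrSim = 120000), n_nucleosomes = 160,
                           depletion = 0.5, seed = 11)
  expect_false(identical(o3$mock$values, o3$induced$values))
  expect_error(simulate_occupancy(spacing = 150), ">= 167")
})

test_that("noise-free occupancy recovers every planted dyad within a bin", {
  occ <- simulate_occupancy(c(chrSim = 150000), n_nucleosomes = 200,
                            noise = "none", seed = 12)
  calls <- call_nucleosomes(occ$mock)
  expect_equal(nrow(calls), 200)
  expect_lte(max(abs(sort(calls$center) - sort(occ$truth$center))), 10)
})

test_that("simulated clusters reach their analytic entropies and ordering", {
  cs <- simulate_counts(
    clusters = list(uniform = list(n_cells = 60),
                    tier40 = list(n_cells = 60, top_fraction = 0.1,
                                  top_share = 0.4),
                    tier50 = list(n_cells = 60, top_fraction = 0.1,
                                  top_share = 0.5)),
    n_genes = 800, depth = 30000, seed = 13
  )
  ent <- entropy_by_cluster(cs$em)
  med <- ent$clusters$entropy_median
  names(med) <- ent$clusters$cluster
  expect_equal(unname(med["uniform"]), log(800), tolerance = 0.01)
  tr <- cs$truth_clusters
  for (cl in tr$cluster) {
    expect_equal(unname(med[cl]),
                 tr$analytic_entropy[tr$cluster == cl], tolerance = 0.02)
  }
  # stronger concentration -> lower entropy (0.5 < 0.4 < uniform)
  expect_lt(med["tier50"], med["tier40"])
  expect_lt(med["tier40"], med["uniform"])
})

test_that("planted marker statistics are recovered at 500 cells", {
  # six markers planted at the same target; their mean recovered statistics
  # isolate the generator's calibration from per-gene sampling noise
  markers <- data.frame(gene = c(1, 10:15), cluster = "expr",
                        pct = c(0.95, rep(0.6, 6)),
                        log2fc = c(8, rep(1, 6)))
  cs <- simulate_counts(
    clusters = list(expr = list(n_cells = 250),
                    rest = list(n_cells = 250)),
    n_genes = 600, depth = 20000, markers = markers, seed = 14
  )
  ms <- marker_stats(cs$em, "gene_00001")
  expect_lt(abs(mean(ms$pct_expressing[10:15]) - 0.6), 0.05)
  expect_lt(abs(mean(ms$log2fc[10:15]) - 1.0), 0.15)
  expect_error(
    simulate_counts(list(a = list(n_cells = 5)), markers =
                      data.frame(gene = 1, cluster = "a", pct = 1.2,
                                 log2fc = 1)),
    "pct"
  )
})

test_that("generator outputs are valid inputs to the readers", {
  d <- withr::local_tempdir()
  g <- make_genome(c(chr1 = 60000), seed = 15)
  pw <- demo_pwms()
  pp <- plant_peaks(g, pw$a, pw$b, n_peaks = 40, seed = 16)
  write_genome(pp$genome, file.path(d, "g.fa"))
  write_narrowpeak(pp$peaks_a, file.path(d, "a.narrowPeak"))
  expect_equal(read_narrowpeak(file.path(d, "a.narrowPeak")), pp$peaks_a)
  expect_equal(chrom_lengths(read_genome(file.path(d, "g.fa"))),
               c(chr1 = 60000L))
  occ <- simulate_occupancy(c(chrSim = 100000), n_nucleosomes = 120,
                            seed = 17)
  write_bedgraph(occ$mock, file.path(d, "m.bedGraph"))
  back <- read_bedgraph(file.path(d, "m.bedGraph"), 10, c(chrSim = 100000))
  expect_equal(back$values, occ$mock$values)
})
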