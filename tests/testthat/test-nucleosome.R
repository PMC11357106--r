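# Nucleosome calling, peak classification, metaprofiles, and differential
# occupancy, validated against planted designs and brute-force oracles.

test_that("a flat track yields no calls and warns", {
  tr <- toy_track(rep(0, 500))
  expect_warning(calls <- call_nucleosomes(tr), "no signal")
  expect_equal(nrow(calls), 0)
  tr <- toy_track(rep(3, 500))  # constant but nonzero: no local maxima pass
  expect_equal(nrow(call_nucleosomes(tr, min_prominence = 1)), 0)
})

test_that("planted Gaussian bumps are recovered at their centers", {
  centers <- data.frame(chrom = "chr1", center = 2005L, amplitude = 25)
  tr <- simulate_signal_track(centers, c(chr1 = 5000), bin_size = 10,
                              sigma = 20, background = 0, noise = "none")
  calls <- call_nucleosomes(tr, min_prominence = 3)
  expect_equal(nrow(calls), 1)
  expect_lte(abs(calls$center - 2005L), 10)
  expect_equal(calls$end - calls$start, 147L)

  # two bumps 200 bp apart give two non-overlapping calls
  centers <- data.frame(chrom = "chr1", center = c(2000L, 2200L),
                        amplitude = 25)
  tr <- simulate_signal_track(centers, c(chr1 = 5000), bin_size = 10,
                              sigma = 20, background = 0, noise = "none")
  calls <- call_nucleosomes(tr, min_prominence = 3)
  expect_equal(nrow(calls), 2)
  expect_gte(abs(diff(calls$center)), 147)
})

test_that("the caller is exact on noise-free tracks and robust to noise", {
  occ <- simulate_occupancy(c(chrSim = 200000), n_nucleosomes = 280,
                            noise = "none", seed = 5)
  calls <- call_nucleosomes(occ$mock)
  # 100% precision and recall: one call within a bin of every planted dyad
  expect_equal(nrow(calls), nrow(occ$truth))
  d <- abs(sort(calls$center) - sort(occ$truth$center))
  expect_lte(max(d), occ$mock$bin_size)

  occ <- simulate_occupancy(c(chrSim = 200000), n_nucleosomes = 280,
                            noise = "poisson", seed = 6)
  calls <- call_nucleosomes(occ$mock)
  hit <- vapply(occ$truth$center, function(ctr) {
    any(abs(calls$center - ctr) <= 73)
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("peak classification matches a brute-force overlap oracle", {
  calls <- data.frame(chrom = "chr1", start = c(1000L, 5000L),
                      end = c(1147L, 5147L))
  mk <- function(summit) peak_set("chr1", summit - 50L, summit + 50L,
                                  summit_offset = 50L)
  # summit at a call center -> nucleosomal
  expect_equal(classify_peaks(mk(1073L), calls), "nucleosomal")
  # summit + window just reaching the call start -> nucleosomal;
  # one bp further away -> non-nucleosomal
  expect_equal(classify_peaks(mk(1000L - 73L), calls), "nucleosomal")
  expect_equal(classify_peaks(mk(1000L - 74L), calls), "non-nucleosomal")

  set.seed(77)
  calls <- data.frame(chrom = sample(c("chr1", "chr2"), 30, TRUE),
                      start = sample.int(50000, 30))
  calls$end <- calls$start + 147L
  pk <- rand_peaks(80, c(chr1 = 60000, chr2 = 60000), seed = 78)
  got <- classify_peaks(pk, calls, window = 73)
  summit <- peak_summits(pk)
  for (i in seq_len(nrow(pk))) {
    brute <- FALSE
    for (j in seq_len(nrow(calls))) {
      if (pk$chrom[i] != calls$chrom[j]) next
      if (summit[i] - 73L < calls$end[j] &&
          summit[i] + 73L + 1L > calls$start[j]) brute <- TRUE
    }
    expect_equal(got[i] == "nucleosomal", brute)
  }
})

test_that("planted nucleosomal/linker peaks are classified perfectly", {
  occ <- simulate_occupancy(c(chrSim = 150000), n_nucleosomes = 200,
                            noise = "none", seed = 9)
  calls <- call_nucleosomes(occ$mock)
  ctr <- occ$truth$center
  linkers <- (ctr[-1] + ctr[-length(ctr)]) %/% 2L
  pk <- peak_set("chrSim", c(ctr, linkers) - 80L, c(ctr, linkers) + 80L,
                 summit_offset = 80L)
  got <- classify_peaks(pk, calls)
  expect_equal(got, rep(c("nucleosomal", "non-nucleosomal"),
                        c(length(ctr), length(linkers))))
})

test_that("point metaprofiles satisfy their construction identities", {
  tr <- toy_track(rep(4, 1000))
  anchors <- data.frame(chrom = "chr1", pos = c(3000L, 6000L))
  pr <- metaprofile_point(tr, anchors, flank = 500, n_bins = 50)
  expect_equal(pr$mean, rep(4, 50))
  expect_equal(pr$mean, colMeans(pr$matrix))
  expect_equal(pr$n_sites, 2)

  # unit signal only at the anchor bin -> spike in the central bin
  v <- rep(0, 1000); v[301] <- 1  # bin 301 covers [3000, 3010)
  tr <- toy_track(v)
  pr <- metaprofile_point(tr, data.frame(chrom = "chr1", pos = 3005L),
                          flank = 100, n_bins = 20)
  expect_equal(which(pr$mean > 0), 10:11)  # 10-bp bins around the center
  expect_equal(sum(pr$mean > 0), 2)

  # minus-strand anchors flip their site vector
  v <- seq_len(1000)
  tr <- toy_track(v)
  pp <- metaprofile_point(tr, data.frame(chrom = "chr1", pos = 5000L,
                                         strand = "+"),
                          flank = 200, n_bins = 40)
  pm <- metaprofile_point(tr, data.frame(chrom = "chr1", pos = 5000L,
                                         strand = "-"),
                          flank = 200, n_bins = 40)
  expect_equal(pm$matrix[1, ], rev(pp$matrix[1, ]))

  # anchors at planted bump centers recover the planted amplitude
  centers <- data.frame(chrom = "chr1",
                        center = seq(5000L, 45000L, by = 2000L),
                        amplitude = 20)
  tr <- simulate_signal_track(centers, c(chr1 = 50000), bin_size = 10,
                              sigma = 20, background = 0, noise = "none")
  pr <- metaprofile_point(tr, data.frame(chrom = "chr1",
                                         pos = centers$center),
                          flank = 500, n_bins = 100)
  expect_equal(max(pr$mean), 20, tolerance = 0.1)
  expect_equal(which.max(pr$mean), 50, tolerance = 1)
  expect_error(metaprofile_point(tr, data.frame(chrom = character(),
                                                pos = integer())),
               "at least one")
})

test_that("scaled gene-body profiles separate body from flank signal", {
  gm <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                   start = c(3000L, 12000L), end = c(5000L, 13500L),
                   strand = c("+", "-"),
                   tss = c(3000L, 13499L), tes = c(4999L, 12000L))
  # constant track -> flat profile
  tr <- toy_track(rep(2, 2000))
  pr <- metaprofile_scaled(tr, gm, body_bins = 100, flank = 1000,
                           flank_bins = 50)
  expect_equal(pr$mean, rep(2, 200))
  expect_equal(pr$mean, colMeans(pr$matrix))

  # signal 1 inside bodies, 0 outside
  v <- rep(0, 2000)
  v[(3000 %/% 10 + 1):(5000 %/% 10)] <- 1
  v[(12000 %/% 10 + 1):(13500 %/% 10)] <- 1
  tr <- toy_track(v)
  pr <- metaprofile_scaled(tr, gm)
  body <- pr$mean[51:150]
  flank <- pr$mean[c(1:45, 156:200)]  # away from boundary bins
  expect_true(all(body > 0.95))
  expect_true(all(flank < 0.05))

  # reversing a gene's strand mirrors its per-site vector
  gma <- gm[1, ]; gmb <- gm[1, ]; gmb$strand <- "-"; gmb$tss <- gmb$end - 1L
  v <- cumsum(runif(2000)); tr <- toy_track(v)
  pa <- metaprofile_scaled(tr, gma)
  pb <- metaprofile_scaled(tr, gmb)
  expect_equal(pb$matrix[1, ], rev(pa$matrix[1, ]))
})

test_that("shared peaks show their planted signal advantage", {
  lens <- c(chr1 = 100000)
  centers <- seq(2000L, 98000L, by = 2000L)
  n <- length(centers)
  shared <- rep(c(TRUE, FALSE), length.out = n)
  pk_a <- peak_set("chr1", centers - 100L, centers + 100L,
                   summit_offset = 100L)
  pk_b <- peak_set("chr1", centers[shared] - 80L, centers[shared] + 80L,
                   summit_offset = 80L)
  # B == A: everything is shared, unique profile omitted with a warning
  expect_warning(r <- shared_unique_signal(pk_a, pk_a,
                                           toy_track(rep(1, 10000))),
                 "no unique")
  expect_null(r$unique)
  expect_equal(r$summary$n_shared, n)
  # disjoint B: everything unique
  pk_far <- peak_set("chr1", 1L, 50L, summit_offset = 10L)
  expect_warning(r <- shared_unique_signal(pk_a, pk_far,
                                           toy_track(rep(1, 10000))),
                 "no shared")
  expect_equal(r$summary$n_unique, n)
  # 2x amplitude planted at shared peaks -> ratio of means ~ 2
  tr <- simulate_signal_track(
    data.frame(chrom = "chr1", center = centers,
               amplitude = ifelse(shared, 20, 10)),
    lens, bin_size = 10, sigma = 20, background = 0, noise = "none"
  )
  r <- shared_unique_signal(pk_a, pk_b, tr, flank = 500, n_bins = 50)
  expect_equal(r$summary$ratio, 2, tolerance = 0.1)
})

test_that("differential occupancy honors its normalization identities", {
  set.seed(91)
  v <- rpois(2000, 8) + 1
  tr <- toy_track(as.numeric(v))
  regions <- data.frame(chrom = "chr1", start = seq(0L, 19000L, by = 1000L),
                        end = seq(500L, 19500L, by = 1000L))
  # identical tracks -> all log2FC exactly 0
  d0 <- differential_occupancy(tr, tr, regions)
  expect_equal(d0$table$log2fc, rep(0, nrow(regions)))
  # a global 2x scale is absorbed by the size factors
  tr2 <- toy_track(as.numeric(2 * v))
  d2 <- differential_occupancy(tr2, tr, regions)
  expect_equal(d2$table$log2fc, rep(0, nrow(regions)), tolerance = 1e-12)
  expect_equal(unname(d2$size_factors[["treat"]] /
                        d2$size_factors[["mock"]]), 2, tolerance = 1e-12)
  # swapping conditions negates every fold change
  trb <- toy_track(as.numeric(rpois(2000, 8) + 1))
  dab <- differential_occupancy(tr, trb, regions)
  dba <- differential_occupancy(trb, tr, regions)
  expect_equal(dab$table$log2fc, -dba$table$log2fc, tolerance = 1e-12)
})

test_that("regions empty in both conditions are flagged with log2FC 0", {
  v <- c(rep(0, 100), rep(5, 1900))
  tr <- toy_track(as.numeric(v))
  regions <- data.frame(chrom = "chr1", start = c(0L, 5000L),
                        end = c(900L, 6000L))
  expect_warning(d <- differential_occupancy(tr, tr, regions),
                 "zero counts in both")
  expect_true(d$table$both_zero[1])
  expect_equal(d$table$log2fc[1], 0)
})

test_that("size factors agree with the DESeq2 median-of-ratios estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(101)
  counts <- matrix(rpois(400, 50) * rep(c(1, 2.5), each = 200), ncol = 2)
  sf <- median_of_ratios(counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(sf), unname(ref), tolerance = 1e-6)
})

test_that("planted depletion is recovered at targets but not elsewhere", {
  occ <- simulate_occupancy(c(chrSim = 300000), n_nucleosomes = 420,
                            depletion = 0.5, target_fraction = 0.1,
                            seed = 13)
  tr <- occ$truth
  regions <- data.frame(chrom = tr$chrom,
                        start = pmax(tr$center - 250L, 0L),
                        end = pmin(tr$center + 250L, 300000L))
  d <- differential_occupancy(occ$induced, occ$mock, regions)
  expect_lt(abs(mean(d$table$log2fc[tr$is_target]) + 1), 0.1)
  expect_lt(abs(mean(d$table$log2fc[!tr$is_target])), 0.1)
})
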