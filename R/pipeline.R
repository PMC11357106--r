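# End-to-end demo pipeline: simulate -> entropy -> overlap -> targets ->
# nucleosome -> spacing -> report, with config validation, seed control,
# and a deterministic output tree (re-running with the same seed and config
# reproduces every table byte for byte).

#' Default pipeline configuration
#'
#' Thresholds default to the study's stated values: targets need expression
#' in at least 25% of factor-expressing cells and log2 fold change at least
#' 0.223; peaks annotate to genes with a 3-kb promoter cutoff; motif
#' occurrence is scored within 100 bp of summits; PWM sites are localized
#' within 50 bp of peak centers. Simulation scales are chosen so the full
#' demo runs in minutes on one CPU.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(
      chrom_lengths = c(chr1 = 300000L, chr2 = 200000L),
      n_peaks = 300L, peak_width = 200L,
      mode = "constrained", delta = 10, sigma = 2,
      occupancy = list(
        chrom_length = c(chrSim = 600000L),
        n_nucleosomes = 800L, spacing = 700L, jitter = 50L,
        fuzziness = 20, amplitude = 25, background = 5,
        bin_size = 10L, depletion = 0.5, target_fraction = 0.1
      ),
      counts = list(
        n_genes = 1000L, depth = 20000L,
        clusters = list(
          uniform = list(n_cells = 100L),
          tier40 = list(n_cells = 100L, top_fraction = 0.1, top_share = 0.4),
          tier50 = list(n_cells = 100L, top_fraction = 0.1, top_share = 0.5)
        ),
        factor_cluster = "tier40",
        factor_gene_index = 1L,
        n_marker_genes = 20L, marker_pct = 0.6, marker_log2fc = 1.0
      )
    ),
    thresholds = list(
      min_pct = 0.25, min_log2fc = 0.223,
      annotate_max_distance = 3000L,
      summit_motif_window = 100L, motif_fpr = 0.001,
      pwm_window = 50L,
      n_perm = 1000L, alpha = 0.01
    ),
    nucleosome = list(
      smoothing_bandwidth = 30, min_prominence = 5,
      classify_window = 73L, diffocc_halfwidth = 250L,
      profile_flank = 1000L, profile_bins = 100L
    ),
    make_plots = FALSE
  )
}

check_names <- function(cfg, tmpl, path = "config") {
  unknown <- setdiff(names(cfg), names(tmpl))
  if (length(unknown) > 0) {
    stopf("unknown %s key(s): %s", path,
          paste(paste0(path, "$", unknown), collapse = ", "))
  }
  for (k in names(cfg)) {
    if (is.list(tmpl[[k]]) && !is.null(names(tmpl[[k]])) &&
        k != "clusters" && k != "chrom_lengths") {
      if (!is.list(cfg[[k]])) stopf("%s$%s must be a list", path, k)
      check_names(cfg[[k]], tmpl[[k]], paste0(path, "$", k))
    }
  }
  invisible(cfg)
}

fill_defaults <- function(cfg, tmpl) {
  for (k in names(tmpl)) {
    if (!k %in% names(cfg)) {
      cfg[[k]] <- tmpl[[k]]
    } else if (is.list(tmpl[[k]]) && !is.null(names(tmpl[[k]])) &&
               k != "clusters" && k != "chrom_lengths") {
      cfg[[k]] <- fill_defaults(cfg[[k]], tmpl[[k]])
    }
  }
  cfg
}

#' Validate and complete a pipeline configuration
#'
#' Unknown keys are errors (typos in threshold names would otherwise be
#' silently ignored); missing keys are filled from [default_config()].
#'
#' @param config Partial configuration list, or a path to a YAML file.
#' @return Completed configuration list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  tmpl <- default_config()
  check_names(config, tmpl)
  cfg <- fill_defaults(config, tmpl)
  cfg$simulate$chrom_lengths <- unlist(cfg$simulate$chrom_lengths)
  cfg$simulate$occupancy$chrom_length <-
    unlist(cfg$simulate$occupancy$chrom_length)
  cfg
}

write_tsv <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full demo pipeline
#'
#' Executes the stages in dependency order; every stage reads its inputs
#' from the files the previous stages wrote, exercising the I/O layer end
#' to end. Each output table carries a header comment with the package
#' version, a hash of the resolved configuration, and the seed. With
#' `resume = TRUE`, stages whose outputs already exist are skipped.
#'
#' @param config Configuration (see [default_config()]; partial lists or a
#'   YAML path are completed via [validate_config()]).
#' @param out_dir Output directory (created if missing).
#' @param seed Overrides `config$seed` when given.
#' @param resume Skip stages whose outputs already exist.
#' @return Invisibly, a list with the paths of all outputs and the summary
#'   table.
#' @export
run_pipeline <- function(config = default_config(), out_dir, seed = NULL,
                         resume = FALSE) {
  cfg <- validate_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)

  # Resolved config is itself an output; its hash goes into every header.
  cfg_json <- p("config.json")
  jsonlite::write_json(cfg, cfg_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  cfg_hash <- unname(tools::md5sum(cfg_json))
  hdr <- sprintf("# chromfate %s | config=%s | seed=%d",
                 as.character(utils::packageVersion("chromfate")),
                 cfg_hash, cfg$seed)

  stage <- function(name, outputs, fn) {
    if (resume && all(file.exists(outputs))) {
      message(sprintf("[%s] outputs exist, skipped", name))
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    fn()
    message(sprintf("[%s] done in %.1f s -> %s", name,
                    proc.time()[["elapsed"]] - t0,
                    paste(basename(outputs), collapse = ", ")))
  }
  sim <- cfg$simulate
  occ <- sim$occupancy
  cnt <- sim$counts
  th <- cfg$thresholds
  nuc <- cfg$nucleosome
  pwms <- demo_pwms()
  placement_half <- th$pwm_window - 5L

  files <- list(
    genome = p("genome.fa"), peaks_a = p("peaks_a.narrowPeak"),
    peaks_b = p("peaks_b.narrowPeak"), genes = p("genes.gff3"),
    mock = p("occupancy_mock.bedGraph"),
    induced = p("occupancy_induced.bedGraph"),
    mtx = p("counts.mtx"), genes_tsv = p("genes.tsv"),
    cells_tsv = p("cells.tsv"),
    truth_spacing = p("truth_spacing.tsv"),
    truth_nuc = p("truth_nucleosomes.tsv"),
    truth_clusters = p("truth_clusters.tsv"),
    truth_markers = p("truth_markers.tsv")
  )

  stage("simulate", unlist(files), function() {
    genome <- make_genome(sim$chrom_lengths, seed = cfg$seed + 11L)
    planted <- plant_peaks(genome, pwms$a, pwms$b, n_peaks = sim$n_peaks,
                           peak_width = sim$peak_width, mode = sim$mode,
                           delta = sim$delta, sigma = sim$sigma,
                           window = th$pwm_window, seed = cfg$seed + 12L)
    write_genome(planted$genome, files$genome)
    write_narrowpeak(planted$peaks_a, files$peaks_a)
    write_narrowpeak(planted$peaks_b, files$peaks_b)
    write_tsv(planted$truth, files$truth_spacing, hdr)

    # One gene per peak: body starts 200 bp downstream of the summit, so
    # the peak falls in the gene's promoter window. Genes are named after
    # the count-matrix universe so peak annotation and marker statistics
    # share gene ids.
    summit <- peak_summits(planted$peaks_a)
    gm <- data.frame(
      gene_id = sprintf("gene_%05d", seq_len(nrow(planted$peaks_a))),
      chrom = planted$peaks_a$chrom,
      start = summit + 200L, end = summit + 1200L, strand = "+",
      stringsAsFactors = FALSE
    )
    gm$tss <- gm$start
    gm$tes <- gm$end - 1L
    write_gene_models(gm, files$genes)

    occ_sim <- simulate_occupancy(
      chrom_lengths = occ$chrom_length, n_nucleosomes = occ$n_nucleosomes,
      spacing = occ$spacing, jitter = occ$jitter,
      fuzziness = occ$fuzziness, amplitude = occ$amplitude,
      background = occ$background, bin_size = occ$bin_size,
      depletion = occ$depletion, target_fraction = occ$target_fraction,
      seed = cfg$seed + 13L
    )
    write_bedgraph(occ_sim$mock, files$mock)
    write_bedgraph(occ_sim$induced, files$induced)
    write_tsv(occ_sim$truth, files$truth_nuc, hdr)

    markers <- data.frame(
      gene = c(cnt$factor_gene_index,
               cnt$factor_gene_index + seq_len(cnt$n_marker_genes)),
      cluster = cnt$factor_cluster,
      pct = c(0.95, rep(cnt$marker_pct, cnt$n_marker_genes)),
      log2fc = c(8, rep(cnt$marker_log2fc, cnt$n_marker_genes))
    )
    cs <- simulate_counts(cnt$clusters, n_genes = cnt$n_genes,
                          depth = cnt$depth, markers = markers,
                          seed = cfg$seed + 14L)
    write_counts(cs$em, files$mtx, files$genes_tsv, files$cells_tsv)
    write_tsv(cs$truth_clusters, files$truth_clusters, hdr)
    write_tsv(cs$truth_markers, files$truth_markers, hdr)
  })

  em <- read_counts(files$mtx, files$genes_tsv, files$cells_tsv)
  ent_files <- c(p("entropy_cells.tsv"), p("entropy_clusters.tsv"))
  stage("entropy", ent_files, function() {
    ent <- entropy_by_cluster(em)
    write_tsv(ent$cells, ent_files[1], hdr)
    write_tsv(ent$clusters, ent_files[2], hdr)
  })

  ov_file <- p("overlap_test.json")
  stage("overlap", ov_file, function() {
    pa <- read_narrowpeak(files$peaks_a)
    pb <- read_narrowpeak(files$peaks_b)
    ov <- permutation_overlap_test(pa, pb, sim$chrom_lengths,
                                   n_perm = th$n_perm,
                                   seed = cfg$seed + 21L)
    jsonlite::write_json(ov[c("observed_overlap", "null_mean", "null_sd",
                              "z_score", "empirical_p", "n_perm")],
                         ov_file, auto_unbox = TRUE, digits = NA)
  })

  tg_file <- p("targets.tsv")
  stage("targets", tg_file, function() {
    pa <- read_narrowpeak(files$peaks_a)
    gm <- read_gene_models(files$genes)
    ann <- annotate_peaks_to_genes(pa, gm,
                                   max_distance = th$annotate_max_distance)
    ms <- marker_stats(em, sprintf("gene_%05d", cnt$factor_gene_index))
    tg <- assign_targets(ms, ann, factor = "simTF",
                         min_pct = th$min_pct,
                         min_log2fc = th$min_log2fc)
    write_tsv(tg, tg_file, hdr)
  })

  nuc_files <- c(p("nucleosome_calls.tsv"), p("peak_classes.tsv"),
                 p("metaprofile_mock.tsv"), p("diffocc.tsv"))
  stage("nucleosome", nuc_files, function() {
    mock <- read_bedgraph(files$mock, occ$bin_size, occ$chrom_length)
    induced <- read_bedgraph(files$induced, occ$bin_size, occ$chrom_length)
    truth <- utils::read.table(files$truth_nuc, sep = "\t", header = TRUE,
                               comment.char = "#")
    calls <- call_nucleosomes(mock,
                              smoothing_bandwidth = nuc$smoothing_bandwidth,
                              min_prominence = nuc$min_prominence)
    write_tsv(calls, nuc_files[1], hdr)

    # Demo classification: probe peaks at planted dyads (nucleosomal) and
    # at inter-nucleosome midpoints (linker, non-nucleosomal).
    half_n <- min(200L, nrow(truth))
    dyads <- truth$center[seq_len(half_n)]
    linkers <- (truth$center[seq_len(half_n - 1)] +
                  truth$center[seq_len(half_n - 1) + 1]) %/% 2L
    probes <- peak_set(
      chrom = truth$chrom[1],
      start = c(dyads, linkers) - 100L, end = c(dyads, linkers) + 100L,
      name = c(sprintf("dyad_%03d", seq_len(half_n)),
               sprintf("linker_%03d", seq_len(half_n - 1))),
      summit_offset = 100L
    )
    cls <- classify_peaks(probes, calls, window = nuc$classify_window)
    write_tsv(data.frame(name = probes$name,
                         planted = rep(c("nucleosomal", "non-nucleosomal"),
                                       c(half_n, half_n - 1L)),
                         called = cls),
              nuc_files[2], hdr)

    anchors <- data.frame(chrom = truth$chrom[truth$is_target],
                          pos = truth$center[truth$is_target])
    prof <- metaprofile_point(mock, anchors, flank = nuc$profile_flank,
                              n_bins = nuc$profile_bins)
    write_tsv(data.frame(position = prof$positions, mean = prof$mean),
              nuc_files[3], hdr)

    # All planted nucleosomes form the region universe, so size factors are
    # driven by the unchanged majority; targets are contrasted with the rest.
    hw <- nuc$diffocc_halfwidth
    regions <- data.frame(
      chrom = truth$chrom,
      start = pmax(truth$center - hw, 0L),
      end = pmin(truth$center + hw, occ$chrom_length[[1]]),
      class = ifelse(truth$is_target, "target", "random")
    )
    do <- differential_occupancy(induced, mock, regions)
    write_tsv(do$table, nuc_files[4], hdr)
  })

  sp_files <- c(p("spacing.tsv"), p("spacing_summary.json"))
  stage("spacing", sp_files, function() {
    genome <- read_genome(files$genome)
    pa <- read_narrowpeak(files$peaks_a)
    pb <- read_narrowpeak(files$peaks_b)
    sp <- pairwise_spacing(pa, pb, pwms$a, pwms$b, genome,
                           window = th$pwm_window,
                           factor_a = "factorA", factor_b = "factorB")
    write_tsv(data.frame(d = sp$d), sp_files[1], hdr)
    cl <- classify_spacing(sp, null_W = placement_half, alpha = th$alpha,
                           min_gap = max(pwm_length(pwms$a),
                                         pwm_length(pwms$b)))
    jsonlite::write_json(
      list(factor_a = sp$factor_a, factor_b = sp$factor_b,
           n_pairs = sp$n_pairs, n_dropped = sp$n_dropped,
           mean = mean(sp$d), sd = stats::sd(sp$d),
           ks_d = cl$ks$statistic, ks_p = cl$ks$p_value,
           class = cl$class, mode = cl$mode, halfwidth = cl$halfwidth),
      sp_files[2], auto_unbox = TRUE, digits = NA)
  })

  rep_files <- c(p("summary.tsv"), p("manifest.tsv"))
  stage("report", rep_files, function() {
    ent <- utils::read.table(ent_files[2], sep = "\t", header = TRUE,
                             comment.char = "#")
    ovr <- jsonlite::read_json(ov_file)
    tg <- utils::read.table(tg_file, sep = "\t", header = TRUE,
                            comment.char = "#")
    cls <- utils::read.table(nuc_files[2], sep = "\t", header = TRUE,
                             comment.char = "#")
    do <- utils::read.table(nuc_files[4], sep = "\t", header = TRUE,
                            comment.char = "#")
    sps <- jsonlite::read_json(sp_files[2])
    summary <- data.frame(
      metric = c(sprintf("entropy_median_%s", ent$cluster),
                 "overlap_empirical_p", "n_targets",
                 "peak_class_accuracy",
                 "diffocc_target_mean_log2fc", "diffocc_random_mean_log2fc",
                 "spacing_class", "spacing_mean_bp", "spacing_sd_bp"),
      value = c(sprintf("%.6g", ent$entropy_median),
                sprintf("%.6g", ovr$empirical_p), sum(tg$is_target),
                sprintf("%.4f", mean(cls$planted == cls$called)),
                sprintf("%.4f", mean(do$log2fc[do$class == "target"])),
                sprintf("%.4f", mean(do$log2fc[do$class == "random"])),
                sps$class, sprintf("%.3f", sps$mean),
                sprintf("%.3f", sps$sd)),
      stringsAsFactors = FALSE
    )
    write_tsv(summary, rep_files[1], hdr)
    if (isTRUE(cfg$make_plots)) {
      grDevices::png(p("figures.png"), width = 1200, height = 400)
      graphics::par(mfrow = c(1, 3))
      ecells <- utils::read.table(ent_files[1], sep = "\t", header = TRUE,
                                  comment.char = "#")
      plot_entropy_clusters(ecells)
      prof <- utils::read.table(nuc_files[3], sep = "\t", header = TRUE,
                                comment.char = "#")
      graphics::plot(prof$position, prof$mean, type = "l",
                     xlab = "distance from dyad (bp)",
                     ylab = "occupancy", main = "target metaprofile")
      spd <- utils::read.table(sp_files[1], sep = "\t", header = TRUE,
                               comment.char = "#")
      plot_spacing_density(spacing_distribution(spd$d, placement_half))
      grDevices::dev.off()
    }
    all_files <- setdiff(list.files(out_dir, full.names = TRUE),
                         p("manifest.tsv"))
    manifest <- data.frame(file = basename(all_files),
                           md5 = unname(tools::md5sum(all_files)),
                           stringsAsFactors = FALSE)
    manifest <- manifest[order(manifest$file), ]
    write_tsv(manifest, rep_files[2], hdr)
  })

  invisible(list(out_dir = out_dir, config = cfg,
                 files = c(files, entropy = as.list(ent_files),
                           overlap = ov_file, targets = tg_file,
                           nucleosome = as.list(nuc_files),
                           spacing = as.list(sp_files),
                           report = as.list(rep_files))))
}
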