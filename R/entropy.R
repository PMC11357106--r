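# Per-cell transcriptional entropy and the two-tier expression model.
#
# Entropy is the Shannon entropy of a cell's transcript proportions,
# S = -sum_i p_i log p_i with p_i = c_i / sum(c), a proxy for the
# differentiation potential of the cell: many uniformly expressed genes give
# high entropy, a skewed profile concentrated on few genes gives low entropy.

#' Shannon entropy of one cell's counts
#'
#' Computes `S = -sum_i p_i log p_i` with `p_i = c_i / sum(c)`; zero-count
#' genes contribute exactly 0. Entropy is reported in nats by default
#' (natural log); pass `base = 2` for bits. The value is invariant under
#' uniform scaling of the counts and bounded by `log(n_expressed)`.
#'
#' @param counts Non-negative numeric vector of per-gene counts for one cell.
#' @param base Logarithm base (default `exp(1)`, nats).
#' @return Entropy (scalar, >= 0).
#' @export
#' @examples
#' cell_entropy(rep(1, 1000))        # log(1000)
#' cell_entropy(c(1, 1, 2))          # 1.0397 nats
cell_entropy <- function(counts, base = exp(1)) {
  if (any(counts < 0) || anyNA(counts)) stopf("counts must be non-negative")
  tot <- sum(counts)
  if (tot == 0) stopf("cannot compute entropy of an all-zero cell")
  p <- counts[counts > 0] / tot
  -sum(p * log(p, base = base))
}

#' Number of expressed genes in one cell
#'
#' @param counts Non-negative numeric vector of per-gene counts.
#' @param min_count Minimum raw count for a gene to be called expressed
#'   (default 1).
#' @return Integer count of genes with `count >= min_count`.
#' @export
expressed_genes <- function(counts, min_count = 1) {
  if (any(counts < 0) || anyNA(counts)) stopf("counts must be non-negative")
  sum(counts >= min_count)
}

#' Per-cell entropy and expressed-gene counts, summarized by cluster
#'
#' @param em An [expression_matrix()].
#' @param min_count Expression threshold for the expressed-gene count.
#' @param base Logarithm base for entropy (default nats).
#' @return List with `cells` (data.frame: cell_id, cluster, entropy,
#'   n_expressed, one row per cell) and `clusters` (data.frame: cluster, n,
#'   median/q25/q75 of entropy and of n_expressed, ordered by the declared
#'   cluster levels).
#' @export
entropy_by_cluster <- function(em, min_count = 1, base = exp(1)) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  m <- methods::as(em$counts, "TsparseMatrix")
  tot <- Matrix::rowSums(em$counts)
  i <- m@i + 1L
  p <- m@x / tot[i]
  ent <- numeric(nrow(em$counts))
  contrib <- rowsum(-p * log(p, base = base), i)
  ent[as.integer(rownames(contrib))] <- contrib[, 1]
  nexp <- integer(nrow(em$counts))
  tab <- rowsum((m@x >= min_count) + 0, i)
  nexp[as.integer(rownames(tab))] <- as.integer(tab[, 1])

  cells <- data.frame(cell_id = em$cell_ids,
                      cluster = as.character(em$clusters),
                      entropy = ent, n_expressed = nexp,
                      stringsAsFactors = FALSE)
  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  lv <- levels(em$clusters)
  summ <- do.call(rbind, lapply(lv, function(cl) {
    idx <- which(em$clusters == cl)
    qe <- qs(ent[idx]); qn <- qs(nexp[idx])
    data.frame(cluster = cl, n = length(idx),
               entropy_q25 = qe[1], entropy_median = qe[2], entropy_q75 = qe[3],
               n_expressed_q25 = qn[1], n_expressed_median = qn[2],
               n_expressed_q75 = qn[3], stringsAsFactors = FALSE)
  }))
  list(cells = cells, clusters = summ)
}

#' Two-tier expression model
#'
#' A piecewise-uniform transcript distribution in which the top
#' `top_fraction` of expressed genes (the "high tier") jointly hold
#' `top_share` of all transcripts, uniformly within each tier. With
#' `top_share = top_fraction` the model reduces to the uniform distribution.
#' `top_fraction = 0.10` with `top_share` 0.4 or 0.5 describes populations
#' where the top 10% of expressed genes comprise 40% or 50% of transcripts.
#'
#' @param n_genes Number of expressed genes (>= 2).
#' @param top_fraction Proportion of genes in the high tier (0 < f < 1).
#' @param top_share Proportion of transcripts held by the high tier
#'   (0 <= s <= 1).
#' @return Object of class `two_tier_model`.
#' @export
two_tier_model <- function(n_genes, top_fraction = 0.10, top_share = 0.40) {
  if (n_genes < 2) stopf("two-tier model needs n_genes >= 2")
  if (top_fraction <= 0 || top_fraction >= 1) {
    stopf("top_fraction must be in (0, 1)")
  }
  if (top_share < 0 || top_share > 1) stopf("top_share must be in [0, 1]")
  k1 <- max(1L, as.integer(round(top_fraction * n_genes)))
  if (k1 >= n_genes) stopf("high tier must leave at least one low-tier gene")
  structure(list(n_genes = as.integer(n_genes), top_fraction = top_fraction,
                 top_share = top_share, k_high = k1,
                 k_low = as.integer(n_genes) - k1),
            class = "two_tier_model")
}

#' Gene probabilities of a two-tier model
#'
#' @param model A [two_tier_model()].
#' @return Numeric vector of length `n_genes` summing to 1 (high-tier genes
#'   first).
#' @export
two_tier_probs <- function(model) {
  stopifnot(inherits(model, "two_tier_model"))
  c(rep(model$top_share / model$k_high, model$k_high),
    rep((1 - model$top_share) / model$k_low, model$k_low))
}

#' Analytic entropy of a two-tier model
#'
#' Closed form for the piecewise-uniform distribution:
#' `S = -[s log(s/k1) + (1 - s) log((1 - s)/k2)]` with `s = top_share`,
#' `k1` high-tier and `k2` low-tier genes. Strictly decreasing in
#' `top_share` above `top_fraction` (more concentration, lower entropy) and
#' strictly increasing in `n_genes` (more expressed genes, higher entropy).
#'
#' @param model A [two_tier_model()].
#' @param base Logarithm base (default nats).
#' @return Entropy (scalar).
#' @export
#' @examples
#' two_tier_entropy(two_tier_model(10, 0.1, 0.5))   # 1.791759 nats
two_tier_entropy <- function(model, base = exp(1)) {
  stopifnot(inherits(model, "two_tier_model"))
  s <- model$top_share
  term <- function(mass, k) {
    if (mass == 0) 0 else -mass * log(mass / k, base = base)
  }
  term(s, model$k_high) + term(1 - s, model$k_low)
}

#' Sample cells from a two-tier model
#'
#' Each cell is an independent multinomial draw of `depth` transcripts from
#' the model's gene probabilities.
#'
#' @param model A [two_tier_model()].
#' @param n_cells Number of cells.
#' @param depth Transcripts per cell (>= 1).
#' @param seed RNG seed (restores the caller's RNG state).
#' @param cluster Cluster label attached to the sampled cells.
#' @return An [expression_matrix()] of `n_cells` x `n_genes` counts.
#' @export
sample_two_tier_cells <- function(model, n_cells, depth, seed = NULL,
                                  cluster = "sim") {
  stopifnot(inherits(model, "two_tier_model"))
  if (depth < 1) stopf("depth must be >= 1")
  counts <- with_seed(seed, {
    t(stats::rmultinom(n_cells, size = depth, prob = two_tier_probs(model)))
  })
  expression_matrix(counts, clusters = rep(cluster, n_cells),
                    cell_ids = sprintf("cell_%05d", seq_len(n_cells)),
                    gene_ids = sprintf("gene_%05d", seq_len(model$n_genes)))
}
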