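---
title: "chromfate: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromfate: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

chromfate bundles the computational analyses used to study how
transcription factors and chromatin remodeling control fate transitions in
the Arabidopsis stomatal lineage. This vignette explains each model, the
parameters that matter, the synthetic designs the test suite relies on,
and the numerical decisions taken where the methodology left choices open.

## Transcriptional entropy

For a cell with raw counts $c_i$ over genes, the package computes the
Shannon entropy of the transcript proportions,
$$S = -\sum_i p_i \log p_i, \qquad p_i = c_i / \textstyle\sum_j c_j,$$
with zero-count genes contributing exactly 0. Entropy is a proxy for
differentiation potential: pluripotent cells with weak transcriptional
constraints express many genes relatively homogeneously (high $S$), while
committed cells concentrate their transcriptome on fewer programs (low
$S$).

Choices made where the method is underdetermined:

* **Log base.** Natural log (nats) by default. The base only rescales all
  entropies by a constant, so every comparison (cluster orderings, the
  two-tier curves) is base-invariant; `base = 2` is exposed.
* **"Expressed" gene.** Raw count $\ge 1$ by default (`min_count`). No
  normalization or gene filtering precedes the entropy sum; $p_i$ is
  computed on raw counts exactly as defined above.
* **Depth dependence.** No per-cell depth correction is applied. The
  plug-in entropy estimator is biased low by roughly $(G-1)/2N$ nats at
  depth $N$ with $G$ expressed genes (about 0.7% for $G = 1000$,
  $N = 7\times10^4$), and the expressed-gene count grows with depth. Both
  are properties of the estimator, shared by any direct use of it;
  cross-cluster comparisons at comparable depth are unaffected.

The **two-tier model** makes the entropy / expressed-genes relationship
analytic: $k_1 = \max(1, \mathrm{round}(f\,G))$ "high-tier" genes share a
fraction $s$ of all transcripts uniformly, and the remaining $k_2$ genes
share $1-s$,
$$S = -\left[s \log\frac{s}{k_1} + (1-s)\log\frac{1-s}{k_2}\right].$$
With $s = f$ it reduces to the uniform distribution ($S = \log G$); $S$
is strictly decreasing in $s$ beyond $f$ (concentration lowers entropy)
and strictly increasing in $G$ (more expressed genes raise it).
`sample_two_tier_cells()` draws multinomial cells from the model, and the
tests verify that sampled entropies converge to the closed form.

## Peak overlap by permutation

`permutation_overlap_test()` counts query peaks overlapping at least one
subject peak (any base pair), then re-places every subject peak uniformly
at random within its own chromosome — widths preserved, no
inter-chromosome moves — `n_perm` times. The empirical p-value is
$(1 + \#\{\text{perm} \ge \text{obs}\})/(1 + n_\text{perm})$, never zero,
and seed-reproducible. Because the overlap count is discrete, this
tie-inclusive p-value is conservative whenever permutations tie with the
observed count; the result also carries the mid-p (ties counted half),
which is the standard quantity for verifying the calibration of a
discrete permutation test and is what the calibration suite checks for
uniformity. Uniform re-placement was chosen over shuffling
variants because its null is simple enough to calibrate exactly: the test
suite checks p-value uniformity under a true null and a closed-form
single-interval case (a re-placed 100-bp interval hits a boundary-anchored
100-bp query on a 1000-bp chromosome with probability $100/901$). A
circular-shift mode is provided for users who want to preserve the
subject's internal spacing structure.

## Motif occurrence and target assignment

PWMs are built from aligned sites with column probabilities
$(n_b + q)/(n + 4q)$ (pseudocount $q = 0.25$; `N` bases are distributed to
the background) and scored as log-odds in bits against the background
composition. `motif_fraction_at_summits()` declares that a peak harbors
the motif if the best site on either strand, with midpoint within 100 bp
of the summit, reaches a hit threshold. Because the study's own motif
scoring lived inside a discovery tool, the threshold here is calibrated
transparently: the top 0.1% (by default) of the single-site null score
distribution, sampled on background sequence; the calibrator also reports
the implied window-level false-positive rate, which for short motifs such
as a hexamer is necessarily much larger than the single-site rate.

`annotate_peaks_to_genes()` assigns a peak to a gene when its summit lies
in the gene body or within 3 kb upstream of the TSS (strand-aware); among
eligible genes the smallest $|$summit $-$ TSS$|$ wins, ties broken
lexicographically. This deliberately replaces a complex annotation
priority scheme with a deterministic, oracle-checkable rule that keeps the
3-kb promoter cutoff.

`marker_stats()` splits cells into factor-expressing (factor count
$\ge 1$) and the rest; per gene it reports the fraction of expressing
cells with count $\ge 1$ and
$\log_2\!\big((m_\text{in} + \varepsilon)/(m_\text{out} + \varepsilon)\big)$
on counts-per-10k means with $\varepsilon = 10^{-4}$. The fold-change
recipe is not fixed by the methodology being followed; this one was chosen
because the stated threshold 0.223 $\approx \log_2 1.17$ matches common
single-cell differential-expression defaults, and it is documented and
exposed. `assign_targets()` then applies the conjunctive rule with
inclusive thresholds: expressed in $\ge 25\%$ of factor-expressing cells,
$\log_2$FC $\ge 0.223$, and at least one annotated binding site.

## Nucleosome occupancy

Occupancy tracks are fixed-bin `SignalTrack`s (default 10 bp — displayed
track resolution is not standardized, so the bin size is a parameter).
bedGraph binning uses length-weighted means with uncovered base pairs
counting zero, so binning conserves signal mass exactly; the final bin of
a chromosome divides by its actual (possibly truncated) extent.

`call_nucleosomes()` replaces an external nucleosome-positioning tool with
a transparent equivalent: Gaussian smoothing (kernel sd 30 bp), local
maxima at least `min_prominence` above the per-chromosome background
(median of the smoothed track), 147-bp calls centered on the maxima,
greedy resolution of overlaps by descending score, and a q-like score
$-\log_{10} P(\mathrm{Pois}(\bar\lambda) \ge \text{value})$ with a
stringency cutoff exposed (`q_min = 50` emulates a $q < 10^{-50}$
preset). The caller is validated by planting: 100% precision and recall on
noise-free tracks, $\ge 95\%$ recall under Poisson noise at background 5
and bump amplitude 25 counts/bin.

A peak is **nucleosomal** iff its summit $\pm 73$ bp (half a nucleosome
footprint) overlaps a call — the overlap rule is not fixed by the
methodology, so it is defined exactly and parameterized. Metaprofiles
(reference-point and scaled gene-body) are plain binned means over
per-site signal matrices, strand-aware, zero-padded and flagged at
chromosome edges; the stored mean always equals the column means of the
per-site matrix.

`differential_occupancy()` re-implements only the normalization and
fold-change core of count-based differential analysis: per-region summed
signal as pseudo-counts, median-of-ratios size factors (each condition's
factor is the median over regions of count / geometric mean across
conditions, on regions positive in both), and
$\log_2((t/s_t + 1)/(m/s_m + 1))$. Dispersion shrinkage and per-region
Wald tests are intentionally out of scope — no per-region significance is
claimed. The implementation is antisymmetric under swapping conditions,
invariant to global rescaling of either track, and its size factors are
cross-checked against an independent median-of-ratios implementation in
the test suite. Analysis regions default to dyad/summit $\pm 250$ bp
(exposed), since the exact region convention is not standardized.

## Binding-site spacing

For two factors sharing peaks, each peak pair (any-bp overlap, matched
one-to-one by nearest summits) is scanned with both PWMs within
$W = 50$ bp of the pair's common anchor (the midpoint of the two summits;
using one common anchor guarantees $|d| \le 2W$). The best log-odds site
per factor gives the signed distance $d = \text{pos}_B - \text{pos}_A$
between motif midpoints. Ties in the scan are resolved by smaller
$|$offset$|$, then plus strand, then leftmost — a fixed total order that
makes results reproducible. Signed distances are the default (an
absolute-distance view can be derived trivially); pairs where a factor has
no site above its threshold are dropped and counted, never imputed.

Under independent uniform placement within $\pm W$ of a common center,
$d$ follows the triangular density $f(d) = (2W - |d|)/(2W)^2$ on
$[-2W, 2W]$. Two sites cannot physically overlap in one sequence, however:
conditioning on $|d| \ge g$ (footprint exclusion, $g$ = motif length)
truncates and renormalizes the triangle to
$f(d) = (2W - |d|)/(2W - g)^2$, with CDF $(d + 2W)^2 / (2(2W-g)^2)$ below
$-g$ and $F(0) = 0.5$ exactly. Both nulls are implemented
(`dtri_spacing(min_gap = )`), and the synthetic dimer generator reports
the $g$ of its own placement process so recovered distances are tested
against the exact null of how they were generated.

`classify_spacing()` calls a distribution **random** when a one-sample KS
test against the independence null is not rejected at $\alpha = 0.01$;
otherwise a Gaussian kernel density is fitted and the central peak's
half-width at half-maximum decides **constrained** ($\le 10$ bp — the
sites keep an essentially fixed spacing, as expected for a heterodimer
binding as one unit) versus **relaxed** (a broad but real preference, as
expected for a flexibly tethered cofactor). The 10-bp boundary is an
operational definition of a qualitative distinction and is exposed. KS
p-values use the asymptotic distribution; distances sit on a 1-bp lattice,
whose CDF steps (at most $\sim 1/(2W)$) are negligible against the KS
critical values at the sample sizes used.

## The synthetic-data generators

Every generator is a pure function of its parameters and seed and emits a
truth table; downstream tests read expectations from the truth, not from
constants.

* `make_genome()`: i.i.d. uniform ACGT. Real genomes have composition
  bias, repeats, and motif clustering; none of these is emulated, so motif
  false-positive rates measured here transfer to real data only as orders
  of magnitude.
* `plant_peaks()`: writes consensus motifs at known offsets within
  $\pm(W - 5)$ bp of peak summits (consensus rather than PWM-sampled
  sites by default, separating scanner correctness from planting noise).
  Constrained mode places factor B at $A + \Delta + \mathcal N(0,\sigma)$
  (defaults $\Delta = 10$, $\sigma = 2$ bp); independent mode places both
  uniformly. Draws that would collide the two footprints are re-drawn
  (bounded retries) — the steric exclusion discussed above. Chance
  occurrences of either consensus inside scan windows are disrupted by a
  point mutation so the planted site is the unique ground truth;
  coincident placement is allowed when both factors share one consensus
  (a heterodimer reading a single site).
* `simulate_occupancy()`: nucleosomes as Gaussian bumps (fuzziness sd
  20 bp, amplitude 25, background 5 counts/bin, Poisson noise per bin) at
  700-bp spacing with $\pm 50$ bp jitter — spaced so that one target's
  depleted window cannot bleed into a neighbor's analysis region, keeping
  planted units independent. Induction multiplies expected occupancy
  within $\pm 250$ bp of target dyads by the depletion factor (default
  0.5, a 2-fold loss). Both conditions share one noise stream, so
  depletion 1.0 reproduces the mock track exactly. Fragment-level read
  simulation, digestion bias, and linker signal are not emulated.
* `simulate_counts()`: per-cluster gene probabilities from two-tier
  models; marker genes are moment-matched in closed form under the Poisson
  approximation ($p_\text{in} = -\log(1 - q)/N$ for a target expressing
  fraction $q$ at depth $N$; $p_\text{out} = p_\text{in}/2^{\text{lfc}}$),
  then renormalized. Doublets, ambient RNA, and realistic
  transcriptome-wide expression calibration are out of scope — passing
  tests show the statistics are computed correctly, not that real tissue
  looks like the simulation.

## Problem sizes and runtime

The default demo (`run_pipeline()`, the package's own choice of scale)
uses two 200–300-kb peak chromosomes with 300 planted peaks, an 600-kb
occupancy chromosome with 800 nucleosomes, and 3 clusters × 100 cells ×
1000 genes at depth 2×10⁴; it completes in well under five minutes on one
CPU and reruns byte-identically under a fixed seed (no timestamps enter
any output; the manifest carries md5 sums). The validation suite uses
n = 500–2000 peaks for spacing, 570–1000 nucleosomes, 200 permutation
replicates for calibration, and 50 cells at depth 10⁶ for entropy
convergence.

## Known limitations

* The nucleosome caller assumes well-separated, similar-amplitude
  nucleosomes; closely phased arrays (spacing < 147 bp) are resolved
  greedily and fuzziness is not scored.
* The annotation rule considers summits only; peaks spanning several
  promoters are still assigned to exactly one gene.
* `marker_stats()` conditions on detection of the factor transcript,
  which undercounts factor-expressing cells at shallow depth; the
  expressing-cell definition is a parameter.
* KS p-values are asymptotic; for very small spacing samples
  (n just above the n ≥ 8 floor) they are approximate.
* The permutation null re-places peaks uniformly, ignoring mappability
  and accessibility structure of real genomes.
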