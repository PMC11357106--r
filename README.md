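# chromfate

Analyses of chromatin-level control of cell fate transitions, modeled on
the Arabidopsis stomatal lineage, where meristemoid precursors commit to
guard-cell fate under the control of bHLH transcription factors acting on
nucleosome-wrapped regulatory DNA. The package re-implements, as tested and
reusable functions, the computational analyses such a study needs:

- **Transcriptional entropy** — per-cell Shannon entropy of transcript
  proportions, `S = -Σᵢ pᵢ ln pᵢ` with `pᵢ = cᵢ / Σc`, a proxy for
  differentiation potential, plus a closed-form "two-tier" expression model
  (the top 10% of expressed genes holding, say, 40% or 50% of transcripts)
  that links entropy to the number of expressed genes and to expression
  concentration.
- **ChIP-seq peak integration** — permutation tests for peak-set overlap
  (subject peaks re-placed uniformly within their chromosomes), PWM motif
  occurrence within 100 bp of peak summits, peak-to-gene annotation with a
  3-kb promoter cutoff, and the target rule: a gene is a factor target iff
  it is expressed in ≥ 25% of factor-expressing cells, has
  log₂ fold change ≥ 0.223, and carries ≥ 1 binding site.
- **Nucleosome occupancy** — a transparent smoothed-peak nucleosome caller
  with a Poisson tail score, nucleosomal vs non-nucleosomal peak
  classification (summit ± 73 bp), reference-point and scaled gene-body
  metaprofiles, shared-vs-unique peak signal comparison, and induced
  differential occupancy with median-of-ratios size-factor normalization.
- **Binding-site spacing** — localization of each factor's best log-odds
  PWM site within 50 bp of peak centers, signed spacing distributions
  `d = pos_B − pos_A` at shared peaks, Kolmogorov–Smirnov comparison
  against the closed-form independence null (a triangular density
  `f(d) = (2W − |d|)/(2W)²` on `[−2W, 2W]`, optionally truncated for
  steric exclusion), and classification into constrained / relaxed /
  random co-binding.
- **Synthetic data with planted truth** — genomes with planted motifs
  (including constrained factor dimers), mock/induced nucleosome occupancy
  tracks with known depletion targets, and clustered single-cell count
  matrices with declared marker genes, so every analysis can be validated
  against ground truth at desk scale.

## Worked example

The full demo pipeline simulates a study-shaped data set and runs every
analysis on it:

```r
library(chromfate)
run_pipeline(out_dir = "demo", seed = 1)
read.table("demo/summary.tsv", header = TRUE, sep = "\t", comment.char = "#")
```

which prints (seed 1, default configuration):

```
                       metric       value
       entropy_median_uniform     6.86352
        entropy_median_tier40      6.5881
        entropy_median_tier50     6.39311
          overlap_empirical_p 0.000999001
                    n_targets          82
          peak_class_accuracy      1.0000
   diffocc_target_mean_log2fc     -0.9761
   diffocc_random_mean_log2fc      0.0046
                spacing_class constrained
              spacing_mean_bp      10.053
                spacing_sd_bp       1.940
```

Reading the numbers: the three simulated cell clusters reproduce the
entropy ordering uniform > 40%-concentration > 50%-concentration (more
expression concentration, lower entropy; the uniform median sits just
below ln 1000 ≈ 6.908 because of finite sequencing depth). The two peak
sets overlap far more than re-placed peaks would (empirical p = 1/1001,
the smallest value 1000 permutations can give). 82 genes pass the
25% / 0.223 / binding-site target rule. Peaks probed at planted nucleosome
dyads vs linkers are classified perfectly; targets of the induced
remodeling lose half their occupancy (mean log₂ fold change −0.98 vs 0.00
at untouched nucleosomes). The planted factor dimer (spacing 10 ± 2 bp) is
recovered as "constrained" with mean 10.05 bp and sd 1.94 bp.

Each stage is also callable on its own (`read_narrowpeak()`,
`cell_entropy()`, `permutation_overlap_test()`, `call_nucleosomes()`,
`pairwise_spacing()`, …); `inst/scripts/run_pipeline.R` is a thin shell
wrapper over `run_pipeline()`.

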