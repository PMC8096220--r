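# polpause

Nucleotide-resolution detection of RNA polymerase II pausing from
nascent-transcription occupancy data, and a model of what makes polymerase
pause.

NET-seq-style protocols record the 3' end of the nascent RNA inside engaged
polymerase, strand-specifically, at single-base resolution. Positions where
polymerase dwells accumulate reads on one exact nucleotide. `polpause`
provides the full analysis path from artifact-bearing reads to pausing
determinants:

* **Artifact filtering** — UMI-based PCR-duplicate collapsing and detection,
  removal and quantification of reverse-transcription mispriming (reads
  whose "UMI" is a copy of the genomic sequence downstream of the
  alignment), including the fraction of artifacts that escape exact-match
  detection through UMI errors.
* **Pause calling** — for every strict local maximum `i` with count `x_i`,
  the local context is the window of `L = 200` nt around it, holding `M`
  reads over `l` occupied positions. Under the null of no accumulation the
  `M` reads fall uniformly on the `l` positions, and the p-value is
  `P(max cell count >= x_i)` — evaluated by an exact multinomial-maximum
  computation where feasible and by `N = 10 000` seeded resamplings
  otherwise — followed by Benjamini–Hochberg correction across all
  candidates (`q < 0.05` is significant).
* **Genomic classification** — promoter-proximal (TSS + 300 nt), gene-body
  (exonic/intronic), antisense (divergent/convergent), intergenic
  (termination zone / enhancer / other), with the documented conflict rules
  and matched non-pausing control sampling.
* **Sequence features** — nucleotide skew differences and identities around
  the pause, RNA–DNA hybrid nearest-neighbor thermodynamics (ΔH, ΔS, ΔG37,
  Tm), nascent-RNA folding energy, DNA-shape summaries, TF/RBP motif-scan
  flags with exact null-calibrated thresholds, methylation and non-B DNA
  overlap flags; enrichment logos between pause and control sites.
* **Random-forest model** — tuned and cross-validated (PR-AUC) on balanced
  pause/non-pause sets, with cluster-aware permutation feature importance
  and significance filtering.
* **Synthetic data** — seeded generators for genomes, annotations, occupancy
  tracks with planted pauses, artifact-bearing reads and feature resources,
  so the whole pipeline is testable with known truth and no downloads.

## Worked example

```r
library(polpause)

# a synthetic study: 200 kb genome, 10 genes, planted 20-fold pauses
cfg    <- sim_config(genome_length = 2e5, n_genes = 10, seed = 7)
genome <- simulate_genome(cfg)
ann    <- simulate_annotation(cfg, genome)
occ    <- simulate_occupancy(cfg, ann, genome)

calls <- call_pauses(occ$track, pda_params(seed = 7))
sum(calls$significant)
#> [1] 29
nrow(occ$truth)   # planted pauses
#> [1] 29

# every planted pause recovered at its exact nucleotide, nothing else called
sig <- calls[calls$significant, ]
mean(paste(occ$truth$strand, occ$truth$pos) %in% paste(sig$strand, sig$pos))
#> [1] 1

classified <- classify_pauses(sig, ann)
table(classified$category)
#>
#> gene-body
#>        29

controls <- sample_nonpausing(classified, ann, seed = 7)
fm <- build_feature_matrix(classified, controls, genome)
dim(fm)   # 35 universal sequence features per site
#> [1] 58 37
```

The call table carries, per candidate position, the observed count, the
local density `(M, l)`, the raw and BH-adjusted p-values, and whether the
exact or resampling route evaluated it. `classify_pauses()` appends the
genomic category and subclass; `build_feature_matrix()` yields the tibble
the random-forest model (`pause_model()`, with `tidy()`/`glance()`
methods) consumes.

A thin command-line front end over the same functions ships in
`inst/cli/polpause` (subcommands `simulate`, `track`, `filter`, `call`,
`reproducibility`, `annotate`, `features`, `model`, `logo`), writing JSON
metadata sidecars for exact reruns.

See the methods vignette (`vignettes/pause-detection-methods.Rmd`) for the
statistical model, parameter conventions, and the design decisions behind
the artifact filter and the importance test.

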