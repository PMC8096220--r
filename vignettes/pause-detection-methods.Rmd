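---
title: "Methods: nucleotide-resolution pause detection and its determinants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nucleotide-resolution pause detection and its determinants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polpause)
```

# The problem

Nascent-transcription protocols such as NET-seq record the genomic position
of the 3' end of the RNA inside engaged RNA polymerase II, strand-specifically
and at single-nucleotide resolution. Where polymerase dwells, reads pile up
on one exact base. `polpause` turns such occupancy tracks into a catalogue
of statistically supported pausing sites, classifies them against a gene
annotation, derives DNA/RNA sequence features around them, and fits a random
forest that asks which of those features distinguish pausing from matched
non-pausing positions.

Two artifact classes are handled before any statistics: PCR duplicates
(removed by collapsing reads with identical position and 10-nt UMI) and
reverse-transcription mispriming, where the RT primer anneals to internal
adapter-like RNA so that the sequencer reads a copy of the *genomic* sequence
downstream of the alignment in place of the random UMI.

# The pause caller

## Null model and test

For every strict local maximum $i$ (a position with $x_{i-1} < x_i >
x_{i+1}$; absent neighbors count 0), the local context is summarised by the
window of length $L = 200$ nt centered on $i$: $M$ = total reads, $\ell$ =
occupied positions. Under the null that polymerase does not accumulate
anywhere, the $M$ reads are dropped uniformly and independently onto the
$\ell$ occupied positions, and the test statistic is the maximum
per-position count. The p-value for the observed count $x_i$ is the null
probability that this maximum reaches $x_i$.

Two evaluation routes exist and agree (a dual-route test asserts it):

* **Exact route** — $P(\max \ge k)$ for the uniform multinomial, via
  $P(\text{all cells} \le c) = \frac{M!}{\ell^M}[z^M]\left(\sum_{x=0}^{c}
  z^x/x!\right)^{\ell}$, computed by log-space polynomial exponentiation.
  For $k \le 4$ the composition sum collapses to closed forms (how many
  cells hold 2 or 3 reads), which covers nearly every candidate on sparse
  tracks and keeps genome-scale calling in seconds. The exact route is used
  whenever $M \cdot \ell$ is below `exact_cutoff` ($10^6$) and $M \le 500$,
  and is flagged `method = "exact"` in the output.
* **Resampling route** — $N = 10\,000$ seeded multinomial redistributions;
  the null pool is cached per $(M, \ell)$ with a seed derived
  deterministically from the run seed, so calls are bit-reproducible
  regardless of candidate order.

The default p-value is the add-one permutation form
$p = (1 + \#\{\max \ge x_i\})/(N + 1)$ rather than the literal "fraction of
simulations higher than observed": the literal rule can return $p = 0$ and
is anti-conservative on discrete ties. `pda_params(strict = TRUE)` restores
the literal rule for comparison.

p-values of **all** candidates of a sample (both strands pooled — the
simplest, most conservative family) are Benjamini–Hochberg adjusted;
`q < 0.05` is called significant. Equal-count plateaus are never candidates
(the strict inequality is taken literally); a two-base pause therefore goes
uncalled, a documented blind spot.

Window edges are clipped at contig boundaries. Downsampling for depth
sensitivity is per-read binomial thinning.

## Artifact handling

A read is an exact-match mispriming event when its UMI equals the 10
genomic bases immediately downstream of its 3' end *in transcription
direction* (the bases a correctly primed RT would have copied next); such
reads are removed outright. A position where more than 5% (strict) of its
reads are exact-match events is mispriming-prone: all of its reads are
removed and the position is masked from the track. Among reads at prone
positions, those with UMI/genome Hamming similarity of at least 0.5 (N
never matches) count as mispriming events, and the escaped fraction is the
share of those events whose UMI is *not* an exact copy — artifacts whose
copied UMI was altered by RT, PCR or sequencing errors.

Quantification runs **before** UMI collapse. Independent mispriming events
piling up at one locus all carry the identical genomic-copy UMI; collapsing
first merges them into a single read and deflates the exact-match count,
biasing the escaped fraction upward (we measured ~0.89 against a planted
truth of 0.40). Removal itself is order-invariant — the criteria depend
only on position and UMI, which PCR duplicates share — and uniform PCR
duplication leaves the escaped/total ratio unbiased, so pre-collapse
counting is the consistent estimator. On synthetic libraries with per-base
UMI corruption $\varepsilon$ the estimate converges to
$1 - (1-\varepsilon)^{10}$.

Splicing intermediates are masked by position: the strand-aware 3'-most
base of every annotated exon and intron plus every pA site (genomic end−1
on the plus strand, genomic start on minus), plus any user-supplied
intervals (abundant structural RNA classes).

# Genomic classification

Categories are assigned strand-aware in transcription direction:
promoter-proximal (within 300 nt downstream of *any* isoform TSS,
inclusive), gene-body (beyond +300 up to the 3'-most pA), antisense
(opposite strand, from 1 kb upstream of the most upstream TSS to the most
downstream pA; divergent upstream of the TSS, convergent within the body),
and intergenic (termination zone within 3.5 kb downstream of a pA, then
enhancer intervals, then other). A site falling in one gene's body and
another gene's antisense region is `undetermined`, as is the antisense
subclass when divergent and convergent assignments collide through
different genes. Promoter-proximal wins over gene-body where the
definitions overlap (the rules are stated in that order); classification is
independent of gene iteration order.

Matched non-pausing controls are drawn uniformly from
$[x, x+20]$ nt up- or downstream of each pause ($x = 50$ for
promoter-proximal, 300 otherwise), rejecting pause or masked positions, up
to 50 attempts before the pause is dropped from the paired set.

Genome-wide statistics follow the same conventions: active genes are
TPM > 1 (strict); the promoter-vs-body intensity comparison is a one-sided
Welch test (alternative: gene-body larger) across genes with pauses in both
regions; splice proximity uses a 40-nt radius with all matching boundary
labels kept; the premature-termination rule flags densities strictly above
the 25th linear-interpolation percentile of pA-site densities.

# Sequence features

The coordinate frame is anchored on the pause base at relative position
**−1** (the last nucleotide added to the nascent RNA); +1 is the
incoming-NTP site; there is no 0. All sequences are reported on the coding
strand 5'→3' in transcription direction, so minus-strand sites are exact
mirror images of their plus-strand constructions (a strand-symmetry test
asserts bit-equality).

* **Skew differences** (6): for each base pair $\{X,Y\}$,
  $\mathrm{skew} = (|X|-|Y|)/(|X|+|Y|)$ in the 20-nt windows whose near
  edges sit 10 nt from the site ([−29,−10] and [+10,+29]); the feature is
  downstream minus upstream. The sentence defining the windows admits a
  second reading (windows abutting the site); `placement = "adjacent"`
  implements it, the offset reading is the default.
* **Nucleotide identities** (24): one-hot at +1, −1, −2, −3, −10, −11 —
  the active center and both ends of the RNA–DNA hybrid.
* **Hybrid thermodynamics** (4): nearest-neighbor ΔH, ΔS, ΔG37 and
  two-state melting temperature of the 10-bp RNA–DNA hybrid (−10…−1),
  using the published Sugimoto RNA/DNA parameter set shipped as a TSV
  (swappable). $T_m$ uses $C_T/4$ with $C_T = 10^{-4}$ M and no salt
  correction; only the monotone ordering matters to the classifier, not
  absolute calibration.
* **Nascent-RNA folding energy** (1): minimum free energy of the −29…−11
  stretch (the hairpin-forming region beyond the exit channel). The
  builtin engine is a deliberately simple stacking-only nearest-neighbor
  model (pairs AU/GC/GU, minimum hairpin loop 3; energy only from stacked
  pair steps, GC = 3, AU = 2, GU = 1 kcal/mol per half-stack) solved
  exactly by dynamic programming and verified against exhaustive structure
  enumeration up to 12 nt. `RNAfold` can be plugged in as an external
  engine; the engine used is recorded in provenance.
* **Shape summaries** (25): user-supplied pentamer table (MGW, Roll, ProT,
  HelT, EP) slid over −10…+5; min, max, mean, span, and mean absolute
  successive difference per descriptor.
* **Motif flags**: log2-odds PWM scans with thresholds set from the exact
  null score distribution (DP over the background) at tail mass $10^{-4}$.
  TF motifs are scanned on both strands in the polymerase footprint
  [−26,+25], upstream [−126,−27] and downstream [+26,+125] regions; RBP
  motifs only on the coding strand of the upstream region — the stretch
  already transcribed into RNA.
* **Methylation / interval flags**: mean methylation over covered positions
  within ±100 nt (0 plus a coverage flag when uncovered); 0/1 overlap flags
  against non-B DNA / G4 interval sets within ±100 nt.

Sites with ambiguous bases or windows leaving the contig are dropped, not
imputed, and recorded. Without optional resources the universal block is
exactly 35 columns. Enrichment logos are per-position
$\log_2((f_{fg}+0.01)/(f_{bg}+0.01))$ matrices between pause and control
sequences.

# The classifier

A probability random forest (the `ranger` backend) on the balanced
pause/non-pause matrix. About 20% of sites (stratified) tune the
hyperparameters by grid search on internally cross-validated PR-AUC; the
remaining 80% are scored by stratified k-fold cross-validation (k = 10 by
default, 5 for small site sets). scikit-learn's four knobs do not map 1:1
onto ranger, so the grid tunes `num.trees`, `max.depth` and
`min.node.size` (the latter subsumes the two minimum-sample knobs); ties
break toward the smaller model. PR-AUC is computed by step-wise summation
over thresholds with ties grouped, verified against brute-force enumeration.

Permutation importance is evaluated on held-out folds: per feature, fold
and repeat, the column is shuffled and the drop in PR-AUC from the fold's
baseline recorded. Repeats within a fold share a fitted model and are
strongly correlated, so repeat values are averaged per fold and a one-sided
t-test is taken across the k independent folds, BH-corrected across
features; treating all repeats-by-folds values as independent overstates
the effective sample size enough to flag pure-noise features. A second
caveat the tests encode: at a saturated PR-AUC of 1, permuting *any*
column can only hurt, handing even noise columns a positive bias — planted
recovery benchmarks therefore operate below saturation.

# The synthetic study

The generator defines the conditions every guarantee is measured under: a
1 Mb i.i.d. genome at GC 0.41; 50 non-overlapping multi-exon genes of
4–12 kb alternating strands (a narrow gap every fifth gene plants
antisense-conflict loci); background reads placed uniformly within gene
spans at 0.1 reads/nt — exactly the caller's null, so null tracks are a
true type-I-error benchmark; planted single-nucleotide pauses at 0.4/kb
receiving 20× the mean count per covered base ("fold over the local mean"
reads as per covered base, not per nucleotide — at 0.1 reads/nt the
per-nucleotide reading would plant 2-read spikes that no resampling test
could ever call, making recovery benchmarks vacuous); 10% PCR duplication;
5% mispriming concentrated at 20 adapter-like loci with the downstream
genomic 10-mer as UMI, each base corrupted at rate 0.05 where escape is
being studied. Deeper backgrounds (0.25–0.6 reads/nt) are used where a
benchmark's stated sample size demands it (≥10⁵ null reads; ≥10⁴ planted
mispriming events).

What the generator does **not** emulate: real base composition and repeat
structure, splicing intermediates beyond position masks, polymerase
processivity or gene-level rate variation, and sequencing errors outside
the UMI. Passing tests therefore demonstrate the statistical machinery is
correct and calibrated under its own assumptions, not that biological
conclusions transfer to any particular organism.

Benchmark problem sizes (1 Mb genomes, 10–20 null seeds, n = 2000 model
matrices, 3–10 recovery seeds) were chosen so the full suite runs on a
laptop-class single core in minutes while keeping every Monte-Carlo bound
comfortably away from its threshold.

# Numerical and degenerate-input conventions

All coordinates are 0-based half-open internally; GTF converts on load;
bedGraph is native. Non-integer bedGraph values are rejected (the null
model needs counts). $\ell = 1$ windows give p = 1. `k ≤ ⌈M/ℓ⌉` short-cuts
to p = 1 by pigeonhole. A zero margin gives Fisher p = 1. Empty tracks
yield empty call sets; empty pA sets are an error for the termination rule.
Quantiles are type-7 (linear interpolation). Every stochastic function
takes an explicit seed and restores the caller's RNG state.

# Known limitations

* Plateaus (adjacent equal maxima) are invisible to the strict definition.
* The BH family pools a whole sample; per-region families would change
  borderline calls.
* The escaped-fraction estimator needs prone loci deep enough to trip the
  5% rule; scattered single-read mispriming escapes both removal and
  quantification.
* The builtin folding model is a ranking device, not a thermodynamically
  calibrated predictor.
* `replicate_overlap` reports the weakest pairwise Fisher p when more than
  two replicates are supplied.
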