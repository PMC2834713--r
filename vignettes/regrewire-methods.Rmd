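---
title: "Methods: comparative ChIP-chip peak calling and network rewiring analysis"
author: "regrewire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative ChIP-chip peak calling and network rewiring analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regrewire)
```

## Scope and model

`regrewire` implements the computational core of a comparative ChIP-chip
study design: two related yeast species are profiled with full-genome
tiling arrays (on the order of 17--20 probes/kb) for a panel of
transcription factors (TFs), and the question is how the *regulons* -- the
sets of genes each TF binds -- and the networks they form have been
rewired between the species. The package covers five stages:

1. **Peak calling** on probe-level log2 IP/control enrichment tracks.
2. **Target assignment** of peaks to genes through intergenic promoter
   regions.
3. **Regulon statistics**: genome coverage, cross-species overlap under an
   orthology map, GO enrichment with hierarchy expansion, TF--GO / TF--TF /
   TF--kinase networks with Pajek export, and randomized nulls.
4. **Sequence analysis**: spaced-triplet ("mini-motif") enrichment in
   300 bp peak windows, and degenerate-consensus matching.
5. **Co-occupancy**: covariance of per-bp binding signals between TFs over
   promoter sets, and reference-anchored peak distances.

A sixth module generates fully seeded synthetic two-species datasets with
planted ground truth, so every stage is testable end to end without
external data.

## Peak detection

For each experiment the pipeline (i) applies a Gaussian blur to the probe
log2 ratios, (ii) interpolates the blurred probe values to every base pair
with a natural cubic spline, and (iii) extracts discrete 1 bp peaks
greedily: take the global argmax of the unmasked signal, emit a peak, mask
the surrounding 600 bp window, repeat. A peak is *significant* when its
height exceeds the experiment's raw probe mean by at least `z` raw
standard deviations (`z = 2.0` by default); the reference distribution is
always the raw, pre-blur probe values of the same experiment, so the blur
cannot shift the significance scale.

Parameter choices that matter:

* **Blur sigma (`sigma_bp`, default 50 bp).** Roughly one probe spacing at
  17--20 probes/kb: it suppresses single-probe outliers without merging
  peaks in adjacent promoters. The kernel weight is
  $\exp(-d^2 / 2\sigma^2)$ over the probe distance $d$ in bp, normalized
  to sum to one per probe. For linear-time evaluation contributions beyond
  $4\sigma$ (weight $< 3.4\times10^{-4}$) are dropped; on the package's own
  worked examples this changes smoothed values by less than $10^{-6}$.
* **Mask window (`mask_window_bp`, default 600).** Interpreted as a total
  width, i.e. $\pm 300$ bp around the emitted summit, endpoints inclusive.
  At 17--20 probes/kb this is about ten probes.
* **Stop rule.** Greedy extraction needs a floor; the pipeline stops when
  the unmasked maximum falls below the raw track mean. Significance is
  applied downstream anyway, so the floor only bounds the candidate list.
* **Ties.** Argmax ties break to the leftmost coordinate, then to the
  lexicographically first chromosome, making extraction deterministic.

The greedy extractor is validated against a brute-force oracle that
rescans an explicit mask array every round, on random tracks up to 10 kb.

## Target assignment

Internally all coordinates are 0-based half-open; GFF3 (1-based inclusive)
and BED are converted at the I/O boundary only. Intergenic regions are the
maximal gaps between merged gene spans plus chromosome-end gaps; together
with the merged spans they tile each chromosome exactly. A region is the
*promoter* of each flanking gene transcribed away from it: divergent
flanks give two promoter genes, convergent flanks none, tandem flanks one.
A significant peak contributes its region's promoter genes to the regulon;
peaks inside ORFs are flagged intragenic and contribute nothing. Binding
in a convergent region is recorded but yields no target -- the region
simply has an empty promoter set. How intergenic binding maps to
regulated genes is a convention, not a measurement; this one is the least
surprising and is confined to `compute_intergenic_regions()` and
`assign_targets()`.

## Enrichment statistics

Every enrichment in the package is an upper-tail hypergeometric
probability $P(X \ge k)$ for $X \sim \mathrm{Hypergeom}(N, K, n)$,
computed with `stats::phyper`. Cross-species regulon overlap counts
**ortholog pairs**: the universe is the set of pairs, $n$ and $K$ are the
numbers of pairs whose species-1 (species-2) member is bound, and $k$ the
pairs bound in both. Counting at the pair level sidesteps any arbitrary
collapsing of many-to-many orthology and is symmetric between species.
Overlaps with $p > 10^{-2}$ are labelled non-significant, matching the
display threshold used for TF--GO edges; a stricter $10^{-4}$ flag is
carried alongside. GO annotations are expanded up the hierarchy before
testing (a gene in a term is a gene in every ancestor), which makes
expansion monotone and idempotent; enrichment p-values are reported raw,
with a Bonferroni column as an auxiliary, because the downstream network
thresholds are defined on raw p.

The promoter-length randomization draws pseudo-regulons either uniformly
or with probability proportional to promoter length
(`weight_by_length = TRUE`). Length-proportional sampling is this
package's reading of a "correction for promoter length": long promoters
accumulate noise peaks roughly in proportion to their length, so a null
that ignores length understates the noise contribution of long promoters.

## Mini-motif scan

The scanner enumerates every motif of the form
`XXX n(g) XXX` with two fixed triplets over ACGT and a fixed gap
$g \in \{0, \dots, 15\}$ ("separated by less than 16 bp"):
$64 \times 16 \times 64 = 65{,}536$ raw motifs. A sequence *contains* a
motif when the motif or its reverse complement occurs with exactly that
gap; `N` matches nothing. Reverse-complement pairs are merged to their
canonical (lexicographically smaller) form before ranking, giving
$33{,}280$ double-stranded classes ($1{,}024$ of the raw motifs are
palindromic and are their own class).

The comparison set is a per-sequence mononucleotide shuffle: identical
length and base composition, order permuted by a seeded generator. The
enrichment of a motif is framed as one hypergeometric urn: the real and
shuffled sequence sets are pooled ($N = n_\mathrm{real} +
n_\mathrm{rand}$), the motif-containing sequences are the successes
($K = k_\mathrm{real} + k_\mathrm{rand}$), and the tail probability of
drawing $k_\mathrm{real}$ successes in $n_\mathrm{real}$ draws is
reported. This framing is one concrete resolution of "over-representation
compared to a randomized sequence space of equal size"; it is isolated in
`minimotif_scan()` so an alternative (e.g. binomial) could be swapped in
one place. Scanning a shuffled set against itself gives
$k_\mathrm{real} = k_\mathrm{rand}$ for every motif and a minimum p of
order 0.5 -- the calibration check in the test suite. A dinucleotide-
preserving shuffle is deliberately not offered: the mononucleotide model
is the one the enrichment framing assumes, and a biased null would need
its own calibration study.

Peak windows are 300 bp centered on each 1 bp summit, clipped (and
flagged) at chromosome ends; `subset = "top_quarter"` restricts to the
top 25% of peaks by height, the subset a discovery tool like MEME would
see, while the exhaustive scan runs on the full window set.

## Co-occupancy

For a pair of TFs and one promoter region with per-bp signals $a, b$, the
co-occupancy score is the normalized scalar product
$\sum_i a_i b_i / \sqrt{\sum_i a_i^2 \sum_i b_i^2}$ (cosine), 0 when
either norm vanishes; the matrix entry is the unweighted mean over
regions. Normalizing per region makes scores comparable across promoters
of different lengths and signal scales; the raw dot product and a
mean-centered (Pearson) variant are available via `method=`. Signals are
used as-is -- log2 ratios may be negative, and negation flips the score's
sign. Peak distances anchor on the *reference* TF's highest peak per
region and measure to the *other* TF's nearest peak; means are reported
with the sample (n−1) standard deviation.

## Differential ORF signal

For two experiments on the same probe grid (e.g. a histone-acetylation
ChIP before/after rapamycin), each ORF gets the mean of probewise log2
differences over the probes it contains, and an ORF is called
significantly *decreased* when its mean lies at least `z` scale units
below the center of the per-ORF distribution (one-sided, `z = 2`). The
center and scale are the median and MAD by default rather than mean and
sd: when a fifth of ORFs share a common decrease, the contaminated mean
and sd place the decreased ORFs at exactly $-2$ standardized units, so a
mean/sd rule at $z = 2$ is knife-edge by construction. The robust default
tests each ORF against the unaffected background; `location = "mean"`
restores the plain rule. The fraction of significant ORFs flagged as
ribosomal-protein genes is attached to the result.

## Synthetic data: what it emulates, and what it does not

`simulate_species_pair()` lays out genes and intergenic gaps (Gaussian
lengths, truncated at 300/200 bp) on i.i.d.-uniform ACGT chromosomes,
draws a 1:1 orthology over a configurable fraction of genes, and builds a
two-level GO hierarchy in which one leaf term is annotated exactly to the
RP-flagged genes. Defaults -- two species, 2 chromosomes × 250 genes
(~1 Mb per species), probe densities 20 and 17 probes/kb with ±20%
grid jitter -- generate in seconds and mirror the scale ratios of a real
tiling design. `plant_binding_sites()` writes motif instances into
promoter DNA and records ground truth; `simulate_chip_experiment()`
renders each site as a Gaussian bump (width sd 100 bp, the scale set by
~300 bp sonication fragments) plus i.i.d. probe noise. The default noise
sd of 0.5 log2 units with planted amplitudes 2 and 4 gives
signal-to-noise ratios of 4 and 8, the regimes in which recovery is
evaluated.

What the generator does **not** model: nucleosome occupancy and
accessibility structure, dye bias and spatial array artifacts, copy-number
and repeat regions, correlated probe noise, GC-skewed background (an
option exists for the motif null but is off by default), and partial or
many-to-many orthology beyond what the 1:1 map expresses. Passing
recovery tests on this generator therefore demonstrates correctness of
the algorithms under their stated model, not robustness to every artifact
of real arrays.

## Numerical and degenerate-input choices

* Blur kernel truncated at $4\sigma$; `sigma_bp = 0` is the exact
  identity.
* Natural-spline evaluation never extrapolates beyond the outermost
  probes; interpolation requires at least two probes.
* `sd_raw = 0` (a constant experiment) is an error for Z-calling, not a
  silent pass-through.
* Zero-norm region signals score 0 co-occupancy; zero scale in the
  differential rule yields no significant ORFs.
* Probe tracks are sorted on ingestion (with a message); duplicate
  positions are an error, since they indicate a malformed track rather
  than a convention difference.
* bedGraph intervals are represented by their midpoint,
  `floor((start + end) / 2)` in 0-based coordinates: the interpolation
  model treats probes as points.
* Greedy matching in `evaluate_recovery()` pairs called peaks to planted
  sites closest-first, one-to-one, within ±50 bp by default.

## Problem sizes used in the shipped checks

The test suite and the acceptance script size their simulations to run on
a single CPU in a few minutes: the two-species default scenario
(2 × ~1 Mb, 500 genes per species, one planted TF at 50 promoters with
50% conservation), mini-motif scans of 200 real + 200 shuffled 300 bp
windows over all 65,536 motifs, brute-force oracle sweeps at $N \le 12$
(hypergeometric) and 100 random ≤10 kb tracks (peak extraction), and
co-occupancy over 20 promoter regions × 4 simulated factors.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_species_pair(seed = 1)
regs <- sample_target_regions(sim, "SpA", 50, ortholog_only = TRUE, seed = 1)
sim <- plant_binding_sites(sim, "SpA", "TF1", regs, minimotif("CAC", 0, "GTG"),
                           amplitude = 2, conservation = 0.5, seed = 1)
track <- simulate_chip_experiment(sim, "SpA", "TF1",
                                  noise_model(probe_sd = 0.5), seed = 1)
regulon <- call_regulon(track, sim$species$SpA$regions, sim$species$SpA$genes)
evaluate_recovery(regulon, sim, "SpA", "TF1")
```

See the package README for this example's printed output and its
interpretation, and `scripts/acceptance.R` for the full set of recomputed
quantities.

## Known limitations

* Peak calling has no FDR control; the Z threshold is a fixed-scale rule
  inherited from the study design the package models.
* Replicates and dye swaps are out of scope; tracks are assumed already
  normalized to log2 ratios.
* The mini-motif p-values are raw; with 33,280 correlated tests, single
  motifs near $p \approx 10^{-4}$ should be treated as screening hits.
* Cross-species edge conservation uses the union convention for the
  denominator; with many-to-many orthology a different identification
  could change the count.
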