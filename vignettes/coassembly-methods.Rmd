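---
title: "Methods: deciding and quantifying SAG co-assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deciding and quantifying SAG co-assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sagco)
```

## The problem

Single-cell genomics of uncultured microbial eukaryotes starts from one
sorted cell whose genome is whole-genome amplified (multiple displacement
amplification, MDA) before sequencing. MDA bias means each single amplified
genome (SAG) recovers a different random ~15-25% of the genome, and deeper
sequencing does not help: recovery saturates. Pooling reads from several
conspecific cells into a co-assembly recovers far more — but only if the
cells really are the same species. `sagco` implements both halves of that
workflow at desk scale:

1. **Screening**: which cells may be co-assembled? Three criteria, all
   required — an identical marker gene (the 18S rDNA in practice), average
   nucleotide identity (ANI) above 95%, and membership in the same
   tetranucleotide-composition cluster.
2. **Quantification**: what did the co-assembly gain? Marker-gene
   completeness, genome-size extrapolation from saturation curves, and a
   per-base partition of the co-assembly by the number of supporting cells.

Everything runs against a bundled simulator, so the full pipeline is
testable offline with known ground truth.

## The simulator: what it emulates, and what it does not

`simulate_genome()` draws an i.i.d. nucleotide sequence at a target GC
(presets 0.339 and 0.441 echo the two study lineages) and embeds
non-overlapping single-copy marker genes — stand-ins for the 248 core
eukaryotic genes used for completeness. Markers are drawn at the host GC
with a fixed purine skew (P(A|AT) = P(G|GC) = 0.65): recognizable
composition, unchanged GC, so the realized genome GC stays within ±0.01 of
target.

`simulate_mda_coverage()` models MDA bias with the simplest mechanism that
reproduces "a different random region per cell": blocks with exponential
lengths (one scale parameter, `mean_block`, default 10 kbp) and uniform
starts are laid down until the union reaches the target fraction `p`
(default 0.20); the last block is trimmed so the covered fraction lands on
`p` exactly. No chemistry is modelled — no chimeras, no branch
displacement, no heterozygosity; the literature gives no quantitative MDA
model, and none of the downstream statistics depends on more than "random
blocks, fixed fraction". Two useful consequences are analytic and are used
as oracles in the tests: the union of n independent cells covers
`1 - (1-p)^n` of the genome in expectation, and the number of cells
supporting a base is Binomial(n, p).

`emulate_assembly()` stands in for a short-read assembler: each covered
block becomes contigs (Poisson breakpoints), point substitutions at a
chosen rate, and contigs under 1 kbp are discarded — the same length filter
used for real SAG assemblies. `simulate_reads()` generates 101 bp
paired-end reads at a fixed insert length (no insert-size distribution;
nothing downstream uses one), constant quality strings, and a read count of
`floor(depth * length / (2 * read_len))`. `inject_contaminant()` appends
contigs from an independently simulated genome at a different GC,
emulating prey or other foreign DNA inside a sorted cell.

The default desk preset (`pipeline_config()`) is a 1 Mbp genome and 14
cells at p = 0.20, echoing the 14-cell clade with ~19% mean per-cell
recovery that motivates the method. Tests use reduced versions
(50-300 kbp genomes, 4-5 cells) chosen so each suite exercises the same
statistics at a few seconds per block; these sizes are stated in the test
files and are a deliberate scaling of the same conditions, not different
conditions.

What passing tests therefore show: the estimators are correct for genomes
whose composition is homogeneous i.i.d. and whose amplification is
independent random blocks. What they cannot show: behaviour under real
repeat structure, chimeric MDA artifacts, heterozygosity, or assembler
errors — the statistics on real data will be noisier than the simulator
suggests.

## Composition screening

Contigs are cut to 2.5-5 kbp fragments (shorter discarded, longer cut into
5 kbp windows, terminal remainder kept only if ≥ 2.5 kbp) and profiled as
256-dimensional tetranucleotide frequency vectors, counted with a 1 bp
slide on both strands (so a fragment and its reverse complement give
exactly the same vector; palindromic tetramers are not collapsed — the
both-strand counting already symmetrizes). Windows containing ambiguous
bases are skipped rather than randomized, for determinism.

Columns are standardized robustly: median-centred, scaled by
1.4826 × MAD (the consistent robust sigma); constant columns map to zero.
A batch self-organizing map on a toroidal lattice (default 20 × 30,
Gaussian neighbourhood, radius decaying linearly from `max(rows, cols)/2`
to 1) is trained for 30 epochs; the toroidal wrap avoids splitting a
cluster across map edges. Training is deterministic given the seed (weights
initialize from sampled data rows). The U-matrix (mean distance of each
neuron to its 8 lattice neighbours) visualizes ridges between composition
clusters.

Cluster extraction connects adjacent neurons whose weight distance falls
below the `ridge_quantile` (default 0.6) quantile of all adjacent-pair
distances; connected components are clusters and fragments inherit their
best-matching unit's cluster. A cluster is flagged **deviant** (candidate
foreign DNA) when it holds fewer than `deviant_frac` = 0.10 of the
fragments; the largest cluster is never flagged. The threshold is a
fragment *share*, not a fixed 1%, because a realistic contamination event
(a few dozen foreign fragments among hundreds) sits in the 2-8% range —
a 1% cut-off would miss exactly the clusters the screen exists to catch,
while 10% still cannot flag either half of a genuine two-species mixture.

## Pairwise identity

`pairwise_local_hits()` is a light local aligner built for
assembly-vs-assembly comparison: exact 15-mer seeds against both subject
strands, merged into maximal exact anchors, chained per (query contig,
subject contig, strand, 32 bp diagonal band) with a 500 bp gap limit.
Inter-anchor gaps of equal length are compared directly (substitution
counting); unequal gaps are globally aligned. Hits under 70% identity or
100 bp are discarded, and overlapping hits on a query region are resolved
best-score-first. The 100 bp minimum-hit-length filter deliberately
replaces an e-value screen: at desk scale, chance 15-mer chains of 100 bp
at ≥ 70% identity are effectively absent, and the package makes no claim
to Karlin–Altschul statistics.

ANI is the alignment-length-weighted mean identity over accepted hits.
Because each cell recovers a different genome region, "shared genomic
content" has no single denominator; both per-assembly shared fractions
(percent of each assembly covered by ≥ 1 accepted hit) are reported.
`decide_compatibility()` ANDs the three criteria; the ANI test is strictly
greater than the 95% threshold, and indels in the marker-gene screen count
as mismatches (conservative: an indel-bearing pair is never "identical").

## Recovery and extrapolation

A marker is detected only when a *single* alignment locus covers ≥ 70% of
its reference at ≥ 95% identity — split detections do not add up,
mirroring how core-gene completeness tools score per protein. Completeness
is `100 * detected / catalog`; the percentage is taken at two decimals
first (the precision completeness tools print) and then reported at one
decimal, half away from zero — this two-stage rounding is what makes
169/248 report as 68.2 rather than 68.1. Genome size is extrapolated as
`100 * assembly_size / completeness`, one decimal.

Saturation is handled twice. Read subsampling (`subsample_reads()`, mate
pairs kept together, default fractions 17/33/50/67/83% with five seeded
replicates) feeds an idealized reassembly (`assemble_from_reads()`: merge
the truth intervals of error-free reads, keep runs ≥ 1 kbp) — an
emulation standing in for re-running a real assembler per subsample, which
is out of scope. Cumulative co-assembly curves
(`cumulative_coassembly_curve()`) average the union size over 20 random
cell orderings (the real ordering protocol is unstated, so averaging is
the neutral choice); with simulator truth present the union is exact
interval arithmetic, otherwise a greedy non-redundant merge on ≥ 95%
hits.

`fit_michaelis_menten()` fits `y = Vmax*x/(Km + x)` by Levenberg-Marquardt
least squares over all points (replicates pooled, not averaged), started
from the Hanes-Woolf linearization `x/y = x/Vmax + Km/Vmax`; degenerate
starts fall back to `1.05 * max(y)` and the median effort. Decreasing or
non-saturating data are flagged `diverged` rather than rejected. One
caveat the package states openly: the expected union curve of independent
block coverage is `G(1 - (1-p)^k)`, an exponential saturation, and the
best least-squares MM fit to that shape overshoots the true genome size by
roughly a third at p = 0.2 — the MM asymptote is an upper extrapolation,
not an unbiased estimator, and the tests check it against the
least-squares optimum (by exhaustive grid search) rather than against the
truth.

## Contribution partitioning

`build_coverage_mask()` marks, per co-assembly base, which cells provide
evidence: by default ≥ 95%-identity contig alignments (deterministic, no
read mapper needed); optionally exact placement of error-free reads. The
sharing spectrum tallies covered bases by the exact number of supporting
cells; fractions are over covered bases (k ≥ 1), since every co-assembly
base derives from at least one cell by construction. Marker gain/loss
classifies each marker found in cells and co-assembly by the mean pairwise
identity of the cell copies — exactly 100 / [95, 100) / below 95 — with
single-cell markers reported as not applicable, and exclusives counted per
side. Concordance statistics report, per cell, the percent of its assembly
inside accepted alignments and mismatch/indel rates per 100 kbp of aligned
bases, with indels counted per gap opening (event counts, the standard
assembly-comparison convention, which the source protocol leaves
unspecified).

## Numerical and design choices, collected

- Coordinates are 0-based half-open internally; FASTA/FASTQ emitted per
  standard. All tabular outputs are TSV with a `#`-prefixed header; nested
  reports are JSON. No binary formats.
- All randomness flows from one root seed; `run_pipeline()` derives a
  per-stage seed as `(seed * 7919 + sum of stage-name codepoints) mod
  2^31-1`, so reruns are byte-identical and stages are independently
  reproducible.
- Reporting rounds half away from zero, only at reporting boundaries.
- Ties in best-matching-unit search break to the lowest neuron index;
  zero-variance tetra columns normalize to zero; empty hit sets yield
  ANI `NA` with shared fractions 0, and zero completeness refuses to
  extrapolate a genome size.
- SOM hyper-parameters (grid 20 × 30, Gaussian kernel, linear radius
  decay) and aligner constants (k = 15, band 32, gap 500) are package
  choices: the tools the protocol names do not document theirs, so
  results are contractually similar, not bit-identical, to any
  particular implementation.

## A small worked run

```{r run, eval = FALSE}
cfg <- pipeline_config(genome_len = 120000, n_markers = 12,
                       marker_len = 900, n_sags = 4,
                       coverage_fraction = 0.3, som_rows = 8,
                       som_cols = 12, som_epochs = 15,
                       n_orderings = 8, seed = 11)
run <- run_pipeline(cfg, outdir = tempfile("sagco_run"))
run
run$compatibility
autoplot(run$contribution$spectrum)
```

## Known limitations

- The MDA block model is uncalibrated: real per-cell recovery fractions
  and block-length spectra are unknown, so absolute simulated numbers
  (e.g. mismatch rates) are not predictions for any real data set.
- Marker detection is alignment-based against a provided catalog; it is
  not an HMM gene finder, and diverged markers below 95% nucleotide
  identity to the catalog will be missed.
- The read mode of the coverage mask places only error-free reads
  exactly; with sequencing errors it undercounts and the contig mode
  should be used.
- Deviant-cluster flagging finds *minor* composition clusters; it cannot
  separate a 50/50 mixture of two genomes into host and contaminant —
  that is what the ANI and marker criteria are for.
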