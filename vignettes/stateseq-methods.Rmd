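---
title: "Models and methods behind stateseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stateseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`stateseq` implements the computational core of a study design that asks how
feeding state reshapes both gene expression in identified *Drosophila*
neurons and sleep behavior in the whole animal. It has two analysis arms —
reconstruction and differential expression of single-neuron 3'-tag
transcriptomes, and sleep scoring with Markov drive statistics from
Drosophila Activity Monitor (DAM) traces — plus a synthetic-data generator
that stands in for the wet-lab inputs so that every downstream stage can be
tested against known ground truth. This vignette explains the models, the
tunable parameters and their defaults, the numerical choices, and what the
synthetic data does and does not emulate.

## The sequencing arm

### Library model

The simulator emulates a CEL-Seq2-style library. Each cell's RT primer
carries a cell barcode and a hexamer unique molecular identifier (UMI), so
read 1 is laid out as `[barcode][UMI][poly-T fill]` and read 2 is a 3'-tag:
the 3'-terminal `read2_length` bases of the originating transcript. The
default geometry is 25 x 50 paired-end. The barcode whitelist is generated
deterministically from the seed under a pairwise Hamming distance >= 3
constraint, which guarantees that demultiplexing with one tolerated
mismatch can never be ambiguous.

Per cell and gene, the true molecule count is negative binomial with mean
$\mu_{gc}$ and dispersion $\alpha$, variance $\mu + \alpha\mu^2$. Starved
cells multiply the mean of each truly differentially expressed gene by
$2^{\mathrm{lfc}}$. Captured molecules are a binomial thinning at
`capture_efficiency` (default 0.3, a realistic single-cell capture rate);
each captured molecule emits $1 + \mathrm{Poisson}(\lambda_{PCR})$ read
pairs and uniform substitution errors are applied per base. Spike-in
molecules are appended to every cell as Poisson draws at the configured
dilution series (default a two-fold series from 0.5 to 16 expected
molecules, sized so spike reads stay a few percent of transcript reads).

One deliberate idealisation: within each (cell, gene) group, UMIs are drawn
uniformly but re-drawn until all pairwise Hamming distances are >= 2. In a
real library two molecules can collide on the same or a neighbouring UMI,
in which case *any* UMI-collapsing scheme undercounts; excluding collisions
makes the truth table the exact expected output of deduplication, so the
end-to-end identity (count matrix equals truth for any PCR duplication rate
at zero sequencing error) is a meaningful test rather than an approximate
one. At the default hexamer length the excluded event is rare anyway
(collision probability about $k^2/2 \cdot 7/4096$ for $k$ molecules of one
gene).

The simulator does not model IVT amplification bias, fragment-size
profiles, or per-base quality scores; passing tests therefore say nothing
about robustness to those artefacts.

### Quantification

Reads are demultiplexed by nearest whitelist barcode within one mismatch
(the whitelist's distance property makes this unambiguous; whitelists that
violate it are rejected outright). Transcript assignment is an exact-match
k-mer lookup (default k = 15) against the indexed 3' region of each
transcript: a read is assigned to the gene it uniquely matches, and reads
matching no gene or more than one are left unassigned — ties are never
broken arbitrarily. This stands in for genomic alignment at toy-reference
scale; there is no gapped alignment or splice awareness.

UMI collapsing uses the directional network rule: a directed edge runs from
UMI $a$ to $b$ when they differ at one base and
$\mathrm{count}(a) \ge 2\,\mathrm{count}(b) - 1$; clusters grow greedily
from the highest-count unvisited node (ties broken lexicographically, for
determinism across platforms) following edges transitively, and each
cluster counts as one molecule. The test suite checks this implementation
against an independent reachability-closure oracle across the space of
small UMI multisets.

### Quality control and normalisation

Cells are admitted by three criteria: spike-in reads over transcript reads
below 0.09, Pearson correlation between expected spike-in amounts and
detected spike-in molecule counts above 0.8, and at least 250,000 aligned
reads. "Aligned reads" counts reads assigned to any reference feature
before deduplication, since it is a read-depth criterion; linearity is
computed on the linear scale between expected molecule amounts and
deduplicated counts. With fewer than three spike-in species, or a
zero-variance detection profile, linearity is undefined and the cell fails
with a distinct flag. The bundled demo rescales only the aligned-read floor
(to 100), because the demo library is orders of magnitude shallower than a
real sequencing run; the 250,000 default is the intended production value.

TPM normalisation divides each gene's molecule count by the cell's total
over non-spike-in genes and multiplies by $10^6$. No transcript-length
division is applied: in a 3'-tag protocol each molecule contributes one tag
regardless of transcript length, and length correction would distort
molecule proportions.

### Differential expression

The test is a deliberately simplified negative-binomial Wald framework.
Size factors are median-of-ratios against the geometric-mean reference
profile (computed over everywhere-nonzero genes, with a positive-counts
fallback), rescaled to geometric mean 1. The analysis restricts itself to
the most variable genes (default 2000), ranked by variance of
$\log_2(\text{normalized count} + 1)$ — the scale choice is a package
decision and configurable.

Per gene, a method-of-moments dispersion is pooled across the two
conditions and floored at $10^{-8}$ (keeping the Wald standard error finite
for near-Poisson genes); condition means $q$ are fitted by maximum
likelihood under $y_i \sim \mathrm{NB}(s_i q, \alpha)$ with the size
factors $s_i$ as offsets. The Wald statistic is
$\log_2(q_\text{starved}/q_\text{fed})$ over its standard error from the
expected Fisher information, referred to the standard normal, with
Benjamini-Hochberg adjustment across genes. Reporting thresholds default to
adjusted p < 0.1 and linear fold change > 1.5 (interpreted as
$|\log_2 FC| > \log_2 1.5$; the alternative reading, $|\log_2 FC| > 1.5$,
is available by setting `fc_highlight = 2^1.5`).

Known limitations, by design: there is no dispersion shrinkage toward a
fitted trend, no fold-change shrinkage and no independent filtering, so
numeric equality with a full DESeq2 analysis is not claimed. A group with
all-zero counts takes a half-molecule continuity value so the fold change
stays finite (flagged in `zero_group`). Calibration of the plug-in Wald
test is good at the study's cell numbers (the null p < 0.05 fraction sits
near 0.05 at 20 cells per condition) but becomes anticonservative below
roughly 15 cells per group; analyses of smaller groups should treat
borderline adjusted p values with caution.

### Over-representation

Gene-set enrichment of the significant genes is a one-sided hypergeometric
test per set: $p = P(X \ge k)$ with universe size $N$, set size $K$
(intersected with the universe) and query size $n$, and fold enrichment
$(k/n)/(K/N)$. The universe defaults to all genes detected in the count
matrix. A raw p-value filter (default 0.1) flags reported sets; BH
adjustment across sets is available but off by default, matching the
raw-filter convention. There is no ontology-graph propagation and no
ranked (GSEA-style) statistic.

## The behavioral arm

### Generative model and scoring

Each fly is a two-state (wake/sleep) Markov chain at one-minute resolution:
`p_doze` is the per-minute wake-to-sleep transition probability and
`p_wake` the sleep-to-wake probability, both varying by genotype and day
(day 1 fed, day 2 starved — 24 h on food then 24 h on agar). Wake minutes
emit Poisson beam crossings (default mean 2 per waking minute, a typical
DAM rate); sleep minutes emit zero. The default fed parameters
(`p_doze` 0.06, `p_wake` 0.04) give a stationary sleep fraction near 0.6
and mean sleep bouts of 25 minutes; the starved parameters (0.03, 0.055)
give roughly 0.35 — together a 30-50% within-fly sleep suppression, the
range wild-type flies show after a day of starvation. Traces are serialized
in the standard DAM monitor dialect (42 tab-separated fields; fields 11-42
are the 32 channel counts) and the reader validates field counts and
minute-by-minute timestamp continuity.

Sleep is scored with the 5-minute immobility rule: every minute inside a
maximal run of >= 5 consecutive zero-activity minutes is sleep. Because a
wake minute can emit zero crossings, short quiescent-wake stretches can
fuse with true sleep; the simulator's `truncate_wake_zeros` option removes
this for tests that must recover the latent chain exactly. Per fly and day
the package reports total/day-phase/night-phase sleep (day phase is ZT0-12,
lights-on), bout counts and mean bout length (bouts attributed to their
start day), waking activity (crossings per waking minute), and the Markov
drive statistics.

Sleep drive is reported as P(doze) and wake drive as P(wake), estimated per
fly as maximum-likelihood transition frequencies of the scored state
sequence; the last minute of a day has no successor and is excluded from
the denominators to keep the estimates unbiased. Pooling across flies and
smoothing are intentionally not applied — per-fly estimates feed directly
into the group statistics.

### Suppression and group statistics

Starvation-induced sleep suppression is the within-fly percent change
$(\text{starved} - \text{fed})/\text{fed} \times 100$ of day-total sleep,
with the absolute difference in minutes reported alongside; day-total
(rather than phase-restricted) sleep is the package's choice of baseline.
When fed sleep is zero the percent change is undefined and reported as
missing. Group comparisons follow the standard battery: one-way ANOVA with
Tukey's HSD across genotypes, Kruskal-Wallis with Dunn's post hoc (pairwise
z on rank sums with the ties correction; implemented in the package, with
Holm adjustment by default), and a two-way repeated-measures ANOVA
(genotype x day, fly as the repeated subject) whose interaction term tests
whether starvation changes sleep differently across genotypes. Flies
missing one day are dropped from the repeated-measures fit with a warning.

## Problem sizes and verification scale

The bundled demo and the test suite run at desk scale, chosen so the full
pipeline completes in minutes on one CPU while every statistical property
remains testable: 20 cells per feeding condition and 200 genes (24 truly
DE at $|\log_2 FC| = 2$, mirroring a 12-up/12-down design), and 16 flies
per genotype over two days. Statistical checks use 200-2000 replicate
genes for fold-change recovery and null calibration, week-long traces for
Markov-drive recovery, and 20 seeded replicates for the suppression
direction. Multi-estimate checks (e.g. 40 per-fly drive estimates against
a 3-standard-error band) use a 95%-within-band joint criterion, since a
per-estimate band cannot be expected to hold simultaneously across dozens
of independent draws.

## Reproducibility

All randomness in a run derives from a single integer seed recorded in the
run log; rerunning any simulation or the full demo with the same seed
reproduces every output file byte-identically. The run log also records
every threshold, so a log plus the package version suffices to reproduce a
report bundle.
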