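---
title: "Methods: models and design choices in crispriscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models and design choices in crispriscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crispriscreen)
```

# Scope

`crispriscreen` implements the computational workflow of a pooled,
inducible CRISPR-interference (CRISPRi) screen in a microbe such as the
cyanobacterium *Synechocystis*: genome-wide sgRNA library design,
counting of sgRNAs from amplicon reads, generation-normalised fitness
scoring from turbidostat competition time courses, per-mutant growth-rate
estimation, clustering of depletion patterns, and hit selection for
stress-tolerance and droplet-sorted productivity screens. A synthetic-data
module generates annotated genomes, competition count time courses and
droplet-screen samples with recorded ground truth, so that every stage can
be validated without external sequencing data.

# sgRNA library design

## Candidate sites

dCas9 blocks transcription most effectively when its sgRNA binds the
non-template strand near the transcription start site, with an NGG PAM on
the coding strand. Candidates are therefore found by scanning the strand
opposite the gene's coding strand for the pattern
5'-CCN[20–25 bases ending in T]-3'. The CC guarantees the NGG PAM on the
coding strand; the terminal T of the scanned pattern means the spacer,
read on the coding strand, begins with A, which the sgRNA promoter
requires for efficient transcription of the sgRNA 5' end. When one PAM
admits several spacer lengths the shortest (20 nt) is kept, holding
spacers in the standard length range.

A candidate is kept when its PAM-proximal protospacer end lies within
`min(max_tss_dist, ceiling(max_gene_fraction * gene_length))` nt
downstream of the anchor — the annotated TSS when available, otherwise
the start codon. Defaults are `max_tss_dist = 500` and
`max_gene_fraction = 0.75`. The "within 500 bp of the TSS or within 75%
of gene length" rule could be read as a union or an intersection of the
two windows; we implement the conservative intersection (both caps apply)
and expose both knobs. Offsets upstream of the anchor are excluded:
repression upstream of the TSS is unreliable.

## Composition filters

Spacers with runs of six or more G, four or more T, or GC content outside
25–75% (boundaries inclusive) are discarded. Long G runs impede oligo
synthesis and quadruplex formation, a T run acts as a terminator for the
sgRNA promoter, and extreme GC content correlates with poor sgRNA
activity.

## Off-target counting

An off-target site is a genomic locus whose PAM-proximal 17 nt match the
spacer's with fewer than two mismatches (0 or 1), adjacent to an NGG *or*
NAG PAM, on either strand; circular replicons wrap. PAM-proximal bases
dominate dCas9 specificity, and NAG is a tolerated alternative PAM, so
both are counted into one number. The intended target itself — including
an overlapping NAG reading of the same locus — is excluded, otherwise
every guide would count at least one "off-target".

The scan delegates the mismatch-tolerant 17-mer search to
`Biostrings::matchPattern(max.mismatch = 1)` and verifies PAM adjacency
afterwards. The test suite proves this scan exactly equivalent to a
position-by-position brute-force evaluation of the definition on random
genomes with planted exact, 1-mismatch and 2-mismatch sites (NGG and NAG,
both strands).

## Guide selection

Per gene, candidates are ranked by off-target count, then anchor
proximity, then genomic coordinate (a deterministic final tie-break the
biology does not constrain). The best candidate is selected; the second
is the next-ranked candidate at least 10 nt away — separation measured
between PAM-proximal protospacer ends, which makes selection invariant
under reverse-complementing the genome — among candidates tying the best
remaining off-target count, falling back to the next-ranked candidate
overall. Spacing is a preference and never justifies accepting more
off-targets. Genes yield two, one or zero guides and are reported in a
per-gene status table; `composition_summary()` turns class-wise design
counts into library totals.

# Quantification

Amplicon reads are `flank5 + spacer + flank3` fragments of the expression
cassette. `extract_spacer()` returns the sequence after the first exact
occurrence of the 5' anchor, truncated at the 3' anchor when present;
`count_reads()` assigns a read to exactly one guide by exact spacer
matching, resolving mixed spacer lengths by the longest match so that a
20-nt spacer that is a prefix of a 25-nt spacer never shadows it. No
mismatch tolerance is applied: library spacers are synthetic sequences
and the flanks are constant, so a mismatched spacer is evidence of a
sequencing error best left unassigned. Assigned, ambiguous and unassigned
reads are tallied per sample and always sum to the total.

# Fitness from competition time courses

## Normalisation and trajectories

Counts are normalised by median-of-ratios size factors (the ratio of each
sample to a per-guide geometric-mean reference, median over guides
nonzero everywhere), the standard for sequencing count data; with no
common nonzero guide the package falls back to total-count scaling with a
warning. Log2 fold-changes against each replicate's own induction (t = 0)
sample use a pseudocount of +0.5 on normalised counts to handle zeros,
and are averaged across replicates. The time axis is cell generations,
`n_gen = mu_pop * t / ln 2`, taken from the population growth rate the
turbidostat imposes.

## Fitness score

The fitness score is the area under the log2 fold-change trajectory over
generations, normalised by the generation span:

$$F = \frac{\mathrm{AUC}(n_{gen}, \log_2 FC)}{\max(n_{gen})}$$

computed with the trapezoid rule (the natural quadrature for an
irregularly sampled time course). Two closed forms pin the
implementation: a constant trajectory at level $c$ has $F = c$, and a
linear decline from 0 to −8 over any span has $F = -4$; $F$ is linear in
the trajectory. The generation span is taken per condition (each
condition's own maximum), so conditions of different length remain
comparable per generation; this is configurable. Differential fitness
between conditions is $\Delta F = F_a - F_b$, flagged when
$|\Delta F| \ge 3$ — a threshold on the scale of log2 units per
generation that separates condition-specific effects from noise. Gene
fitness is the mean of the gene's two guide scores, and a gene is
eligible for condition-differential calls only when both guides fall in
the same depletion cluster (discordant guides usually mean one inactive
guide).

## Significance

Differential abundance between two sample groups uses a Wald test on the
log fold-change of normalised means with a method-of-moments
negative-binomial dispersion pooled across groups. With typical replicate
numbers (four) the raw moment estimator is unstable, so per-guide
dispersions are floored at the library-wide median dispersion; guides
whose raw estimate was non-positive are flagged, and a fully degenerate
library reduces to Poisson. P-values are Benjamini–Hochberg adjusted
across guides. This is a deliberately transparent approximation of a
package-based NB analysis; the test suite cross-checks it against DESeq2
on simulated data (same size-factor ratios, same planted-depletion calls)
and verifies its null calibration by simulation.

# Growth-rate estimation

A clone growing slower than the population washes out of a turbidostat.
With rates in h⁻¹ and time in hours, the mutant fraction follows the
discrete depletion model

$$f(t) = f(0)\,\bigl(1 - (\mu_{pop} - \mu_{mut})\bigr)^{t},$$

applied as a per-hour decay factor. Fitting
$\log f(t) = \log f(0) + t \log(1 - \mu_{diff})$ by least squares over
points with $f > 0$ inverts the model exactly in the noiseless limit;
$\mu_{mut} = \mu_{pop} - \mu_{diff}$. Clones whose later points are all
zero fell below detection; they receive a lower-bound-only estimate
(flagged), derived from at least a halving of abundance by the first zero
point.

Because the total density in a turbidostat is constant, *observed*
fractions are renormalised at every timepoint: depleting clones inflate
everyone else's share, which biases naive per-clone slopes upward. The
matrix-level estimator therefore iterates (twice by default): after each
pass the population survival factor implied by the fitted clone models is
computed and divided out before refitting. On simulated libraries with a
realistic depleted fraction the median absolute error is ~1.6% of
$\mu_{pop}$ at sequencing depths of 10⁶ reads, against a 5% working
tolerance.

# Clustering depletion patterns

Per-guide feature vectors concatenate replicate-averaged log2
fold-changes over all conditions and timepoints (the t = 0 anchor is
identically zero and dropped; missing values are imputed as 0 with a mask
recorded). Clustering is agglomerative with Ward's minimum-variance
criterion on Euclidean distances, the classic choice for compact
time-course clusters. The mean silhouette width is reported for k = 3–9;
screens of this kind separate about equally well over that range, so k is
a configuration choice (default 6) rather than an automatic optimum.
Clusters whose centroid trajectories all stay inside a near-zero band
(max |centroid| < 0.5 log2 units) are merged into a single "unchanged"
cluster: splits inside that band reflect technical variation such as a
transient enrichment at single timepoints, not biology. Labels are
ordered from strongest depletion (cluster 1) to the unchanged cluster
(last).

# Screen hit selection

**Tolerance, enriched side.** A guide is a hit when it passes log2 FC ≥ 2
and −log10 p ≥ 20 in the stress condition and does not pass both in the
control: enrichment specific to the stressor, not to its osmotic or
handling side effects. At gene level both guides must be
selected-or-above-average in stress but not control.

**Tolerance, depleted side.** Guides are ranked by
$dF = F_{control} - F_{stress}$ and the top 200 taken (ties at the cutoff
break by guide id); genes with both guides inside the top set are
reported.

**Droplet productivity screen.** Counts below 32 reads are removed per
sample (the floor is "fewer than 32", so exactly 32 is kept) — below that
depth relative abundances in the small sorted population are dominated by
PCR jackpotting. Enrichment factors are ratios of relative abundances,
sorted over unsorted, computed after the floor (the order of flooring and
normalisation is a package choice; applying the floor first keeps
unreliable counts out of both numerator and denominator totals). Guides
whose EF differs ≥10-fold between replicate runs are dropped (boundary
inclusive); a clone scores 1 for every run with EF ≥ 3 and is a candidate
producer with a summed score of at least 2 of 4. The per-run threshold is
3 by default (`ef_min`), matching the selection procedure; a threshold of
2 has also been used for reporting summary tables, so the knob is
exposed.

**Expression-variability binning.** Per protein, a one-way ANOVA across
growth-rate levels yields a p-value; proteins are binned into the ranges
1–0.1, 0.1–0.05, 0.05–0.01, 0.01–0.001, <0.001 using right-closed
intervals (p = 0.05 falls in the 0.05–0.01 bin; constant proteins get
p = 1), and the fitness distribution per bin is summarised.

# The synthetic-data module

The generator emulates the study conditions a screen of this kind
presents to the analysis code:

* **Genomes** — a circular replicon at a target GC content with
  non-overlapping genes on both strands, ~80% of them with a TSS 0–60 nt
  upstream of the start codon, 20% annotated as ncRNA. `plant_site()`
  edits in protospacer+PAM copies with a controlled number of mismatches
  confined to the PAM-proximal 17-mer, re-randomising if the edit would
  disturb other matches — the ground truth for off-target tests.
* **Competition time courses** — expected fractions follow the depletion
  model above, renormalised per timepoint (recorded both raw and
  renormalised); reads are multinomial at the configured depth, or
  Dirichlet-multinomial for overdispersion (concentration 200 × clone
  number by default — mild extra-multinomial noise typical of library
  prep; `Inf` gives exact multinomial draws for closed-form tests). The
  default depth of 75 reads per clone matches the 50–100 reads/sgRNA
  regime of a pooled-screen NGS run. Replicates (default 4) share
  expected fractions and differ by sampling only.
* **Truth tables** — by default 28% of clones carry a growth defect
  (the observed share of significantly depleted guides in genome-wide
  screens of this organism), with mutant rates uniform between 5% and
  95% of the population rate, covering near-knockouts to mild defects.
* **Droplet screens** — Poisson cell loading (λ = 0.3 per droplet,
  single-cell regime), droplet fluorescence equal to the summed cell
  productivities times log-normal noise of mean 1 and CV 0.5, top 2% of
  cell-containing droplets sorted (default four runs: two cultivation
  occasions × two assay timepoints), then multinomial read sampling of
  sorted and unsorted pools. Empty droplets have zero fluorescence and
  are excluded from the cell-containing denominator.
* **Reads** — each counted unit emits one `flank5+spacer+flank3` read,
  truncated to the read length and shuffled deterministically, so
  simulation → counting round-trips the count matrix exactly.

All samplers derive per-sample/per-run substreams from one master seed by
fixed offsets and are bit-reproducible.

What the generator does **not** emulate: sequencing errors inside the
spacer, PCR jackpotting beyond Dirichlet overdispersion, guide-efficacy
variation (a guide either carries its clone's fitness effect or the clone
is neutral), polar effects within operons, induction kinetics, droplet
optics or assay-chemistry saturation, and light-regime physiology.
Passing tests therefore demonstrate correctness of the computations under
the stated statistical model, not robustness to every artefact of real
screens.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally and 1-based inclusive in
  GFF3 and output tables; circular replicons wrap in all scans.
* The trapezoid AUC requires at least two points; single-point
  trajectories are an error, not a silent zero.
* `size_factors()` needs one guide nonzero everywhere; otherwise it
  falls back to total-count scaling with a warning.
* Zero group means in the NB test are stabilised with the same +0.5
  pseudocount used for fold-changes.
* EFs with a zero denominator are undefined (NA) for that run, never
  infinite; single-replicate EFs pass the concordance filter but are
  flagged.
* Ties in ranked selections break by guide id so outputs are
  deterministic and order-invariant.

# Problem sizes in the validation suite

The test and acceptance runs use scaled synthetic instances chosen to
exercise every code path while completing quickly on one CPU: 15–50 kb
genomes with 8–40 genes for design and off-target equivalence (10 genomes
× 20 spacers for the exhaustive-scan comparison), 1000 clones × 8
timepoints at depth 10⁶ for growth-rate recovery, 500–600 trajectories
for cluster recovery, and a 2000-clone droplet screen with 20 spiked
10×-productivity clones across 4 runs of 180,000 droplets. These sizes
give stable statistics (recovery metrics vary by <1% across seeds) while
keeping the full suite around a minute.

# Known limitations

* The NB Wald test approximates, not reproduces, DESeq2's shrinkage-based
  inference; exact p-values differ even though calls agree on clear
  effects. Conclusions that hinge on borderline significance should use
  the count-model package directly on the exported tables.
* The off-target count weighs NGG and NAG sites equally and does not
  score off-target severity; spec-compliant but cruder than modern guide
  scorers.
* Growth-rate estimates for clones that wash out below detection are
  lower bounds only.
* The window rule's union reading ("within 500 bp of TSS *or* 75% of
  gene length") would admit more candidates for long genes than the
  implemented intersection; genes designed as `none` under the
  intersection may gain guides under the union.
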