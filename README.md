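# crispriscreen

Design and analysis of pooled, inducible CRISPR-interference (CRISPRi)
fitness and productivity screens, modelled on genome-wide repression
libraries in cyanobacteria.

In a pooled CRISPRi screen, thousands of clones — each expressing dCas9 and
one sgRNA that represses one gene — compete in a turbidostat. The spacer
doubles as a barcode: sequencing the sgRNA cassette over time measures each
clone's abundance, and a clone washing out faster than the population
reveals a fitness cost of repressing its target. Coupling the same library
to a fluorescence-activated droplet sorter turns it into a productivity
screen for secreted products. This package provides the complete
computational side of that workflow for screen designers and analysts:

* **Library design** — scan an annotated genome for sgRNA candidates
  (pattern 5'-CCN[20–25]T-3' on the template strand, giving an NGG PAM on
  the coding strand and an A-starting spacer), filter by composition (no
  G₆/T₄ runs, GC 25–75%) and a TSS/gene-length window, count off-target
  sites (< 2 mismatches in the PAM-proximal 17 nt, NGG *and* NAG PAMs,
  both strands), and pick two well-separated guides per gene.
* **Quantification** — extract spacers from amplicon reads between
  constant cassette flanks and count them by exact, longest-match
  dictionary lookup.
* **Competition analysis** — median-of-ratios normalisation, replicate-
  averaged log2 fold-change trajectories versus cell generations
  (n_gen = μ·t/ln 2), fitness scores

  F = AUC(n_gen, log2FC) / max(n_gen),

  condition contrasts ΔF with |ΔF| ≥ 3 flags, an NB Wald significance
  test (BH-adjusted), per-mutant growth rates by inverting the depletion
  model f(t) = f(0)·(1 − (μ_pop − μ_mut))^t, and Ward/Euclidean clustering
  of depletion patterns with silhouette reporting and a near-zero merge
  rule.
* **Screen selections** — lactate/stress tolerance hits (enriched:
  log2FC ≥ 2 and −log10 p ≥ 20 in stress only; depleted: top-200 by
  dF = F_control − F_stress with a both-guide gene rule) and droplet-sort
  hits (32-read floor per sample, enrichment factor = relative abundance
  sorted / unsorted, 10-fold replicate-concordance filter, score 1 per run
  at EF ≥ 3, hit at ≥ 2 of 4 runs).
* **Synthetic data** — simulators for annotated genomes with planted
  off-target sites, turbidostat competition counts under the depletion
  model (multinomial or Dirichlet-multinomial reads), amplicon reads, and
  paired sorted/unsorted droplet screens — all seeded and with recorded
  ground truth.

## Worked example

Design a library on a simulated genome, run a competition, and score
fitness:

```r
library(crispriscreen)

genome <- make_genome(seed = 1, length_nt = 30000, n_genes = 20,
                      gc_fraction = 0.48)
lib <- design_library(genome)
lib
#> GuideLibrary: 40 guides for 20 of 20 genes
head(lib$guides[, c("guide_id", "spacer", "offset_nt", "offtarget_count")], 4)
#>   guide_id                    spacer offset_nt offtarget_count
#> 1  g0001_1  AGTTTCTAGTCACTTGCCAATACA        10               0
#> 2  g0001_2     ATAGGTAACTAGCACTGCGTC        42               0
#> 3  g0002_1 AGCTGCTGCGCAATTCAGCTGATGT        72               0
#> 4  g0002_2    AGTTGTCAGTGCAGCTCCACTT       165               0

truth <- random_truth(lib$guides$guide_id, mu_pop = 0.07, seed = 1)
cfg <- competition_config(mu_pop = 0.07,
                          timepoints_h = c(0, 24, 48, 96, 192, 317),
                          replicates = 4, seed = 1)
sim <- simulate_competition(lib$guides$guide_id, truth, cfg,
                            condition = "L300")
traj <- log2fc_trajectory(sim$counts, sim$meta, "L300")
fit <- fitness_scores(traj)
head(fit, 4)
#>   guide_id condition           F
#> 1  g0001_1      L300 -6.05194755
#> 2  g0001_2      L300 -0.15260528
#> 3  g0002_1      L300  0.05246317
#> 4  g0002_2      L300 -4.59719809
```

Guide `g0001_1` (F ≈ −6) marks a clone with a strong growth defect — it
loses about six log2 units of abundance per generation span — while
guides near F = 0 are neutral. Growth rates recovered from the same
counts track the simulated truth closely:

```r
est <- estimate_growth_rates(sim$counts, sim$meta, mu_pop = 0.07)
cor(est$mu_mut, truth$mu_mut[match(est$clone_id, truth$clone_id)])
#> [1] 0.9949989
```

A command-line front end wrapping the same functions is installed at
`inst/cli/crispri.R` (subcommands `simulate-genome`, `design`,
`simulate-competition`, `count`, `fitness`, `droplet`; see
`?crispri_cli`). All subcommands are seeded and byte-reproducible.

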