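# mimir — integrated miRNA–mRNA differential expression and enrichment

`mimir` is an R package for the joint analysis of paired mRNA and miRNA
expression experiments with small two-group designs (e.g. triplicate
control vs. knockdown microarrays). It chains the standard stages of
such a study into one reproducible, fully testable pipeline:

1. **Normalization** — quantile normalization and single-shot log2
   scaling of feature × sample matrices.
2. **Differential expression** — an empirical-Bayes *moderated
   t-statistic* for the mRNA arm and a plain pooled two-sample *t*-test
   for the miRNA arm, with Benjamini–Hochberg adjustment and signed
   linear fold-change filters (defaults |FC| ≥ 1.5; BH p < 0.05 for
   genes, raw p < 0.05 for miRNAs).
3. **Pre-ranked gene-set enrichment** — the weighted
   Kolmogorov–Smirnov running-sum statistic with a size-stratified
   permutation null, normalized enrichment scores (NES), nominal p and
   GSEA-style FDR q, and leading-edge extraction.
4. **Consensus miRNA targets** — multi-database link tables collapsed
   per (miRNA, gene) pair; a pair is kept when experimentally validated
   or reported by ≥ 5 distinct databases (the *hit-score* rule).
5. **Integration** — DE miRNAs and DE mRNAs coupled through the kept
   target links by pre-ranked enrichment (either arm can be the ranked
   list), yielding enriched miRNAs and their associated target genes.
6. **Annotation & network** — enriched miRNAs annotated with the
   significant pathways their targets overlap, and a typed
   miRNA → gene → pathway network with signed fold-change edge weights,
   exported as SIF, GraphML or a flat edge table (Cytoscape-ready).

A synthetic-data generator (`sim_config()` / `simulate_study()`) emits
every input with known ground truth — planted fold changes, planted
enriched sets, noisy multi-database links — so each stage is verifiable
without any external download.

## The statistics in brief

For feature *g* with pooled two-group variance *s²g* on *d_g* degrees
of freedom, the moderated t shrinks variances toward a prior:

    s̃²g = (d0·s0² + d_g·s²g) / (d0 + d_g)
    t̃g  = Δg / sqrt(s̃²g (1/n1 + 1/n2)),   df = d0 + d_g

with (d0, s0²) estimated by moment-matching the marginal distribution
of log *s²g* (digamma/trigamma closed forms). For a ranked list of N
features and a set S of size N_H, the enrichment score is the extremum
of the running sum of P_hit − P_miss, where in-set items contribute
|score|^p weight (p = 1 by default) and out-of-set items a uniform
1/(N − N_H) step; NES divides the ES by the mean same-sign permutation
ES of the same set size, and FDR q compares observed and null NES tail
fractions.

## Worked example

```r
library(mimir)

study <- simulate_study(sim_config(seed = 1))   # 2000 genes, 300 miRNAs, 3 vs 3
write_simulation(study, "sim")

rc <- run_config(
  mrna_matrix  = "sim/mrna_matrix.tsv",  mrna_design  = "sim/mrna_design.tsv",
  mirna_matrix = "sim/mirna_matrix.tsv", mirna_design = "sim/mirna_design.tsv",
  gene_sets    = "sim/gene_sets.gmt",    target_links = "sim/target_links.tsv",
  outdir = "run", seed = 1)
summary <- run_all(rc)
```

The run log prints the per-stage counts; with seed 1 and the default
thresholds:

```
mRNA DE: 78 up, 78 down
miRNA DE: 19 up, 19 down
pathway enrichment: 13 significant of 50 sets
consensus targets: 1013 kept, 5033 dropped
integration: 12/11 up/down miRNAs, 36/36 up/down targets
```

Reading: 156 genes pass the |FC| ≥ 1.5 + BH p < 0.05 filter, 152 of
them carrying planted effects (sensitivity 0.76, empirical FDR 0.026
against the generator's truth); 13 gene sets reach nominal p < 0.05 and FDR q ≤ 0.25, including
all 10 sets built preferentially from planted DE genes; the hit-score
rule keeps 1013 consensus pairs (all of them true links at the default
database noise); and the integration stage associates 23 enriched
miRNAs with 72 DE target genes, which form the exported network
(108 nodes, 868 edges in `run/network.sif` / `.graphml`).

All intermediates are TSVs in `run/`, with `summary.json` and the
resolved `config.yaml` for provenance. A thin command-line wrapper is
installed at `system.file("cli/mimir-pipeline.R", package = "mimir")`
with `simulate` and `run-all` subcommands.

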