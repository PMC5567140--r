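---
title: "Methods: integrated miRNA–mRNA differential expression and enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated miRNA–mRNA differential expression and enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimir)
```

`mimir` implements the analysis chain used in small-n two-group
transcriptomic studies that profile both mRNA and miRNA arms of the
same perturbation — typically a gene knockdown assayed on triplicate
microarrays — and then asks which miRNAs plausibly regulate the
observed mRNA changes. This vignette is the package's account of the
statistical methods, the choices that were genuinely open, and what
the simulation-based tests do and do not establish.

## Data model

Both arms are feature × sample matrices of log2 intensities with a
two-level design (`control` / `treated`). Missing values are rejected
at load: with three samples per group there is no defensible
imputation, and silent imputation would distort the variance moment
estimates below. The pipeline starts from probe-set-level summaries;
probe-level background correction and summarization (the first two
RMA steps) require raw array files and are out of scope, so the
package provides the remaining reproducible steps: quantile
normalization and single-shot log2 scaling, each applied exactly once
and recorded in the object's scale flag.

Quantile normalization replaces each column's order statistics by the
cross-sample means of the order statistics. Tied values receive the
mean of the reference values over the rank interval they jointly
occupy; this keeps the map well defined, idempotent on tie-free data,
and rank-preserving within columns. The implementation is checked in
the tests against `limma::normalizeQuantiles` on tie-free matrices.

## Differential expression

**mRNA arm.** With n = 3 per group, per-feature variance estimates on
4 degrees of freedom are unstable; the package uses the hierarchical
empirical-Bayes model in which pooled sample variances
\(s_g^2\) (df \(d_g = n_1+n_2-2\)) are drawn around a prior
\(s_0^2\) with prior df \(d_0\). The posterior variance
\(\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0+d_g)\) gives the
moderated statistic
\(\tilde t_g = \Delta_g / \sqrt{\tilde s_g^2 (1/n_1+1/n_2)}\)
on \(d_0 + d_g\) df. The prior is estimated by moment-matching the
marginal distribution of \(\log s_g^2\): under the model,
\(e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)\) has variance
\(\psi'(d_0/2) + \psi'(d_g/2)\), so \(d_0\) is obtained by inverting
the trigamma function (Newton iteration) on the excess variance of
\(e_g\), and \(s_0^2\) from the mean of \(e_g\). When the observed
spread of log-variances does not exceed its sampling component the
estimate degenerates to \(d_0 = \infty\) (all posterior variances
equal \(s_0^2\)). Features with numerically zero variance are floored
at machine epsilon, flagged, and excluded from the moment estimation
so they cannot drag \(s_0^2\) to zero. The implementation is verified
against `limma::eBayes` to 1e-6 on heterogeneous-variance fixtures,
and against the ordinary pooled t in the forced \(d_0 = 0\) limit.

**miRNA arm.** A plain pooled two-sample t on \(n_1+n_2-2\) df. The
BH-adjusted column is computed for both arms, but the customary filter
for the miRNA arm uses the raw p-value: miRNA arrays carry far fewer
features, and small-n miRNA analyses conventionally report raw-p
selections. The defaults encode this split (genes: BH p < 0.05;
miRNAs: raw p < 0.05; both: signed linear |FC| ≥ 1.5, i.e.
\(|\log_2 FC| \ge \log_2 1.5\)). Fold changes are reported on the
signed linear scale (a halving prints as −2.0), the convention used
throughout the output tables and network weights.

## Pre-ranked enrichment

Features are ranked by signed linear fold change, descending, with
lexicographic id order breaking ties so results are deterministic. For
a set S of size \(N_H\) in a list of length N, the running sum
accumulates \(P_{hit}-P_{miss}\): in-set items add
\(|r_i|^{p}/N_R\) (score weight, default exponent p = 1), out-of-set
items \(1/(N-N_H)\). The enrichment score ES is the extremum of
largest magnitude; the leading edge is the in-set prefix (ES > 0) or
suffix (ES < 0) at the extremum. With p = 0 the statistic reduces to
the classical two-sample KS distance between in-set and out-of-set
rank distributions, a reduction the tests assert exactly, alongside
brute-force running-sum oracles and agreement with
`fgsea::calcGseaStat`.

The null is built by tag permutation — random same-size subsets of the
ranked items — which is the only exchangeable null available for
pre-ranked input. One pool of B scores (default 1000) is drawn per
distinct set size and shared across sets, keeping runtime linear in
the number of distinct sizes. For the null draws the ES is evaluated
only at hit positions and the positions immediately before them (the
running sum is piecewise linear in between), an O(set size) shortcut
asserted equal to the full running sum in the tests.

NES divides ES by the mean same-sign null ES of the set's size;
nominal p is the same-sign tail fraction; FDR q follows the GSEA
construction — the fraction of pooled same-sign null NES at least as
extreme divided by the fraction of observed same-sign NES at least as
extreme, clipped to [0, 1] and made monotone within each sign. A
nominal p of zero is stored as 1/(B+1) so that downstream −log
transforms stay finite. Sets are called significant when nominal
p < 0.05 *and* q ≤ 0.25 jointly (both boundaries configurable; the
q boundary is inclusive).

## Consensus targets and integration

miRNA→gene link tables carry per-database provenance and a validation
flag. Links are collapsed per (miRNA, gene) pair; the hit score is the
number of distinct reporting databases (names compared
case-insensitively, since aggregated resources are inconsistent about
capitalization), and a pair is kept when validated anywhere or when
the hit score reaches 5. miRNA identifier harmonization (e.g. mature
arm suffixes) is deliberately not attempted: identifiers are opaque
strings, and any mapping should happen upstream of the link table.

The integration stage couples the two DE arms through the kept links.
The default construction (`mirna_ranked`) ranks the DE miRNAs by
signed fold change and forms, for each DE mRNA, the set of miRNAs
targeting it; the mRNA is "enriched" when its set passes both
thresholds and its associated miRNAs are the set's leading edge. The
transposed construction (`mrna_ranked`) — DE mRNAs ranked, per-miRNA
target-gene sets — is equally defensible from the flow of such
analyses and is provided as a first-class mode; the two answer
slightly different questions and the output records which was used.
The up- and down-regulated halves of the set-forming arm run
separately and are merged afterwards, so enrichment is assessed within
each expression-direction stream. Target sets restricted to DE
features are small, so the minimum set size defaults to 3 here (the
conventional 15 would discard nearly everything); no anti-correlation
constraint is imposed — both sign combinations are biologically
admissible and appear in real data.

## Annotation and network

Each enriched miRNA is annotated with every significant pathway whose
DE members overlap the miRNA's associated targets; the overlap genes
are the record. Pathway category labels come from a user-editable
keyword map (`default_categories()`) because any grouping of pathway
names into themes is ultimately manual. The network has typed nodes
(miRNA, gene, pathway) and typed edges: miRNA→gene edges carry the
miRNA's signed fold change, gene→pathway edges the gene's own signed
fold change — the edge is the gene's membership, so its weight belongs
to the gene. Signs are preserved rather than absolute-valued so that
up- and down-regulation remain distinguishable in the export. SIF (+
edge-attribute table), GraphML and a flat edge TSV are emitted; the
TSV round-trips to an isomorphic graph and is the provenance format.

## The synthetic-data generator

The generator emulates the study design this pipeline targets: two
groups of 3 samples; log2 baselines Normal(7, 2) to mimic microarray
intensity dynamic range; a 10% planted-DE fraction with signed effects
of mean magnitude 1.5 log2 units (signs split 50/50) and residual SD
0.5; 2000 genes and 300 miRNAs, scaled down from array scale (tens of
thousands of probe sets, ~1–2 thousand miRNAs) so the full pipeline
and its permutation nulls run in seconds. Each planted miRNA receives
a regulon of 40 true target genes, 70% of them drawn from planted
genes of the opposite sign (the canonical repression pattern); the
miRNA count and regulon size were chosen so that, after restriction to
DE features, per-gene targeting sets reach the integration minimum
size the way real consensus databases (several hundred targets per
miRNA) do — with sparser settings the integration stage would be
structurally empty regardless of signal strength. Databases report
each true link independently with recall 0.7 (8 databases), add
uniform spurious links at rate 0.001, and a 10% validated subset is
always surfaced by at least one source. Gene sets (50, sizes 15–100)
include 20% "enriched" sets drawing 80% of members from planted genes
of one sign.

A single root seed drives one sub-stream per artifact (derived by
hashing the artifact label), so generating an additional artifact
never perturbs earlier draws, and identical configurations are
byte-identical end to end. The miRNA matrices are emitted already
normalized; miRNA platform normalization varies by vendor and is not
modeled.

What the generator does *not* emulate: probe-level effects, spatial
artifacts, correlated noise across features, batch structure,
sequence-driven target prediction biases, or realistic pathway overlap
topology. Passing the planted-recovery tests therefore demonstrates
that the statistics are implemented correctly and calibrated under
exchangeable noise — not that the pipeline's operating
characteristics transfer to any particular real dataset.

## Numerical and degenerate-input choices

- Quantile-normalization ties: mean of reference values over the
  occupied rank interval (exactly idempotent on tie-free input).
- Zero-variance features: machine-epsilon floor + flag, excluded from
  prior estimation.
- Ranking ties: lexicographic id order, for determinism.
- ES extremum ties: first (earliest) position.
- All-zero score weights in a window (possible with weight exponent
  > 0 and zero scores): the set's hit mass falls back to equal
  weights.
- Sets covering the whole ranked list are errors (the miss
  denominator is undefined); sets missing the list entirely are
  skipped with a log entry.
- p = 0 under permutation → stored as 1/(B+1).
- Sign-empty null pools (no same-sign permutation ES) leave NES
  undefined; the set is flagged and never called significant.

## Problem sizes in the tests

The test suite generates all fixtures in code at small scale —
matrices of 100–2000 features, ranked lists of 10–300 items,
permutation counts of 100–500, and 8–20 replicate seeds for the
recovery and calibration benchmarks — sizes at which the brute-force
oracles (exhaustive running sums, per-row `t.test`, step-up BH by
definition) are exact and fast. The acceptance script runs the full
default-scale study (2000 × 300, B = 1000) in a few seconds.

## Known limitations

- No multi-factor designs, covariates, paired tests or array weights;
  the linear model is strictly two-group.
- No probe→gene collapsing: features are the analysis unit, and
  many-probes-per-gene ambiguity is the caller's concern. Published
  per-gene DE counts from probe-level arrays depend on that collapsing
  rule and may not be exactly reproducible without it.
- No phenotype-permutation GSEA mode (pre-ranked only).
- Identifier aliasing (gene symbols, miRNA arms) is out of scope.
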