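---
title: "Models and methods behind dupdyn"
author: "dupdyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dupdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dupdyn)
```

`dupdyn` reconstructs the duplication history of gene repertoires in
pairs (or sets) of related genomes and links duplicated gene classes to
expression phenotypes.  This vignette explains the models, the tunable
parameters with their defaults and units, the numerical choices, what
the simulators emulate, and the limits of what the package's own tests
can show about real data.

## Gene families: a similarity graph clustered with MCL

Families are clusters of an undirected protein-similarity graph.  Input
hits (the 12-column tabular dialect) are filtered with a *strict*
E-value threshold (retain only E < 1e-5) and a coverage rule: the
alignment must span at least 50% of the *longer* sequence of the pair.
Edge weights are `min(200, -log10 E)` with E = 0 mapped to the cap;
reciprocal hits merge by maximum.  The cap and the `-log10` transform
are the standard protein-clustering protocol; the hit-derived weight is
a plumbing choice, not part of any published contract.

Clustering is the Markov Cluster algorithm implemented directly on the
dense column-stochastic flow matrix: self-loops with each node's
strongest incident weight (1 for isolated nodes), then alternating
expansion (matrix squaring) and inflation (elementwise power, default
2.1, followed by column renormalisation) until the flow matrix changes
by less than `convergence_tol` (1e-8).  Entries below `prune_threshold`
(1e-5) are zeroed and the column renormalised after each inflation;
this approximates the pruning schemes of the optimised command-line
implementations, and we make no claim of cluster-level parity with any
particular binary's pruning preset — the tests instead require exact
agreement with a *pruning-free* dense reference recurrence on small
graphs.  Clusters are read off the limit matrix as attractor systems
(support of the converged flow); overlapping systems are merged, so the
output is always a strict partition, asserted on every run.  Ties in
family naming are broken by family size then lexicographically smallest
member, so the clustering is invariant to node relabelling and input
order.

Lineage-specific accumulation rates divide the count of group-specific
genes (or families — both counts are exposed, since either reading of a
"group-specific" tally is defensible) by the group's *stem plus crown
age* in relative-time units: the branch subtending the group's MRCA
plus the depth of the MRCA above its deepest descendant tip.  For a
single species the crown age is zero.  A non-monophyletic group is an
error, and a group whose MRCA is the root has no stem and errors too.

## Paralog ages: NG86 on threaded codon alignments

For each gene the *nearest paralog* is its highest-bitscore non-self
within-genome hit, after requiring ≥ 150 aligned residues and ≥ 30%
identity; per-gene choices are deduplicated on unordered pairs.  When
A's best hit is B but B's best is C, both (A,B) and (B,C) survive — the
selection is read per-protein.  Ties on bitscore break to the
lexicographically smallest subject.

Protein pairs are aligned globally (Needleman–Wunsch with affine gaps,
BLOSUM62, gap open 11 / extend 1 — the standard protein-search
defaults; a gap of length L costs 11 + L).  The aligner is the
exact-optimum dynamic program provided by Biostrings; our tests verify
its scores against exhaustive alignment enumeration for short peptides.
Its internal tie-breaking among co-optimal alignments is deterministic
but not configurable; since all downstream quantities are computed from
counts over aligned columns, co-optimal tie choice has no effect on the
reported estimates beyond column bookkeeping.

The amino-acid alignment guides a codon alignment: each residue is
replaced by its source codon, each gap by `---`; a CDS whose
translation disagrees with its protein is an error naming the offending
residue.  Columns containing a gap, an ambiguous base (N) or a stop
codon are excluded from counting.

Divergence is estimated by Nei–Gojobori (1986) codon counting:

- *Sites*: at each codon position, the fraction of the three possible
  changes that are synonymous; changes creating stop codons count as
  nonsynonymous, which keeps the invariant S + N = 3 × codons exact.
  Site counts are averaged over the two sequences.
- *Differences*: per codon pair, substitution counts are averaged over
  all orderings of the single-nucleotide steps; orderings that pass
  through a stop codon are excluded, and in the rare case that every
  ordering is blocked the raw differences are split evenly between the
  classes.
- *Correction*: Jukes–Cantor, d = −(3/4)·ln(1 − (4/3)p), applied to the
  aggregated proportions; (4/3)p ≥ 1 raises the `saturated` flag.

The published analysis we emulate used the YN00 maximum-likelihood-free
counting method, which additionally corrects for codon frequencies and
transition/transversion bias.  NG86 shifts absolute dS slightly
relative to YN00, but every downstream decision in the pipeline is
*threshold-relative* (old/young against the mean ortholog dS, computed
with the same estimator), so the classification logic is unaffected.
For exact-parity runs on externally computed tables,
`read_dnds_table()` feeds the rest of the pipeline unchanged.

A documented quirk of pathway counting: under a purely synonymous
history (ω = 0), a codon hit twice can yield orderings with
nonsynonymous intermediate steps, so estimated dN is near but not
exactly zero; the tests assert protein identity (exact) and dN ≪ dS.

## Speciation threshold, age classes and loss rates

1:1 orthologs are families with exactly one member in each of the two
species; their mean dS (after excluding dS > 2) marks the speciation
time on the dS axis (`speciation_threshold`).  A paralog pair is
*old* (pre-speciation) iff its dS exceeds the threshold — a tie is
young, a deliberate rule so the classification is a total function.
Pairs with dS > 2 are discarded as saturated throughout (strictly
greater: dS = 2 is kept).  For ω comparisons a stricter filter drops
pairs with dN < 0.01 OR dS < 0.01 OR fewer than 50 synonymous sites;
the grammatically plausible alternative (the site condition conjoined
with the divergence condition) is available via `rule = "and_sites"`.

*Ancestral-duplicate loss* is operationalised at the family level: a
family carries an ancestral duplicate in species X when it contains a
within-X pair with threshold < dS ≤ 2, and that duplicate is lost in
species Y when the family retains at most one Y member.  The published
counts state the arithmetic (lost / ancestral) but not the exact rule;
this family-level rule reproduces the printed 2×2 table arithmetic and
is documented here as the package's reference definition.  Whether the
published ancestral-duplicate tallies count genes or families is
ambiguous in the source text; the loss-rate arithmetic is identical
under either reading.

Age distributions bin dS into half-open `[lo, hi)` bins of width 0.05
(the source figures do not state their bin width; 0.05 matches their
granularity) up to the saturation bound.

## Birth–death family-size evolution

Family size evolves by a linear birth–death process with equal
per-gene gain and loss rate λ (per gene per relative-time unit) — the
classical model behind family-size likelihood tools.  Equal rates are
assumed because nothing in the emulated analysis indicates otherwise.
With α = λt/(1 + λt), the transition probability has the closed form

P(c | s, t) = Σ_j C(s, j) C(s + c − j − 1, s − 1) α^{s+c−2j} (1 − 2α)^j,
P(0 | s, t) = α^s,

with j up to min(s, c); size 0 is absorbing.  Note α > 1/2 makes
(1 − 2α)^j alternate in sign, so terms are summed in ordinary (not log)
space with log-magnitude exponentials, and tiny negative round-off is
clamped to zero.  Transition rows are validated in tests against the
matrix exponential of the truncated generator to 1e-8.

The family likelihood is Felsenstein pruning over size states
0..`s_max` (default: max observed + max(10, half the max) — transitions
can overshoot observed sizes at internal nodes) with per-node scaling
of partial likelihoods, so the result is invariant to the scaling.  The
root prior is uniform on 1..`root_max` (default: max observed size),
conditioning on presence at the root; published tools differ across
versions in their root handling, and this choice is documented rather
than matched to any one of them.  Because the model conditions on root
presence, families are pre-filtered by Fitch parsimony on
presence/absence (ties at the root count as present — conservative,
i.e. retaining borderline families) and by a copy-number range filter
(range > 200 excluded; exactly 200 kept).

λ is fitted by maximising the summed log-likelihood: golden-section
search on log λ for a single class, Nelder-Mead from a deterministic
two-point start grid around the single-rate optimum for multi-class
partitions (branch classes are defined by `edge_partition`, which lets
any nested ladder of clade-specific-rate models be built).  Nested
models are compared with likelihood-ratio tests (2ΔlogL against
χ² with df = parameter difference, statistic clamped at 0).  Ancestral
sizes are the max-product (Viterbi) assignment over the same state
space, ties to the smaller size; a branch with positive child-minus-
parent change is an expansion.  Per-family expansion p-values are not
implemented; "expanded" means positive ML branch change, and the
two-aphid comparison uses the exact two-sided binomial test.  Per-taxon
counts are normalised by the taxon's terminal branch length (relative
divergence time from its first ancestor); a zero-length terminal branch
is an error rather than an infinite rate.

## Enrichment statistics and the DE filter chain

The 2×2 chi-square is Pearson's N(ad − bc)²/[(a+b)(c+d)(a+c)(b+d)] with
df 1 and *no continuity correction by default* — required to reproduce
printed genome-scale statistics (Yates is available by flag).  A zero
marginal is an error.  The DE-enrichment harness builds the table as
DE-vs-rest (the genome row excludes DE genes); the overlapping-fraction
variant is available for sensitivity analysis but does not reproduce
the printed values, which is why DE-vs-rest is the default.

Mann–Whitney U reports U = #{x > y} (+½ per tie).  With no ties and
min(n) ≤ 8 the exact distribution is used; otherwise the normal
approximation with tie correction and 0.5 continuity correction.

The DE chain is: (1) drop the lowest 40% of genes by mean count across
all samples (ties broken by gene id; the source protocol does not state
its ranking statistic, so mean-across-samples is the documented
default, configurable); (2) a deliberately simple NB test — median-of-
ratios size factors, a common-scale dispersion estimated as the median
of per-gene method-of-moments values, and a Wald test on the log
difference of normalised condition means referenced against t with
n − 2 df as a small-sample guard; (3) Benjamini–Hochberg at 10% FDR;
(4) a linear fold-change requirement |FC| ≥ 1.5 (equivalently
|log2FC| ≥ log2 1.5 — whether the original threshold was applied to
normalised-mean FC or to a model-fitted FC is unstated, and linear FC
of normalised means is the documented default).  The test is explicitly
*not* a substitute-quality reimplementation of a shrinkage-based NB
framework: `de_call()` accepts any external (gene, log2FC, p) table so
the filter chain can run on real DESeq-style output.  qPCR
quantification is the comparative 2^−ΔCt method against a reference
gene from the same sample.

## Tandem arrays

Same-family genes on the same scaffold are joined into an array when
separated by at most `max_intervening` (default 1) genes of other
families in scaffold order, transitively closed; arrays need ≥ 2
members and strand is ignored (tandem duplicates frequently invert).
This is an explicit reimplementation of the conventional tandem rule;
parity with any specific synteny tool is not claimed, and the tests
compare against a brute-force quadratic scan instead.

## What the simulators emulate

- `simulate_family_sizes` runs exact Gillespie birth–death per branch
  (total rate 2λn), so empirical transition frequencies can be checked
  against the closed form without discretisation bias, and E[size]
  stays at the root size (the critical-process martingale).
- `simulate_two_species_world` plants explicit duplication times: a
  speciation at age 0.13 per lineage (relative-time units) so that with
  unit per-nucleotide substitution intensity the expected 1:1-ortholog
  dS is 2 × 0.13 = 0.26; pre-speciation duplications at ages ≥ 0.075
  above the split (so planted old-pair dS sits well clear of the
  threshold but below saturation, given the root age 0.65);
  post-speciation duplications younger than the split; ω = 0.2
  (purifying selection typical of paralog pairs); and per-species loss
  of one ancestral copy with probabilities 0.5 vs 0.25 — a planted
  two-fold loss asymmetry in the direction of the streamlined genome.
  Sequences evolve by proposal-and-acceptance: proposals Poisson at the
  stated intensity per nucleotide, synonymous changes always accepted,
  nonsynonymous with probability ω, stops rejected.  Defaults of 40
  families × 150 codons describe the baseline world; tests state their
  own sizes where they differ.
- `simulate_hits` derives a BLAST-like table deterministically from the
  sequences: candidate pairs seeded by two shared amino-acid 4-mers
  (ubiquitous words masked), global alignment, bit score
  (0.267·S + 3.19)/ln 2 from the standard gapped BLOSUM62
  Karlin–Altschul constants, E-value = len_q × db_len × 2^−bits.
- `simulate_counts` draws NB counts with per-sample size factors in
  [0.7, 1.3], log-normal baselines, a planted DE fraction with random
  sign and fixed |log2FC|, and DE membership odds multiplied for chosen
  gene categories — the structure needed to exercise the enrichment
  harness with known truth.
- `simulate_positions` scatters genes on scaffolds and plants chosen
  families as contiguous tandem blocks.

What passing on these worlds does *not* show: real proteomes have
domain shuffling, alignment ambiguity, isoform annotation noise, codon
usage bias and rate variation among sites and genes — none of which the
generators produce.  The simulations validate the *inference machinery*
(filters, estimators, likelihoods, tests) against known truth, not the
biological robustness of the thresholds.

## Problem sizes and runtimes in the test suite

The suite is sized to run comfortably on one CPU: the LRT null
calibration uses 500 replicates of 40 families on a 4-taxon timetree;
rate recovery uses 500 families on 6 taxa; ω recovery uses 200 pairs of
300 codons; the end-to-end loss-asymmetry check runs 50 replicate
worlds of 80 families × 80 codons through the full
cluster → dN/dS → threshold → loss-rate chain.  These sizes give the
stated statistical resolution (e.g. a ±2-SE band of roughly ±0.02
around a 0.05 type-I rate at 500 replicates) while keeping each
property within minutes.

## Known limitations

- NG86 rather than YN00: absolute dS differs slightly; all downstream
  decisions are threshold-relative, and external tables are accepted.
- The MCL pruning scheme approximates, not reproduces, binary presets;
  clusterings of large dense graphs may differ at the margin.
- The birth–death model has no assembly-error component and no
  among-family rate variation; per-family expansion significance is
  out of scope.
- The NB test is a transparent stand-in with a common-scale dispersion;
  for real RNA-seq, use a full NB framework and feed its output into
  `de_call()`.
- Multifurcating trees are handled by pairwise folding in the Fitch
  filter (exact for binary trees, heuristic otherwise); the likelihood
  machinery itself is agnostic to the degree of internal nodes.
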