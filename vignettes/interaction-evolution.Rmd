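---
title: "Methods: cross-species interaction screening, trajectory classification, dN/dS and co-IP enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species interaction screening, trajectory classification, dN/dS and co-IP enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppievo)
```

This vignette documents the models and conventions behind `ppievo`: how
matrix-format yeast two-hybrid (Y2H) screens are scored, how cross-species
interaction patterns are classified, how pairwise dN/dS is counted, how
co-IP/MS enrichment statistics are computed, and what the synthetic-data
generators do and deliberately do not emulate.

## The screen design model

A cross-species matrix screen is the product of a gene roster and a species
roster, minus declared absences (a species may simply lack an ortholog). The
default design models the germline piRNA precursor biogenesis pathway: 11
genes x 5 *Drosophila* species with Kipferl absent in *D. persimilis* and
*D. virilis*, i.e. 53 proteins. Published descriptions of this screen
variously state 53 or 54 proteins; only 53 is consistent with the pair
combinatorics (1431 unique pairs = 308 intra-species + 1123 inter-species =
53 x 54 / 2), so the roster here has 53.

Every protein is cloned as four constructs: bait and prey, each N- and
C-terminally tagged. A heterotypic pair is testable in 8 bait x prey
configurations (2 bait tags x 2 prey tags x 2 orientations); a homotypic
pair in 4, because swapping orientation reproduces the same construct pair.
Pairs are canonically ordered lexicographically on their `(gene, species)`
labels so that unordered identity is stable across file orderings and
orientations.

Divergence times are configuration inputs, not estimates made by this
package. The defaults (Dmel–Dsim 5, melanogaster subgroup–Dere 13,
melanogaster group–Dper 30, anything–Dvir 40 million years) are approximate
literature values and can be replaced in the design config.

## Replication scoring

Colony readouts are discretized to growth scores 0 / 1 / 3: no growth,
background (a single small colony), full growth. The published scoring
convention counts only 1 and 3; the explicit 0 for "no colony" is this
package's representation of missing growth so that the denominator of every
ratio is the number of stamped positions. On the simulator's normalized
0–1 size scale the default thresholds are (0.25, 0.6), with the upper
boundary inclusive (a colony exactly at the full-growth threshold scores
3); real-data thresholds are instrument-specific and must be supplied.

For one configuration in one biological replicate, the replication ratio is
the fraction of technical positions at score 3 (maximum 1). A configuration
contributes to its pair only if it "showed the interaction" in the required
biological replicates. The published rule ("if all biological replicates
showed the interaction") is implemented literally as: ratio > 0 in **every**
biological replicate in which that configuration was tested, in which case
the contribution is the highest ratio across replicates, else 0. Two points
are ambiguous in the source description and are resolved as explicit,
configurable choices:

* a configuration tested in only one biological replicate passes the gate
  vacuously (a single replicate is all the evidence there is); and
* a `"majority"` gate (> 50% of replicates positive) is available as an
  alternative to the all-replicates default.

The pair score is the sum of its configuration contributions, bounded by
the number of testable configurations (at most 8). A pair is called
interacting at `score >= 0.75`; the comparison is inclusive because a
"cutoff of 0.75" with calls reported at the threshold is otherwise
undefined. Both the threshold and the comparison convention are surfaced in
`score_y2h()` / `call_interactions()`.

Auto-activity QC mirrors bench practice: baits are flagged from no-prey
control plates (default: any full-growth control position flags the bait; a
minimum fraction can be required instead), and preys are flagged when they
score positive with more than half of the tested baits (default 0.5; the
published description says "many" without a number). Flagged constructs are
excluded before scoring; the configurations that remain still produce a
valid score, just over fewer testable configurations.

## Trajectory classification

Calls for one ortholog gene pair form a species x species matrix (rows:
species providing gene A; columns: species providing gene B; homotypic gene
pairs are symmetrized by OR). Cells are positive, negative, or
untested/absent; untested cells never enter denominators. Each tested cell
belongs to the evolutionary-distance group of its species pair
(intra-species = 0 My; grouping defaults to exact unique divergence values,
custom bins are supported), and the per-group fraction positive is the
`n_positive / n_tested` profile.

The published analysis interprets these profiles qualitatively; the explicit
rule set here is this package's formalization, with all parameters exposed:

1. `not_detected` — no positive cell.
2. `conserved` — fraction >= theta_c (default 0.5) in every tested group,
   including the largest-distance group.
3. `coevolving` — intra fraction >= theta_c, fractions compatible with a
   non-increasing trend in distance, and fraction <= theta_f (default 0.25)
   in the largest-distance tested group.
4. `species_restricted` — positives exist and, for at least one gene, the
   orthologs appearing in any positive cell come from at most k_restrict
   (default 2) species.
5. `sporadic` — anything else.

The monotone-decay check deserves a note. Distance groups in a 5-species
design contain between 2 and 8 cells, so adjacent-group fractions are
extremely granular: an intra fraction of 0.8 next to a 2-cell group at 1.0
is perfectly compatible with a decaying interaction signal. Comparing
adjacent groups directly would therefore reject valid decaying profiles on
rounding noise alone. Instead, the check fits the best non-increasing
(antitonic, pool-adjacent-violators) curve to the group fractions and
requires the maximum deviation from that fit to be at most `mono_tol`
(default 0.1). For profiles like (0.8, 1.0, 0, 0, 0) the antitonic fit pools
the first two groups at 0.9 and the profile passes; genuinely increasing
profiles fail. This is the standard way to express "non-increasing up to a
tolerance" for small-count fractions.

In a degenerate single-species design only `not_detected` and `conserved`
are reachable (a 1 x 1 matrix is either empty or fully positive); this is
asserted in the test suite.

## Pairwise dN/dS (NG86)

The estimator is Nei–Gojobori (1986) codon counting, re-implemented from
first principles (the original analysis used DnaSP's pairwise estimates;
this is a methodological stand-in for that family of counting estimators,
not a bit-exact clone of any program):

* **Sites.** For each codon position, the synonymous site fraction is the
  fraction of the three single-nucleotide changes that preserve the amino
  acid. Changes creating stop codons are excluded and the position
  renormalized, so `s + n = 3` per codon — one of the two standard
  conventions, fixed here and enforced against an exhaustive oracle over
  all 61 sense codons.
* **Differences.** For k mismatched positions between two codons, the
  synonymous/nonsynonymous step counts are averaged over all k! substitution
  pathways, skipping pathways through stop codons; if no stop-free pathway
  exists, all pathways are used (documented fallback).
* **Distances.** Site counts are averaged over the two sequences;
  `pS = Sd / S`, `pN = Nd / N`; Jukes–Cantor correction
  `d = -3/4 ln(1 - 4p/3)`. Estimates are flagged rather than forced:
  `saturated` when p >= 3/4, `undefined_omega` when dS = 0, `no_sites`
  when an alignment contains no synonymous (or no nonsynonymous) sites.
* **Filtering.** Codon columns containing a gap, ambiguity code or stop in
  either sequence are removed entirely (complete deletion).

The codon-pair simulator is a deliberately simple mutation–acceptance
scheme: substitution attempts arrive as a Poisson process (expected
`divergence / 2` attempts per codon per lineage), each attempt mutates one
random position (transitions weighted by kappa, default 1), stop-creating
attempts are rejected, and selection enters through relative acceptance
probabilities `1 / max(1, omega)` for synonymous and `omega / max(1, omega)`
for nonsynonymous attempts. It is not a full time-reversible codon model
(no codon-frequency equilibrium, no rate heterogeneity); its adequacy for
calibration is established empirically: over 50 seeds at 3000 codons and
divergence 0.2 the mean estimated omega under neutrality (omega = 1) falls
within +/-10% of 1, and estimates at true omega 0.2 / 1 / 2 are strictly
ordered. Those checks run in the acceptance suite; single-gene dN/dS values
of the original study are not reproduced here because they require the
underlying CDS data.

## co-IP/MS enrichment

The downstream statistics for protein-group intensity tables follow the
published processing order, with unnamed steps made explicit:

* log2 transform of raw intensities (0 = not detected).
* "Normalized across all protein groups of all samples" is implemented as
  per-sample median centering (each sample's median log2 intensity is
  shifted to the common median); quantile normalization via limma is
  available, as the original description does not name the method.
  Centering is idempotent: already-centered samples pass through unchanged.
* A protein group is kept in a biological-replicate sample only if detected
  in **every** technical replicate of that sample; surviving technical
  replicates are averaged. This reproduces the published filtering semantics
  as a rule (groups seen in only one technical replicate never enter the
  statistics).
* GFP-relative ratios: per sample group, each protein's log2 value minus
  the group-average log2 value of the eGFP reference; the reference's own
  group mean is exactly 0.
* Differential enrichment: mean log2 fold change over biological
  replicates, Welch (unequal-variance) two-sided unpaired t test, and
  Benjamini–Hochberg adjustment — the published description says only
  "t tests" and "adjusted P values", so the most conservative common
  choices are the defaults. Volcano hits require a linear fold change
  strictly greater than 1.5 (|log2 FC| > log2 1.5) **and**
  -log10(adjusted p) > 2. Protein groups with fewer than two retained
  replicates on a side are flagged untestable, never silently dropped;
  missing values are never imputed.
* Tukey fences for box-plot outliers: Q1 - 1.5 IQR and Q3 + 1.5 IQR with
  type-7 (linear interpolation) quantiles, fixed and documented; at least
  4 values are required.

## What the generators emulate — and what they do not

`simulate_y2h()` reproduces the screen's observable structure: the full
ordered bait x prey construct grid, 2–3 biological replicates per bait,
3–4 technical positions per prey, no-prey control plates, 10 auto-active
bait and 2 sticky prey constructs (the counts excluded in the original
screen), and colony sizes drawn from two beta modes on [0, 1] (background
mean ~0.1, full growth mean ~0.8) so that size discretization is a
meaningful step. True pairs (default 199, the size of the original call
set) are detectable per configuration with probability 0.8 — modelling
tag fusions that mask a binding surface — and detectable configurations
have per-position detection probabilities in [0.6, 0.95]. Background
positions reach full growth with probability 0.005. The generator does not
model yeast growth kinetics, plate spatial effects, or mating efficiency;
recovery statistics on it measure the scoring pipeline, not Y2H itself,
and say nothing about the false-negative rate of the real assay.

`simulate_trajectory_matrices()` plants one of four generative patterns per
gene pair. Noise is **signal dropout**: a signal cell is observed positive
with probability 1 - noise. A symmetric per-cell flip would make the
`not_detected` label unreachable at any positive noise (a single flipped-on
cell contradicts "no positives"), so false positives are a separate rate,
default 0. The coevolving pattern decays logistically with divergence
(midpoint 9 My, scale 1 My by default — between the 5 My and 13 My
neighbour groups, i.e. "close relatives only"); at noise 0 the pattern is
effectively deterministic, which is why zero-noise classification accuracy
is exactly 1.

`simulate_coip()` plants linear fold enrichment on a random protein subset
in bait groups, keeps the eGFP reference abundant and never missing, and
applies intensity-dependent missingness scaled to an overall target rate
(`missing_rate = 1` removes everything except the reference). It does not
model peptide-level quantification, shared-peptide protein-group inference,
or correlated contaminants.

All generators are pure functions of their configuration and seed.

## Problem sizes and numerical choices

The test and acceptance suites run: one full-scale simulated screen
(53 proteins, ~100,000 colony observations) per run; 200 simulated gene
pairs per noise level for trajectory recovery; 50 seeds x 3000 codons for
the neutral omega calibration; and 1 + 20 co-IP simulations (300 protein
groups, 4 biological x 2 technical replicates) for hit recovery and the
null false-positive control. These sizes give stable stochastic margins
(e.g. classification accuracy ~0.97 against a 0.9 bound) at a few seconds
per suite.

Other conventions: floating-point tolerance 1e-12 on the antitonic
monotonicity check; inclusive comparisons at the score threshold and the
discretization upper boundary; `score_y2h()` is invariant to row order of
the observation table (grouped reductions only); TSV writers emit '#'
header comments (tool version, content hash) that all readers skip.

## Known limitations

* The trajectory rule set is a formalization of a qualitative published
  argument; labels near rule boundaries (e.g. a conserved pair with one
  sparse distance group at 0.4) are sensitive to theta_c and should be
  read together with the underlying profile, which every result object
  carries.
* NG86 ignores transition/transversion bias and unequal codon frequencies;
  with strongly biased mutation the estimator inherits NG86's known biases.
  The simulator's kappa parameter exists precisely to explore this.
* The replicate gate treats biological replicates symmetrically; batch
  effects between replicates are not modelled.
* Statistical significance is attached to enrichment calls only; trajectory
  labels carry no p-values because no test is defined for them in the
  source analysis.
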