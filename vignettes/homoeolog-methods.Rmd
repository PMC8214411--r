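---
title: "Methods: homoeolog inference, synteny scoring and category comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homoeolog inference, synteny scoring and category comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homoeologr)
```

## The problem and the model

An allopolyploid genome contains two subgenomes, A and D, that diverged as
separate species and were reunited by hybridisation and whole-genome
doubling. Homoeologs are cross-subgenome gene pairs descending from one
ancestral gene through that history. Two conventions dominate homoeolog
inference, and both bias the result toward the best-conserved fraction of
the genome:

* **BBH** (bidirectional best hit) forces at most one partner per gene, so
  any gene family that duplicated after subgenome divergence loses all but
  one of its true relations;
* a **synteny requirement** keeps only pairs whose neighbourhoods still
  match, so transposed or dispersed-duplicated homoeologs are discarded.

This package infers a *comprehensive* many-to-many homoeolog set, scores
local synteny for each pair separately, and then classifies pairs by the
cross of the two criteria rather than filtering on them. The four
categories — BBH & syntenic, BBH & nonsyntenic, non-BBH & syntenic,
non-BBH & nonsyntenic — can then be compared on duplication extent,
evolutionary distance, protein length, expression and GO enrichment.

## Pair inference

All-vs-all cross-subgenome protein similarity comes from local alignment
(Smith–Waterman, BLOSUM62, affine gaps: opening 10, extension 1 per
residue) or, for larger sets, NCBI BLAST+ run with default scoring and
ingested through the 14-column tabular dialect (`-outfmt "6 std qlen
slen"`); the two full-sequence lengths are required because coverage is
defined as aligned span over full protein length. A pair passes the
coverage filter when the *minimum* of its two coverages is ≥ 0.60.

Directed scores are collapsed to one score per unordered pair (the maximum
over the two directions; BLAST's directional asymmetries are far below the
tolerance used downstream). On these collapsed scores:

* **BBH**: (a, d) is kept iff each is the other's highest-scoring partner.
  Ties are broken deterministically — score descending, then partner id
  ascending — so the BBH set is always a matching. No coverage filter is
  applied here, mirroring a plain reciprocal-best-BLAST extraction; this
  asymmetry is what makes the "BBH-only pairs failing coverage" accounting
  possible.
* **Tolerant set**: (a, d) is kept iff it passes coverage and
  s(a,d) ≥ (1−ε)·best(a) and s(a,d) ≥ (1−ε)·best(d), with ε = 0.05 by
  default. At ε = 0 this reduces to mutually-best pairs (with ties). The
  relative-score tolerance is a deliberately simple surrogate for
  mutually-closest-within-a-confidence-interval criteria used by
  production orthology systems; it is not a reimplementation of any of
  them, and ε is the single knob controlling how much post-divergence
  duplication survives inference.

A note on an invariant worth knowing: "every tolerant-set gene with exactly
one relation on both sides forms a BBH pair" holds exactly at ε = 0 and
empirically on sequence-derived scores at ε = 0.05, but it is *not* a
theorem for arbitrary score matrices at ε > 0 — a gene's only surviving
relation need not be its best hit if the best hit was excluded from the
partner's side of the tolerance. The test suite asserts it in the two
regimes where it holds.

### Witness of nonhomoeology

Differential loss of an old duplication makes two paralogs the mutually
closest genes across subgenomes ("hidden paralogs"). Given an outgroup
proteome, a candidate pair (a, d) is flagged when a's best outgroup hit
o_a and d's best outgroup hit o_d are distinct outgroup genes that are
each closer to their in-pair partner than to each other
(s(o_a, o_d) < min(s(a, o_a), s(d, o_d))). That score geometry holds
precisely when the duplication predates the outgroup split — the only
scenario in which the outgroup can testify. A missing outgroup-internal
score counts as −∞ (flagged); with no outgroup data the filter is the
identity. Production systems use richer verification; this criterion is the
minimal explicit form of the same idea.

### Evolutionary distance

Distance is estimated from percent identity with the correction
d = −100·ln(1 − p − 0.2p²), p the fraction of differing residues,
reported on a PAM-like scale (1 unit ≈ 1% expected amino-acid change).
The correction saturates at p ≥ 0.85, which is an error rather than a
clamped value. Estimates from identity are systematically different from
distances read out of curated orthology databases (which fit full
substitution models), so absolute per-category medians are not comparable
across the two routes; within one analysis the estimates are fine for
ranking and distribution comparison.

## Synteny score

For a pair (a, d), take up to `half_window` = 5 genes on each side of each
member on its own scaffold, truncated at scaffold ends and excluding the
focal gene. With windows W_A and W_D, the score is

> (#{g ∈ W_A with a partner in W_D} + #{h ∈ W_D with a partner in W_A}) / (|W_A| + |W_D|)

— the pooled fraction over both windows, a single ratio. An alternative
reading averages the two per-window proportions; the two definitions agree
whenever the windows are full and differ only on truncated windows, where
pooling weights neighbours equally rather than windows equally. Partner
membership uses the *full* tolerant homoeolog index, not the BBH subset:
synteny is evidence about neighbourhoods, and neighbourhood relations
include duplicates.

The score is undefined (pair excluded, reason `small_scaffold`) when either
window has fewer than `min_neighbors` = 2 genes, which reproduces the
small-scaffold exclusion rule of window methods. Nonsyntenic means score
exactly 0 — no epsilon — and the 11-bin histogram gives {0} its own bin
with right-closed bins (0, 0.1], …, (0.9, 1] for the rest. Windows never
wrap across scaffolds, the denominator is the actual neighbour count (not
20), and strand is ignored: gene order is the only positional signal, so
inversions that preserve neighbourhood content do not reduce the score.

## Classification and accounting

Scored pairs are classified by crossing BBH membership with the zero/positive
synteny rule; pairs without a score are `excluded` and leave the analysis.
All reported percentages are recomputable from the reported integer counts
(the pipeline verifies this before writing `report.json`) and displayed
half-up at one decimal. The two-method overlap report decomposes the
BBH-only pairs into those failing the coverage filter, those flagged by the
witness check, and a residual, summing exactly.

Gene-centric metrics (relations per gene, protein length, expression)
deduplicate each category's gene list — a gene appears at most once per
category but may appear in several categories. Evolutionary distance is
pair-centric. Distributions are compared with the two-sided two-sample
Kolmogorov–Smirnov test using the asymptotic p-value (sample sizes here
make exact small-sample enumeration pointless; ties are handled by the
ECDF jumps).

## Expression

Sample-level TPM is averaged to condition level first (time-point samples
within a tissue are arithmetic-averaged; single-sample conditions pass
through), and the expression threshold TPM ≥ 2 — inclusive — is applied to
condition-level values. The order matters: a gene at 3.9 TPM in one time
point and 0 in another is *not* expressed in that condition (mean 1.95),
and a property test pins this down against regressions. Breadth counts
expressing conditions out of 12; level is the mean TPM across *all* 12
conditions including sub-threshold ones; "expressed" means breadth ≥ 1.
Per-category breadth/level distributions are restricted to expressed genes.
Transcript-to-gene aggregation is not performed: abundance-table
`target_id`s are taken as gene ids, a documented limitation when feeding
real quantifier output.

## GO enrichment

Annotations are closed over `is_a` ancestors (true-path closure; the
closure is idempotent and monotone, and diamond ancestry counts once).
Closure toward ancestors is the only direction that makes term counts
coherent — annotating descendants would claim more specific knowledge than
the curator asserted. Per category, a one-sided (over-representation)
Fisher exact test is run for every term annotating at least one study gene,
against the background of all genes in the gene-centric sets. The
Bonferroni family size m is the number of tested terms, fixed before any
filtering; corrected p < 0.05 is reported as enriched. Redundancy
summarisation of enriched term lists is out of scope; outputs are sorted
tables.

## The synthetic generator

The generator is the package's study system, and its defaults are the
conditions under which the recovery properties are asserted:

| parameter | default | meaning |
|---|---|---|
| `n_ancestral_genes` | 500 | genes in the common ancestor |
| `n_scaffolds_per_subgenome` | 5 | layout of the ancestral order |
| `divergence_distance` | 6 | substitutions per 100 residues between subgenome copies |
| `tandem_dup_rate` | 0.05 | per-gene tandem duplication (child adjacent to parent) |
| `dispersed_dup_rate` | 0.05 | per-gene dispersed duplication (child at a random position) |
| `transposition_rate` | 0.02 | per-gene cut-and-paste move |
| `loss_rate` | 0.03 | per-gene per-subgenome loss |
| `hidden_paralog_rate` | 0.02 | per-gene hidden-paralog scenario (needs outgroup) |
| `mean_protein_length` | 200 | residues, log-normal with sdlog 0.25 |
| `outgroup_divergence` | 30 | substitutions per 100 residues to the outgroup |
| `dup_divergence` | 2 | extra divergence of a duplicate from its parent |
| `paralog_divergence` | 50 | age of the duplication behind hidden paralogs |

Sequence evolution is i.i.d. per-site substitution with Poisson-style
saturation (a site changes with probability 1 − e^(−r), to a uniformly
chosen different residue), split evenly over the two branches. This is
sufficient because downstream stages consume only similarity ranks,
coverages and an identity-based distance estimate. Tandem duplicates
preserve synteny by construction (cut-and-paste vs copy-and-paste
mechanisms place tandem children adjacent to the parent, dispersed children
and transposed genes at uniform random positions). Hidden paralogs are
planted as a duplication *older than the outgroup split*
(`paralog_divergence` > `outgroup_divergence`, the regime in which the
witness geometry holds) followed by complementary losses, with the
outgroup retaining both copies. Truth labels carry each relation's event
class and a best-effort expected category; edge effects (a duplicate
landing inside a syntenic block) can legitimately differ, so recovery is
asserted as precision-style rates, not exact label equality.

Expression is log-normal with a per-gene effect (the total log-sd splits
evenly between gene effect and residual, so a zero log-sd design yields
exactly constant TPM), 12 conditions with the five multi-time-point tissues
carrying 4, 5, 5, 8 and 3 samples (32 samples total), and per-gene-per-
condition dropout. The GO generator builds a small rooted `is_a` DAG (one
root, an intermediate layer, the rest leaves) and annotates genes to leaf
terms independently with per-term baseline probabilities in [0.1, 0.4];
the planted term's odds are multiplied by `enrichment_odds` for genes of
the planted category.

What the generator does **not** emulate — and what passing recovery
therefore does not show about real data: insertions/deletions (all
alignments are full-coverage, so the coverage-failure pathway is exercised
only by constructed tests), codon-level and rate-heterogeneous evolution,
intergenic sequence and read-level expression noise, category-dependent
expression silencing (the generator's expression is independent of the
homoeolog category, so the per-category expression contrasts seen in real
allopolyploids are not reproduced here), and genome-scale gene counts.

## Numerical and operational choices

* Determinism: every stochastic step is seeded; identical configuration and
  seed give byte-identical fixtures and an identical `report.json`.
* Tie-breaks: (score desc, id asc) everywhere a best partner is chosen.
* Rounding: reported percentages are half-up at one decimal.
* Degenerate inputs: empty match lists give empty (not failing) pair sets;
  empty categories are reported as absent, never as zeros; KS comparisons
  with fewer than 2 values are skipped with a warning; a gene missing from
  the expression table counts as not expressed and is tallied.
* Genes without a subgenome assignment are dropped before inference with a
  logged count.
* Problem sizes: module tests run on 40–400-gene genomes; the recovery
  properties run at the full default conditions (500 ancestral genes, five
  seeds) — the package's chosen desk-scale study size, sufficient for
  ~2,000 interior ancestral pairs and ~250 surviving dispersed duplicates
  per five-seed pool.
* Null calibration: with `enrichment_odds = 1`, the fraction of leaf terms
  at raw p < 0.05 is checked against [0.005, 0.075] rather than a
  symmetric band around 5%: Fisher's exact test is discretely conservative,
  so its null rejection rate sits at or below the nominal level — at study
  sizes of ~90 genes, visibly below it. A symmetric band would mistake that
  known property for a calibration failure.

## Known limitations

Beyond the generator's simplifications above: the tolerant criterion is a
surrogate, not an orthology-system reimplementation; distance estimates are
identity-based and not comparable to model-based distances; synteny uses
gene order only (no orientation, no collinearity chains); the witness check
requires a single outgroup proteome and uses best hits only; and BLAST
bitscores are the similarity currency whenever BLAST is the engine, so
score-sensitive results can differ marginally from the in-R aligner on
borderline ties.
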