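---
title: "Entropy-based conservation patterns in paralog families: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-based conservation patterns in paralog families: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paraldiv)
```

## The model

`paraldiv` analyses a multiple sequence alignment of a paralogous protein
family in which every sequence is assigned to one of *k* paralog groups
(for the mammalian ABCG transporters: ABCG1, ABCG2, ABCG4, ABCG5, ABCG8,
sampled across species). The unit of analysis is the alignment column. The
question asked of each column is not "how conserved is it?" but "**which
groups conserve it, and do they conserve the same residue?**" — the
information needed to separate type I from type II functional divergence
and to compare multiple groupings at once.

Conservation is called with the plug-in Shannon entropy of the observed
residue frequencies,

$$H = -\sum_{a \in \text{AA}_{20}} p_a \log_2 p_a,$$

computed without pseudocounts or sequence weighting, on the 20-letter
amino-acid alphabet. $H$ runs from 0 bits (one residue) to
$\log_2 20 \approx 4.32$ bits (uniform). A column (or a group's slice of a
column) is *conserved* when $H$ is **strictly below 2/3 bit** — low enough
that, say, 7-of-8 agreement qualifies (0.544 bits) while 3-of-4 does not
(0.811 bits).

The classification procedure per column, in order:

1. **Gap filter.** If at least 10 % of all sequences, or at least 30 % of
   any single group, are gapped, the column is `GAP` and excluded. Both
   comparisons are inclusive ("at least"). Gap and ambiguity characters
   are never part of an entropy denominator.
2. **Family-wide test.** Whole-column $H < 2/3$ bit gives `ALL_CONSERVED`
   (divergence class `TOTAL`).
3. **Per-group test.** Each group's entropy is computed separately. Groups
   under the cutoff record their most common residue; conserved groups
   recording the same residue merge into a *block*. No conserved group
   gives `NOT_CONSERVED`; otherwise the column is a `PATTERN`, and the
   divergence class follows from the block structure: `TYPE_II` when every
   group is conserved in two or more blocks, `TYPE_I` when a single block
   faces only unconserved groups, `MIXED` otherwise.

A *conservation pattern* is the residue-agnostic identity of that outcome:
the partition of the conserved groups into blocks, written
`(ABCG1,ABCG4)(ABCG2)(ABCG5)(ABCG8)`-style, with unconserved groups
omitted. Canonical form sorts blocks by size (descending), then by
lexicographically smallest member, so equality is string equality.

## Pattern combinatorics and significance

Every non-empty subset of the $k$ groups can be the conserved set, and a
conserved set of size $i$ admits $\mathrm{Bell}(i)$ block partitions, so

$$N_\text{patterns} = \sum_{i=1}^{k} \binom{k}{i}\,\mathrm{Bell}(i),$$

which is 202 for $k=5$. Observed counts per pattern are compared with a
Poisson null in which the non-gap columns spread uniformly over the
possible patterns: $\lambda = N_\text{cols}/N_\text{patterns}$. The family
significance level (default $\alpha = 0.1$) is Bonferroni-divided by
$N_\text{patterns}$, and the threshold is the smallest $n$ with
$F_\text{Pois}(n;\lambda) \ge 1 - \alpha/N_\text{patterns}$, computed with
the exact CDF (`stats::ppois`), never a normal approximation. A pattern is
significant when observed in **strictly more** than $n$ columns. At 595
non-gap columns, 202 patterns and $\alpha = 0.1$ the threshold is 10.

Expected counts per pattern combine (i) each group's empirical
conservation frequency $p_g$ over non-gap columns (columns conserved
family-wide count as conserved for every group), treated as independent
across groups, and (ii) the probability that a conserved set of size $n$
falls into one specific partition with $m$ blocks when each group's
conserved residue is an independent uniform draw from 20 letters:

$$P(\text{partition}) = \frac{19!}{(20-m)!\; 20^{\,n-1}}.$$

Two groups share a residue with probability $1/20 = 0.05$; the
probabilities over all partitions of an $n$-set sum to one (both facts are
unit tests). Independence across paralog groups is a deliberate
simplification — paralogs are phylogenetically correlated, so expected
counts are a null reference rather than a fitted model. The package
computes expectations per specific partition; sums over partitions of a
fixed conserved set (the "by shape" aggregation) are available by adding
the returned values, and the normalisation test covers exactly that
identity.

## Structure mapping

`build_column_residue_map()` is a bijection between the non-gap columns of
a chosen reference sequence and its ungapped residue numbers, plus a fixed
offset to match a structure's author numbering (e.g. alignment column 1011
↔ R482 of human ABCG2). Binding pockets and dimer interfaces are residue
sets at a distance cutoff (default 5 Å, inclusive): a residue belongs to
the set when **any heavy atom** lies within the cutoff of any heavy atom
of the ligand or partner chain. Hydrogens are excluded by default and the
highest-occupancy alternate conformer is kept; both choices are
configurable. Interface extraction considers polymer (ATOM-record)
residues only, so waters or ligands sitting between protomers never
mediate membership. Sidechain summaries classify a pattern's conserved
residues per group as charged ({D, E, K, R, H} by default — histidine's
inclusion is configurable since its protonation is context-dependent),
hydroxylated ({S, T}), or other.

## The synthetic-data generator

Real alignments of this kind are ~174 sequences over ~1269 columns with
five groups of ~35; the generator's default layout is five groups of 35.
Each column is planted from a plan (`GAP`, `ALL_CONSERVED`,
`NOT_CONSERVED`, or `PATTERN` with explicit blocks and block residues):

* conserved groups emit their block residue, each sequence independently
  substituted with probability `noise_rate` (uniform over the other 19
  letters);
* unconserved groups receive an as-even-as-possible multiset over a
  10-letter sub-alphabet (disjoint from the column's block residues),
  randomly assigned to sequences. The even spread guarantees a per-group
  entropy of at least 1 bit for any group of two or more sequences —
  safely above the 2/3-bit cutoff — so noise-free recovery of the planted
  classification is exact by construction, not just with high probability;
* gap columns place `ceiling(gap_rate * n)` gaps (never fewer than the
  overall filter needs) on a random subset of sequences.

Feasibility is checked analytically before generation: a conserved plan
needs the expected noisy entropy $h(\varepsilon) + \varepsilon\log_2 19$
below the threshold, and an all-conserved-blocks plan needs the
block-share entropy of the whole column at or above it (otherwise the
column would be called `ALL_CONSERVED`, not `PATTERN`). One seed in the
`simulation_spec` governs all randomness, and the caller's random state is
restored afterwards.

What the generator does **not** emulate: phylogenetic correlation within
and between groups (sequences are exchangeable within a group), indel
structure (gaps are placed independently per column), composition bias,
and alignment error. Passing recovery tests therefore demonstrates the
classifier's correctness under its own statistical assumptions — not
robustness to tree-shaped noise in real families.

At a small noise rate the recovery of planted calls degrades gracefully
and predictably: with 35 sequences per group at a 2 % substitution rate, a
conserved group's sampled entropy crosses the cutoff only when 4 or more
of its 35 residues are substituted (probability ≈ 0.005), so per-group
conservation calls are recovered at ≈ 99.5 % and full five-group column
patterns at ≈ 97.5 %. The test suite asserts both at their attainable
levels.

## Numerical and design choices

* **Strict vs inclusive comparisons.** Conservation is $H$ *strictly
  below* the threshold; gap flagging is *at or above* its fractions.
* **Ties.** The most common residue of a group is tie-broken
  alphabetically. (A two-way tie forces $H \ge 1$ bit, so ties cannot
  actually occur in a conserved call at the default threshold; the rule
  matters only for user-raised thresholds.)
* **Ambiguity codes.** B, J, Z, X, U, O are tallied as "ambiguous": they
  count toward a column's sequence total but never enter entropies, which
  stay on the 20-letter alphabet.
* **Single-block boundary.** A column where every group conserves the
  *same* residue yet whole-column entropy sits at or above the threshold
  (possible with diverse minority residues) is kept as a `PATTERN` with
  one all-group block, typed `TYPE_II` and flagged `boundary = TRUE`, so
  it is never silently merged with `ALL_CONSERVED`.
* **NOT_CONSERVED semantics.** A column is `NOT_CONSERVED` only when *no*
  group is conserved; any conserved group yields a pattern record.
* **Degenerate inputs.** Groups need at least two sequences (singleton
  entropy is trivially 0); columns or group-slices with no usable residues
  raise an explicit empty-column error (the gap filter pre-empts this in
  practice).
* **Problem sizes.** Tests run the full pipeline at the realistic scale —
  5 × 35 sequences × 1269 columns for the planted-census test — which
  takes a few seconds; property tests use 4–8 sequences per group where
  the oracle is exhaustive enumeration.

## Limitations

Entropy thresholding at 2/3 bit is a hard cutoff: columns straddling it
flip status with single-sequence changes, and no uncertainty is attached
to a call. The Poisson/Bonferroni significance rule treats patterns as
exchangeable and columns as independent, both of which real alignments
violate (adjacent columns co-vary; patterns aligned with the gene tree are
a priori likelier). Expected counts inherit the independence assumption.
The structure stage maps single reference sequences; it does not model
conformational ensembles or do any docking.
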