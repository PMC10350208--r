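---
title: "Methods: clonal lineage assignment and repertoire statistics for ASC populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal lineage assignment and repertoire statistics for ASC populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ascrep)
```

## Scope and data model

`ascrep` analyzes heavy-chain AIRR-seq rearrangement tables of sorted
antibody-secreting cell (ASC) populations within one subject. The input
unit is a rearrangement: a sequenced VDJ read with V/J gene calls, the
junction (CDR3 plus anchor) nucleotide string, a duplicate count, and
optionally a V-region mutation count assigned by the upstream germline
aligner. Everything upstream — basecalling, quality filtering, V(D)J
alignment — is out of scope; the package consumes the aligner's output and
never recomputes gene calls or mutation counts from sequence.

## The clonal lineage model

The estimator `assign_lineages()` partitions all rearrangements of one
subject, pooled across populations, into clonal lineages. Two sequences
belong to the same lineage when they share the V gene, the J gene, the
junction length, and are connected at ≥ 85 % junction nucleotide identity
under single linkage. Practical consequences of each choice:

**Gene-level matching.** Raw calls carry allele suffixes and sometimes
several comma-separated candidates. Allele calls are unstable under
somatic hypermutation, so matching is at the gene level: the first listed
call (aligners list the best match first) with the allele suffix stripped.

**The homology substrate is the junction nucleotide string as provided**,
anchors included. Amino-acid homology would be an alternative reading;
nucleotide identity is chosen because it is the reproducible
operationalization on the standard `junction` column and is stricter
(silent mutations count as differences). This choice is surfaced here
rather than buried: results at a fixed threshold differ slightly between
the two substrates.

**Single linkage.** Only a homology threshold is assumed, not a cluster
shape; single linkage (lineage = connected component of the threshold
graph) is the weakest assumption consistent with a threshold and the
standard practice for BCR clonal grouping. The implementation runs a
union-find over candidate pairs within each V/J/length group, with exact
all-pairs comparison inside a group; duplicate junction strings are
collapsed first. Groups at the tool's intended depth (tens of thousands of
sequences per sample, spread over hundreds of V/J/length keys) stay well
within exact all-pairs range.

**Inclusive boundary, exact arithmetic.** Identity is the rational
matches/length, and "85 % homology" is read as attained-at-85: a pair at
exactly 0.85 links. The comparison is performed on integer match counts
(`matches >= ceiling(0.85 * L - 1e-9)`), so no pair is ever linked or
split by floating-point representation. Whether the original in-house
implementations compared strictly or inclusively is not documented
anywhere we know of; inclusive is the choice here, and the generator's
`boundary_pairs()` makes the consequence testable (a pair at exactly the
threshold must co-cluster, one mismatch more must not).

**Determinism.** Component labels are canonicalized by the smallest member
sequence id, groups by sorted key, so the partition — and the emitted
lineage ids — are invariant under input row permutation.

Clone size is reported both as unique retained sequence count (the
default for all presence/absence statistics) and duplicate-weighted count.
Presence of a clone in a population should not depend on read-depth
weighting, hence the unique-count default.

## Repertoire statistics

**Rank profiles.** Per population, lineages with nonzero size are sorted
by descending size (ties broken by lineage id), giving fractions
`p_1 ≥ p_2 ≥ …` of the population total and their cumulative sums — the
quantities plotted in clonality rank/cumulative curves. The y-axis
normalization is fraction-of-repertoire; no other normalization of
"lineage size" is applied.

**Expanded clones.** The rule is a threshold of 0.1 percentage points on
the drop between consecutive size-ranked clones. A one-sentence rule
admits two readings: the maximal prefix over which every consecutive drop
qualifies, or everything above the *deepest* qualifying drop. The deepest
reading is the default (`rule = "deepest"`) because it matches the visual
elbow of a rank plot — a run of near-equal large clones followed by a
cliff is all "expanded"; the prefix reading is available via
`rule = "prefix"`. Only observed consecutive pairs are scanned; no virtual
clone of size 0 is appended after the last rank. Drops are compared with a
1e-9 absolute epsilon so that profiles constructed to sit exactly at the
threshold in double precision qualify.

**Morisita overlap.** The legend definition — 0 for no similarity, 1 for
an identical repertoire — is satisfied by the Morisita-Horn form on
per-lineage fraction vectors over the union of lineages,
`MH = 2 Σ p_i q_i / (Σ p_i² + Σ q_i²)`. It is exactly 1 for identical
fraction vectors and exactly 0 for disjoint supports (the implementation
computes numerator and denominator from the same products, so the bounds
are attained bit-exactly, not within rounding). The classical Morisita
index on integer counts (which can slightly exceed 1 on small samples) is
available as `variant = "classical"`; Morisita-Horn is the default
because the documented [0, 1] range is part of the statistic's contract
here.

**Connectivity and sharing curves.** Connectivity from reference `r` to
population `o` is 100 × (scoped lineages of `r` detected in `o`) /
(scoped lineages of `r`), with scope all, expanded, or top-n. Clones are
counted, not sequences. An empty scope (no expanded clones) yields `NA`
with a warning — never 0, which would silently bias cohort averages. A
top-n request beyond the available lineages uses all of them and flags
`truncated`. `sharing_curve()` evaluates the top-n scope over a grid
(default 5, 10, 25, 50, 100; 25 is the conventional headline point);
monotonicity in n is not assumed. `link_table()` emits one row per
(lineage, population pair) present in both, sized both ways, for
chord/Circos rendering — the package does not render the graphic.

## SHM summaries

`shm_load()` reports mean, median and quartiles of the per-sequence
V-mutation count per population, over sequences with non-missing counts;
populations without data are reported missing, not dropped.
`intraclonal_divergence()` operationalizes "sequential progression of
somatic mutation" — for which no formula exists in the literature this
package follows — as the within-lineage mutation-count range, flagged
above a cutoff of 5 mutations by default. The cutoff is a tool parameter,
not a literature value. Mean pairwise junction mismatches per lineage
accompany it as a sequence-level divergence measure. Singleton lineages
are excluded from the divergence table rather than zero-filled: a
singleton provides no evidence about intraclonal behavior.

## The synthetic generator

`simulate_repertoires()` emulates the structures the statistics are meant
to detect, with known truth:

- **Populations**: default 4, labeled pop2–pop5 after the CD19/CD138 ASC
  sorting scheme (cosmetic); default depth 50,000 sequences per
  population, matching the sequencing depth the pipeline targets (tests
  and examples scale this down).
- **Clone sizes**: Zipf law with exponent α = 1.5 over each population's
  lineages (heavy-tailed rank-abundance as observed in clonally expanded
  repertoires); integer sizes with a minimum of 1 so membership is always
  realized.
- **Sharing**: the first population is the base and holds all
  `n_lineages`; each additional population shares each base lineage
  independently with probability `s` and is topped up with private
  lineages to the same `n_lineages`. Under this design the expected
  all-scope connectivity from the base population is exactly `100·s`,
  which is what the recovery tests exploit. With `s = 0` populations are
  full but disjoint; `identical_populations = TRUE` gives identical
  fraction vectors (Morisita exactly 1).
- **Identity margins**: within-lineage variants mutate at most
  `floor(0.075·L)` positions from the founder, so any two variants are at
  ≥ 85 % identity; founders sharing a V/J/length key are rejected until
  below 70 % pairwise identity. For junction lengths that are multiples
  of 3 in [30, 66] nt these margins leave a strict dead zone around the
  threshold, so clustering recovery is exact by construction, and a
  recovery failure is always an implementation defect, not bad luck.
  `boundary_pairs()` deliberately breaches the dead zone to probe the
  boundary rule.
- **Mutation load**: one Poisson(λ, default 8) base per lineage shared by
  all members across populations, plus per-sequence rounded Normal(0, σ)
  jitter floored at 0; `shm_jitter = 0` gives the zero-jitter mode in
  which no lineage can be flagged divergent.
- **Corruption mode**: `corrupt_repertoire()` injects N-containing
  junctions and inconsistent lengths to exercise validation.

What the generator does **not** emulate: biological V(D)J recombination,
junction indels within lineages (variants are substitution-only, so
equal-length grouping is lossless here but real indel variants would split
lineages), realistic gene-usage frequencies, isotypes, or sequencing
error. Passing recovery tests therefore demonstrates correctness of the
computations under the stated clonal model — not robustness to upstream
artifacts of real data.

## Validation design and problem sizes

The test suite validates each operation against an independent oracle:
hand-computed rational identities; brute-force all-pairs threshold graphs
(components via igraph) against the union-find clustering on 100 random
structured groups of up to 200 sequences; binomial ground truth for
sharing recovery (20 seeds × s ∈ {0.1, 0.4, 0.8}, 500 lineages per
population, 1,500 sequences per population — sizes chosen to keep the full
suite in a few minutes while leaving binomial noise well inside the
5-percentage-point recovery band); a log-log rank-slope check of the Zipf
law at 500 lineages and 50,000 sequences; and byte-identity of repeated
pipeline runs for determinism. The acceptance script sweeps the two
decision boundaries directly: pairwise identity in exact 1 % steps on
length-100 junctions (co-clustering first at 85 %), and the consecutive
rank-drop in 0.01 pp steps (the expanded boundary first moves at 0.1 pp).

## Known limitations

- Equal junction length is a hard partition: lineages with indel variants
  are split by construction, as in any V/J/length-keyed clonal grouping.
- Nucleotide-vs-amino-acid homology and strict-vs-inclusive thresholds
  are documented choices, not established facts about every upstream
  pipeline; comparisons across tools should fix both.
- The intraclonal divergence cutoff (5 mutations) is heuristic; treat the
  flag as a screen, not a test with error control.
- Cross-subject analyses are intentionally unsupported: lineage identity
  is meaningful only within a subject.
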