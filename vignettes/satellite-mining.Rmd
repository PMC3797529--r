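---
title: "Mining and evolution of tandem satellite repeats: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and evolution of tandem satellite repeats: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

satmine annotates a tandemly repeated satellite DNA family across a genome
assembly and quantifies how the family evolves: local tandem duplication,
spreading between non-homologous chromosome ends, exchange between
subtelomeres and centromeres, and occasional recombination between monomer
lineages. This vignette is the package's account of the models behind each
stage, the parameters that matter, and the choices made where the design
was genuinely open.

## The profile model and the scanner

A satellite family is summarised by a position-specific scoring model
built from a seed alignment of monomers (`build_profile()`). Alignment
columns gapped in more than `gap_col_threshold` (default 0.5) of rows are
treated as insert states and dropped; the remaining columns are match
positions. Emissions are log-odds scores in bits,

$$e_i(b) = \log_2 \frac{(c_{ib} + \lambda) / (R + 4\lambda)}{q_b},$$

with per-column counts $c_{ib}$, row count $R$, pseudocount $\lambda$
(default 1, which keeps every score finite) and background $q$ (uniform by
default, so scores do not depend on the composition of any particular
genome). `N` residues contribute a quarter-count to each base, and score
zero (neutrally) when scanned. A full profile HMM with forward-algorithm
scoring would add little here: monomer detection is a thresholding
problem, and a Viterbi-style glocal affine-gap aligner (global over the
profile, local over the sequence; compiled in C++) is deterministic and
directly testable. Traceback ties break match > delete > insert. The gap
penalties (open −6, extend −1 bits) are mild relative to the typical
match/mismatch contrast (about +1/−0.6 bits per position), because
monomers mostly differ by substitutions; they only need to beat paying
mismatches through an indel.

Scanning (`scan_genome()`) seeds candidate windows from exact 12-mer
matches against the profile consensus, requiring at least 3 seeds per
window — with 5 % monomer divergence the expected number of intact
12-mers per 528-bp unit is still in the hundreds, so recall is not
seed-limited — then scores each window and keeps hits above `min_score`.
The default threshold is 40 % of the consensus self-score: clade-level
divergence within a satellite family runs to ~28 % nucleotide distance
(units ≥ 72 % identical), which scores well above 0.4 of self, while the
empirical null from 1000 random background sequences stays far below half
the self-score (a property the test suite re-establishes on every run).
Overlapping hits (> 50 % reciprocal) are resolved greedily by score, ties
to the leftmost start and `+` strand, making the scan deterministic and
strand-symmetric.

## Blocks, filters, arms, names

Tandem blocks are maximal runs of units separated by at most `max_gap`
(default 600 bp ≈ one monomer plus slack; satellite arrays are
head-to-tail, so intra-array gaps are essentially zero and the precise
value is uncritical until it approaches the inter-block distance). The
"clean set" filter removes, in order: the first and last unit of every
block (array termini are often truncated or degenerate; a one-unit block
loses its unit, a two-unit block both), units whose genomic span is
≤ 500 bp (retention is strictly greater-than: a 501-bp unit stays, a
500-bp unit goes), and units containing `N`. The order matters only for
the tallies; the retained set is order-independent, which is tested.

Centromeres are located from centromeric satellite monomers (CentPv1/
CentPv2-style) with the package's own scanner — each repeat becomes a
single-sequence profile, hits at ≥ 80 % identity are clustered, clusters
closer than 100 kb merge, and the largest merged cluster per chromosome
(by summed hit length) wins. Units wholly before the interval are S,
wholly after are L, anything overlapping is C; without a detectable
centromere a chromosome falls back to a midpoint S/L split with a
warning. The 5′ end of each pseudomolecule is called the short arm: arm
identity is a karyotype fact that a sequence-only pipeline cannot know,
so the convention follows the pseudomolecule orientation. Names are
`<prefix><chrom><arm>k<#####>` with ordinals 10, 20, 30, … per
chromosome, 5′→3′, leaving room to interleave later annotations.

## Recombination screening

Mosaic monomers — left and right segments descending from different
lineages — distort phylogenies and are removed before tree building. For
a (child, parent A, parent B) triplet, the only informative columns are
those where the parents differ and the child matches one of them; at each
candidate breakpoint the 2×2 table (left/right × matches-A/matches-B) is
scored by chi-square with Yates continuity correction (small marginal
counts are routine near the scan edges, hence the correction and the
20-column margin), and the scan returns the argmax. The p-value of the
maximum is taken from the 1-df chi-square distribution and Bonferroni-
corrected over the number of triplets scored; calls are accepted at
corrected p ≤ 0.001.

Triplet selection is the one place the package departs from the plain
"two nearest plus two furthest neighbours" heuristic. Mosaics sharing
parents are each other's nearest neighbours, so a nearest-neighbour pool
fills up with fellow recombinants and the true parental lineages are
never tested; the screen then misses exactly the signal it exists to
find. Instead, units are grouped by average-linkage clustering of the
p-distance matrix cut at half the median pairwise distance, and each
child's candidate parents are the nearest member of each *foreign*
cluster of at least `min_cluster` units (two nearest plus two furthest
representatives, all pairs — at most six triplets per child, the same
budget). The cluster-size floor matters: tiny clusters are
disproportionately mosaics, and a triplet whose *parents* are mosaics
fakes a textbook breakpoint signal in a perfectly clean child. For the
same reason, significant calls are attributed greedily — the strongest
call removes its child, and weaker significant calls involving an
already-removed unit in any role are treated as echoes of that mosaic,
not as independent removals. With this selection and attribution,
recombination-free 50-unit families screen clean in 20/20 seeded
replicates while planted mid-monomer mosaics between ~15 %-divergent
lineages are recovered at ≥ 4/5, with no innocent units removed.

## Phylogeny

With thousands of near-identical monomers, progressive multiple alignment
is both slow and unstable; an effectively gap-averse alignment of
monomers is positional. The implied MSA therefore anchors every unit to
the profile's match positions (insertions relative to the profile are
discarded, deletions become gaps), giving a deterministic O(n) alignment
whose columns are comparable by construction. Units covering less than
half the profile are excluded with a warning.

Distances are Jukes–Cantor, $d = -\tfrac34\ln(1-\tfrac43 p)$, with $p$
computed under pairwise deletion (sites gapped in either row are skipped
for that pair, preserving signal for indel-bearing units) and saturated
proportions ($p \ge 0.75$) capped at $d = 5$ with a flag. Trees are
canonical neighbor joining — implemented in C++ with ties in the Q
criterion broken by the smallest index pair and negative branch estimates
clamped to zero — rather than an approximate-ML heuristic: NJ is exactly
specifiable, recovers additive matrices perfectly (the tests verify this
against an exhaustive least-squares search over all topologies up to
eight taxa), and the analysis surface is clade membership, not fine
topology. Bootstrap support resamples alignment columns (default 100
replicates, seeded), counting each bipartition of the midpoint-rooted
main tree across replicate trees; a majority-rule consensus is also
available.

A *major clade* is a supported bipartition read as a clade: an internal
node with support strictly above 0.75 (reading "support > 75 %"
strictly), at least `min_size` tips (default 2 % of units — major clades
are large, and the floor is configurable), and at most half the tips.
The half-tree cap is what makes the definition well-posed on an unrooted
backbone: the complement of a supported clade carries the same edge
support but spans the backbone, and midpoint rooting would otherwise
promote one arbitrary giant "clade". Candidates are accepted greedily by
decreasing size subject to disjointness, so clades are maximal; on
simulated eight-lineage families the eight lineages are recovered at
purity 1.

## Concordance metrics

The clade × location contingency table (locations are chromosome-arm
labels, with centromeric units aggregated per chromosome, e.g. `08C`)
supports three read-outs: *spreading* (clades present on ≥ 2 locations),
*local duplication* (clades with ≥ 80 % of units on one location), and
*centromere exchange* (clades containing both C and arm units, with the
co-occurring arms listed). The two thresholds quantify claims that are
otherwise qualitative; both are arguments, not constants. Note a clade
can count as both spread and locally duplicated — a dominant home arm
plus a scatter of transferred copies is in fact the common pattern.

## Assembly QC

Independent (e.g. BAC) contigs are placed by unique 31-mer anchor
chaining — 31-mers sampled every 7 bp that occur exactly once in contig
and genome, chained by consistent offset within a 2-kb band that absorbs
small indels; edit-free substrings are recovered to the base. Units are
then paired one-to-one greedily by descending identity (global alignment
identity; ties by position). Contig units with no local partner define
the gap spans the assembly is missing, and any such unit identical
(identity 1.0 by default) to a unit on another chromosome, or > 1 Mb
away on the same one, is flagged as a misassembly candidate — the
signature by which a handful of centromere-assigned units can be traced
back to a subtelomeric origin.

## The simulator and what the tests do (and do not) show

`simulate_genome()` plants what the analysis is meant to recover:
uniform-background chromosomes; a tandem centromeric satellite array; and
per-arm tandem blocks grown as birth chains (each new copy mutates a
random existing block member at rate μ), founded from arm-resident
lineages with interchromosomal transfer probability τ, mosaic probability
ρ (breakpoint uniform in the middle 60 %), and centromeric placement
probability κ — centromeric blocks are embedded between segments of the
satellite array, as real centromeric insertions sit inside the array
span. Default study conditions: 3 chromosomes × 2 Mb, 8 founder
lineages at 8 % divergence from the ancestral monomer (≈ 15–16 %
pairwise, matching the divergence scale between satellite clades),
blocks-per-arm Poisson with mean 6.5 and geometric block sizes with mean
8 truncated at 55 (giving the intended desk scale of roughly 40 blocks
and 300 units on 6 Mb), μ = 0.03, τ = 0.1, ρ = 0.02, κ = 0.05,
subtelomere span 300 kb, seed 42. Scenario tests vary one dial at a
time: τ = ρ = κ = 0 for arm confinement, κ = 0.2 when a planted
centromeric block must be present at desk scale, τ ∈ {0, 0.5} over 20
paired seeds for the transfer monotonicity.

What passing means: the scanner, filters, phylogeny and concordance
recover planted structure essentially perfectly under substitution-only
divergence at these rates. What it does not mean: real assemblies add
transposable-element background (false seed matches), higher-order repeat
structure, unequal crossing-over, assembly collapse inside long arrays,
and IUPAC ambiguity — the simulator models none of these, which is why
the QC module treats independently sequenced contigs, not simulations, as
the arbiter of assembly quality on real data. Mutations are substitutions
only by default so that implied-MSA columns stay crisp; gap handling is
exercised separately through deletion fixtures.

## Numerical and degenerate-input choices

Scores are bits throughout (any log base works; one must be fixed).
Coordinates are 0-based half-open internally, converted to 1-based
inclusive only at GFF3 serialisation — a single conversion point instead
of per-call arithmetic. Degenerate cases are defined, not accidental:
empty genomes scan to empty tibbles; a chromosome without centromere hits
falls back to the midpoint rule with a warning; triplets with fewer than
`2 × min_margin` informative columns are flagged no-calls, not errors;
zero-margin chi-square tables score 0; equal-distance NJ inputs resolve
deterministically via the smallest-index tie-break; `alpha = 0` removes
nothing. All randomness (simulation, bootstrap, screen subsampling) flows
from explicit seeds, and seeded code saves and restores the caller's RNG
state.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline on the
6-Mb default scenario (a few hundred units, 100 bootstrap replicates) and
smaller 0.8–1.8 Mb genomes for scanner/QC unit tests — sizes chosen so a
complete run takes minutes on a single core while leaving every rate
(recall, precision, error control) measurable. The same code scales to
pseudomolecule-sized inputs; the scanner and NJ kernels are compiled, and
stage costs grow linearly in genome size and quadratically (distances) to
cubically (NJ) in retained unit count.

## Known limitations

* The monomer orientation of a `-`-strand unit is reported relative to
  the profile, so a family whose seed alignment mixes orientations will
  scan inconsistently; orient the seed alignment first.
* Major-clade labels (A, B, …) are size-ordered, not stable across runs
  with different unit sets; compare clades by membership, not by letter.
* The recombination screen tests each child against cluster
  representatives only; recombination between close relatives within one
  cluster is invisible to it (and to distance-based detection generally).
* `place_contig()` assumes a single collinear placement; a contig
  spanning a true rearrangement breakpoint will be placed by its larger
  side and the remainder surfaces as missing units/gaps.
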