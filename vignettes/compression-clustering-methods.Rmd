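---
title: "Methods: compression distances, graph clustering, and the evolution simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compression distances, graph clustering, and the evolution simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ncdclust` clusters whole nucleotide sequences without alignment. Its
distance is a normalized compression distance (NCD) built on a
deliberately simple, fully reversible codec — a cyclic Burrows–Wheeler
transform followed by run-length encoding — and its clustering is a
multi-stage graph procedure over the resulting distance matrix. This
vignette explains each model, the tunables that matter, the numerical
choices, and what the package's synthetic benchmarks do and do not show.

```{r setup}
library(ncdclust)
```

## The codec and its octet cost

The transform sorts the `n` cyclic rotations of a string
lexicographically (by byte code) and reads the last character of each
rotation. No end-of-string sentinel is appended; reversibility instead
requires keeping the rank `s` of the original rotation among the sorted
rotations. Inversion is LF-mapping with stable ordering of equal
characters. For periodic strings all duplicated rotations are
interchangeable; we define `s` as the smallest sorted index holding the
original rotation, and inversion is insensitive to this choice.

The run-length serialization is `<rank><count><char><count><char>...`,
every count explicit in decimal — including counts of one. The *octet
length* (character count) of this text is the compression cost `C(x)`:

```{r}
rle_encode(bwt_forward("BANANA"))$serialized
compressed_length("BANANA")
compressed_length("BANANACANADA")
```

Two consequences of this dialect are worth stating plainly:

* A run of count `c` costs `nchar(c) + 1` octets, so genome-scale runs
  with counts ≥ 10 cost more than two octets. This is the cost model, not
  an approximation of an entropy coder.
* The concatenated text is not self-delimiting — the rank digits and the
  first count's digits merge — so `rle_decode()` operates on the
  structured runs and validates the `serialized` field for consistency.
  The text is a cost function and a debugging aid, not a wire format.

The rotation sort runs on a prefix-doubling ranking in compiled code
(`O(n log^2 n)`); a 2 Mb genome transforms in a few seconds, and the
naive rotation-sort oracle used in the tests confirms the ranking
exhaustively for all short words.

## The normalized compression distance

For sequences `x`, `y` and their concatenation `xy`, with
`Cx = compressed_length(x)` etc., the package computes

* `max` (default): `d(x, y) = (Cxy − min(Cx, Cy)) / max(Cx, Cy)` — the
  standard NCD normalization;
* `min`: the same numerator over `min(Cx, Cy)`.

Both dialects are exposed because the classic worked example
(`BANANA` vs `CANADA`, distance 0.57) is only reproduced by the `min`
denominator under this codec: the three costs are 7, 9 and 11 octets, so
`(11 − 7)/7 = 0.57` while the `max` form gives `4/9 = 0.44`. Which
normalization an upstream implementation used cannot be decided from the
printed value alone; neither is guessed to be canonical, and the choice
is a per-call parameter.

An ideal NCD is a metric. A run-length codec only approximates one, so
`ncd_matrix()` does not hide the deviations:

* **Symmetry.** `C(xy)` and `C(yx)` can differ by a few octets. The
  matrix is symmetrized by the arithmetic mean of both concatenation
  orders and the raw matrix is kept so `metric_report()` can quantify the
  asymmetry that was averaged away.
* **Identity.** `d(x, x)` is small but positive (the serialization of a
  doubled string is never shorter than the string's). The diagonal is
  recorded as computed; clustering consumes only off-diagonal entries.
* **Triangle inequality.** `metric_report()` scans all ordered triples
  exhaustively and reports the violation count and the largest excess
  rather than asserting zero.

## The clustering procedure

`mac_cluster()` = `forward_pass()` + `auto_correct()` over a labelled
distance matrix.

1. **Triangle filtering** (`sigma_filter`, default 2). All `C(n,3)`
   Heron areas are computed; a triangle is an outlier when its area
   exceeds `mean + sigma_filter × sd` (one-sided — small areas are
   benign, only large deformed triangles indicate forced groupings). An
   edge survives if it lies in at least one non-outlier triangle: this
   removes exactly the edges that only ever participate in deformed
   triangles. Triples violating the triangle inequality have their
   radicand clamped to area 0 and are flagged. The σ-rule is scale-free,
   which makes the whole pipeline invariant under rescaling of `D`.
2. **Mutual nearest-neighbour pruning** (`knn`, default 1). An edge is
   kept when each endpoint is among the other's `knn` nearest retained
   neighbours; additionally every node's single nearest retained edge is
   always kept, so no node is isolated merely because its nearest
   neighbour is popular.
3. **Local-minima partitioning.** Within each connected component, a
   node's closeness is its mean distance to the other members; local
   minima are nodes with no strictly-closer graph neighbour. Two or more
   minima indicate an internal boundary; nodes are assigned to their
   nearest minimum by shortest weighted path (graph Voronoi), and parts
   are re-examined with closeness recomputed until each has one minimum.
   On an exact plateau (all closenesses equal, as in toy matrices) only
   the lexicographically smallest node counts as a minimum: under a
   strict-only rule every node of a symmetric pair or blob would be a
   minimum and the component would shatter into singletons, which is the
   degenerate limit, not a boundary. A perfectly equilateral dumbbell is
   therefore *not* split — with no asymmetry there is no evidence for a
   boundary — while dumbbells whose blobs have distinct centres are.
4. **Singletons and final recall.** Parts of size ≥ 2 become clusters;
   isolated labels become singletons. The pipeline then re-runs exactly
   once on the singleton submatrix, promoting any new groups of size ≥ 2.
   One recall is a fixed design: the wording "re-cluster the rejected
   population" gives no loop count, and iterating to fixpoint would
   eventually merge arbitrary leftovers.
5. **Auto-correction** (`multiset_max`, default 3; `max_cycles`,
   default 5). A cluster's representatives are its medoids — every member
   whose distance sum is within `tie_tol` (default 1e-9, an absolute
   tolerance on sums of distances) of the minimum. A representative
   multiset larger than `multiset_max` marks a cluster grown beyond one
   coherent group; it is dissolved and its members reassigned to the
   nearest surviving representative multiset (distance to a multiset =
   minimum over its members), repeating to fixpoint or `max_cycles`.

Every ordering and tie in the pipeline breaks lexicographically by
label, and the matrix is put into canonical label order on entry, so the
output is deterministic and permutation-equivariant. There is no hidden
randomness anywhere in the clustering.

Human-in-the-loop curation of singletons (an interactive backward pass)
is exposed only implicitly: `auto_correct()` is the automated feedback
cycle, and callers can edit a `mac_clustering` object between passes if
they wish; the shipped pipeline is fully automated.

## The AL-pentamer statistic

The archetypal loop (AL) is a 22-base circular RNA proposed as a relic
of early peptide synthesis; its hairpin head fragments into ten
pentamers (`al_pentamers()`). For a sequence of length `n`, `O` counts
the windows (all `P = n − 4` start positions, overlaps included)
matching the set, and the score is `z = (O − P·p) / sqrt(P·p·(1 − p))`.

Two modes handle an inconsistency inherited from the statistic's
published form: the printed set has ten pentamers but the published
probability is 9/1024. `"published"` mode keeps both as printed, so
published values can be approached; `"consistent"` mode sets
`p = |set|/1024`, the exact per-window probability for a uniform
i.i.d. sequence, and is the mode used for calibration.

**The binomial null is overdispersed for this set.** The ten pentamers
are consecutive windows of one ring, so nine ordered pairs chain (the
4-mer suffix of one is the prefix of the next). The probability that two
adjacent windows both hit is then `4^-6 ≈ 2.4e-4`, far above
`p² ≈ 0.95e-4`, and occurrences arrive in clumps. Empirically (2000
uniform 10 kb sequences) the variance of `O` is about 1.55× the binomial
value and the empirical `sd(z) ≈ 1.25`, while a control set of ten
non-chained pentamers gives `sd(z) ≈ 0.97`. The mean of `z` is 0 as it
should be. Users comparing `z` values across sequences are unaffected
(the ranking is monotone in `O` at fixed `n`), but absolute σ-statements
made with this null overstate significance by roughly the same factor;
the package reports the statistic as defined and documents the
overdispersion rather than silently rescaling it.

The ring constant is shipped exactly as printed (23 characters,
DNA-normalized, carrying an anomalous duplicated `T`) and as the
22-mer with that character removed; AL-pair operations
(`enumerate_al_pairs()`, `al_pair_statistic()`) always take the ring
explicitly. Degenerate purine/pyrimidine matching uses the standard
families (R = A/G, Y = C/T) — note that some published descriptions swap
the two labels; the implementation follows the standard assignment.
Translation uses the standard genetic code table from `Biostrings` as
data.

## The evolution simulator

`simulate_phylogeny()` draws independent uniform ancestors and derives
each clade as conditionally independent descendants of one ancestor — a
star phylogeny per clade. Per descendant, each of the eleven operators
fires `Poisson(rate)` times and events apply in random order. The
operator definitions follow standard genome-rearrangement usage; three
deserve disambiguation because names alone do not fix them:
*inversion* replaces a segment by its reverse complement,
*symmetrization* by its plain mirror (reversal without complement), and
*palindromization* appends the segment's reverse complement after it.
*Crossing over* exchanges the descendant's suffix with its ancestor's at
a random point: recombining with siblings instead would create
sub-lineage families inside a clade — real biology, but structure the
star model does not declare, and it measurably fragments clades into
recombination families.

Default rates (per descendant of a 20 kb genome): substitutions at 1% of
genome length (200 events), two each of insertion / deletion /
translocation / transposition / inversion (segments uniform 50–500 bp),
one each of symmetrization / palindromization / circular permutation /
crossing over. These describe clearly diverged but recognizable clades —
roughly a few percent sequence divergence plus a handful of structural
events, the regime where alignment-free methods are typically applied.
Segment lengths are clamped to the current sequence length so late
events always fit; sequences eroded to a single base accept only point
events. Event counts are Poisson and segment lengths uniform because
they are the simplest defensible nulls; no claim of realism beyond that
is made (no GTR-style substitution process, no coalescent times, no
selection).

What the simulator does *not* emulate: base composition bias, repeat
families, mobile elements, horizontal transfer across clades, and
rate heterogeneity along the genome. Recovery results on these
simulations therefore show that the pipeline separates
compression-distinguishable clades; they do not certify performance on
real genomes, where within-genome repeat structure also feeds the
compressor.

## Problem sizes and numerical choices

The test suite exercises the codec exhaustively on all ACGT words up to
length 8 and on 1000 random strings up to length 200 over alphabets of
2–8 symbols; statistics are calibrated on 200 uniform sequences of
10 kb; and the end-to-end benchmark clusters 24 genomes of 20 kb
(3 clades × 8 descendants, seed 42), for which the package computes 576
concatenation transforms of ~40 kb in about two minutes on one core.
These sizes were chosen so that every claim is recomputed from scratch
at each run while the whole suite stays interactive.

Further numerical conventions, in one place: rotation sorting compares
byte codes, never locale collation; the triangle-area radicand is
clamped at zero and flagged when a triple violates the triangle
inequality; `Cxy < min(Cx, Cy)` would make the NCD negative and is
clamped at zero with a warning (never observed in practice);
representative ties use an absolute tolerance because distance sums are
O(1) quantities on NCD scales; and all randomness in the simulator
derives from a single integer seed, making FASTA outputs byte-identical
across runs.

## Known limitations

* The octet cost model penalizes long runs logarithmically; it is a
  counting convention, not an optimal code, and NCD values depend on it.
* NCD values between unrelated random genomes concentrate near 1, so
  between-clade distances carry little gradient; the clustering relies
  on within-clade contrast, not on meaningful deep branch lengths. The
  exported Newick trees resolve structure within and between clusters by
  average linkage, and their deep branch lengths should be read with the
  same caution.
* The binomial null of the pentamer statistic is overdispersed for
  chained pentamer sets (see above).
* Clustering is quadratic in the number of genomes (and each pair costs
  a transform of the concatenation); hundreds of genomes are practical,
  tens of thousands are not.
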