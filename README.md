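# ncdclust

Alignment-free comparison and unsupervised clustering of whole
nucleotide sequences, for people who want a phylogeny-shaped signal out
of complete genomes without choosing marker genes, aligning anything, or
training anything.

Building a tree from whole genomes usually means picking a handful of
conserved RNAs or proteins, aligning them, and fitting a substitution
model. `ncdclust` takes the information-theoretic shortcut: if two
genomes share evolutionary history, a compressor should compress their
concatenation better than unrelated genomes. The package implements

* a **reversible compression codec** — the cyclic Burrows–Wheeler
  transform (rotations sorted lexicographically, last column + rank of
  the original rotation) followed by run-length encoding; the character
  count ("octets") of the serialization is the compression cost *C(x)*;
* the **normalized compression distance**,
  *d(x, y) = (C(xy) − min(Cx, Cy)) / max(Cx, Cy)*, with an alternative
  min-denominator dialect, pairwise matrices, and diagnostics that
  measure (rather than assume) symmetry, zero diagonal, and the triangle
  inequality;
* a **multi-stage graph clustering** of the distance matrix: Heron
  triangle-area outlier filtering, mutual-nearest-neighbour pruning,
  local-minima Voronoi partitioning, singleton recall, and
  auto-correction of overgrown clusters via medoid multisets — ending in
  clusters, singletons, and a Newick tree;
* the **AL-pentamer enrichment statistic**: a z-score
  *(O − E)/σ* for occurrences of the ten archetypal-loop pentamers
  under a binomial null (*E = (n−4)·p*, *σ = sqrt((n−4)p(1−p))*), plus
  circular AL-pair amino-acid statistics;
* a **genome-evolution simulator** implementing the eleven classical
  operators (mutation, insertion, deletion, inversion, repetition,
  translocation, transposition, symmetrization, palindromization,
  circular permutation, crossing over) to produce labelled clades for
  end-to-end validation.

## Worked example: the codec and the distance

```r
library(ncdclust)

bwt_forward("BANANA")
#> Cyclic BWT: n = 6, rank = 3
#>   F = NNBAAA
rle_encode(bwt_forward("BANANA"))
#> RLE(BWT): 3 runs, 7 octets
#>   32N1B3A
```

The serialization is the rank (`3`) followed by `count + character` for
every run (`2N 1B 3A`) — 7 octets. The three costs of the classic word
pair are

```r
compressed_length("BANANA")        #> 7
compressed_length("CANADA")        #> 9
compressed_length("BANANACANADA")  #> 11
```

so the distance between `BANANA` and `CANADA` is
`(11 − 7)/9 = 0.44` under the standard normalization and
`(11 − 7)/7 = 0.57` under the min-denominator dialect:

```r
ncd_pair("BANANA", "CANADA")                     #> 0.4444444
ncd_pair("BANANA", "CANADA", dialect = "min")  #> 0.5714286
```

## Worked example: simulate, cluster, recover

```r
sim <- simulate_phylogeny(evo_config(n_ancestors = 2, clade_size = 3,
                                     genome_length = 2000, seed = 11))
D <- ncd_matrix(sim$sequences)
mac_cluster(D)
#> Clustering: 2 cluster(s), 0 singleton(s)
#>   [1] 3 members (rep: g005; mean radius 0.4118): g001 g003 g005
#>   [2] 3 members (rep: g006; mean radius 0.4716): g002 g004 g006
sim$truth
#>     id  clade
#> 1 g001 clade2
#> 2 g002 clade1
#> ...
```

The two recovered clusters are exactly the two simulated clades (ids are
shuffled so they carry no clade information; the truth table is the
referee). `clusters_to_newick(C, D)` renders the clustering as a Newick
tree, and `run_pipeline()` drives FASTA → distance matrix → clusters →
tree in one call, writing `D.phylip`, `clusters.json`, `tree.nwk` and a
reproducibility manifest.

The enrichment statistic, applied to the 22-base archetypal-loop ring
itself:

```r
al_proximity(al_ring(trimmed = TRUE))
#> AL-proximity: n = 22, O = 6, E = 0.1582, sigma = 0.3960, z = +14.752
```

six of its eighteen windows are AL-pentamers — about 15σ above what a
random 22-mer would show.

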