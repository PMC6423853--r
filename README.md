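# paracentric

Reconstructing the evolutionary history of paracentric chromosomal
inversions from marker-annotated genomes.

## The problem

Closely related *Drosophila* species often differ by large paracentric
inversions. Given chromosome-level assemblies for two or more taxa plus an
outgroup, the questions are: where are the inversion breakpoints, by what
mechanism did each inversion originate (clean "straight" double-strand
breaks, staggered breaks that leave inverted duplications on the flanks of
the derived arrangement, or ectopic recombination between inverted repeats,
which leaves repeats on the flanks of *both* arrangements), which
arrangement is ancestral, on which branch of the species tree did each
inversion arise, and do fixation rates differ between the sex chromosome
and the autosomes, or between lineages?

`paracentric` implements that entire analysis for genomes represented as
ordered, oriented gene markers over nucleotide sequence, together with a
genome-rearrangement simulator that provides ground truth for every stage:

* **Synteny** — ortholog anchors from shared marker ids are chained into
  signed synteny blocks; per-chromosome block orders become signed
  permutations.
* **Breakpoints** — the interval between contiguous blocks is the synteny
  breakpoint; its flanks (breakpoint ± flank into each block) are aligned
  locally against the other genome; a true inversion breakpoint splits the
  query into two strand-discordant hits with overhangs, reciprocally
  consistent whichever taxon is the query. Local alignment of one flank
  against the reverse complement of the other detects flanking inverted
  duplications, from which the origin mechanism is classified.
* **History** — a taxon shows the ancestral arrangement iff its
  breakpoint-flanking marker window is contiguous in the outgroup's gene
  order. Scrambled multi-block segments are resolved into an optimal
  reversal scenario with an exact sorting-signed-permutations-by-reversals
  distance (breakpoint graph: `n + 1 − cycles + hurdles + fortress`),
  cross-checked in tests against an exhaustive compiled BFS oracle.
  Inversions are placed on the species tree by single-origin parsimony
  (supporting fixed, polymorphic and extinct-ancestral tip states), and
  per-lineage fixation rates are compared with an exact conditional test
  (given `n = k1 + k2`, `k1 ~ Binomial(n, t1/(t1+t2))` under equal
  Poisson rates; two-sided p by tail doubling).
* **Genome statistics** — G-tests of feature counts against
  chromosome-length expectations (`G = 2 Σ O ln(O/E)`), windowed repeat
  densities with Monte-Carlo random-placement envelopes, density
  gradients, N50/L50, coverage, gene density and flow-cytometry genome
  sizing (`GS_target = GS_standard × fluorescence ratio`).

## A worked example

The template scenario simulates a five-chromosome (plus dot) karyotype at
1/100 scale and a twelve-inversion history on the
`((subobscura, madeirensis), guanche) + outgroup` tree — six inversions on
the sex chromosome A (four of them overlapping), three fixed autosomal
inversions, two polymorphic ones and one fixed on the guanche branch, with
staggered-break duplications of 689, 1007, 513 and 538 bp — then runs the
whole detection chain:

```r
library(paracentric)
cfg <- default_config(seed = 1, outdir = "paracentric_out")
res <- run_pipeline(cfg, stages = "all")
res$analysis
#> <inversion_analysis> subobscura vs guanche: 28 blocks (9 inverted), mean 0.042 Mb
#>   8 isolated inversion call(s); 1 complex region(s)
#>   region A [9018..98903]: 6 blocks, reversal distance 4
res$history$rates
#>              comparison k1   t1 rate1 k2   t2 rate2 ratio p_two_sided
#> 1        A_vs_autosomes  6 1.72   3.5  3 6.88  0.44     8 0.006132736
#> 2 continental_vs_island  9 1.72   5.2  1 2.64  0.38    14 0.002984946
```

All twelve simulated inversions are recovered: eight as isolated calls
(reciprocally consistent breakpoints, mechanisms classified from the
flanking-duplication evidence — the four staggered events recover their
duplication lengths to within a few bp — correct polarity, no gene
disruptions) and four as the optimal reversal scenario of the scrambled
proximal-A region. The A chromosome fixed 6 inversions in 1.72 Myr
(3.5 inversions/Myr) against 3 on four autosomes (0.44 inversions/Myr per
average autosome): an 8-fold "faster-A" contrast, two-sided exact
P = 0.006. `paracentric_out/` holds TSV tables (blocks, calls, branch
table, rates, report), each stamped with the config hash and seed so
reruns are byte-identical.

A thin command-line wrapper is installed as `exec/paracentric`
(`paracentric all --config cfg.yaml`).

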