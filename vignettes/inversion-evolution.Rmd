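---
title: "Reconstructing paracentric inversion histories from marker genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing paracentric inversion histories from marker genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`paracentric` analyses genome structural evolution in a small species
group — the motivating system is the *Drosophila subobscura* subgroup,
with five large acrocentric chromosomes (A, J, U, E, O) plus a dot, and a
`((subobscura, madeirensis), guanche)` tree with an outgroup — under three
modelling commitments:

1. **Genomes are ordered, oriented gene markers over sequence.** Orthology
   is by marker id, one copy per taxon (paralogy is rejected, not
   resolved). This replaces sequence-level anchor discovery with an exact
   id match, which is the right level of abstraction for validating the
   downstream logic: anchor *placement* noise can be simulated, anchor
   *identification* noise cannot change the combinatorics.
2. **Only paracentric inversions.** No translocations, transpositions,
   duplications beyond inversion footprints, or nucleotide evolution.
   Blocks mapping one reference chromosome onto two target chromosomes are
   an error, not a call.
3. **Single origin.** Each derived arrangement arose once; it can be lost
   only by replacement through nested derivatives (the `extinct_ancestral`
   tip state).

All coordinates are 0-based half-open internally; GFF3's 1-based closed
convention exists only inside the readers and writers.

# The simulator

The simulator is the source of ground truth for every claim the package
makes, so its event semantics are spelled out precisely.

**Straight breaks** reverse-complement `[left, right)`; contained markers
reverse order and flip strand; length is unchanged. Applying the same
event twice restores the genome exactly.

**Staggered breaks** cut at `left`/`left+offset_left` and
`right−offset_right`/`right`. Writing `A` and `B` for the two stagger
fragments and `M` for the interior, the derived sequence is
`prefix + A + rc(B) + rc(M) + rc(A) + B + suffix`. Each derived flank
thus carries an inverted duplicate of the opposite flank's fragment, and
the genome grows by `offset_left + offset_right`. The placement of the
duplicates (duplicate outside, inverted original inside) is a documented
convention of this simulator — the molecular data only constrain the
*presence* of inverted flanking duplications in the derived state, not
their exact cut geometry. Default simulated duplication lengths span
0.3–1.2 kb, bracketing the 513–1007 bp footprints the template scenario
uses.

**Ectopic recombination** requires a pre-placed inverted repeat pair
(`place_inverted_repeat_pair()`); the inversion spans from the start of
the forward copy to the end of the inverted copy. Because the segment
begins with the forward copy and ends with its reverse complement,
inverting it leaves the same repeat structure in place: both the ancestral
and the derived arrangement carry the pair on their flanks — exactly the
signature that separates this mechanism from staggered breaks.

`evolve_subgroup()` applies events branch by branch from root to tips,
keeping the ground-truth coordinates of earlier events current as later
events shift or reflect them. A polymorphic event yields two haplotype
genomes for its tip. Breakpoints are recorded as the full rearranged span
`[left, right + offsets)`; the *detectable* homology breaks of a staggered
event sit at the inner cuts, which is why recovery checks allow the
duplication span as the admissible junction window.

Repeat landscapes place per-class counts by inverse-CDF sampling on a 1 kb
grid with a uniform base, an exponential pericentromeric bump (decay scale
10% of the chromosome, centromere at coordinate 0) and a linear
telomere-ward gradient. With enrichment 1 and slope 0 the placement is
exactly uniform — the calibration tests depend on that exactness.

**What the simulator does not emulate:** nucleotide substitutions and
small indels, assembly gaps and errors, repeat-mediated misassembly,
incomplete marker conservation, and breakpoint reuse. Passing tests
therefore demonstrate the correctness of the detection logic under clean
data of realistic geometry, not robustness to annotation noise — on real
genomes the sequence-alignment stages (flank mapping, duplication
detection) would absorb that noise, and their thresholds exist for that
reason.

# Synteny and its parameters

Anchors sorted by reference position are chained greedily: a block extends
while the relative strand is constant, target positions move monotonically
in the strand's direction, and inter-anchor gaps stay within `max_gap` in
*both* genomes. Runs shorter than `min_anchors` are dropped — their
anchors are treated as micro-rearrangements and discarded, not merged —
and the survivors are re-chained to a fixed point, so collinear runs merge
across the hole when the gap constraint still holds.

Defaults: `min_anchors = 3`; `max_gap` of 1 Mb at full genome scale, and
1/20 of the longest chromosome when unset at the package's 1/100 working
scale. At that scale the template karyotype uses ~130–190 markers per
large chromosome (mean spacing ≈ 1.6 kb). The spacing matters: with mean
spacing s and exponential gap tails, the probability that a random
intergenic gap exceeds `max_gap` must be negligible or true blocks
fragment; `max_gap/s ≈ 9–10` achieves that while still rejecting genuine
long-range discontinuities.

Per-chromosome signed permutations number blocks by target order (ties by
target start) and sign them by orientation. The block decomposition then
splits into: in-place positive blocks (no rearrangement), isolated
in-place negative blocks (single inversions, analysed individually), and
minimal segments whose value set equals their position set (overlapping
inversion regions, analysed as reversal scenarios).

# Breakpoint isolation

A synteny breakpoint is the interval between contiguous blocks; abutting
blocks give a zero-length interval. For a terminal inverted block the
junction is only known to lie beyond the anchor hull, so the interval
honestly extends to the chromosome end until alignment refines it.

Flank mapping extracts the interval plus `flank_width` into each flanking
block and aligns it locally against the other genome on both strands
(match +1, mismatch −2, gap open 4, extend 1 — fixed in configuration for
reproducibility). After the best hit, the unexplained query remainder is
realigned to recover the second hit; a hit explaining ≥ 90% of a
segment's achievable score short-circuits the remaining strand/window
combinations. Overhangs are the unaligned query bases beyond each hit.
`flank_width` defaults to 5 kb at full scale and 1.5 kb at the working
scale — it must exceed the longest expected duplication plus alignment
slack, since both stagger fragments of a junction must fit inside one
flank window for the duplication alignment to recover the full length.

Two independent localizations of each junction are combined: the
reference query's own interior alignment ends (homology breaks in
reference coordinates), and the junction-facing target endpoints of the
reverse-direction hits (used only when that query's breakpoint interval
is narrower than `2×tol`, since side classification is meaningless for a
wide edge interval). The refined interval feeds the gene-disruption test,
which lists genes overlapping the interval (zero-length intervals tested
as a point, cuts at a gene boundary not counted as disruption).

Reciprocal consistency requires, in both directions, some hit endpoint
within `tol` (default 1 kb) of the other direction's breakpoint
*interval* — interval distance, not endpoint distance, because the
breakpoint is only localized to an intergenic gap.

Duplication detection aligns the left flank against the reverse
complement of the right flank; a local alignment of length
≥ `min_dup_len` (default 50 bp — duplications shorter than this are
considered below long-term detectability, hence
"straight **or nearly straight**" for the negative class) at identity
≥ 0.9 is a duplication call. The mechanism table is: derived-only →
staggered; both arrangements → ectopic recombination; neither → straight
or nearly straight; ancestral-only → undetermined (flagged — inconsistent
with either mechanism under known polarity).

# Polarity, scenarios, branches, rates

**Polarity.** A taxon shows the ancestral state iff its six-marker window
around the breakpoint (three per side, fewer → undetermined, never a
guess) occurs as one contiguous monotone run — forward or reversed, to
allow for opposite assembly orientation — in the outgroup's gene order. A
derived junction joins markers from two distant outgroup locations and
breaks contiguity. Both windows contiguous means no inversion at the
site; neither means undetermined.

**Reversal scenarios.** The distance of a signed permutation to the
positive identity is computed exactly on the breakpoint graph as
`n + 1 − cycles + hurdles + fortress`, with hurdles detected as unoriented
components whose positions are circularly consecutive, superhurdles by
deletion testing, and a fortress when all of an odd number of hurdles are
superhurdles. An independent exhaustive BFS over the full
`2^n n!`-state reversal graph (compiled, cached per `n ≤ 8`) serves as the
oracle in tests; the two routes agree exhaustively for `n ≤ 5` and on
hundreds of random permutations up to `n = 8`. One optimal scenario is
produced greedily by always taking the lexicographically smallest
`(start, end)` reversal that reduces the distance, which yields the
lexicographically smallest optimal scenario deterministically.

**Branches.** Tip states per inversion (`fixed`, `polymorphic`, `absent`,
`extinct_ancestral`) are mapped to the earliest branch consistent with a
single origin: the branch above the MRCA of all carrying tips; a
non-clade carrier pattern is an error naming the conflicting taxa.

**Rates.** Fixation rate is `k/t` (inversions/Myr), displayed to two
significant figures. Branch durations default to 1.72 Myr to the subgroup
ancestor and 0.92 Myr to the madeirensis split, used as fixed input
constants. The A-versus-autosome comparison divides the autosomal
exposure by the four large autosomes (the dot, which carries no
inversions, is excluded); this per-average-autosome convention is what
makes 3 fixed autosomal inversions over 4 × 1.72 Myr equal 0.44
inversions/Myr. The island rate divides one fixed island inversion by the
combined island branch time 1.72 + 0.92 = 2.64 Myr (0.38, displayed 0.4
at one decimal). Rate equality is tested exactly: conditional on
`n = k1 + k2`, `k1` is binomial with probability `t1/(t1+t2)` under equal
Poisson rates; the one-sided p is the upper tail at `k1`, and the
two-sided p doubles the smaller tail, capped at 1. The construction of a
"Poisson" comparison from two exposures is ambiguous in general; the tail
doubling convention is this package's documented choice, and with the
template counts (6 vs 3 over 1.72 vs 6.88 Myr) gives a two-sided
P = 0.0061.

# Distributional statistics

The G-test against chromosome-length expectations uses the natural-log
form `G = 2 Σ O_i ln(O_i/E_i)` with `E_i = ΣO · L_i/ΣL` (zero cells
contribute 0), chi-square on `k − 1` df. Windowed repeat densities count
midpoints in 500 kb windows at 250 kb steps at full scale (scaled
proportionally); midpoint membership is a convention. The 95% envelope
under random placement is Monte-Carlo (default `B = 1000`, seeded)
rather than analytic-binomial, to avoid assuming independence across
overlapping windows; its calibration (~5% of windows outside under a
uniform truth) is a tested property. N50 is the length of the scaffold at
which the cumulative sorted length first reaches half the total, L50 its
rank; both are permutation-invariant. Flow-cytometry sizing is the
standard genome size times the propidium-iodide fluorescence ratio.

# Numerical and design choices

* Alignment scoring fixed (match 1, mismatch −2, gap open 4, extend 1);
  local alignments via Biostrings' exact affine-gap implementation;
  compiled code only for the BFS oracle, where R is impractical.
* Duplication length is reported as the aligned length of the best local
  alignment; chance extension past the true boundary costs more than it
  gains at these scores, so recovered lengths sit within a few bp of
  truth.
* RNG: one top-level seed, split deterministically per
  chromosome/event/class (a multiply-add hash below 2^31); identical
  configuration and seed reproduce every output byte for byte, and every
  output table carries the configuration hash and seed.
* Degenerate inputs: empty marker lists, zero-count repeat classes,
  zero-length breakpoint intervals, empty block sets and `k = 0` counts
  all return well-defined empty or zero results; infeasible marker
  packing, out-of-bounds coordinates, in-marker breakpoints (unless
  disruption is simulated explicitly), missing repeat pairs and
  non-positive exposures are errors.
* Problem sizes: the template runs a ~1.27 Mb six-chromosome genome with
  ~750 markers and 12 inversions; validation suites use 100 simulations
  per mechanism, 20 random histories, 1000 null tables and the exhaustive
  permutation spaces up to `n = 8`. These sizes make the full analysis
  reproducible on a laptop in minutes while keeping every statistical
  check at conventional power.

# Known limitations

Paralogy, translocations and breakpoint reuse are out of scope; polarity
requires an outgroup with conserved local gene order; mechanism calls
inherit the detectability floor of `min_dup_len` (a staggered event with
shorter offsets is indistinguishable from straight breaks — by design the
class is named accordingly); and the per-average-autosome exposure
convention, while explicit, is one of several defensible normalizations
for chromosome-class rate comparisons.
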