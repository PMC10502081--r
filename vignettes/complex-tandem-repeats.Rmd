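---
title: "Determining complex tandem repeat structure: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining complex tandem repeat structure: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctrkit)
```

# The problem

A tandem repeat (TR) is a stretch of genome in which one or more short
units occur consecutively.  Complex TRs — whose optimal parse mixes two or
more distinct units, such as `(AAAG)i (AG)j (AGGG)k` — and minisatellites
(units longer than about 10 bp) are poorly served by classical detectors,
which tend to flatten them into a single-unit call.  Long accurate (HiFi
class, ~99.9% accuracy) reads span whole TR alleles, so the structure of a
complex TR can be determined read by read, allele by allele, and compared
across a population.  `ctrkit` implements that computational stack: unit
selection and decomposition, allele and representative clustering, flanking
SNV anchoring, per-locus divergence summaries, a read-coverage detection
model, and copy-number-aware phylogenies — together with seeded generators
that emulate every input, since real human read sets of this kind are
restricted-access.

# Unit selection and decomposition

## The parsimony penalty

For a TR sequence `S` and a unit set `U`, a decomposition `D` tiles `S`
into segments that are copies of units in `U` plus uncovered literal
segments.  The selection penalty is

```
sum over u in U of (|u| + occ(u))  +  (uncovered bases)
```

— fewer copies of fewer, shorter units, explaining more of the sequence,
are preferred (maximum parsimony over slippage events).  `occ(u)` counts
exact occurrences: a region generated by a *different* unit must stay
uncovered (expensive) until its own unit enters `U`.  If edited copies were
allowed to count, absorbing a foreign block as noisy copies of the first
unit would always beat paying `|u| + occ(u)` for the true second unit, and
compound repeats would collapse into single-unit calls — precisely the
failure complex TRs suffer in classical tools.

## The decomposition dynamic program

Minimising edit distance alone over parses is degenerate (an entirely
uncovered parse has distance zero), so [decompose_with_units()] minimises a
combined parsimony cost

```
(edit cost) + copy_cost * (#copies) + unc_cost * (#uncovered bases)
```

with unit costs `mismatch = indel = copy_cost = unc_cost = 1` by default;
cost ties break toward the parse with the smaller edit distance, then
toward uncovered segments and earlier units in the given order, making the
result deterministic.  The copy and uncovered terms are exactly the
variable part of the selection penalty, so a single parse supports the
penalty, the reported Levenshtein distance, and the per-TR mutation rate
(`distance / |S|`).  The program runs in `O(|S| * sum |u|)` time — linear
in the TR length for a fixed unit set.

## Candidate units and the greedy loop

[select_units()] starts from the empty set (penalty `|S|`) and repeatedly
adds the candidate unit with the lowest penalty, stopping when no candidate
lowers it; ties prefer the shorter unit, then the smaller canonical
rotation.  Candidate generation matters more than the loop:

* **Tandem adjacency.** Candidates are substrings of length 2 to
  `max_unit` (default 100) immediately followed by an identical copy.
* **Primitivity and phase.** Exact powers of shorter strings are dropped;
  rotation-equivalent candidates collapse to the phase with the longest
  tandem run (ties prefer the canonical rotation).  Inside a periodic block
  every rotation ties within one copy, and keeping an arbitrary phase can
  clip one base off a neighbouring block.
* **Explained-candidate pruning.** A candidate that a single rotation of a
  shorter kept candidate decomposes with at most 10% of its bases as edits
  or uncovered is discarded.  Taken literally, the penalty *prefers* a
  k-copy composite `u^k` over `u` for a long expansion
  (`km + n/(km) < m + n/m`), and one sequencing error makes such a
  composite technically primitive; pruning explained candidates keeps the
  pool at generating units.  One rotation at a time is essential — a
  mixed-rotation tiling would also "explain" genuine units that merely
  share rotated fragments.
* **Run-restricted scoring.** During selection, copies count only inside
  tandem runs of at least `max(3, 1 + ceiling(6/m))` adjacent exact copies
  (4 for dinucleotides, 3 otherwise).  True generating units are laid down
  in runs by slippage; scattered chance matches of a short unit inside
  error-broken stretches are not, and a single sequencing indel creates a
  genuine tandem *pair* — never a triple — of a one-edit variant unit.
  The final reported decomposition is unrestricted.

## Key units

Units are ranked by bases covered; the smallest prefix covering at least
90% of the TR length are its key units, and `k >= 2` marks the TR as
complex.  A locus is complex as soon as one representative is complex (an
alternative pooled-key-unit rule is available via
`classify_locus(method = "union")`).

# Allele and representative clustering

All pairwise distances are unit-cost edit distances from optimal *global*
alignments (a local alignment could match a short similar core between two
different alleles).  Clustering uses the neighbor-joining (NJ)
agglomeration over that matrix, with one validity criterion: a group is
valid when its diameter (largest pairwise distance) is at most 1% of its
longest member — two alleles are assumed to differ by more than 1%.  Group
representatives are centroids: the member minimising the summed distance to
the group (ties: shorter sequence, then lexicographic).

[population_representatives()] repeatedly extracts a *maximally valid* node
(a valid node none of whose ancestors is valid; largest leaf count first,
then smaller diameter, then smallest label), removes its leaves, refreshes
diameters, and stops when the remaining set is itself valid.
[call_alleles()] runs the same extraction on one individual's reads and
keeps the two largest groups as the (one or two) alleles; reads in any
further group are reported as unassigned rather than silently dropped.
The obvious alternative — splitting at the two children of the rooted NJ
root — turned out to be fragile: with two tight read clusters and many
zero-distance ties the Q criterion can legitimately attach the
opposite-cluster aggregate inside a cluster's star, so the final join does
not separate the haplotypes.  Maximally-valid extraction does not depend
on where the root lands.

The NJ merge order itself is deterministic: Q ties (always present at the
three-cluster stage, where Q is constant) break toward the closest pair,
then the earliest pair; negative branch-length estimates are clamped to
zero.

# Flanking SNVs

Within 1 kb flanks, substitutions are separated from sequencing error by
an exact binomial test: at depth `n` with per-read substitution probability
`p` (default 0.05%, half the HiFi error rate), a substitution seen `k`
times is significant when its count reaches
[significant_substitution_threshold()].  The default tail convention is the
smallest `k` with `P(X > k) < alpha`; the literal "k or more" reading
(smallest `k` with `P(X >= k) < alpha`) is one larger and available as
`tail = "geq"`.  The two conventions differ because the reference worked
value (k = 4 at n = 3000, p = 0.05%) is only reproduced by the first —
`P(X >= 4)` is 0.066, already above the 5% level — so the reproducing
convention is the default and the discrepancy is documented rather than
guessed away.  Indels are excluded by construction of the pileup (HiFi
indel errors dominate substitution errors).  Each TR's nearest significant
SNV strictly upstream and downstream defines its SNV pair; representatives
sharing an identical pair form a TR group whose length spread (longest
minus shortest member) measures how badly flanking SNVs impute the TR.

# The locus catalog

Detector outputs (two interval lists) are merged by closing overlaps and
then gaps of at most 10 bp, repeated to a fixed point, giving sorted
non-overlapping loci with all gaps above 10 bp; loci overlapping a mask
(e.g. segmental duplications, where anchoring is unreliable) by one or more
bases are removed.  Coordinates are 0-based half-open (BED) throughout.
Per-read TR segments are cut from reads whose alignment spans a locus
entirely, projecting locus boundaries through the record's CIGAR blocks;
records without blocks are rejected rather than interpolated.  Read bases
inserted relative to the reference attach to the segment holding the
reference base on their left.  Loci where fewer than half the possible
alleles are observed are flagged for exclusion
([allele_observation_ratio()]): at low coverage one allele of a
heterozygote is easily missed and such loci would bias population
summaries.

# Divergence summaries

Per locus, with each representative weighted by its allele count: the locus
length is the weighted median TR length; the IQR ratio is
`(Q3 - Q1) / median` (type-7 interpolated quantiles — the most common
convention; configurable); the locus mutation rate is the weighted mean of
the representatives' decomposition mutation rates; and a locus whose
longest representative exceeds the median by strictly more than 100 bp is
flagged as extended, the candidate class for disease-associated expansion.
(The extension baseline is the median locus length; "mode" appears once in
the source literature's summary but the operational definition is the
median, which is what is implemented.)

# Read-coverage detection model

An SV of length `d` at `[x, x+d)` is covered by a read of length `L`
exactly when a read starts within `[x+d-L, x]` — `L - d + 1` positions.
With `N` reads uniform on a genome of size `G` (coverage `c = LN/G`), the
miss probability is `(1 - N/G)^(L-d+1) ~ exp(-c (1 - (d-1)/L))`.
[prob_detect_sv()] evaluates the exponential form by default and the exact
power form when `G` is supplied; for one allele of a diploid genome the
coverage is halved.  The printed reference percentages round as if the
exponent used `1 - d/L`; the difference is below 0.01 percentage points
and the printed equation is implemented as stated.

# EDDC phylogenies

Within a TR locus, unit duplication and contraction outpace point
mutation, so tree distances must price whole-unit copy-number events.  The
edit distance with duplication and contraction (EDDC) allows substitutions,
insertions and deletions (+1 each) plus duplication (`u -> uu`) and
contraction (`uu -> u`) of any unit at `+m/2` for a unit of length `m` — a
whole-unit event is cheaper than the `m` single-base edits it replaces, and
longer units gain or lose copies more rarely.  (The six-parameter cost
model fixes match at 0; insertion and deletion both take +1.)

[eddc_distance()] is a dynamic program over sequence prefixes: alongside
the standard edit-distance transitions, per-unit chain states track blocks
routed through a pure unit copy — paired blocks (one each from `s` and
`t`), surplus blocks removed by contraction or created by duplication after
at least one pair, and pure runs seeded by one full insertion or deletion.
Every transition corresponds to a realisable edit script, so the value is
always achievable; block lengths are searched within ±2 of the unit length.
Optimality is not proved in general — the test suite pins the
implementation to an exhaustive A*-search over edit scripts on small
instances, and checks symmetry, the Levenshtein upper bound, and the
triangle inequality on random cases.  Inputs are capped (default 2000 bp)
because the constants are cubic-like; the cap raises an error instead of
silently truncating.  Pairwise EDDC matrices feed the same NJ machinery as
clustering, and leaves are labeled `(length, allele count, discrepancy
rate)`, the discrepancy rate being the representative's decomposition
mutation rate.  Newick output single-quotes the labels so the parentheses
and commas survive parsing.

# Synthetic data: what it emulates, and what it does not

Three seeded generators stand in for the restricted-access inputs; all are
byte-reproducible given a seed and restore the caller's RNG state.

* [sim_tr()] concatenates `(unit, copies)` blocks and applies i.i.d. point
  edits (substitution : insertion : deletion = 2 : 1 : 1), logging truth.
* [sim_reads()] draws Poisson read counts per haplotype (matching
  stochastic cell yield), each read spanning the whole TR segment, with
  i.i.d. errors split 20% substitutions / 80% indels (indels dominate HiFi
  error).
* [sim_population()] evolves `2 x n` haplotypes independently from a
  founder.  Slippage events (duplication or contraction of one unit copy,
  equally likely) occur only at sites carrying `min_pure_copies`
  consecutive exact copies — slippage requires local homology, so mutation
  load halts expansion.  `founder_mut_rate` applies substitutions once to
  the founder before divergence, modelling the *shared* mutation load of an
  old locus.  This matters for population summaries: private per-haplotype
  mutations would make every allele distinct and inflate representative
  counts, whereas the biology to emulate is that old, mutation-laden loci
  stopped slipping long ago — shared load suppresses slippage without
  manufacturing false diversity.

The generators deliberately do not model context-dependent error
(homopolymer length effects), partial-span reads, mapping/anchoring noise,
or recombination.  Passing tests therefore demonstrate correctness of the
algorithms under the stated error model, not performance on real
alignments.

## Study sizes used by the test suite

The package's property studies run at sizes chosen to exercise the claimed
behaviour while keeping the default check fast: planted-unit recovery uses
200 TRs of 2–4 units (2–10 bp, 10–200 copies per block) at 0.5% per-base
error; allele recovery uses 100 diploid loci at coverage 10 per haplotype
and 0.1% error; the divergence correlations use 300 loci (one 6-mer unit,
70 copies, 8 diploid individuals, 8 generations, slippage 0.04 per eligible
site with `min_pure_copies = 12`, ancestral load log-uniform on
`[1e-4, 0.08]`, private mutation `1e-6`); EDDC is checked exhaustively on
strings up to 10 bp and against the Levenshtein bound on 1000 random pairs.

# Numerical and degenerate-input choices

* Decomposition ties: lower edit distance, then uncovered over copies,
  then earlier unit; all parses are deterministic.
* A sequence with no tandem substring selects the empty unit set (penalty
  = length, fully uncovered); [key_units()] on a fully uncovered parse is
  an error, as is a zero-length input anywhere.
* Zero-length groups never arise in clustering; a single read yields one
  allele with one member.
* `iqr_ratio` requires a positive median; weighted medians expand
  multiplicities exactly rather than interpolating weights.
* Binomial thresholds use exact tail sums (`pbinom`), never a normal
  approximation; `p = 0` gives `k = 0` (any observation is significant).

# Limitations

* The greedy unit selection optimises a heuristic penalty; it is not
  guaranteed to find the global penalty optimum (that problem's
  tractability is open), and interleaved single copies of a unit
  (`... X u X u X ...` with runs below the selection threshold) will not
  recruit `u`.
* EDDC optimality is validated, not proved; for very dissimilar sequences
  the chain DP may overestimate slightly relative to an unconstrained
  script search.
* The 1% validity rule makes allele calling conservative for very short
  loci, where a single sequencing error can exceed the diameter budget;
  representatives of loci under ~200 bp should be read with that in mind.
* Clustering cost is quadratic in reads/alleles (distance matrix), cubic
  in the NJ step; population-scale runs should batch by locus.
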