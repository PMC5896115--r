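---
title: "Detecting transcriptomic structural variants with genome segment graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting transcriptomic structural variants with genome segment graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsvgraph)
```

## The model

A transcriptomic structural variant (TSV) is a pair of oriented genome
breakpoints joined in the sample's transcribed sequence but not in the
reference. `tsvgraph` infers TSVs by building a single consistent model of
the rearranged genome rather than by thresholding read clusters
individually.

**Concordance.** Each aligned read end is an ordered list of aligned parts
(split or spliced alignments contribute several). An end is
split-concordant when all parts share one chromosome and orientation and
their genome starts are strictly increasing in read order on the forward
strand (strictly decreasing on the reverse strand); a pair is concordant
when both ends are split-concordant, all parts lie on one chromosome, the
ends have opposite orientations, and the leftmost part of the forward end
starts at or before the leftmost part of the reverse end. Ends may overlap
completely, so the order condition is evaluated with "at or before" rather
than strictly before: short fragments sequenced from both sides are
otherwise penalized for overlapping. An important consequence of the
splice-tolerant definition: any same-chromosome, same-orientation,
forward-gap junction — whatever the gap — is *concordant*, indistinguishable
from an intron.

**Segments.** Breakpoints are (1) the start and end of every maximal
interval of strictly overlapping discordant-alignment parts and (2) the
starting point of every zero-coverage run, where coverage counts aligned
parts only (a spliced read covers its exonic parts, not the intron).
Book-ended discordant spans are not merged: the junction between two
abutting pileups is exactly the boundary we want to keep. Type-(1)
breakpoints put the two sides of a candidate junction into different
segments; type-(2) breakpoints disconnect genes from each other so graph
components stay small. Segments tile the genome; there is no minimum
segment length.

**The genome segment graph.** Vertices are segment ends (head $s_h$ =
lower coordinate, tail $s_t$). Every read pair is laid out as one fragment
traversal — first end's parts in read order, second end's parts in
reverse-complement layout — and each consecutive part pair contributes a
connection from the trailing end of the segment it leaves to the leading
end of the segment it enters (forward parts leave through the tail and
enter through the head; reverse parts the opposite). Connections inside one
segment are dropped; the rest aggregate into weighted edges.

**Arrangements and compatibility.** An arrangement is a permutation $\pi$
of segments plus an orientation function $f$ with $f(s_h) + f(s_t) = 1$;
the reference arrangement is the identity order with all heads first. An
edge $(u_i, v_j)$ is compatible with $(\pi, f)$ iff
$1 - f(v_j) = \mathbf{1}[\pi(v) < \pi(u)] = f(u_i)$. Each connected
component is solved for the arrangement maximizing total compatible edge
weight; edges discordant under the reference but compatible with the
optimum are the TSV calls.

**Chromosome-aware reference concordance.** Compatibility as defined above
is blind to chromosomes, and under the identity arrangement it would accept
a tail–head edge between two different chromosomes (the concatenated genome
would indeed spell that junction). The reference genome, however, spells
chromosomes separately, and such an edge's supporting read pairs are
discordant. The package therefore flags an edge reference-concordant only
when it is compatible with the identity arrangement *and* both segments
share a chromosome (`edge_reference_concordant()`); with this definition,
pair concordance and reference edge concordance are provably equivalent for
single-connection pairs, and the equivalence is asserted over randomized
pairs in the test suite. Compatibility with rearranged arrangements stays
chromosome-blind — that is precisely how inter-chromosomal junctions become
satisfiable and get called.

## The solver

The objective is the integer program: binary $x_e$ (edge compatible),
$y_u$ (segment head-first), $z_{uv}$ (u before v), maximizing
$\sum_e w(e) x_e$ subject to the side-specific linking inequalities and the
tournament/transitivity constraints on $z$. No MILP back-end is required:
because an edge's compatibility depends only on its endpoints' orientations
and relative order, the optimum is computed exactly by a dynamic program
that appends segments left-to-right over states (subset of placed segments
× orientation of each placed segment), $3^n$ states for an $n$-segment
component, scoring each edge when its later endpoint is placed. The DP is
implemented in C++ and verified against an independent exhaustive
enumeration of all $n!\,2^n$ arrangements (`brute_force_optimum()`, capped
at $n \le 8$) on hundreds of random components in the tests.

Numerical and tie-breaking choices:

* Ties are broken lexicographically: maximize satisfied weight, then the
  number of satisfied reference-concordant edges, then the number of
  forward segments (fewest inversions). This keeps solutions deterministic
  and avoids reporting rearrangements the evidence does not force. The
  reverse-complement arrangement always ties on the first two terms; the
  third usually resolves it.
* All-concordant components short-circuit to the identity arrangement,
  which is provably optimal for them.
* Components larger than `max_component` (default 14, the practical
  memory bound of the $3^n$ state space at roughly half a gigabyte) are
  skipped with a warning and keep the identity arrangement, so their
  discordant edges yield no calls. Under the defaults a gene contributes
  roughly one segment per exon, so components only approach the cap when
  many genes are fused into one cluster.
* DP backtracking compares floating-point objectives with a $10^{-9}$
  tolerance; edge weights are read counts times $\alpha$, so well within
  exact double range.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 1 | discordant edge weight multiplier; the assumed normal/tumor transcript ratio. 1 is appropriate for homogeneous samples; raise it when normal transcripts may outnumber tumor transcripts. |
| `theta` | 5 | minimum supporting read count per edge (strictly below is removed). Applied to the raw count, not the α-scaled weight, so the two parameters do not interact; the analogue of the read-support threshold of conventional SV callers, controlling the precision–sensitivity tradeoff. |
| `gamma` | 5 | maximum number of distinct segments a segment may touch through discordant edges; beyond it, all its discordant edges are dropped as low-mappability artifacts. Concordant backbone edges are kept so genes are not disconnected. |
| `max_component` | 14 | exact-solver size cap (see above). |
| `min_mapq` | 0 | optional mapping-quality filter at read-in; off by default. |

**Interleaving filter.** The qualitative idea — an interleaving pattern of
exons from two regions is more plausibly alignment error than a single
rearrangement — is formalized here as: group segments into maximal runs of
genome-consecutive segments linked by concordant edges (the expressed
backbone of a gene); for a pair of runs, if their discordant edges attach
at two or more distinct interior points of *both* runs, the two regions
would have to be spliced into each other's middles at multiple places at
once, and all discordant edges between the runs are removed. A genuine
single insertion attaches at one interior point of the host run (and at
the ends of the guest run) and survives.

**Breakpoint refinement.** For each side of a called edge, if at least
three supporting alignments share the junction-abutting coordinate (the
discordant alignment plus two others ending or starting at the same
position), that coordinate is reported; otherwise the segment boundary is.
Ties go to the higher count, then the smaller coordinate.

## The simulator and what it does (not) emulate

`simulate_dataset()` builds a small genome (default 4 × 50 kb, 20 genes of
3 exons ≈ 200–300 bp with 450–550 bp introns), plants SVs of five types,
and emulates alignment analytically: fragments (default 300 bp, reads
76 bp, 30× coverage) are sampled uniformly from the original genome's
spliced transcripts and pushed through the exact base-level coordinate map
onto the rearranged genome, which plays the alignment reference — the
role-swap that keeps the original annotation usable for expression.
Alignment parts shorter than 12 bp are dropped, mimicking an aligner's
minimum anchor. Ground truth is derived from the same maps: every pair of
transcript-adjacent bases whose images violate reference adjacency is a
truth junction (consecutive exonic bases for a mid-exon breakpoint, the
flanking exon endpoints for an intronic one). Under the role swap,
deletions make sample bases unmappable and novel insertions and tandem
duplications leave intron-like forward-gap junctions, so only inversions
and translocations produce observable truth junctions — the same reason the
method itself cannot distinguish small deletions from introns.

Geometry is chosen so that the assumptions of segment construction hold:
SVs are placed in distinct genes and inversion spans exceed twice the
fragment length, keeping the discordant pileups of different junctions
disjoint. Defaults mirror the evaluation conditions used throughout the
tests (30× coverage, noise-free, `theta = 3`, `alpha = 1`).

Deliberately not emulated: sequencing errors and quality values,
misalignment (noise pairs are uniform random rather than paralog-driven),
isoform mixtures and alternative splicing, expression-level variation
(uniform coverage per transcript), overlapping or nested SVs, and real
aligner behavior at junctions (clipping heuristics, multi-mapping).
Passing the recovery tests therefore demonstrates correctness of the
graph/optimization machinery under clean evidence, not robustness to
aligner artifacts on real data, where the filters (θ, γ, interleaving)
carry more of the burden.

```{r example}
sim <- simulate_dataset(seed = 7)
res <- detect_tsvs(sim$alignments, theta = 3)
res$calls
match_tsvs(res$calls, sim$truth)[c("tp", "fp", "fn")]
```

## Evaluation conventions

Predictions match truth when both breakpoints agree in chromosome and
side/orientation and lie within a 30-kb window (large because a true
genomic breakpoint may sit in an intron while RNA evidence appears at the
nearest expressed base); matching is greedy nearest-first and each truth
record is consumed once. With no predictions, precision is 1 by
convention. The partner-entropy statistic bins breakpoints (10 kb default),
and for each breakpoint occurring at least 3 times reports the Shannon
entropy (base 2 by default; the base is configurable since entropy
thresholds in the literature are unit-ambiguous) of its partner
distribution — 0 means a fixed partner.

## Degenerate inputs and edge cases

Empty alignment sets, chromosomes with no coverage, and all-concordant
graphs all yield empty call sets rather than errors; pairs with one
unmapped end are excluded at read-in; records beyond the declared
chromosome length raise an error (inconsistent header). Duplicate
breakpoints are deduplicated silently. Book-ended discordant intervals stay
separate. Components with a single segment are trivially identity.

## Limitations

* Same-chromosome forward-gap junctions (deletion-type fusions) are
  invisible in principle: they are concordant under splice-tolerant
  alignment.
* One consistent genome model is sought per component; conflicting
  subclonal rearrangements resolve to the dominant, compatible subset.
* Component size is capped by the exact solver; pathological hub
  components (which the γ and interleaving filters are designed to
  prevent) would be left unrearranged with a warning.
* Breakpoint coordinates are only as precise as read support allows;
  without three agreeing alignments the segment boundary is reported.
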