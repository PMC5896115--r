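# tsvgraph

Detection of **transcriptomic structural variants (TSVs)** — rearrangements
observable in transcribed sequence, including but not limited to fusion
genes — directly from paired-end RNA-seq alignments, with no reliance on
gene annotation. The package is aimed at researchers analyzing tumor or
other rearranged transcriptomes who want both fusion-gene and
non-fusion-gene breakpoints from standard RNA-seq BAMs.

## The method

RNA-seq read pairs aligned to a reference genome are classified as
*concordant* (consistent with the reference layout: one chromosome, proper
forward–reverse orientation and order; split parts may skip introns) or
*discordant*. The genome is partitioned into segments *s = (s_h, s_t)* using
two kinds of breakpoints: the boundaries of each interval of overlapping
discordant alignments, and the start of each zero-coverage run (so separate
genes fall into separate graph components).

A weighted, undirected **genome segment graph** *G = (V, E, w)* is built on
segment ends: every read pair contributes one edge per split and one mate
edge, connecting the segment ends that would make the pair concordant if
those ends were joined (a proper pair gives tail–head, a both-forward pair
tail–tail, both-reverse head–head, outward-facing head–tail). Multi-edges
collapse into one edge weighted by its supporting read count; discordant
edges are up-weighted by a coefficient α ≥ 1 to compensate for normal/tumor
transcript mixtures. Low-support edges (< θ reads), segments with more than
γ discordant neighbor segments, and interleaving edge ladders between two
exon runs are filtered as likely alignment artifacts.

Each connected component is then **rearranged**: the solver searches over
permutations π and orientation functions *f* (with *f(s_h) + f(s_t) = 1*)
for the arrangement maximizing the total weight of compatible edges, where
an edge (u_i, v_j) is compatible iff

    1 − f(v_j) = 1[π(v) < π(u)] = f(u_i),

i.e. it joins the trailing end of the earlier segment to the leading end of
the later one. Concordant and discordant evidence thereby compete in one
objective instead of a bare read-count threshold. Edges that are discordant
under the reference arrangement but compatible with the optimum are
reported as TSVs: pairs of oriented breakpoints, refined to exact
coordinates when three or more supporting alignments end at the same
position, written as BEDPE.

The optimization is solved exactly per component by a dynamic program over
(placed-set, orientation) states — provably equivalent to the integer
linear program formulation of the objective — with an independent
exhaustive oracle (`brute_force_optimum()`) used for verification.

The package also ships a **simulator** (`simulate_dataset()`) that plants
deletions, inversions, novel insertions, tandem duplications, and
reciprocal translocations into a small multi-chromosome genome, emulates
paired-end RNA-seq alignments analytically through the exact coordinate
maps (reads from the original transcriptome, aligned to the rearranged
genome used as the reference), derives the ground-truth TSV junctions, and
an **evaluation** module with the 30-kb window/orientation matching rule
and the breakpoint-partner entropy statistic.

## Worked example

```r
library(tsvgraph)

sim <- simulate_dataset(seed = 7)   # 200-kb genome, 20 genes, 6 planted SVs
sim$planted
#> <planted_genome> 6 SV(s): inversion, inversion, deletion, duplication, insertion, translocation

res <- detect_tsvs(sim$alignments, theta = 3)
res
#> <tsv_result> 6 TSV call(s) over 79 segments
#>    chrom1  pos1  side1 chrom2  pos2  side2 support component_id
#> 1:   chr1  1474   tail   chr3 11190   head      63            2
#> 2:   chr1  1958   head   chr3 10706   tail      78            4
#> 3:   chr2  7697   tail   chr2  8542   tail      66           11
#> 4:   chr2  8251   head   chr2  9028   head      67           11
#> 5:   chr4  7129   tail   chr4  7855   tail      73           32
#> 6:   chr4  7580   head   chr4  8374   head      81           32

match_tsvs(res$calls, sim$truth)[c("precision", "sensitivity")]
#> $precision   [1] 1
#> $sensitivity [1] 1
```

Each call is a pair of oriented breakpoints. `side = "tail"` (BEDPE strand
`+`) means the retained sequence lies upstream (left) of the breakpoint,
`"head"` (`-`) downstream. Calls 3–6 are the four junctions of the two
inversions (tail–tail and head–head pairs); calls 1–2 are the two
reciprocal junctions of the chr1/chr3 translocation; `support` is the
number of read alignments behind each junction. Deletions, novel
insertions, and tandem duplications leave intron-like (same-chromosome,
forward-gap) junction images that are concordant by construction, so they
neither appear in the truth set nor produce calls.

Running on a SAM/BAM file from the shell:

```sh
Rscript inst/cli/predict.R --bam aligned.bam --out calls.bedpe --theta 5
```

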