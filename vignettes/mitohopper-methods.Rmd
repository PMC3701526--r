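---
title: "Methods: models, parameters and design choices in mitohopper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in mitohopper}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitohopper)
```

mitohopper implements the quantitative core of comparative insect
mitogenomics: composition and strand-skew statistics, codon usage, circular
gene-order rearrangement analysis, cloverleaf tRNA classification,
control-region tandem-repeat (VNTR) detection, and intraspecific
haplotype/divergence analysis. This vignette documents the models behind each
module, the parameters that matter, the behaviour of the synthetic-data
generators, and the design decisions taken where the methodology was
genuinely open.

## Coordinates and the genome model

A genome is a circular DNA molecule represented as an upper-case string over
`{A,C,G,T,N}`. All coordinates are 1-based inclusive positions on the
majority (J) strand, the GenBank convention; a feature wrapping the
replication origin is encoded with `end < start` and has length
`L - start + 1 + end`. Minority-strand (N) genes are stored with J-strand
coordinates plus a strand flag, and `extract_feature_seq()` returns the
reverse complement so gene sequences always read 5'→3' on their own coding
strand. `N` is tolerated in sequences but excluded from all composition
denominators.

The canonical vocabulary is the 37-gene insect set — 13 PCGs, 22 tRNAs with
the leucine and serine isoacceptors distinguished (`trnL1`/CUN vs
`trnL2`/UUR; `trnS1`/AGN vs `trnS2`/UCN), two rRNAs — plus `CR` for the
control region. Aliases common in GenBank records (`COI`, `ND4L`, `16S`,
`D-loop`, `tRNA-Ser(UCN)`, ...) are normalized on input; tandem duplicates of
a gene keep one name and are distinguished by `copy_index`.

## Composition, skew and codon usage

AT-skew and GC-skew are `(A−T)/(A+T)` and `(G−C)/(G+C)`. Whole-genome values
are computed on the J strand, per-gene values on the coding strand. A zero
denominator yields `NA` rather than an error, since single-base or two-base
sequences legitimately arise in unit tests and edge cases.

Codon usage fixes the genetic code to the invertebrate mitochondrial code
(NCBI translation table 5), under which AGA and AGG encode serine, TGA
tryptophan and ATA methionine; only TAA and TAG terminate, so there are 62
sense codons. Codons are read in frame from position 1; a trailing partial
codon — the incomplete stop (`T` or `TA`) completed to UAA by
polyadenylation — is excluded from counts, and full stop codons are tallied
separately from the sense-codon total. RSCU is `count × k / family total`
for a synonymous family of size `k`, so every family with nonzero usage
averages to exactly 1 and absent codons score 0.

## Gene orders and rearrangements

A gene order is a signed circular permutation; sign encodes strand. Two
orders are compared through their adjacency sets, where the signed adjacency
`x→y` is identified with `−y→−x` (reading the circle from the other strand).
The breakpoint distance is the number of adjacencies of one order absent
from the other; it is symmetric and invariant under rotation and under
simultaneous reflection-with-sign-flip, but it is not a metric on signed
circular orders, so no triangle inequality is asserted anywhere.
`diff_blocks()` decomposes an order into maximal runs whose internal
adjacencies are shared (the decomposition starts immediately after the first
breakpoint, making blocks leftmost-longest and never straddling a
breakpoint) and calls a gene *displaced* when both of its flanking
adjacencies are broken — a single-gene translocation therefore shows up as
exactly one displaced gene.

The package ships three reference orders (`inst/extdata/gene_orders.txt`):
the putative ancestral insect order, the shared planthopper order (trnC–trnW
swapped; the nad4L–cob stretch reordered to nad6–trnP–trnT), and a prior
small-brown-planthopper annotation in which trnH sits between nad4L and nad6
rather than between nad5 and nad4. The full published figures are not
reproduced verbatim in text form anywhere, so these files are
reconstructions from the stated differences; every order-level claim the
package tests (breakpoints confined to the two rearranged neighbourhoods,
trnH the sole displaced gene between the two annotations) holds on them.
They are data, not code: users can supply their own order files in the same
one-line-per-genome format. Duplicated genes are collapsed to their first
occurrence before comparison because adjacency analysis is ill-defined on
multisets; the duplication itself is reported separately. The control region
is excluded from orders by default (it is not a gene), with a flag to
include it.

## Cloverleaf folding

tRNA genes are validated by a deterministic, layout-constrained stem search,
not by free-energy minimization: the anticodon arm is anchored first (at a
supplied anticodon, or the best-scoring candidate), then stem lengths in the
acceptor, D and T arms are maximized subject to the cloverleaf layout.
Pairing is Watson–Crick plus G:U wobble (wobble can be disabled). The layout
grammar is: acceptor stem (target 7 bp, minimum 5), spacer 1–3 nt, D arm
(stem target 3, minimum 2; loop 3–14 nt), spacer 0–2 nt, anticodon arm (stem
target 5, minimum 4; loop exactly 7 nt with the anticodon at its centre),
variable region 0–30 nt, T arm (stem target 4, minimum 2; loop 3–12 nt), the
3' acceptor strand and an optional 1-nt discriminator. A stem must pair at
every position; an arm that cannot pair at its minimum stem length is
reported `loop_only`, which is exactly the configuration of the DHU arm in
insect trnS1. Classification is `canonical` (all arms full),
`dhu_loop_only`, `t_loop_only`, or `degenerate`.

The search is exhaustive over the layout bounds and fully deterministic:
ties are broken by total paired bases, then longer acceptor stem, then
smaller variable region, then leftmost anchor, then the remaining layout
variables. The test suite checks the implementation against an independent
brute-force enumeration of every layout tuple on sequences up to 64 nt.
"Weak" stems (the published observation of a marginal T arm in one trnH) are
not given a threshold; the structure object exposes stem lengths and pair
counts and leaves that judgement to the user.

## Tandem-repeat (VNTR) detection

The detector compares the sequence with itself at every candidate period
`p` (default 10–50 bp): windows of length `p` in which the sequence matches
itself `p` positions away at identity ≥ `min_identity` (default 0.8) seed
candidate arrays; runs of such windows are merged, bridging at most one
strongly divergent copy. The tiling phase is then refined — the window chain
can begin a few bases into the flank, which would rotate every copy — by
choosing the phase that maximizes the number of perfect copies (a mis-phased
tiling smears a divergent copy across two tiles and loses a perfect copy),
with ties preferring the later start so that a coincidentally matching flank
base is never absorbed. Boundaries are finally extended copy-by-copy:
adjacent full copies at ≥ `min_identity + 0.1` are accreted outright, and a
divergent copy (≥ 0.6) is bridged only when the copy beyond it also matches.
The consensus is the per-column majority; a copy is *complete* iff its
identity is ≥ `min_identity` and its length ≥ 0.8 periods; a truncated final
copy is reported when at least 0.4 periods of the consensus prefix match at
≥ 0.9. Arrays need ≥ `min_copies` (default 3) copies; overlapping calls at
different periods are resolved longest-span-first with ties to the smaller
period, and an array whose consensus is itself made of near-identical
sub-tiles is re-called at the primitive period (the tiles are compared
pairwise: a majority consensus over two tiles would split their differences
and overstate identity).

Defaults were chosen once so that 21-bp units in tens of copies are
comfortably detected while A+T-rich random sequence is not; on 5-kb uniform
random sequence the detector reports no array with three complete copies
across 20 seeds. One identifiability caveat is inherent: if a flank base
happens to extend the array's periodicity, the maximal periodic region
genuinely starts one base earlier, so planted-array starts are recovered up
to that ambiguity while period, copy number and span length are exact.

## Haplotypes, networks and divergence

Variable sites are positions with ≥ 2 distinct unambiguous alleles.
Haplotypes are equivalence classes of signatures over the variable sites,
numbered by descending count with ties by first occurrence. The network is a
*minimum spanning network*: Kruskal's algorithm over Hamming distances with
all within-weight-class ties retained, so every edge that belongs to any
minimum spanning tree is kept and reticulations among equally parsimonious
connections survive. Median-vector inference (inferring unobserved
intermediate haplotypes) is deliberately out of scope; the simple topologies
of single-species surveys do not require it.

Mutation effects are classified inside a *fragment map* — named segments
with coding flags and frame offsets partitioning the sequenced fragment.
The codon number of a site is `floor((site − coding start)/3) + 1`; the
reference and alternate codons are translated under table 5 and reported in
`M93L` style. Nucleotide diversity is the mean pairwise p-distance with
ambiguous positions excluded pair by pair. Two-genome divergence compares
equal-length shared genes position-wise, excluding length-variant genes with
an explicit reason rather than silently aligning them; users supply
pre-aligned sequences (and `indel_report()`) for the length-variant cases.

## The synthetic-data generators

The generators define the study conditions under which the package is
validated; they are deterministic functions of their spec (including its
seed).

`make_mitogenome()` realizes a signed gene order exactly on a circle.
Defaults describe a planthopper-like genome: the Delphacidae order with the
control region between rrnS and trnI, target composition A 0.42 / T 0.35 /
G 0.094 / C 0.136 (A+T = 0.77), 2-bp intergenic spacers, incomplete stops in
cox1/cox3/atp6/nad5, ATA initiation in nad3 and atp6, and a 1-bp atp8/atp6
overlap (7 bp in the SBPH flavour, realized through fixed junction sequences
that keep the upstream stop and downstream start codons intact). PCG bodies
are sampled codon-wise from the 62 sense codons with probabilities
proportional to the target base composition, so no in-frame stops occur;
tRNAs are built by `make_trna_seq()`; the BPH flavour triplicates trnC. The
control region carries a guarded 23-bp poly-T run, a spacer, and the repeat
array: 55 copies of `GGAAAAAATGTCACGTTTTTC` with copy 2 degenerate
(~0.71 identity) in the BPH flavour; 35 copies of the rotated unit
`CACGATTTTTGGAAAAAATGT` with copies 3 and 14 degenerate and copy 35
truncated to 12 bp in the SBPH flavour. After assembly, composition is
repaired by rewriting only free positions (rRNAs, spacers, control-region
flanks) with the exact base multiset that brings the genome to target.

One compositional limit is structural: with both strands' genes sampled from
a single coding-strand composition, half the J strand reads as the
complement of coding sequence, so the J-strand G fraction cannot reach
0.094 exactly. The repair therefore preserves A+T and G+C contents exactly
(A+T is within ±0.01 of target well below 10 kb already) and absorbs the
overshoot within the G/C pair; the realized J-strand GC-skew is negative but
smaller in magnitude than in real planthopper genomes, where strand-specific
mutation pressure does the work. Published skew values are consequently
always computed from published base counts, never from generated genomes.

`make_population()` plants a 642-bp fragment survey: a 482-bp nad5 portion
(coding frame from position 1), the complete 62-bp trnH, 2 intergenic
nucleotides and a 96-bp nad4 portion; 309 individuals in 16 haplotypes with
counts 178/93/18 for the three major ones and the remaining 20 spread over 7
doubletons and 6 singletons — a realistic post-sweep frequency spectrum —
across 16 variable sites (15 in nad5, 1 intergenic), including the two major
nonsynonymous changes at positions 277 (M93L) and 391 (D131N).
`mutate_genome()` plants exact per-gene substitution counts and indel events
and returns the implied alignment, so detection can be compared with planted
truth.

What the generators do *not* emulate: real mutational strand asymmetry (see
above), secondary structure in rRNAs, sequencing error, heteroplasmy, and
recombination. Passing round-trip tests therefore demonstrates that the
detectors recover planted structure exactly under clean conditions, not that
they are robust to artefacts of real assemblies; the published-count
computations in the acceptance script are the contact points with real data.

## Numerical and implementation choices

Problem sizes throughout the tests are the study's own: ~16.5–17.5 kb
genomes, 55/35-copy repeat arrays, 309-individual surveys, 62-codon tables.
The folding oracle runs on sequences ≤ 64 nt where exhaustive enumeration is
exact; breakpoint distances are checked against an adjacency-scanning oracle
on signed circular permutations of up to 6 labels; codon tables, Pearson
correlations, pairwise diversity and MST weights are each checked against
independent brute-force implementations (the MST against `ape::mst`).
Degenerate inputs — empty sequences, zero denominators, single haplotypes,
zero-copy repeat specs, all-identical alignments — return well-defined empty
or `NA` results rather than errors wherever a downstream computation can
meaningfully continue, and errors with named offenders otherwise.
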