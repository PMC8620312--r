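---
title: "Marker k-mer barcoding: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker k-mer barcoding: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kbarcode)
```

## The model

`kbarcode` treats a genome as a set of words. With word length $k$
(default 18) and a reference collection $\mathcal{G}$, the barcode of a
target genome $g$ at specificity level $\ell$ is

$$B_\ell(g) \;=\; K(g) \setminus \bigcup_{s \in E_\ell(g)} K(s),$$

where $K(\cdot)$ is the k-mer set of a sequence and the exclusion set
$E_\ell(g)$ contains all plasmid sequences, all host-genome sequences,
and the chromosomes of every genome whose taxonomy label differs from
$g$'s at rank $\ell$; at strain level $E$ is every genome except $g$
itself. Because the exclusion sets are nested in $\ell$, the barcodes
are nested too ($B_{strain} \subseteq B_{species} \subseteq
B_{genus}$), a property the test suite asserts on randomized
collections against a brute-force window-enumeration oracle.

At $k = 18$ a random 18-mer has $4^{18} \approx 6.9\times10^{10}$
possible values, so chance collisions between unrelated genomes are
rare and a surviving word is a nearly unambiguous signature. Shorter
words inflate the exclusion sets; longer words make barcodes fragile
to sequencing errors. $k$ is exposed (`kmer_params()`) but 18 is the
default the rest of the defaults are calibrated around.

Two genomes are compared through the Sørensen (Dice) distance on their
barcodes, $D = 1 - 2|A\cap B|/(|A|+|B|) \in [0,1]$, and a set of
genomes through the neighbor-joining tree of the pairwise matrix.
Metagenome abundance of (relatives of) a barcoded genome is the
percentage of reads carrying at least one marker, rescaled by barcode
size:

$$\mathrm{normalized} = \frac{100\cdot \mathrm{reads\_hit}}{\mathrm{reads\_total}}\cdot\frac{C}{\mathrm{markers}_n}.$$

Counting reads rather than k-mer occurrences avoids multiple-counting
of long unique tracts while keeping the measure quantitative; a read
can hit several genomes and then counts once for each (there is no
unique-assignment or EM reallocation step).

## Strand handling

Genome databases record one strand; shotgun reads come from either.
The package therefore defaults to *canonical* k-mers — each word is
identified with its reverse complement and stored as the
lexicographically smaller of the two — which makes barcode
construction and read scanning strand-agnostic. A literal single-strand
mode (`canonical = FALSE`) is provided for compatibility with
single-strand matching pipelines; both modes are covered by tests,
including the invariance of canonical results under
reverse-complementing every input.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k` | 18 | word length, in bases |
| `canonical` | `TRUE` | identify a k-mer with its reverse complement |
| `min_len` | 20 b | shortest read retained by `scan_reads()` |
| `C` (species) | $10^6$ | normalization constant per million markers |
| `C` (strain) | $3.7\times10^4$ | normalization constant; the rounded mean size (36,794) of the retained strain-specific sets in the bundled catalog |
| `threshold` | 0.2 | relative-change band for trajectory classification |
| `alpha` | 0.05 | significance level for volcano tables (raw p by default) |
| `eps` | half the smallest nonzero abundance | pseudocount for log2 fold changes |

The read-length cutoff exists because a read shorter than `min_len`
(which must be at least $k$) carries too few windows to be
informative; dropped reads are excluded from the denominator, so the
reported percentage refers to reads that could in principle have
matched. Whether one normalizes per reads-before or reads-after
filtering is a genuine convention choice; this package fixes the
denominator to reads passing the length filter and records both
`reads_total` and `n_short` so the other convention is recomputable.

Degenerate bases (N and other IUPAC codes) invalidate only the windows
that overlap them, not the whole record; a `strict` mode that rejects
such records outright is available in `extract_kmers()`.

## Numerical and algorithmic choices

**Neighbor joining.** The implementation is the classic
Saitou–Nei agglomeration: minimize $Q(i,j) = (r-2)d(i,j) - R_i - R_j$,
join, assign branch lengths $l_i = d_{ij}/2 + (R_i - R_j)/(2(r-2))$,
update distances by $(d_{ik}+d_{jk}-d_{ij})/2$. Two details are
unspecified by the algorithm and fixed here for reproducibility: ties
in $Q$ are broken by the lexicographically smallest pair of node
labels, and negative branch lengths (possible on non-additive input)
are clamped to zero with the clamped total reported in a message.
Branch lengths are carried at full double precision internally
(17 significant digits in the intermediate Newick representation), so
on additive matrices the output path-length matrix reproduces the
input to well below $10^{-9}$; the tests assert exact topology
recovery (Robinson–Foulds 0) and that bound on 50 random additive
matrices up to 12 taxa, plus agreement with an independent
implementation (`ape::nj`). Only neighbor joining is provided: on
barcode distance matrices the tree is empirically robust to the choice
of distance-based builder, so a second builder would add surface
without information.

**Mann–Whitney U.** The U statistic uses midranks, so
$U_x + U_y = n_x n_y$ holds under ties. For group sizes up to 10 the
p-value is exact, by enumerating all $\binom{n_x+n_y}{n_x}$
assignments of the pooled values (correct under ties); larger groups
use the normal approximation with tie correction and continuity
correction. The two-sided p is $\min(1,\, 2\min(P(U\le u), P(U\ge
u)))$. Tests verify the exact path against a full-permutation oracle
for all group sizes up to 6 and the approximate path against
`stats::wilcox.test`. Sidedness defaults to two-sided; the paired
contrast in `volcano_table()` is an unpaired Mann–Whitney on the two
time-point groups (the compared groups are the two sets of samples), a
deliberate choice with `paired_signed_rank()` exposed as the paired
alternative. No multiple-testing correction is applied by default
(volcano significance is a raw 0.05 line); Benjamini–Hochberg is a
flag.

**Fold changes.** $\log_2((\mathrm{after}+\epsilon)/(\mathrm{before}+\epsilon))$
with $\epsilon$ defaulting to half the smallest nonzero abundance in
the dataset — large enough to keep zeros finite, small enough not to
shrink genuine ratios. Swapping the contrast negates the fold change
and preserves p, which the tests assert.

**Trajectory classification.** With baseline $v_1$, post-perturbation
$v_2$ and final $v_3$, the response is *decrease* / *no-change* /
*increase* according to whether $v_2$ leaves the $\pm 20\%$ band
around $v_1$, and the outcome is *recovery* / *overshoot* /
*further-decline* by the same band applied to $v_3$. A zero baseline
makes any nonzero later value an increase/overshoot. Subjects missing
a time point are flagged incomplete and excluded from scenario counts
rather than imputed.

**Empty barcodes.** Two identical genomes in a collection leave each
other no strain-specific markers. This is a legitimate outcome, not an
error: `build_barcode()` returns a size-0 barcode with a warning,
downstream profiling skips such genomes with a warning, and dropping
them is therefore always an explicit, visible step (the bundled
catalog shows the same pattern: 16 of 47 strain-specific sets were
dropped as too small, two of them empty).

**Order invariance and streaming.** Barcode subtraction is performed
incrementally, one exclusion genome at a time, so the peak working set
is a single genome's k-mer set; correctness is defined by the
order-invariance property (any permutation of exclusion genomes gives
byte-identical barcodes), which the tests check directly.

**Determinism.** All simulation functions take explicit integer seeds
and restore the caller's RNG state; identical configurations produce
byte-identical FASTA/FASTQ/barcode/tree/TSV artifacts, asserted
end-to-end in the tests.

## What the synthetic data does and does not emulate

`simulate_pangenome()` builds each strain as three contigs: a core
shared by all strains, an accessory block shared by the strain's
phylogroup, and a strain-private segment. Emitting segments as
separate contigs means the private segment's windows are exactly the
strain-specific markers (no junction k-mers), which gives the tests a
closed-form expected barcode size ($L_u - k + 1$). Sequences are
i.i.d. uniform over A/C/G/T: there is no GC bias, no repeat structure,
no horizontal transfer, no rearrangement. `simulate_metagenome()`
draws reads uniformly within contigs with uniform strand choice and
substitution-only errors (no indels, matching the exact-match
profiling contract), and constant placeholder qualities.

Passing tests on this model demonstrates *algorithmic* correctness —
set operations, distances, tree reconstruction, counting and
normalization arithmetic — under known ground truth. It does not
demonstrate robustness to the things real data add: repeat-induced
k-mer sharing between unrelated genomes, coverage and GC bias,
indel-containing reads, contamination, or incompleteness of the
reference collection. Those affect how many markers survive exclusion
and how often reads hit by chance, not the correctness of the
bookkeeping, and are the reason profiled abundances should be read as
*relative* signals of presence, not absolute cell counts.

## Problem sizes used in the packaged checks

The randomized suites run at sizes chosen to exercise every code path
while keeping the whole suite comfortably interactive: barcode-oracle
equivalence on 100 random collections of up to 8 genomes and 2 kb
total sequence at $k \le 5$ (small k makes collisions — the
interesting case — frequent); neighbor joining on 50 additive matrices
up to 12 taxa; profiler recovery on 8 strains of ~28 kb each with
planted proportions spanning a 20-fold range and 50,000 error-free
100 b reads, where the Spearman correlation between planted and
recovered abundance is required to reach 0.9 and in practice is 1.0.

## Known limitations

- The reference collection must fit the analysis: markers are only as
  specific as the collection is complete, and adding genomes can only
  shrink barcodes.
- Species-level barcodes of related strains overlap; profiling many of
  them at once double-counts shared signal unless
  `clear_cross_links()` is applied (exposed as a flag in strain mode).
- Quality trimming is out of scope: the profiler applies only the
  length cutoff and degenerate-window skipping, and expects reads to
  have been quality-controlled upstream.
- No bootstrap support values or rooting beyond what `ape` offers on
  the returned `phylo` object; no tree rendering.
- Exact Mann–Whitney enumeration is capped at group sizes of 10;
  beyond that the tie-corrected normal approximation is used.
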