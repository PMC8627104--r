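---
title: "Iterative Hi-C scaffolding with mutual N-best-neighbor graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative Hi-C scaffolding with mutual N-best-neighbor graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

A draft genome assembly arrives as contigs: gapless sequences far shorter
than chromosomes. Hi-C proximity-ligation reads carry long-range linkage
information, because two loci close in the nucleus are overwhelmingly
likely to lie on the same chromosome, and the contact frequency between
intra-chromosomal loci decays with their genomic distance. hicscaf exploits
these two properties to order and orient contigs into chromosome-scale
scaffolds without requiring the chromosome number as input.

The procedure, per iteration:

1. **Contact matrix.** Each current sequence of length $l_i$ is split into
   three equal parts (`parts = 3`; optionally two halves). The first and
   last parts — the *head* and *tail* ends — act as graph vertices, so that a
   join between two sequences also encodes their relative orientation; the
   middle third is ignored because contacts landing there carry no reliable
   end information and promote misjoins. A read pair contributes one count
   to the end pair its two 5′ coordinates fall in, provided it passes the
   filters below.
2. **Normalization.** Raw counts are length-biased, so the count $c_{ix,jy}$
   between ends of sequences $i$ and $j$ is normalized as
   $nc = c_{ix,jy} / (l_i/3 + l_j/3)$ (*summation* mode, the default) or
   $nc = c_{ix,jy} / ((l_i/3)(l_j/3))$ (*multiplication* mode). End pairs
   with raw count below `w` are discarded first, so that very short
   sequences cannot attain spuriously large normalized contacts. Per end,
   the `nbest` partners with the highest $nc$ are its N-best neighbors.
3. **Scaffolding graph.** An edge exists between two ends iff each is among
   the other's N-best neighbors. Pruning then enforces degree one: every
   vertex nominates its incident edge of *strictly unique* maximum weight
   (a tie nominates nothing and discards all edges at that vertex), and an
   edge survives only as the nominee of both endpoints. After adding the
   implicit head–tail edge inside every sequence, each component is a simple
   path or cycle and is read out as an ordered, oriented scaffold.
4. **Iteration.** The scaffolds become the sequences of the next round;
   alignment coordinates are lifted from contigs to scaffold coordinates
   through the SAT document, always from the original alignments. Repeating
   (default three rounds) exploits links that only become mutual-best once
   intervening joins are made.
5. **Misjoin breaking.** After the last round, pairs mapping to the same
   contig or to adjacent members of one scaffold add one unit of *physical
   spanning coverage* to every base between their 5′ positions. A join is
   broken when its maximum coverage is below `break_percent`% (default 30)
   of the maximum of **each** of its two neighboring contigs. Requiring
   both neighbors makes the rule robust: a dip caused by a short or
   missing sequence fails against only one side and is kept, and the
   criterion compares a join only to its local neighborhood, so it is
   unaffected by total scaffold length.

## Pair filters

A pair is counted only if both mates are primary alignments, mapped, free
of soft/hard clipping, with mapping quality at least `q` (default 10), and
not duplicates. A duplicate is a record pair flagged as such upstream *or*
an orientation-normalized tuple (target, 5′ position, strand) seen before —
so the filter works whether or not an upstream deduplication ran. The 5′
coordinate is the leftmost reference base for forward-strand alignments and
the rightmost for reverse-strand ones; it is used for part assignment,
duplicate keys, and spanning coverage. Input must be name-collated (mates
adjacent, as produced by an unsorted or name-sorted mapper stream);
position-sorted input is rejected rather than buffered unboundedly.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `q` | 10 | minimum mapping quality per mate |
| `w` | 5 | minimum raw contacts for an end pair to be ranked; must exceed sporadic noise links (a handful of stray pairs) on small inputs |
| `nbest` | 3 | neighbors retained per end; 1 reproduces strict mutual-best linking, 3 tolerates non-reciprocal best neighbors |
| `parts` | 3 | split granularity; 2 uses halves and leaves no ignored middle |
| `norm` | summation | length normalization; summation empirically yields fewer misjoins than multiplication |
| `iterations` | 3 | scaffolding rounds; more rounds lengthen scaffolds and rely on the break stage for accuracy |
| `break_percent` | 30 | misjoin threshold p, percent, compared strictly |
| `gap_len` | 200 | bp of N between members; Hi-C cannot estimate gap sizes, so a fixed conventional value is used |

## The SAT document

Scaffolding state persists in a GFA-derived tab-separated text format:
`S` records carry contigs (id, length, optional sequence), `L` records
weighted oriented joins (`wt:f:` tag holds the normalized contact), `P`
records scaffold paths (id, length, comma-separated oriented members),
`A` records named assembly sets of paths, and `C` names the current set.
This dialect is normative for this package: field order is as above,
unknown tags are preserved opaquely, record order on output is fixed
(S, L, P sorted by id, A, C) so files are diffable, and a `C` record naming
a set with no `A` record denotes the empty set. Coordinates are 0-based
half-open internally; AGP v2.1 output (gap lines: type U, gap type
`scaffold`, linkage `yes`, evidence `proximity_ligation`) and SAM input are
1-based.

Choices where the format description left room: the `A` record's fields are
`A <set-name> <comma-separated path ids>` and `C <set-name>`, which may
diverge from files written by other SAT implementations; scaffold ids are
`u` followed by a 9-digit zero-padded counter.

## Numerical and algorithmic choices

* Part boundaries use `floor(length/parts)`; normalization denominators use
  real division.
* Ties in N-best ranking are broken by larger raw count, then lexicographic
  partner id — determinism across runs is a design goal, and the whole
  pipeline is free of randomness.
* Pruning compares weights with exact floating-point equality; ties arise
  in practice from equal integer counts between equal-length sequences.
* Cycles (which the degree-one invariant permits) are broken at the
  lexicographically smallest member, starting from its head vertex and
  dropping the edge into that head. Acyclic paths are emitted with the
  lexicographically smaller terminal contig first.
* A read is assigned to an end by its 5′ coordinate alone, even when the
  alignment straddles a part boundary.
* The join region for misjoin detection is the gap interval plus one
  flanking base on each side (for zero-length gaps, the two boundary
  bases), so a junction is a well-defined closed interval under the
  closed-span coverage accumulation. Pairs with identical 5′ coordinates
  still count one base of span.
* Coverage uses difference arrays, so profiles over megabase scaffolds stay
  cheap.

## What the simulator emulates — and what it does not

`simulate_genome()` and `simulate_hic_pairs()` produce the package's test
bed: random nucleotide chromosomes cut at sorted random breakpoints into
contigs (half emitted reverse-complemented, truth recorded), and read pairs
whose intra-chromosomal separation follows
$P(s) \propto (s + s_0)^{-\alpha}$ truncated at the chromosome length
(defaults $\alpha = 1$, $s_0 = 1$ kb — the standard contact-decay shape),
with a 5% inter-chromosomal fraction and injected clipped, duplicated and
MAPQ-0 records to exercise every filter. Alignments are emitted directly,
so tests do not depend on an external mapper.

The default minimum contig length is half the equal-split size
(`chrom_len / contigs_per_chrom / 2`). This is deliberate: the three-part
split requires a contig's end third to carry contact signal comparable to
its neighbors'. A short contig between two long ones loses the mutual-best
ranking to the skip edge across it by a geometric (depth-independent)
margin and is relocated out of the chain — the method's known failure mode
on real assemblies with highly skewed contig lengths, reproduced and
asserted as such in the test suite. Keeping the recovery fixture inside the
model's regime is what makes exact reconstruction a meaningful property to
test; it also means passing tests say nothing about inputs dominated by
very short contigs, sequencing error, repeat-induced mapping ambiguity, or
restriction-site bias, none of which are modeled.

Reference problem sizes exercised by the suite: the recovery experiment
uses 3 chromosomes × 2 Mb, 10 contigs each and 200,000 pairs; the chimera
experiment chains 5 × 1 Mb chromosome paths and expects exactly the 4
boundary joins broken; oracle-equivalence checks run 100 random instances
per operation at up to 20 contigs / 10 kb scaffolds.

## Known limitations

* Misassemblies *within* a contig are invisible: breaking operates on
  joins only.
* The iteration count is user-specified; there is no automatic stopping
  rule, and too few rounds leave short scaffolds.
* Gap sizes are a convention, not an estimate.
* Short contigs flanked by long ones may be skipped (see above); the break
  stage does not reinsert them.

## A worked example

```{r, eval = FALSE}
library(hicscaf)
wx <- worked_example()              # transcribed 11-contig fixture
g  <- build_scaffold_graph(wx$neighbors)   # 9 mutual edges
pg <- prune_scaffold_graph(g)              # 6 survive
paths <- extract_scaffold_paths(pg)        # 6 paths: 3 singletons,
                                           # one cyclic triple, 3+2 chains
doc <- compose_scaffolds(sat_from_lengths(wx$lengths), paths)
write_sat(compact_sat(doc), "example.sat") # 11 S, 5 L, 6 P records
```
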