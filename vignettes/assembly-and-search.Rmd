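---
title: "Unitig assembly, contig simplification and k-mer search: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unitig assembly, contig simplification and k-mer search: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unitigr)
```

This vignette explains the models and procedures behind `unitigr`, the
assumptions they rest on, the tunable parameters, and the design choices
made where the design was genuinely open.

## The de Bruijn graph and its adjacency

All counting, assembly and indexing operate on *canonical* k-mers: the
numerically smaller (under 2-bit packing, A<C<G<T) of a k-mer and its
reverse complement. This collapses the two strands of a molecule into one
representation. `k` is capped at 31 so codes fit 64-bit integers, and odd
by default so no k-mer is its own reverse complement (even `k` needs an
explicit override). The conventional A<C<G<T order matches most k-mer
tooling.

K-mers seen only once in an accession are discarded before graph
construction (`min_count = 2`). This is the coarsest possible error
filter: at coverage c and per-base error rate e, an erroneous k-mer
recurs only when two reads err identically, so singletons are
overwhelmingly artifacts, while genuine k-mers at c ≥ 5 are essentially
never singletons.

The graph is *bidirected*: each canonical k-mer is a node with two ends,
and an edge is an exact (k−1)-base overlap between oriented nodes.
Adjacency is **edge-centric**: an overlap only counts as an edge when its
junction (k+1)-mer was actually observed in the reads. The alternative
(node-centric: every textual overlap is an edge) manufactures edges
between k-mers that never co-occurred in any read — at small k this
riddles even a clean genome with spurious branches. The (k+1)-mer count
table, which the abundance heuristic needs anyway, doubles as the edge
support set. `build_compacted_graph(edges = NULL)` still offers
node-centric compaction for set-only inputs.

Unitigs are the maximal non-branching paths of this graph. Every solid
k-mer lands in exactly one unitig, exactly once; output order (length
descending, then sequence) and stored strand (lexicographically smaller)
are fixed so assemblies are byte-reproducible. Windows containing
ambiguous bases (N) are skipped rather than rejected, since real archive
reads contain them.

## Abundance quantization

Per-k-mer abundance is approximated from (k+1)-mer counts: the counts of
all distinct canonical (k+1)-mers containing the k-mer (as prefix or
suffix, either strand) are summed and divided by two. For a k-mer
internal to every read that covers it, each read contributes two
(k+1)-mers and the division cancels exactly. Two biases remain: read-end
k-mers are undercounted by half per end occurrence, and a k-mer is only
supported by reads that contain it entirely, a factor of (L−k)/L at read
length L. Tests that check abundance against nominal coverage therefore
use reads long relative to k.

Abundances pass through an 8-bit codec before averaging, mirroring
byte-per-k-mer storage during construction. The codec is a hybrid ladder:
code 0 is reserved for zero, codes 1–64 store counts exactly (exactness
at low counts matters because solidity decisions and low-coverage
abundances live there), and the remaining 191 codes form a geometric
ladder from 64 to a hard ceiling of 50,000 with ratio
(50000/64)^(1/191) ≈ 1.035. The worst-case round-trip relative error is
about 2% — comfortably inside the 5% design bound, which is enforced as
worst-case (the stricter reading) by an exhaustive sweep over 1..50,000.
Counts at or above 50,000 saturate. Half-integer abundances (an odd
(k+1)-mer count sum) round half-up before encoding.

## Simplification into contigs

Three conservative heuristics are alternated until fixpoint (at most
`max_rounds = 10` rounds), each expressed as an edit to the solid k-mer
set or to a junction blacklist followed by full recompaction — one code
path, no orientation surgery on unitig records:

* **Tip clipping** removes dead-end spurs of length ≤ 2.5·k whose
  junction offers a competing branch with strictly higher mean abundance.
  The competing-branch condition (rather than comparing against the
  through path itself) is what protects genuine linear-genome ends: a
  terminal unitig at ~30x next to a through path at ~30x is not a tip,
  while an error spur at ~2x next to a genuine continuation is. Isolated
  unitigs are never clipped.
* **Bubble popping** finds pairs of single-unitig parallel branches
  sharing both oriented endpoints (the shape a SNP or small indel leaves
  after compaction), with branch length difference ≤ 3 nt, and removes
  the minor branch when its mean abundance is ≤ 0.5× the major's.
  Balanced bubbles — genuine heterozygosity — are kept; ties break by
  canonical sequence for determinism.
* **Weak-link removal** cuts a junction when its flanking mean abundances
  differ by more than 10× and at least one side has an alternative link
  at the involved end. The redundancy condition keeps well-supported
  paths connected (their flanks have similar abundance); requiring it on
  the *lower* side only would make an erroneous spur's attachment — the
  typical chimeric junction — uncuttable, since the spur itself has
  degree one. Branches stranded by a cut fall to the tip clipper or the
  emission filter. A cut is recorded as a blacklisted canonical
  (k+1)-mer: a bidirected edge is uniquely identified by its junction
  word, so the blacklist survives recompaction.

All thresholds (`tip_len_max = 2.5k`, `bubble_len_tol = 3`,
`bubble_abund_ratio = 0.5`, `weak_link_ratio = 0.1`) are deliberately
conservative and exposed in `simplify_params()`. Superbubbles and
scaffolding are out of scope; nested double-bubbles resolve through the
weak-link + tip interplay.

**Circularity.** A contig assembled from a circular molecule closes on
itself: its terminal link re-enters its own start with consistent
orientation, and its sequence ends with its own first k−1 bases. Such
contigs are emitted untrimmed (length = genome + k − 1) with a circular
flag; `trim_terminal_repeat()` is a separate explicit step that finds the
largest prefix/suffix repeat r ≥ r_min (default 30, i.e. k−1 at k = 31)
and drops the last r bases, restoring the true genome length. A circular
candidate whose terminal 31 bp window is more than half covered by
tandem repeats of period ≤ 5 and run length ≥ 8 is flagged as a
low-complexity artifact — a simple repeat can fake the prefix/suffix
signature without any circular molecule.

**Emission.** The default rule discards a contig only when it is
simultaneously non-circular, shorter than `min_len` (150 bp) and an
isolated graph node — short isolated linear fragments are more likely
artifacts than biology, while an isolated circular contig (a small
plasmid) is kept at any length. A strict mode keeps only contigs longer
than `min_len` that are connected to at least one other contig; both
formulations exist in the literature on assembly reporting, so both are
implemented, with the permissive one as default. The length comparisons
are strict ("shorter than", "longer than"), so a 150 bp contig survives
the default rule and fails the strict one.

## The per-accession search index

Each accession's unitig k-mers are indexed in a Bloom filter over
*s-mers* with s = k − z (default z = 3, so 28-mers at k = 31). A query
k-mer is declared present iff all z+1 = 4 of its constituent canonical
s-mers are positive — the Findere composition. Because the four tests
are (hash-)independent, setting the per-s-mer false-positive rate to
target^(1/(z+1)) ≈ 8.4% makes the composed per-k-mer rate meet the
0.005% target at a fraction of the memory a direct 0.005% filter would
need. Two false-positive sources remain and are accepted: the composed
Bloom collisions, and "construction" false positives — absent k-mers
whose four s-mers all genuinely occur in different contexts; for random
queries against random content both are captured by the empirical
measurement the acceptance script performs. Present k-mers can never
answer negative.

Filters use the textbook optimal sizing (m = −n·ln p/ln²2,
h = ln 2·m/n, h ≥ 1) per accession, with double hashing from two fixed
64-bit seeds, so index bytes are a pure function of the inserted set.
One filter per accession keeps the design desk-scale — no partitioned
color matrices; per-accession metadata travels in a manifest and is
attached to query results. Queries are capped at 1,000 nt by default
(overridable), and the hit threshold — the fraction of query k-mer
windows found — has no default: it is the user's sensitivity/specificity
dial. Matching-sequence extraction is exact (canonical k-mer set
intersection), independent of the filters.

The index container is a small versioned binary file (magic bytes,
format version, serialized payload); saving and loading round-trips
bitsets, parameters, seeds and manifest losslessly.

## Synthetic data: what it emulates and what it does not

`simulate_genome()` draws i.i.d. bases at a chosen GC content;
`simulate_reads()` places fixed-length fragments uniformly (wrapping for
circular genomes; overhanging and truncated at linear ends so terminal
bases see the same expected coverage as the interior) and applies
i.i.d. substitution errors. Everything is a pure function of its seed;
the caller's RNG state is saved and restored. The optional
unique-k-mer rejection sampling yields genomes whose assembly must be a
single unitig, the cleanest possible oracle for recovery tests.

This emulates coverage, strandedness, sequencing error and circularity —
the features the assembler and index are built around. It does **not**
emulate repeats longer than k (real genomes break into multiple unitigs
at repeats), indels or platform-specific error profiles, coverage bias,
or paired-end structure. Passing tests therefore demonstrate
correctness of the graph algorithms and probabilistic data structures
under their stated models, not assembly quality on real biological data.

## Numerical and testing choices

Problem sizes in the test suite are chosen to exercise every code path
in seconds to a few minutes: oracle-equivalence runs 200 seeded
instances of 200–800 bp genomes at k ∈ {11, 15, 21} against an
independent pure-R brute-force assembler; genome recovery runs twenty
5 kb simulations at 30× coverage and 0.5% error; the false-positive
measurement indexes a 100 kb accession (~10⁵ distinct 31-mers) and
probes two million random absent 31-mers. The recovery criterion
(≥ 18/20 exact) tolerates the rare run where two identical errors create
a structure the conservative heuristics refuse to resolve.

Degenerate inputs are defined, not exceptional: empty read sets and
reads shorter than k give empty graphs; an empty accession gives a
filter that answers false to everything; empty record sets give valid
empty files and all-zero statistics. Ambiguity (N) skips windows.
Abundance ties in bubble popping keep both branches; the weak-link ratio
is a strict inequality, so a boundary-exact junction is retained.

## Known limitations

* Exact in-memory counting only: inputs are bounded by RAM, by design.
* Simple two-path bubbles only; superbubbles and repeat resolution are
  out of scope, as are scaffolding and paired-end evidence.
* The abundance estimator's (L−k)/L support bias is not corrected.
* The circular-contig breakpoint is wherever compaction started, not
  shifted to an intergenic position (that would require gene prediction).
* One Bloom filter per accession scales to thousands, not millions, of
  accessions.
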