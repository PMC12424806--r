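# unitigr

Desk-scale de Bruijn graph assembly and k-mer search across sequencing
accessions, in R with C++ kernels.

Public sequencing archives hold millions of small read sets ("accessions").
Two questions dominate their reuse: *what sequence content does each
accession hold* (assembly) and *which accessions contain a sequence I care
about* (search). `unitigr` implements a compact, fully testable version of
the modern answer to both, for datasets that fit on a desk:

1. **Unitigs.** Reads are decomposed into canonical k-mers (k = 31 by
   default; the canonical form collapses the two strands). K-mers seen only
   once in an accession are discarded as likely sequencing errors; the
   survivors form a bidirected de Bruijn graph whose edges are the
   (k+1)-mers observed in the reads. Unitigs are the maximal non-branching
   paths of this graph — a near-lossless representation of read content in
   which every k-mer occurs exactly once.
2. **Abundances.** Each k-mer's abundance is approximated from (k+1)-mer
   counts (sum over containing (k+1)-mers, divided by two) and stored
   through an 8-bit codec: counts 1–64 exact, then a geometric ladder up to
   a saturation ceiling of 50,000, with worst-case round-trip relative
   error ≈ 2% (bounded by 5%). Unitigs carry the mean of their quantized
   k-mer abundances.
3. **Contigs.** SPAdes-style simplification — tip clipping, bubble popping
   (SNPs collapse to the major allele), weak-link removal — turns unitigs
   into consensus contigs. Circular contigs are recognized by their
   self-closing terminal link and trimmed of the duplicated (k−1)-mer;
   low-complexity terminal repeats are flagged as artifacts. Non-circular
   contigs shorter than 150 bp that are isolated graph nodes are discarded.
4. **Search.** Each accession's unitig k-mer content goes into a Bloom
   filter over s-mers (s = k − z, z = 3) sized so that the Findere
   composition — a k-mer is positive iff all z+1 constituent s-mers are —
   meets a 0.005% per-k-mer false-positive target. A query sequence
   (≤ 1 kb by default) returns, per accession, the fraction of its k-mer
   windows found; exact matching-sequence extraction recovers the unitigs
   sharing k-mers with the query.

Output formats follow field conventions: FASTA with BCALM2-style
`LN:i:`/`km:f:`/`L:±:id:±` headers, GFA 1.0 graphs, TSV stats (N50, total
length, longest).

## Worked example

```r
library(unitigr)

genome <- simulate_genome(5000, seed = 1, unique_kmers_k = 21)
reads  <- simulate_reads(genome, coverage = 30, read_length = 100,
                         error_rate = 0.005, seed = 2)
g <- assemble_unitigs(reads, k = 21)
nrow(g$unitigs)
#> [1] 42                      # errors fragment the raw graph
contigs <- emit_contigs(simplify(g))
nrow(contigs); contigs$length
#> [1] 1
#> [1] 5000                    # one contig, the genome exactly
contigs$seq == genome || contigs$seq == revcomp(genome)
#> [1] TRUE

idx <- build_search_index(list(sample1 = g$unitigs$seq))
query_index(idx, substr(genome, 1001, 1500), threshold = 0.5)
#>   accession_id fraction n_found n_total
#> 1      sample1        1     470     470
```

The printed `fraction` is the share of the query's 470 k-mer windows found
in the accession's filter — 1.0 because the query is a genuine subsequence.

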