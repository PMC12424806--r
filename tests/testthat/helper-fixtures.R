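# shared fixture builders; everything is generated in code, seeded

# genome + error-free reads + assembled graph in one go
clean_assembly <- function(len = 2000, k = 21, seed = 5, coverage = 30,
                           circular = FALSE,
                           read_length = min(100L, len %/% 2L)) {
  genome <- simulate_genome(len, seed = seed, circular = circular,
                            unique_kmers_k = k)
  reads <- simulate_reads(genome, coverage = coverage,
                          read_length = read_length, seed = seed + 1)
  list(genome = genome, reads = reads,
       graph = assemble_unitigs(reads, k = k))
}

# strand-insensitive sequence identity
same_up_to_strand <- function(a, b) a == b | a == revcomp(b)

# circular contigs start at an arbitrary point of the circle: compare up to
# rotation and strand
same_up_to_rotation <- function(a, genome) {
  doubled <- paste0(genome, genome)
  nchar(a) == nchar(genome) &&
    (grepl(a, doubled, fixed = TRUE) ||
       grepl(revcomp(a), doubled, fixed = TRUE))
}

# naive window-slicing k-mer extractor (independent of the C++ scanner)
naive_windows <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  w <- substring(seq, 1:(n - k + 1), k:n)
  w[grepl("^[ACGT]+$", w)]
}

# a hand-built 4-unitig graph for emission-rule tests:
# fabricated records, links and circular flags under direct control
toy_graph <- function(unitigs, links, k = 5) {
  unitigr:::new_assembly_graph(unitigs, links, k)
}
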