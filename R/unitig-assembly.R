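# Unitig assembly: solid k-mer filtering, compacted de Bruijn graph
# construction, and approximate mean-abundance annotation.
#
# The graph is bidirected: nodes are canonical k-mers, edges are exact
# (k-1)-base overlaps between oriented nodes. Unitigs are the maximal
# non-branching paths; every solid canonical k-mer is placed in exactly one
# unitig, exactly once. Output order is deterministic (length descending,
# sequence ascending) and each unitig is stored on its lexicographically
# smaller strand, so assemblies are bit-reproducible.
#
# Link records follow the BCALM2 end-sign convention: a link
# (from, from_end, to, to_end) means the from-unitig, oriented by from_end
# ('+' = stored strand, '-' = reverse strand), overlaps the first k-1 bases
# of the to-unitig oriented by to_end. Links always come in mirrored pairs.

new_assembly_graph <- function(unitigs, links, k, counts_k1 = NULL,
                               blacklist = character(), edges = NULL) {
  structure(list(unitigs = unitigs, links = links, k = k,
                 counts_k1 = counts_k1, blacklist = blacklist,
                 edges = edges),
            class = "assembly_graph")
}

#' @export
print.assembly_graph <- function(x, ...) {
  cat(sprintf("assembly_graph: %d unitig(s), %d link record(s), k = %d\n",
              nrow(x$unitigs), nrow(x$links), x$k))
  if (length(x$blacklist))
    cat(sprintf("  %d junction(s) blacklisted\n", length(x$blacklist)))
  invisible(x)
}

#' Canonical k-mers of an assembly graph
#'
#' Every canonical k-mer currently placed in the graph's unitigs (each
#' occurs exactly once by construction), sorted by code.
#'
#' @param g an `assembly_graph`.
#' @return character vector of canonical k-mers.
#' @export
graph_kmers <- function(g) {
  if (nrow(g$unitigs) == 0L) return(character(0))
  cpp_count_canonical(g$unitigs$seq, g$k)$kmer
}

#' Filter solid k-mers
#'
#' Keeps the canonical k-mers seen at least `min_count` times. The default
#' of 2 discards k-mers seen only once in an accession, which removes most
#' isolated sequencing errors before graph construction.
#'
#' @param counts a `kmer_counts` table from [count_canonical()].
#' @param min_count minimum count to retain (default 2).
#' @return character vector of canonical k-mers, with attribute `k`.
#' @export
solid_kmers <- function(counts, min_count = 2L) {
  stopifnot(inherits(counts, "kmer_counts"))
  out <- counts$kmer[counts$count >= min_count]
  attr(out, "k") <- attr(counts, "k")
  out
}

#' Per-k-mer abundance from (k+1)-mer counts
#'
#' The abundance of a k-mer is approximated by summing the counts of all
#' distinct canonical (k+1)-mers containing it (as prefix or suffix, on
#' either strand) and dividing by two. For a k-mer internal to every read
#' it occurs in, each occurrence contributes two (k+1)-mers and the
#' division cancels exactly; read-end k-mers are undercounted by half per
#' end occurrence.
#'
#' @param kmer character vector of k-mers.
#' @param counts_k1 a `kmer_counts` table at word length k+1.
#' @return numeric abundance per k-mer (possibly half-integer).
#' @export
kmer_abundance <- function(kmer, counts_k1) {
  stopifnot(inherits(counts_k1, "kmer_counts"), length(kmer) >= 1L)
  k <- unique(nchar(kmer))
  if (length(k) != 1L) stop("all k-mers must have the same length")
  if (attr(counts_k1, "k") != k + 1L)
    stop("counts_k1 must be counted at word length k+1")
  ab <- cpp_kmer_abundances(kmer, k, counts_k1$kmer, counts_k1$count)
  vapply(ab, function(a) a[1L], numeric(1))
}

#' Mean 8-bit-quantized abundance of a sequence's k-mers
#'
#' Per-k-mer abundances pass through the 8-bit codec (round-trip
#' encode/decode) before averaging, mirroring how abundances are stored
#' during graph construction.
#'
#' @param seq character vector of unitig/contig sequences.
#' @param k word length.
#' @param counts_k1 `kmer_counts` at length k+1.
#' @return numeric mean abundance per sequence.
#' @export
unitig_mean_abundance <- function(seq, k, counts_k1) {
  ab <- cpp_kmer_abundances(seq, k, counts_k1$kmer, counts_k1$count)
  vapply(ab, function(a) {
    if (!length(a)) return(NA_real_)
    mean(decode_abundance(encode_abundance(a[!is.na(a)])))
  }, numeric(1))
}

#' Build the compacted de Bruijn graph from a solid k-mer set
#'
#' Unitigs are the maximal non-branching paths of the bidirected graph whose
#' nodes are the given canonical k-mers and whose edges are exact (k-1)
#' overlaps. Each k-mer is placed exactly once. Adjacency is edge-centric
#' when `edges` is given: an overlap only counts as an edge if its junction
#' (k+1)-mer was actually observed in the reads, which is how read-based
#' assembly avoids spurious overlaps between k-mers that never co-occurred.
#' With `edges = NULL` every exact overlap is an edge (node-centric).
#' Junctions listed in `blacklist` (as canonical (k+1)-mers) are treated as
#' absent, which is how weak links are cut during simplification.
#'
#' @param solid canonical k-mer set: a character vector or a `kmer_counts`
#'   table (its `kmer` column is used).
#' @param k word length.
#' @param counts_k1 optional `kmer_counts` at length k+1; when given, each
#'   unitig is annotated with its mean quantized abundance and the observed
#'   (k+1)-mers serve as edge support unless `edges` overrides.
#' @param blacklist canonical (k+1)-mer junctions to suppress.
#' @param edges canonical (k+1)-mers supporting edges, or NULL for
#'   node-centric adjacency; defaults to the keys of `counts_k1`.
#' @return an `assembly_graph`: `$unitigs` (id, seq, length, mean_abund),
#'   `$links` (from, from_end, to, to_end, mirrored pairs), `$k`.
#' @export
build_compacted_graph <- function(solid, k, counts_k1 = NULL,
                                  blacklist = character(),
                                  edges = if (!is.null(counts_k1))
                                    counts_k1$kmer) {
  if (inherits(solid, "kmer_counts")) solid <- solid$kmer
  stopifnot(is.character(solid))
  k <- as.integer(k)
  res <- cpp_build_unitigs(solid, k, blacklist, edges)
  seqs <- res$seq
  unitigs <- data.frame(id = seq_along(seqs), seq = seqs,
                        length = nchar(seqs),
                        mean_abund = rep(NA_real_, length(seqs)),
                        stringsAsFactors = FALSE)
  if (!is.null(counts_k1) && nrow(unitigs) > 0L)
    unitigs$mean_abund <- unitig_mean_abundance(seqs, k, counts_k1)
  links <- res$links
  if (nrow(links) > 0L) {
    ord <- order(links$from, links$from_end, links$to, links$to_end)
    links <- links[ord, , drop = FALSE]
    rownames(links) <- NULL
  }
  new_assembly_graph(unitigs, links, k, counts_k1, blacklist, edges)
}

#' Assemble unitigs from reads
#'
#' The full unitig pipeline: count canonical k-mers, discard singletons
#' (counts below `min_count`), count (k+1)-mers for abundance annotation,
#' build the compacted graph, and annotate each unitig with its mean
#' quantized abundance. Reads shorter than k are skipped.
#'
#' @param reads character vector of reads (or `DNAStringSet`), or a path to
#'   a FASTA/FASTQ file (plain or gzip).
#' @param k word length (default 31).
#' @param min_count solidity threshold (default 2: k-mers seen once are
#'   discarded).
#' @param allow_even permit even k (odd k is the default so no k-mer is its
#'   own reverse complement).
#' @return an `assembly_graph` carrying the (k+1)-mer count table used for
#'   abundance annotation.
#' @export
#' @examples
#' g <- assemble_unitigs(c("ACTTAGC", "ACTTAGC"), k = 3, min_count = 2)
#' g$unitigs$seq # one unitig spelling the input (up to strand)
assemble_unitigs <- function(reads, k = 31L, min_count = 2L,
                             allow_even = FALSE) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_seqs(reads)
  k <- check_k(k, allow_even)
  counts <- count_canonical(reads, k)
  solid <- solid_kmers(counts, min_count)
  counts_k1 <- count_canonical(reads, k + 1L)
  build_compacted_graph(solid, k, counts_k1)
}
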