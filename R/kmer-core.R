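# Canonical k-mer primitives.
#
# A k-mer is packed 2 bits per base (A=0, C=1, G=2, T=3, most-significant
# base first) into an integer code. The canonical form of a k-mer is the
# numerically smaller of the k-mer and its reverse complement; all counting,
# assembly and indexing operate on canonical k-mers so the two strands of a
# molecule collapse to one representation. k is capped at 31 so codes fit in
# 64 bits; odd k is the default so no k-mer equals its own reverse
# complement. Note that R numerics hold codes exactly for k <= 26 (2k <= 52
# bits); the internal C++ engine always uses full 64-bit integers.

check_k <- function(k, allow_even = FALSE) {
  if (length(k) != 1L || is.na(k) || k != as.integer(k))
    stop("k must be a single integer")
  k <- as.integer(k)
  if (k < 1L || k > 31L) stop("k must be in 1..31")
  if (!allow_even && k %% 2L == 0L)
    stop("k must be odd (set allow_even = TRUE to override)")
  k
}

#' Encode a DNA word as a 2-bit packed integer code
#'
#' Bases map to A=0, C=1, G=2, T=3, most-significant first, so e.g.
#' `"ACGT"` encodes to 27. Case-insensitive; any other character is an
#' error naming the offending position.
#'
#' @param seq a single DNA string (the word length k is its number of
#'   characters, at most 31).
#' @return a numeric code in `[0, 4^k)`. Codes are exact R numerics for
#'   k <= 26.
#' @seealso [decode_kmer()], [revcomp_code()], [canonical_code()]
#' @export
#' @examples
#' encode_kmer("ACGT") # 27
encode_kmer <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  cpp_encode_kmer(seq)
}

#' Decode a 2-bit packed k-mer code back to a DNA string
#'
#' @param code numeric code as produced by [encode_kmer()].
#' @param k word length.
#' @return a DNA string of length `k`.
#' @export
decode_kmer <- function(code, k) {
  cpp_decode_kmer(code, as.integer(k))
}

#' Reverse complement of a k-mer code
#'
#' An involution: applying it twice returns the original code.
#'
#' @inheritParams decode_kmer
#' @return the code of the reverse complement.
#' @export
revcomp_code <- function(code, k) {
  cpp_revcomp_code(code, as.integer(k))
}

#' Canonicalize a k-mer code
#'
#' Returns `min(code, revcomp_code(code, k))`: the strand-collapsed
#' representative used throughout counting, assembly and indexing.
#'
#' @inheritParams decode_kmer
#' @export
canonical_code <- function(code, k) {
  cpp_canonical_code(code, as.integer(k))
}

#' Reverse complement of a DNA string
#'
#' @param seq character vector of DNA strings (ACGT plus ambiguity codes;
#'   non-ACGT IUPAC characters map through [Biostrings::reverseComplement()]).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Canonical form of k-mer strings
#'
#' The lexicographically smaller of each string and its reverse complement
#' (equivalently, the numerically smaller 2-bit code).
#'
#' @param seq character vector of DNA words.
#' @export
canonical_kmer <- function(seq) {
  rc <- revcomp(seq)
  ifelse(rc < seq, rc, seq)
}

#' Scan the canonical k-mers of a sequence
#'
#' Yields every length-k window consisting only of A/C/G/T, left to right,
#' in canonical form. Windows containing ambiguous bases (e.g. N) are
#' skipped; a sequence shorter than k yields no windows.
#'
#' @param seq a single DNA string.
#' @param k word length (odd, at most 31).
#' @param allow_even permit even k.
#' @return a data.frame with columns `pos` (1-based window start) and
#'   `kmer` (canonical k-mer string).
#' @export
#' @examples
#' scan_kmers("ACGNT", 3) # one window: ACG at pos 1
scan_kmers <- function(seq, k, allow_even = FALSE) {
  k <- check_k(k, allow_even)
  stopifnot(is.character(seq), length(seq) == 1L)
  res <- cpp_scan_kmers(seq, k)
  data.frame(pos = res$pos, kmer = res$kmer, stringsAsFactors = FALSE)
}

#' Exact canonical k-mer counting over a read collection
#'
#' Counts the canonical k-mers of every read, in memory. Reads shorter than
#' k contribute nothing; windows containing ambiguous bases are skipped.
#' The result is deterministic and independent of read order.
#'
#' @param reads character vector of read sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @param k word length in 1..32; even lengths are allowed since (k+1)-mer
#'   abundance tables for odd k are themselves even.
#' @return a `kmer_counts` data.frame with columns `kmer` (canonical) and
#'   `count`, sorted by k-mer code, with attribute `k`.
#' @export
count_canonical <- function(reads, k) {
  if (methods::is(reads, "XStringSet")) reads <- as.character(reads)
  stopifnot(is.character(reads))
  if (length(k) != 1L || is.na(k) || k != as.integer(k))
    stop("k must be a single integer")
  k <- as.integer(k)
  # even word lengths are routine here: (k+1)-mer abundance tables for odd k
  if (k < 1L || k > 32L) stop("k must be in 1..32")
  res <- cpp_count_canonical(reads, k)
  out <- data.frame(kmer = res$kmer, count = res$count,
                    stringsAsFactors = FALSE)
  attr(out, "k") <- k
  class(out) <- c("kmer_counts", "data.frame")
  out
}
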