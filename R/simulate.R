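# Seeded generators for genomes and error-bearing short reads. All
# generators are pure functions of their arguments (including the seed):
# the caller's RNG state is saved and restored around every draw.

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a random genome
#'
#' I.i.d. bases at the requested GC content, deterministic for a given
#' seed. With `unique_kmers_k` set, the genome is rejection-resampled
#' (seed, seed+1, ...) until all its canonical k-mers at that word length
#' are distinct (wrap-around windows included for circular genomes), which
#' guarantees clean single-unitig assembly from error-free reads.
#'
#' @param length genome length in nucleotides.
#' @param gc GC fraction in `[0, 1]` (default 0.5).
#' @param circular logical; recorded as an attribute and honored by
#'   [simulate_reads()].
#' @param seed RNG seed.
#' @param unique_kmers_k if non-NULL, resample until all canonical k-mers
#'   of this length are distinct.
#' @param max_attempts resampling budget before giving up.
#' @return a DNA string with attribute `circular`.
#' @export
simulate_genome <- function(length, gc = 0.5, circular = FALSE, seed = 1L,
                            unique_kmers_k = NULL, max_attempts = 50L) {
  stopifnot(length >= 1, gc >= 0, gc <= 1)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  for (attempt in seq_len(max_attempts)) {
    g <- with_seed(seed + attempt - 1L, paste(
      sample(names(probs), length, replace = TRUE, prob = probs),
      collapse = ""))
    if (is.null(unique_kmers_k)) break
    k <- as.integer(unique_kmers_k)
    scan <- if (circular) paste0(g, substr(g, 1L, k - 1L)) else g
    counts <- count_canonical(scan, k)
    n_windows <- nchar(scan) - k + 1L
    if (nrow(counts) == n_windows && all(counts$count == 1)) break
    if (attempt == max_attempts)
      stop("could not sample a genome with unique ", k,
           "-mers in ", max_attempts, " attempts; try a larger k")
  }
  attr(g, "circular") <- circular
  g
}

#' Simulate uniform-coverage short reads
#'
#' `ceiling(coverage * genome_length / read_length)` reads with start
#' positions uniform over the whole genome, wrapping across the origin for
#' circular genomes and truncated at the 3' end for linear ones (so
#' terminal k-mers keep enough coverage to stay solid), and i.i.d.
#' substitution errors at `error_rate` per base. Deterministic for a given
#' seed.
#'
#' @param genome DNA string (attribute `circular` honored unless
#'   overridden).
#' @param coverage fold coverage (> 0).
#' @param read_length read length in nucleotides (at most the genome
#'   length).
#' @param error_rate per-base substitution probability in `[0, 1)`.
#' @param seed RNG seed.
#' @param circular override the genome's circularity attribute.
#' @return character vector of reads.
#' @export
simulate_reads <- function(genome, coverage = 30, read_length = 100L,
                           error_rate = 0, seed = 1L,
                           circular = isTRUE(attr(genome, "circular"))) {
  G <- nchar(genome)
  stopifnot(read_length <= G, coverage > 0, error_rate >= 0, error_rate < 1)
  n_reads <- ceiling(coverage * G / read_length)
  with_seed(seed, {
    if (circular) {
      starts <- sample.int(G, n_reads, replace = TRUE)
      template <- paste0(genome, substr(genome, 1L, read_length))
      reads <- substring(template, starts, starts + read_length - 1L)
    } else {
      # fragments placed uniformly with overhang at both ends, truncated to
      # the genome, so terminal bases see the same expected coverage as the
      # interior
      starts <- sample.int(G + read_length - 1L, n_reads, replace = TRUE) -
        (read_length - 1L)
      reads <- substring(genome, pmax(starts, 1L),
                         pmin(starts + read_length - 1L, G))
    }
    if (error_rate > 0) {
      bases <- c("A", "C", "G", "T")
      lens <- nchar(reads)
      n_err <- stats::rbinom(n_reads, lens, error_rate)
      for (i in which(n_err > 0)) {
        pos <- sample.int(lens[i], n_err[i])
        chars <- strsplit(reads[i], "")[[1L]]
        for (p in pos)
          chars[p] <- sample(setdiff(bases, chars[p]), 1L)
        reads[i] <- paste(chars, collapse = "")
      }
    }
    reads
  })
}

#' Substitute one base to create a second haplotype
#'
#' @param genome DNA string.
#' @param position 1-based position to change.
#' @param alt_base replacement base; must differ from the reference base.
#' @return the substituted copy (attributes preserved).
#' @export
inject_variant <- function(genome, position, alt_base) {
  stopifnot(position >= 1L, position <= nchar(genome),
            alt_base %in% c("A", "C", "G", "T"))
  ref <- substr(genome, position, position)
  if (identical(ref, alt_base))
    stop("alt base equals the reference base at position ", position)
  out <- genome
  substr(out, position, position) <- alt_base
  attributes(out) <- attributes(genome)
  out
}
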