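# Per-accession Bloom-filter k-mer index with Findere-style querying.
#
# Each accession's unitigs are decomposed into canonical s-mers (s = k - z)
# which are inserted into a Bloom filter sized by the standard optimal
# formula. A query k-mer answers positive iff all z+1 of its constituent
# s-mers are positive, so with the per-s-mer false-positive rate set to
# target^(1/(z+1)) the composed per-k-mer rate meets the target (default
# 0.005%) at no extra memory. Present k-mers can never answer negative.

# fixed hash seeds: index content is a pure function of the inserted set
.default_seed1 <- 0x9E3779B9
.default_seed2 <- 0x85EBCA77

#' Index specification
#'
#' @param k query word length (default 31).
#' @param z Findere reduction parameter (default 3); indexed words are
#'   s-mers with s = k - z.
#' @param target_fpr effective per-k-mer false-positive target (default
#'   5e-5, i.e. 0.005%).
#' @param max_query_len queries longer than this are refused unless
#'   explicitly allowed (default 1000 nt).
#' @param seed1,seed2 64-bit hash seeds (fixed defaults for
#'   reproducibility).
#' @return an `index_spec` list (with derived `s` and `per_smer_fpr`).
#' @export
index_spec <- function(k = 31L, z = 3L, target_fpr = 5e-5,
                       max_query_len = 1000L,
                       seed1 = .default_seed1, seed2 = .default_seed2) {
  stopifnot(z >= 0L, z < k, target_fpr > 0, target_fpr < 1)
  structure(list(k = as.integer(k), z = as.integer(z),
                 s = as.integer(k - z), target_fpr = target_fpr,
                 per_smer_fpr = target_fpr^(1 / (z + 1)),
                 max_query_len = as.integer(max_query_len),
                 seed1 = seed1, seed2 = seed2),
            class = "index_spec")
}

#' Optimal Bloom filter sizing
#'
#' The textbook formulas: `m = ceil(-n * ln(p) / ln(2)^2)` bits and
#' `h = max(1, round(ln(2) * m / n))` hash functions for `n` distinct
#' elements at false-positive rate `p`.
#'
#' @param n_distinct number of distinct elements to insert (at least 1).
#' @param per_smer_fpr per-element false-positive rate in (0, 1).
#' @return a list with `m` (bits) and `h` (hash count).
#' @export
#' @examples
#' size_bloom(100000, 0.01) # m = 958506, h = 7
size_bloom <- function(n_distinct, per_smer_fpr) {
  stopifnot(n_distinct >= 1, per_smer_fpr > 0, per_smer_fpr < 1)
  m <- ceiling(-n_distinct * log(per_smer_fpr) / log(2)^2)
  h <- max(1, round(log(2) * m / n_distinct))
  list(m = m, h = as.integer(h))
}

#' Build the Bloom filter of one accession
#'
#' Inserts every canonical s-mer of the accession's unitig sequences. The
#' filter is sized for `per_smer_fpr = target_fpr^(1/(z+1))` so the
#' Findere-composed per-k-mer rate meets the target.
#'
#' @param seqs character vector of unitig (or contig) sequences.
#' @param accession_id accession identifier string.
#' @param spec an [index_spec()].
#' @return an `accession_filter` object.
#' @export
build_accession_filter <- function(seqs, accession_id = "accession",
                                   spec = index_spec()) {
  stopifnot(is.character(seqs))
  n <- cpp_distinct_smers(seqs, spec$s)
  if (n == 0) {
    f <- list(bits = as.raw(0L), n_inserted = 0, m = 8, h = 1L)
  } else {
    sz <- size_bloom(n, spec$per_smer_fpr)
    built <- cpp_bloom_build(seqs, spec$s, sz$m, sz$h, spec$seed1, spec$seed2)
    f <- list(bits = built$bits, n_inserted = built$n_inserted,
              m = sz$m, h = sz$h)
  }
  structure(c(f, list(accession_id = accession_id, spec = spec)),
            class = "accession_filter")
}

#' Findere membership of k-mers in an accession filter
#'
#' A k-mer answers TRUE iff all its z+1 constituent canonical s-mers are
#' positive in the Bloom filter. Never FALSE for a k-mer genuinely present
#' in the indexed sequences; windows with ambiguous bases answer FALSE.
#'
#' @param filter an `accession_filter`.
#' @param kmers character vector of length-k windows.
#' @return logical vector.
#' @export
findere_contains <- function(filter, kmers) {
  sp <- filter$spec
  cpp_findere_contains(filter$bits, filter$m, filter$h, sp$seed1, sp$seed2,
                       kmers, sp$k, sp$z)
}

#' Measure a filter's empirical false-positive rate
#'
#' Draws uniformly random k-mers from a dedicated RNG stream, discards any
#' whose canonical form appears in `exclude` (the k-mers truly present in
#' the accession), and reports the fraction of the remainder that the
#' Findere composition answers positive.
#'
#' @param filter an `accession_filter`.
#' @param n_queries number of random k-mers to draw (default 2e6).
#' @param seed RNG seed for the query stream.
#' @param exclude character vector of truly present k-mers to skip.
#' @return a list with `n_tested`, `n_positive` and `fpr`.
#' @export
measure_filter_fpr <- function(filter, n_queries = 2e6, seed = 1L,
                               exclude = character(0)) {
  sp <- filter$spec
  res <- cpp_measure_fpr(filter$bits, filter$m, filter$h, sp$seed1,
                         sp$seed2, sp$k, sp$z, n_queries, seed, exclude)
  list(n_tested = res[1L], n_positive = res[2L],
       fpr = if (res[1L] > 0) res[2L] / res[1L] else 0)
}

#' Build a search index across accessions
#'
#' One Bloom filter per accession plus a metadata manifest. Accession ids
#' must be unique.
#'
#' @param accessions named list: accession id -> character vector of unitig
#'   sequences.
#' @param manifest optional data.frame of per-accession metadata with an
#'   `accession_id` column.
#' @param spec an [index_spec()].
#' @return a `search_index` object.
#' @export
build_search_index <- function(accessions, manifest = NULL,
                               spec = index_spec()) {
  ids <- names(accessions)
  if (is.null(ids) || any(ids == "") || anyDuplicated(ids))
    stop("accessions must be a named list with unique, non-empty ids")
  filters <- lapply(ids, function(id)
    build_accession_filter(accessions[[id]], id, spec))
  names(filters) <- ids
  if (is.null(manifest))
    manifest <- data.frame(accession_id = ids, stringsAsFactors = FALSE)
  stopifnot("accession_id" %in% names(manifest))
  structure(list(filters = filters, manifest = manifest, spec = spec,
                 version = 1L),
            class = "search_index")
}

#' Coverage-fraction query across accessions
#'
#' For each accession, the fraction of the query's valid k-mer windows that
#' answer positive in its filter. Accessions reaching the user-set
#' threshold are returned sorted by fraction (descending, ties by id),
#' with manifest metadata attached.
#'
#' @param index a `search_index`.
#' @param seq the query: a DNA string (at least k, at most `max_query_len`
#'   nucleotides unless `allow_long`).
#' @param threshold required fraction in `[0, 1]` (no default: the
#'   threshold is user-set).
#' @param allow_long permit queries longer than `max_query_len`.
#' @return a data.frame: `accession_id`, `fraction`, `n_found`, `n_total`,
#'   plus manifest columns.
#' @export
query_index <- function(index, seq, threshold, allow_long = FALSE) {
  stopifnot(inherits(index, "search_index"))
  if (missing(threshold) || is.null(threshold))
    stop("a k-mer fraction threshold is required (user-set)")
  stopifnot(threshold >= 0, threshold <= 1)
  sp <- index$spec
  if (nchar(seq) < sp$k)
    stop("query shorter than k = ", sp$k)
  if (nchar(seq) > sp$max_query_len && !allow_long)
    stop("query longer than the ", sp$max_query_len,
         " nt limit; set allow_long = TRUE to override")
  rows <- lapply(index$filters, function(f) {
    res <- cpp_findere_query(f$bits, f$m, f$h, sp$seed1, sp$seed2, seq,
                             sp$k, sp$z)
    data.frame(accession_id = f$accession_id,
               fraction = if (res[1L] > 0) res[2L] / res[1L] else 0,
               n_found = res[2L], n_total = res[1L],
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(hits) || nrow(hits) == 0L) return(empty_hits(index))
  hits <- hits[hits$fraction >= threshold, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty_hits(index))
  hits <- hits[order(-hits$fraction, hits$accession_id), , drop = FALSE]
  out <- merge(hits, index$manifest, by = "accession_id", all.x = TRUE,
               sort = FALSE)
  out <- out[order(-out$fraction, out$accession_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_hits <- function(index) {
  meta <- index$manifest[0, setdiff(names(index$manifest), "accession_id"),
                         drop = FALSE]
  cbind(data.frame(accession_id = character(0), fraction = numeric(0),
                   n_found = numeric(0), n_total = numeric(0),
                   stringsAsFactors = FALSE), meta)
}

#' Extract the sequences of one accession matching a query
#'
#' Exact (no Bloom filter): returns every sequence sharing at least one
#' canonical k-mer with the query, annotated with the number of shared
#' distinct canonical k-mers.
#'
#' @param seqs character vector of one accession's unitig/contig sequences
#'   (names kept if present).
#' @param query query DNA string.
#' @param k word length (default 31).
#' @return a data.frame: `name`, `seq`, `shared_kmers`.
#' @export
extract_matching_sequences <- function(seqs, query, k = 31L) {
  stopifnot(is.character(seqs))
  k <- as.integer(k)
  qk <- if (nchar(query) >= k) unique(cpp_count_canonical(query, k)$kmer)
        else character(0)
  nm <- if (is.null(names(seqs))) as.character(seq_along(seqs)) else names(seqs)
  shared <- vapply(seqs, function(s) {
    sk <- cpp_count_canonical(s, k)$kmer
    length(intersect(sk, qk))
  }, integer(1), USE.NAMES = FALSE)
  keep <- shared >= 1L
  data.frame(name = nm[keep], seq = unname(seqs[keep]),
             shared_kmers = shared[keep], stringsAsFactors = FALSE)
}

#' Save / load a search index
#'
#' A small versioned binary container: magic bytes, a format version, and
#' the serialized index (bitsets, sizing parameters, hash seeds, manifest).
#' Round-tripping is lossless; truncated files and version mismatches are
#' load errors.
#'
#' @param index a `search_index`.
#' @param path file path.
#' @return `save_index`: the path, invisibly. `load_index`: the
#'   `search_index`.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "search_index"))
  payload <- serialize(index, NULL)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("UTGRIDX1"), con)
  writeBin(1L, con, size = 4L, endian = "little")
  writeBin(length(payload), con, size = 4L, endian = "little")
  writeBin(payload, con)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 8L)
  if (length(magic) < 8L || !identical(rawToChar(magic), "UTGRIDX1"))
    stop("not a search index file (bad magic bytes)")
  version <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (!identical(version, 1L))
    stop("unsupported index version: ", version)
  len <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  payload <- readBin(con, "raw", n = len)
  if (length(payload) < len) stop("truncated or corrupt index file")
  index <- unserialize(payload)
  if (!inherits(index, "search_index")) stop("corrupt index payload")
  index
}
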