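# Graph simplification into contigs.
#
# Three SPAdes-style heuristics are alternated until fixpoint: tip clipping
# (short dead-end spurs with lower abundance than their through neighbor),
# bubble popping (the minor branch of a pair of parallel simple paths is
# removed when clearly under-covered), and weak-link removal (a junction is
# cut when its two flanks have wildly different abundance and the weak side
# has an alternative). Every edit is expressed as a removal of k-mers
# and/or a blacklisting of junction (k+1)-mers, after which the graph is
# recompacted from scratch -- one code path, no orientation surgery.

#' Simplification parameters
#'
#' Thresholds for tip clipping, bubble popping and weak-link removal. The
#' defaults are conservative: tips up to 2.5*k nucleotides, bubbles popped
#' only when the minor branch has at most half the major's abundance, links
#' cut only below a 10x abundance imbalance.
#'
#' @param k word length of the graph to simplify.
#' @param tip_len_max maximum tip length in nucleotides (default
#'   `round(2.5 * k)`).
#' @param bubble_len_tol maximum branch length difference for a poppable
#'   bubble (default 3 nt).
#' @param bubble_abund_ratio minor/major mean-abundance ceiling for bubble
#'   removal (default 0.5).
#' @param weak_link_ratio a link is cut when the lower flanking abundance is
#'   strictly below this fraction of the higher (default 0.1) and the lower
#'   side has an alternative link at that end.
#' @param max_rounds maximum simplification rounds (default 10).
#' @return a `simplify_params` list.
#' @export
simplify_params <- function(k, tip_len_max = round(2.5 * k),
                            bubble_len_tol = 3L, bubble_abund_ratio = 0.5,
                            weak_link_ratio = 0.1, max_rounds = 10L) {
  stopifnot(tip_len_max > 0, bubble_len_tol >= 0,
            bubble_abund_ratio > 0, bubble_abund_ratio <= 1,
            weak_link_ratio > 0, weak_link_ratio <= 1, max_rounds >= 1)
  structure(list(tip_len_max = tip_len_max, bubble_len_tol = bubble_len_tol,
                 bubble_abund_ratio = bubble_abund_ratio,
                 weak_link_ratio = weak_link_ratio, max_rounds = max_rounds),
            class = "simplify_params")
}

# degree of one unitig end
end_degree <- function(links, id, end) {
  sum(links$from == id & links$from_end == end)
}

rebuild_graph <- function(g, drop_ids = integer(0), blacklist = g$blacklist) {
  keep <- g$unitigs$seq[!(g$unitigs$id %in% drop_ids)]
  kmers <- if (length(keep)) cpp_count_canonical(keep, g$k)$kmer else character(0)
  build_compacted_graph(kmers, g$k, g$counts_k1, blacklist, edges = g$edges)
}

#' Clip dead-end tips
#'
#' A tip is a unitig with exactly one dead end (the other end connected)
#' and length at most `tip_len_max`. It is clipped only when, at the
#' junction where it attaches, a competing branch (another link from the
#' same neighbor end) has strictly higher mean abundance -- i.e. the graph
#' offers a better-supported continuation. A dead-end unitig that is the
#' sole continuation of its neighbor is genuine sequence (e.g. a linear
#' genome end) and is never clipped; nor are isolated unitigs (two dead
#' ends). All tips are identified on the current graph, removed together,
#' and the graph recompacted.
#'
#' @param g an `assembly_graph` with abundance annotation.
#' @param p a [simplify_params()] object.
#' @return the simplified `assembly_graph`.
#' @export
clip_tips <- function(g, p) {
  u <- g$unitigs
  if (nrow(u) == 0L || nrow(g$links) == 0L) return(g)
  L <- g$links
  drop <- integer(0)
  for (i in seq_len(nrow(u))) {
    id <- u$id[i]
    dp <- end_degree(L, id, "+")
    dm <- end_degree(L, id, "-")
    if (xor(dp == 0L, dm == 0L) && u$length[i] <= p$tip_len_max) {
      e <- if (dp > 0L) "+" else "-"
      att <- L[L$from == id & L$from_end == e & L$to != id, , drop = FALSE]
      if (nrow(att) == 0L) next
      # competing branches: other links leaving the same anchor end(s)
      comp_ab <- numeric(0)
      for (j in seq_len(nrow(att))) {
        anchor_end <- if (att$to_end[j] == "+") "-" else "+"
        comp <- L[L$from == att$to[j] & L$from_end == anchor_end &
                    L$to != id, , drop = FALSE]
        comp_ab <- c(comp_ab, u$mean_abund[match(comp$to, u$id)])
      }
      if (length(comp_ab) && !is.na(u$mean_abund[i]) &&
          any(!is.na(comp_ab) & comp_ab > u$mean_abund[i]))
        drop <- c(drop, id)
    }
  }
  if (!length(drop)) return(g)
  rebuild_graph(g, drop_ids = drop)
}

# endpoint signature of a single-unitig branch: both its links, as an
# unordered pair of oriented ends
branch_signature <- function(links, id) {
  rows <- links[links$from == id, , drop = FALSE]
  eps <- sort(paste0(rows$to, rows$to_end))
  paste(eps, collapse = "|")
}

#' Pop simple bubbles
#'
#' A bubble is a pair of single-unitig parallel branches sharing both
#' oriented endpoints (e.g. the two alleles of a SNP). When the branch
#' lengths differ by at most `bubble_len_tol` and the minor branch's mean
#' abundance is at most `bubble_abund_ratio` times the major's, the minor
#' branch is removed and the graph recompacted. Ties are broken
#' deterministically by canonical sequence, and balanced bubbles are kept.
#'
#' @inheritParams clip_tips
#' @export
pop_bubbles <- function(g, p) {
  u <- g$unitigs
  L <- g$links
  if (nrow(u) == 0L || nrow(L) == 0L) return(g)
  cand <- u$id[vapply(u$id, function(id) {
    end_degree(L, id, "+") == 1L && end_degree(L, id, "-") == 1L &&
      !any(L$from == id & L$to == id)
  }, logical(1))]
  if (length(cand) < 2L) return(g)
  sig <- vapply(cand, function(id) branch_signature(L, id), character(1))
  drop <- integer(0)
  for (s in unique(sig[duplicated(sig)])) {
    grp <- cand[sig == s]
    if (length(grp) < 2L) next
    gi <- match(grp, u$id)
    if (anyNA(u$mean_abund[gi])) next
    # major branch: highest abundance, canonical sequence as tie-break
    ord <- order(-u$mean_abund[gi], u$seq[gi])
    grp <- grp[ord]; gi <- gi[ord]
    major <- gi[1L]
    for (j in seq_along(grp)[-1L]) {
      minor <- gi[j]
      if (abs(u$length[minor] - u$length[major]) <= p$bubble_len_tol &&
          u$mean_abund[major] > 0 &&
          u$mean_abund[minor] / u$mean_abund[major] <= p$bubble_abund_ratio)
        drop <- c(drop, grp[j])
    }
  }
  if (!length(drop)) return(g)
  rebuild_graph(g, drop_ids = drop)
}

# canonical (k+1)-mer spelling the junction of one link record
junction_kmer <- function(g, from, from_end, to, to_end) {
  k <- g$k
  u <- g$unitigs
  s <- u$seq[match(from, u$id)]
  if (from_end == "-") s <- revcomp(s)
  t <- u$seq[match(to, u$id)]
  if (to_end == "-") t <- revcomp(t)
  endk <- substr(s, nchar(s) - k + 1L, nchar(s))
  stopifnot(substr(endk, 2L, k) == substr(t, 1L, k - 1L))
  canonical_kmer(paste0(endk, substr(t, k, k)))
}

#' Remove weak links
#'
#' A link is cut when the lower of its two flanking mean abundances is
#' strictly below `weak_link_ratio` times the higher and at least one side
#' of the junction has an alternative link at the involved end (the
#' junction is redundant for that flank, so a strong coverage imbalance
#' marks it as erroneous; a well-supported path is never disconnected
#' because its flanks have similar abundance). Cut junctions are
#' blacklisted as (k+1)-mers and the graph recompacted; branches stranded
#' by a cut fall to the tip clipper or the emission filter.
#'
#' @inheritParams clip_tips
#' @export
remove_weak_links <- function(g, p) {
  u <- g$unitigs
  L <- g$links
  if (nrow(u) == 0L || nrow(L) == 0L) return(g)
  flip <- function(e) ifelse(e == "+", "-", "+")
  key <- paste(L$from, L$from_end, L$to, L$to_end)
  mirror <- paste(L$to, flip(L$to_end), L$from, flip(L$from_end))
  once <- L[key <= mirror, , drop = FALSE]
  bl <- character(0)
  for (i in seq_len(nrow(once))) {
    from <- once$from[i]; fe <- once$from_end[i]
    to <- once$to[i]; te <- once$to_end[i]
    if (from == to) next
    af <- u$mean_abund[match(from, u$id)]
    at <- u$mean_abund[match(to, u$id)]
    if (is.na(af) || is.na(at) || af == at) next
    ratio <- min(af, at) / max(af, at)
    if (ratio < p$weak_link_ratio &&
        (end_degree(L, from, fe) >= 2L ||
         end_degree(L, to, flip(te)) >= 2L))
      bl <- c(bl, junction_kmer(g, from, fe, to, te))
  }
  if (!length(bl)) return(g)
  rebuild_graph(g, blacklist = unique(c(g$blacklist, bl)))
}

#' Simplify an assembly graph into contig form
#'
#' Alternates [clip_tips()], [pop_bubbles()] and [remove_weak_links()],
#' recompacting after each pass, until a fixpoint or `max_rounds`. The
#' result is idempotent: simplifying a simplified graph changes nothing.
#'
#' @param g an `assembly_graph` (from [assemble_unitigs()]).
#' @param p a [simplify_params()] object; defaults to `simplify_params(g$k)`.
#' @return the simplified `assembly_graph`.
#' @export
simplify <- function(g, p = simplify_params(g$k)) {
  for (round in seq_len(p$max_rounds)) {
    before <- list(sort(g$unitigs$seq), length(g$blacklist))
    g <- clip_tips(g, p)
    g <- pop_bubbles(g, p)
    g <- remove_weak_links(g, p)
    after <- list(sort(g$unitigs$seq), length(g$blacklist))
    if (identical(before, after)) break
  }
  g
}

#' Detect circular contigs
#'
#' A contig is circular when its terminal link closes onto its own start
#' with consistent orientation: it carries a self-link from its '+' end to
#' its own '+' end, and (by construction of the de Bruijn graph) its
#' sequence then ends with its own first k-1 bases.
#'
#' @param g an `assembly_graph`.
#' @return logical vector, one entry per unitig row.
#' @export
detect_circular <- function(g) {
  u <- g$unitigs
  L <- g$links
  k <- g$k
  vapply(seq_len(nrow(u)), function(i) {
    id <- u$id[i]
    if (!any(L$from == id & L$to == id & L$from_end == "+" & L$to_end == "+"))
      return(FALSE)
    s <- u$seq[i]
    n <- nchar(s)
    n >= k && substr(s, 1L, k - 1L) == substr(s, n - k + 2L, n)
  }, logical(1))
}

#' Trim the terminal repeat of a circular contig
#'
#' A contig assembled from a circular molecule carries its first k-1 bases
#' duplicated at its end. This finds the largest repeat length `r` with
#' `r_min <= r <= floor(len/2)` such that the first `r` bases equal the
#' last `r`, and drops the last `r` bases (restoring the true circular
#' genome length). If no such repeat exists, `r = 0` and the sequence is
#' unchanged.
#'
#' @param seq a single DNA string of length at least `2 * r_min`.
#' @param r_min minimum repeat length to accept (default 30, i.e. k-1 for
#'   k = 31).
#' @return a list with `seq` (trimmed) and `r` (repeat length found).
#' @export
trim_terminal_repeat <- function(seq, r_min = 30L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  n <- nchar(seq)
  if (n < 2L * r_min)
    stop("sequence shorter than 2 * r_min; nothing to screen")
  for (r in seq.int(n %/% 2L, r_min)) {
    if (substr(seq, 1L, r) == substr(seq, n - r + 1L, n))
      return(list(seq = substr(seq, 1L, n - r), r = r))
  }
  list(seq = seq, r = 0L)
}

#' Fraction of a window covered by low-complexity tandem repeats
#'
#' Positions covered by maximal exact tandem repeats of period at most 5
#' whose total run length is at least 8, as a fraction of the window
#' length. Used to flag circular candidates whose terminal repeat is a
#' low-complexity artifact rather than genuine circularity.
#'
#' @param window a non-empty DNA string.
#' @return a fraction in `[0, 1]`.
#' @seealso [terminal_lowcomp_artifact()]
#' @export
#' @examples
#' low_complexity_fraction("AAAAAAAAAA")   # 1.0
#' low_complexity_fraction("ATATATATATAT") # 1.0
low_complexity_fraction <- function(window) {
  stopifnot(is.character(window), length(window) == 1L, nchar(window) > 0L)
  n <- nchar(window)
  chars <- strsplit(window, "")[[1L]]
  covered <- logical(n)
  for (p in 1:5) {
    if (n <= p) break
    eq <- chars[(p + 1L):n] == chars[1L:(n - p)]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      run_len <- r$lengths[j] + p   # region includes the seed period
      if (run_len >= 8L)
        covered[starts[j]:(ends[j] + p)] <- TRUE
    }
  }
  mean(covered)
}

#' Flag a circular candidate as a low-complexity artifact
#'
#' TRUE when more than half of the terminal window (default: the last 31
#' bases) is covered by low-complexity tandem repeats, in which case the
#' apparent terminal repeat likely arose from a simple repeat rather than
#' circularity.
#'
#' @param seq a DNA string (a circular contig candidate).
#' @param window terminal window length to screen (default 31).
#' @export
terminal_lowcomp_artifact <- function(seq, window = 31L) {
  n <- nchar(seq)
  w <- min(window, n)
  low_complexity_fraction(substr(seq, n - w + 1L, n)) > 0.5
}

#' Emit contigs from a simplified graph
#'
#' Default rule: a contig is discarded iff it is non-circular, shorter than
#' `min_len`, and an isolated node (no links to other contigs); everything
#' else is emitted. Strict rule (`strict = TRUE`): only contigs longer than
#' `min_len` that are connected to at least one other contig are kept.
#'
#' @param g a simplified `assembly_graph`.
#' @param min_len length threshold in nucleotides (default 150).
#' @param strict use the strict emission rule.
#' @return a data.frame with columns `id`, `seq`, `length`, `circular`,
#'   `mean_abund`, `n_links` (ids renumbered 1..n).
#' @export
emit_contigs <- function(g, min_len = 150L, strict = FALSE) {
  u <- g$unitigs
  if (nrow(u) == 0L)
    return(data.frame(id = integer(0), seq = character(0),
                      length = integer(0), circular = logical(0),
                      mean_abund = numeric(0), n_links = integer(0),
                      stringsAsFactors = FALSE))
  L <- g$links
  circ <- detect_circular(g)
  n_links <- vapply(u$id, function(id) sum(L$from == id & L$to != id),
                    integer(1))
  keep <- if (strict) u$length > min_len & n_links >= 1L
          else !(!circ & u$length < min_len & n_links == 0L)
  out <- data.frame(id = seq_len(sum(keep)), seq = u$seq[keep],
                    length = u$length[keep], circular = circ[keep],
                    mean_abund = u$mean_abund[keep],
                    n_links = n_links[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
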