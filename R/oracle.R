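# Brute-force reference assembler, used in tests as an independent oracle
# for the compacted-graph builder. Pure R, string-based: a hash set of
# canonical k-mers, exhaustive neighbor probing, and path walking. Refuses
# large inputs by design.

rc_chr <- function(seq) {
  vapply(seq, function(s) {
    rawToChar(rev(charToRaw(chartr("ACGTacgt", "TGCAtgca", s))))
  }, character(1), USE.NAMES = FALSE)
}

canon_chr <- function(seq) {
  rc <- rc_chr(seq)
  ifelse(rc < seq, rc, seq)
}

#' Brute-force unitig assembly (test oracle)
#'
#' A naive reference implementation of canonical k-mer counting, solidity
#' filtering and maximal non-branching path walking, independent of the
#' package's graph engine. Intended for equivalence testing on small
#' inputs; refuses more than 100 kb of input.
#'
#' @param reads character vector of reads.
#' @param k word length.
#' @param min_count solidity threshold (default 1).
#' @return sorted character vector of unitig sequences, each on its
#'   lexicographically smaller strand.
#' @export
oracle_assemble <- function(reads, k, min_count = 1L) {
  if (sum(nchar(reads)) > 100000)
    stop("input too large for the brute-force oracle (> 100 kb)")
  words <- unlist(lapply(reads, function(r) {
    n <- nchar(r)
    if (n < k) return(character(0))
    w <- substring(r, 1L:(n - k + 1L), k:n)
    w <- toupper(w)
    w[grepl("^[ACGT]+$", w)]
  }))
  if (!length(words)) return(character(0))
  counts <- table(canon_chr(words))
  solid <- sort(names(counts)[counts >= min_count])
  inset <- new.env(parent = emptyenv(), size = length(solid))
  for (x in solid) assign(x, TRUE, envir = inset)
  present <- function(x) !is.null(inset[[x]])

  # edge support: the (k+1)-mers actually observed in the reads
  junc <- unlist(lapply(reads, function(r) {
    n <- nchar(r)
    if (n < k + 1L) return(character(0))
    w <- toupper(substring(r, 1L:(n - k), (k + 1L):n))
    w[grepl("^[ACGT]+$", w)]
  }))
  eset <- new.env(parent = emptyenv())
  for (x in unique(canon_chr(junc))) assign(x, TRUE, envir = eset)

  right_exts <- function(fwd) {
    bases <- c("A", "C", "G", "T")
    cands <- paste0(substr(fwd, 2L, k), bases)
    ok <- vapply(canon_chr(cands), present, logical(1)) &
      vapply(canon_chr(paste0(fwd, bases)),
             function(j) !is.null(eset[[j]]), logical(1))
    cands[ok]
  }

  visited <- new.env(parent = emptyenv(), size = length(solid))
  unitigs <- character(0)
  for (start in solid) {
    if (!is.null(visited[[start]])) next
    assign(start, TRUE, envir = visited)
    path <- start
    circular <- FALSE
    repeat {
      exts <- right_exts(path[length(path)])
      if (length(exts) != 1L) break
      nxt <- exts
      if (length(right_exts(rc_chr(nxt))) != 1L) break
      if (identical(nxt, path[1L])) { circular <- TRUE; break }
      if (!is.null(visited[[canon_chr(nxt)]])) break
      path <- c(path, nxt)
      assign(canon_chr(nxt), TRUE, envir = visited)
    }
    if (!circular) {
      left <- character(0)
      repeat {
        cur <- if (length(left)) left[length(left)] else rc_chr(path[1L])
        exts <- right_exts(cur)
        if (length(exts) != 1L) break
        nxt <- exts
        if (length(right_exts(rc_chr(nxt))) != 1L) break
        if (!is.null(visited[[canon_chr(nxt)]])) break
        left <- c(left, nxt)
        assign(canon_chr(nxt), TRUE, envir = visited)
      }
      if (length(left)) path <- c(rc_chr(rev(left)), path)
    }
    seq <- paste0(path[1L],
                  paste(substr(path[-1L], k, k), collapse = ""))
    rcs <- rc_chr(seq)
    unitigs <- c(unitigs, if (rcs < seq) rcs else seq)
  }
  sort(unitigs)
}
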