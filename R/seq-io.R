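# Sequence I/O: FASTA/FASTQ reading (via Biostrings, gzip-transparent),
# assembly FASTA with BCALM2-style link headers, GFA1 export, and assembly
# statistics. FASTQ quality lines are ignored entirely -- only the sequence
# content matters downstream.

#' Read sequences from FASTA or FASTQ (plain or gzip)
#'
#' Format is inferred from the file extension (`.fq`/`.fastq`, optionally
#' `.gz`, is FASTQ; anything else FASTA). Quality values and FASTQ headers
#' are discarded.
#'
#' @param path input file path.
#' @param format `"auto"`, `"fasta"` or `"fastq"`.
#' @return named character vector of sequences.
#' @export
read_seqs <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  if (format == "auto") {
    base <- sub("\\.gz$", "", path)
    format <- if (grepl("\\.(fq|fastq)$", base, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  x <- Biostrings::readDNAStringSet(path, format = format)
  out <- as.character(x)
  names(out) <- names(x)
  out
}

format_abund <- function(x) sprintf("km:f:%.2f", x)

wrap_seq <- function(seq, width = 80L) {
  n <- nchar(seq)
  if (n <= width) return(seq)
  starts <- seq.int(1L, n, by = width)
  substring(seq, starts, pmin(starts + width - 1L, n))
}

#' Write an assembly FASTA with BCALM2-style link headers
#'
#' One record per sequence. Headers carry `LN:i:<length>`,
#' `km:f:<mean_abund>` (2 decimals) when abundance is known, zero or more
#' `L:<sign>:<to_id>:<sign>` link fields, and `circ:Z:true` for circular
#' contigs. Sequences are wrapped at 80 columns. A `.gz` path writes
#' gzip-compressed output.
#'
#' @param x an `assembly_graph`, or a records data.frame with columns `id`,
#'   `seq` and optionally `mean_abund`, `circular`.
#' @param path output file path (`.gz` for compressed).
#' @param links optional links data.frame (taken from `x` when it is an
#'   `assembly_graph`).
#' @return the path, invisibly.
#' @export
write_assembly_fasta <- function(x, path, links = NULL) {
  if (inherits(x, "assembly_graph")) {
    links <- x$links
    x <- x$unitigs
  }
  stopifnot(is.data.frame(x), all(c("id", "seq") %in% names(x)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  lines <- character(0)
  for (i in seq_len(nrow(x))) {
    hdr <- paste0(">", x$id[i], " LN:i:", nchar(x$seq[i]))
    if (!is.null(x$mean_abund) && !is.na(x$mean_abund[i]))
      hdr <- paste(hdr, format_abund(x$mean_abund[i]))
    if (!is.null(links) && nrow(links) > 0L) {
      lr <- links[links$from == x$id[i], , drop = FALSE]
      if (nrow(lr) > 0L)
        hdr <- paste(hdr, paste(sprintf("L:%s:%d:%s", lr$from_end,
                                        as.integer(lr$to), lr$to_end),
                                collapse = " "))
    }
    if (!is.null(x$circular) && isTRUE(x$circular[i]))
      hdr <- paste(hdr, "circ:Z:true")
    lines <- c(lines, hdr, wrap_seq(x$seq[i]))
  }
  writeLines(lines, con)
  invisible(path)
}

#' Read an assembly FASTA written by [write_assembly_fasta()]
#'
#' Plain FASTA is also accepted (links and abundance simply absent).
#' Unknown header tags are preserved verbatim in an `extra` column.
#' A malformed `L:` field is a parse error naming the line.
#'
#' @param path input path (`.gz` transparent).
#' @return a list with `records` (id, seq, length, mean_abund, circular,
#'   extra) and `links` (from, from_end, to, to_end).
#' @export
read_assembly_fasta <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  hdr_at <- grep("^>", lines)
  ids <- character(0); abunds <- numeric(0); circs <- logical(0)
  extras <- character(0); seqs <- character(0)
  lfrom <- integer(0); lfe <- character(0); lto <- integer(0); lte <- character(0)
  for (j in seq_along(hdr_at)) {
    ln <- hdr_at[j]
    toks <- strsplit(sub("^>", "", lines[ln]), "[ \t]+")[[1L]]
    id <- toks[1L]
    abund <- NA_real_; circ <- FALSE; extra <- character(0)
    for (tok in toks[-1L]) {
      if (grepl("^LN:i:", tok)) {
        next # redundant with the sequence itself
      } else if (grepl("^km:f:", tok)) {
        abund <- as.numeric(sub("^km:f:", "", tok))
      } else if (grepl("^circ:Z:", tok)) {
        circ <- identical(sub("^circ:Z:", "", tok), "true")
      } else if (grepl("^L:", tok)) {
        parts <- strsplit(tok, ":", fixed = TRUE)[[1L]]
        if (length(parts) != 4L || !parts[2L] %in% c("+", "-") ||
            !parts[4L] %in% c("+", "-") ||
            is.na(suppressWarnings(as.integer(parts[3L]))))
          stop("malformed L: field '", tok, "' at line ", ln)
        lfrom <- c(lfrom, suppressWarnings(as.integer(id)))
        lfe <- c(lfe, parts[2L])
        lto <- c(lto, as.integer(parts[3L]))
        lte <- c(lte, parts[4L])
      } else {
        extra <- c(extra, tok)
      }
    }
    to_line <- if (j < length(hdr_at)) hdr_at[j + 1L] - 1L else length(lines)
    seqs <- c(seqs, paste(lines[(ln + 1L):to_line], collapse = ""))
    ids <- c(ids, id); abunds <- c(abunds, abund); circs <- c(circs, circ)
    extras <- c(extras, paste(extra, collapse = " "))
  }
  ids_int <- suppressWarnings(as.integer(ids))
  records <- data.frame(
    id = if (!anyNA(ids_int)) ids_int else ids,
    seq = seqs, length = nchar(seqs), mean_abund = abunds,
    circular = circs, extra = extras, stringsAsFactors = FALSE)
  links <- data.frame(from = lfrom, from_end = lfe, to = lto, to_end = lte,
                      stringsAsFactors = FALSE)
  list(records = records, links = links)
}

#' Export an assembly graph as GFA 1.0
#'
#' Header line with `VN:Z:1.0`; one `S` line per unitig (sequence inline,
#' `LN` and `km` tags); one `L` line per undirected link with overlap
#' `<k-1>M` (each mirrored pair written once).
#'
#' @param g an `assembly_graph`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
export_gfa <- function(g, path) {
  u <- g$unitigs
  L <- g$links
  lines <- "H\tVN:Z:1.0"
  for (i in seq_len(nrow(u))) {
    s <- sprintf("S\t%d\t%s\tLN:i:%d", u$id[i], u$seq[i], u$length[i])
    if (!is.na(u$mean_abund[i]))
      s <- paste0(s, "\t", format_abund(u$mean_abund[i]))
    lines <- c(lines, s)
  }
  if (nrow(L) > 0L) {
    flip <- function(e) ifelse(e == "+", "-", "+")
    key <- paste(L$from, L$from_end, L$to, L$to_end)
    mirror <- paste(L$to, flip(L$to_end), L$from, flip(L$from_end))
    keep <- L[key <= mirror & !duplicated(pmin(key, mirror)), , drop = FALSE]
    lines <- c(lines, sprintf("L\t%d\t%s\t%d\t%s\t%dM", keep$from,
                              keep$from_end, keep$to, keep$to_end, g$k - 1L))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Assembly statistics (counts, total length, N50, longest)
#'
#' N50 is the largest length L such that sequences of length at least L sum
#' to at least half the total length (descending-length cumulative sum).
#' An empty input yields all zeros.
#'
#' @param x sequence lengths (numeric), sequences (character), a records
#'   data.frame with a `length` or `seq` column, or a path to a FASTA
#'   file.
#' @return a one-row data.frame: `n_sequences`, `total_length`, `n50`,
#'   `longest`.
#' @export
#' @examples
#' assembly_stats(c(5, 4, 3, 2, 1)) # N50 = 4
assembly_stats <- function(x) {
  lens <- if (is.numeric(x)) {
    x
  } else if (is.data.frame(x)) {
    if (!is.null(x$length)) x$length else nchar(x$seq)
  } else if (is.character(x) && length(x) == 1L && file.exists(x)) {
    nchar(read_seqs(x))
  } else if (is.character(x)) {
    nchar(x)
  } else stop("cannot derive sequence lengths from input")
  if (!length(lens))
    return(data.frame(n_sequences = 0L, total_length = 0, n50 = 0,
                      longest = 0))
  lens <- sort(as.numeric(lens), decreasing = TRUE)
  total <- sum(lens)
  n50 <- lens[which(cumsum(lens) >= total / 2)[1L]]
  data.frame(n_sequences = length(lens), total_length = total, n50 = n50,
             longest = lens[1L])
}
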