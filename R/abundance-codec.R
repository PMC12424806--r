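# 8-bit lossy abundance codec.
#
# During graph construction per-k-mer abundances are held in one byte. The
# scheme is a hybrid exact-then-geometric ladder: code 0 is reserved for
# count 0, codes 1..64 store counts 1..64 exactly, and the remaining 191
# codes are a geometric ladder from 64 up to the saturation ceiling of
# 50,000 (ratio r = (50000/64)^(1/191), about 3.5% per step, so the
# worst-case round-trip relative error is about 1.75% -- well inside the 5%
# contract). Counts at or above 50,000 saturate to the top code.

codec_env <- new.env(parent = emptyenv())

codec_levels <- function(exact_max = 64L, cap = 50000L, n_codes = 256L) {
  key <- paste(exact_max, cap, n_codes, sep = "_")
  if (!is.null(codec_env[[key]])) return(codec_env[[key]])
  n_geom <- n_codes - 1L - exact_max            # codes exact_max+1 .. n_codes-1
  r <- (cap / exact_max)^(1 / n_geom)
  geom <- floor(exact_max * r^seq_len(n_geom) + 0.5)
  levels <- c(0, seq_len(exact_max), geom)      # indexed by code + 1
  stopifnot(all(diff(levels[-1]) > 0), levels[n_codes] == cap)
  out <- list(levels = levels, r = r, exact_max = exact_max, cap = cap,
              n_geom = n_geom)
  codec_env[[key]] <- out
  out
}

#' Encode an abundance as an 8-bit code
#'
#' Code 0 is returned iff the count is 0; counts 1..`exact_max` map to
#' dedicated exact codes; larger counts map to the nearest level (by
#' relative error) of a geometric ladder running from `exact_max` to `cap`;
#' counts at or above `cap` all map to the top code. Non-integer counts
#' (e.g. half-integer k-mer abundances) are rounded half-up before
#' encoding.
#'
#' @param count numeric vector of non-negative counts.
#' @param exact_max largest count stored exactly (default 64).
#' @param cap saturation ceiling (default 50,000).
#' @return integer vector of codes in 0..255.
#' @seealso [decode_abundance()]
#' @export
#' @examples
#' decode_abundance(encode_abundance(60000)) # 50000: saturated
#' decode_abundance(encode_abundance(37))    # 37: exact band
encode_abundance <- function(count, exact_max = 64L, cap = 50000L) {
  stopifnot(all(count >= 0, na.rm = TRUE))
  cd <- codec_levels(exact_max, cap)
  count <- floor(count + 0.5)
  code <- integer(length(count))
  code[count >= cap] <- 255L
  ex <- count > 0 & count <= exact_max
  code[ex] <- as.integer(count[ex])
  mid <- count > exact_max & count < cap
  if (any(mid)) {
    c0 <- count[mid]
    j <- log(c0 / exact_max) / log(cd$r)
    jlo <- pmax(0, pmin(cd$n_geom, floor(j)))
    jhi <- pmax(0, pmin(cd$n_geom, ceiling(j)))
    vlo <- cd$levels[exact_max + jlo + 1L]
    vhi <- cd$levels[exact_max + jhi + 1L]
    pick_hi <- abs(vhi - c0) / c0 < abs(vlo - c0) / c0  # ties -> lower code
    code[mid] <- as.integer(exact_max + ifelse(pick_hi, jhi, jlo))
  }
  code
}

#' Decode an 8-bit abundance code
#'
#' Inverse of [encode_abundance()] up to the quantization error: exact for
#' counts in the exact band, within 5% relative error everywhere up to the
#' ceiling, and `decode_abundance(255)` is exactly `cap`.
#'
#' @param code integer vector of codes in 0..255.
#' @inheritParams encode_abundance
#' @return numeric vector of decoded counts.
#' @export
decode_abundance <- function(code, exact_max = 64L, cap = 50000L) {
  stopifnot(all(code >= 0 & code <= 255, na.rm = TRUE))
  cd <- codec_levels(exact_max, cap)
  cd$levels[as.integer(code) + 1L]
}
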