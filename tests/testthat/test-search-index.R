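test_that("Bloom sizing follows the optimal closed form", {
  sz <- size_bloom(100000, 0.01)
  expect_equal(sz$m, 958506)
  expect_equal(sz$h, 7L)
  sz2 <- size_bloom(1, 0.5)
  expect_equal(sz2$m, 2)
  expect_equal(sz2$h, 1L) # floor applied
  # smaller p => strictly larger m at fixed n
  ms <- vapply(c(0.1, 0.01, 0.001, 1e-4), function(p)
    size_bloom(5000, p)$m, numeric(1))
  expect_true(all(diff(ms) > 0))
})

test_that("filters are complete: indexed k-mers never answer negative", {
  sp <- index_spec(k = 5, z = 2)
  f <- build_accession_filter("ACTTAGC", "A", sp)
  expect_equal(f$n_inserted, 5) # the 5 distinct canonical 3-mers
  kmers <- substring("ACTTAGC", 1:3, 5:7)
  expect_true(all(findere_contains(f, kmers)))
  # reverse-complement queries hit too (canonical s-mers)
  expect_true(all(findere_contains(f, revcomp(kmers))))
  # empty accession: everything absent
  fe <- build_accession_filter(character(0), "E", sp)
  expect_false(any(findere_contains(fe, kmers)))

  # exhaustive completeness on a simulated accession at full k = 31
  fx <- clean_assembly(len = 3000, k = 31, seed = 101)
  f31 <- build_accession_filter(fx$graph$unitigs$seq, "S", index_spec())
  all31 <- unitigr:::cpp_count_canonical(fx$graph$unitigs$seq, 31)$kmer
  expect_true(all(findere_contains(f31, all31)))
})

test_that("Findere composition dominates the raw per-s-mer rate", {
  fx <- clean_assembly(len = 20000, k = 31, seed = 102, coverage = 15)
  sp <- index_spec()
  f <- build_accession_filter(fx$graph$unitigs$seq, "S", sp)
  present <- unitigr:::cpp_count_canonical(fx$graph$unitigs$seq, 31)$kmer
  kres <- unitigr:::cpp_measure_fpr(f$bits, f$m, f$h, sp$seed1, sp$seed2,
                                    31, sp$z, 2e5, 7, present)
  # same bit array queried as plain Bloom membership of s-mers (z = 0)
  pres_s <- unitigr:::cpp_count_canonical(fx$graph$unitigs$seq, sp$s)$kmer
  sres <- unitigr:::cpp_measure_fpr(f$bits, f$m, f$h, sp$seed1, sp$seed2,
                                    sp$s, 0L, 2e5, 8, pres_s)
  fpr_k <- kres[2] / kres[1]
  fpr_s <- sres[2] / sres[1]
  expect_lte(fpr_k, fpr_s)
  expect_gt(fpr_s, 0) # the raw rate is genuinely non-null at this sizing
})

test_that("coverage-fraction queries rank accessions and attach metadata", {
  fxA <- clean_assembly(len = 5000, k = 31, seed = 401, coverage = 10)
  fxB <- clean_assembly(len = 5000, k = 31, seed = 411, coverage = 10)
  manifest <- data.frame(accession_id = c("A", "B"),
                         organism = c("metagenome", "soil metagenome"),
                         stringsAsFactors = FALSE)
  idx <- build_search_index(
    list(A = fxA$graph$unitigs$seq, B = fxB$graph$unitigs$seq),
    manifest = manifest)
  # an indexed unitig queries back at fraction 1.0
  q <- substr(fxA$graph$unitigs$seq[1], 1, 400)
  hits <- query_index(idx, q, threshold = 0.5)
  expect_equal(hits$accession_id[1], "A")
  expect_equal(hits$fraction[1], 1.0)
  expect_equal(hits$organism[1], "metagenome")
  # half-genomic, half-random query: fraction = genomic windows / total
  q2 <- paste0(substr(fxA$genome, 1001, 1300),
               simulate_genome(300, seed = 403))
  h2 <- query_index(idx, q2, threshold = 0.3)
  expect_equal(h2$accession_id, "A")
  expect_equal(h2$n_total, 570)
  expect_lt(abs(h2$fraction - 270 / 570), 0.02) # FPR headroom
  # empty index, no hits
  idx0 <- build_search_index(list(Z = character(0)))
  expect_equal(nrow(query_index(idx0, q, threshold = 0.1)), 0L)
})

test_that("query validation enforces length limits and a user-set threshold", {
  idx <- build_search_index(list(A = "ACTTAGCACTTAGCACTTAGCACTTAGCACTTAGC"),
                            spec = index_spec())
  expect_error(query_index(idx, "ACGT", 0.5), "shorter than k")
  long_q <- strrep("ACGT", 300) # 1200 nt > the 1 kb default
  expect_error(query_index(idx, long_q, 0.5), "1000 nt")
  expect_silent(query_index(idx, long_q, 0.5, allow_long = TRUE))
  expect_error(query_index(idx, strrep("ACGT", 10)), "threshold")
  expect_error(build_search_index(list("a", "b")), "named")
  expect_error(
    build_search_index(stats::setNames(list("ACGT", "ACGT"), c("x", "x"))),
    "unique")
})

test_that("matching sequences are extracted exactly, with shared counts", {
  fx <- clean_assembly(len = 4000, k = 21, seed = 421)
  g <- assemble_unitigs(c(fx$reads), k = 21)
  seqs <- g$unitigs$seq
  # substring query of one unitig -> that unitig only
  q <- substr(seqs[1], 10, 80)
  m <- extract_matching_sequences(seqs, q, k = 21)
  expect_equal(m$seq, seqs[1])
  expect_equal(m$shared_kmers, 71 - 21 + 1)
  # no shared k-mers -> empty
  m0 <- extract_matching_sequences(seqs, simulate_genome(100, seed = 422),
                                   k = 21)
  expect_equal(nrow(m0), 0L)
  # query spanning a junction of two unitigs returns both, counts matching
  # a brute-force canonical set intersection
  gf <- assemble_unitigs(c("AAACGTAC", "AAACGTAC", "AAATG", "AAATG"), k = 3)
  q2 <- "AAACG"
  m2 <- extract_matching_sequences(gf$unitigs$seq, q2, k = 3)
  brute <- vapply(gf$unitigs$seq, function(s) {
    length(intersect(canonical_kmer(naive_windows(s, 3)),
                     canonical_kmer(naive_windows(q2, 3))))
  }, integer(1))
  expect_setequal(m2$seq, gf$unitigs$seq[brute >= 1])
  expect_equal(sort(m2$shared_kmers), sort(unname(brute[brute >= 1])))
})

test_that("index container round-trips losslessly and rejects corruption", {
  fx <- clean_assembly(len = 2000, k = 31, seed = 431)
  manifest <- data.frame(accession_id = "A", biome = "marine",
                         stringsAsFactors = FALSE)
  idx <- build_search_index(list(A = fx$graph$unitigs$seq), manifest)
  path <- withr::local_tempfile(fileext = ".utgridx")
  save_index(idx, path)
  idx2 <- load_index(path)
  q <- substr(fx$genome, 101, 500)
  expect_identical(query_index(idx, q, 0.5), query_index(idx2, q, 0.5))
  expect_equal(idx2$manifest$biome, "marine")
  expect_identical(idx2$filters$A$bits, idx$filters$A$bits)
  # truncation and bad magic are load errors
  raw <- readBin(path, "raw", file.size(path))
  trunc <- withr::local_tempfile()
  writeBin(raw[1:20], trunc)
  expect_error(load_index(trunc), "truncat|corrupt")
  bad <- withr::local_tempfile()
  writeBin(c(charToRaw("NOTANIDX"), raw[-(1:8)]), bad)
  expect_error(load_index(bad), "magic")
})

test_that("index bytes and query results are deterministic", {
  fx <- clean_assembly(len = 1500, k = 31, seed = 441)
  f1 <- build_accession_filter(fx$graph$unitigs$seq, "A")
  f2 <- build_accession_filter(fx$graph$unitigs$seq, "A")
  expect_identical(f1$bits, f2$bits)
})
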