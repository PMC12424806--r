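params21 <- simplify_params(21)

test_that("tip clipping removes error spurs but never genuine dead ends", {
  fx <- clean_assembly(len = 2000, k = 21, seed = 51)
  # one erroneous read, duplicated so its k-mers stay solid; the error sits
  # near the read end so the error path dead-ends (a spur, not a bubble)
  bad <- fx$reads[which(nchar(fx$reads) == 100)[1]]
  substr(bad, 95, 95) <- setdiff(c("A", "C", "G", "T"),
                                 substr(bad, 95, 95))[1]
  g <- assemble_unitigs(c(fx$reads, bad, bad), k = 21)
  expect_gt(nrow(g$unitigs), 1L)
  gt <- clip_tips(g, params21)
  expect_equal(nrow(gt$unitigs), 1L)
  expect_true(same_up_to_strand(gt$unitigs$seq, fx$genome))

  # a clean single-unitig graph has two dead ends: never clipped
  g0 <- fx$graph
  expect_identical(clip_tips(g0, params21)$unitigs$seq, g0$unitigs$seq)
})

test_that("bubble popping collapses under-covered branches, keeps balanced ones", {
  g1 <- simulate_genome(3000, seed = 77, unique_kmers_k = 21)
  alt <- setdiff(c("A", "C", "G", "T"), substr(g1, 1500, 1500))[1]
  g2 <- inject_variant(g1, 1500, alt)
  mk <- function(c1, c2, s) c(
    simulate_reads(g1, coverage = c1, read_length = 100, seed = s),
    simulate_reads(g2, coverage = c2, read_length = 100, seed = s + 1))
  # 16:4 -> minor/major = 0.25 <= 0.5: collapse to the major allele
  gb <- assemble_unitigs(mk(16, 4, 78), k = 21)
  expect_equal(nrow(gb$unitigs), 4L) # two anchors + two branches
  popped <- pop_bubbles(gb, params21)
  expect_equal(nrow(popped$unitigs), 1L)
  expect_true(same_up_to_strand(popped$unitigs$seq, g1))
  # 10:10 -> ratio 1.0 > 0.5: both branches retained
  gbal <- assemble_unitigs(mk(10, 10, 90), k = 21)
  expect_equal(nrow(pop_bubbles(gbal, params21)$unitigs),
               nrow(gbal$unitigs))
  # graph without parallel paths is untouched
  fx <- clean_assembly(len = 1000, k = 21, seed = 91)
  expect_identical(pop_bubbles(fx$graph, params21)$unitigs$seq,
                   fx$graph$unitigs$seq)
})

test_that("weak links are cut at chimeric junctions, not in uniform graphs", {
  gA <- simulate_genome(2000, seed = 301, unique_kmers_k = 21)
  gB <- simulate_genome(2000, seed = 302, unique_kmers_k = 21)
  reads <- c(simulate_reads(gA, coverage = 30, read_length = 100, seed = 303),
             simulate_reads(gB, coverage = 30, read_length = 100, seed = 304))
  chim <- paste0(substr(gA, 900, 949), substr(gB, 1000, 1049))
  g <- assemble_unitigs(c(reads, chim, chim), k = 21)
  expect_gt(nrow(g$unitigs), 2L) # the chimera bridges the genomes
  gs <- simplify(g)
  cc <- emit_contigs(gs)
  expect_equal(nrow(cc), 2L)
  expect_equal(sum(same_up_to_strand(cc$seq, gA)), 1L)
  expect_equal(sum(same_up_to_strand(cc$seq, gB)), 1L)

  # uniform-coverage graph: nothing to cut
  fx <- clean_assembly(len = 1500, k = 21, seed = 305)
  gw <- remove_weak_links(fx$graph, params21)
  expect_identical(gw$unitigs$seq, fx$graph$unitigs$seq)

  # ratio exactly at the threshold is retained (strict inequality): force
  # abundances 3 vs 30 on a two-unitig junction
  fork <- assemble_unitigs(c("AAACG", "AAACG", "AAATG", "AAATG"), k = 3,
                           min_count = 1)
  fork$unitigs$mean_abund <- c(30, 3, 30)[seq_len(nrow(fork$unitigs))]
  p <- simplify_params(3, weak_link_ratio = 0.1)
  expect_identical(remove_weak_links(fork, p)$unitigs$seq,
                   fork$unitigs$seq)
})

test_that("simplification reaches an idempotent fixpoint and recovers genomes", {
  fx <- clean_assembly(len = 2000, k = 21, seed = 61)
  expect_identical(simplify(fx$graph)$unitigs$seq, fx$graph$unitigs$seq)

  gg <- simulate_genome(5000, seed = 62, unique_kmers_k = 21)
  rr <- simulate_reads(gg, coverage = 30, read_length = 100,
                       error_rate = 0.01, seed = 63)
  g <- simplify(assemble_unitigs(rr, k = 21))
  cc <- emit_contigs(g)
  expect_equal(nrow(cc), 1L)
  expect_true(same_up_to_strand(cc$seq, gg))
  # fixpoint idempotence
  g2 <- simplify(g)
  expect_identical(g2$unitigs$seq, g$unitigs$seq)

  # monotone shrinkage: simplification never grows total sequence
  expect_lte(sum(g$unitigs$length),
             sum(assemble_unitigs(rr, k = 21)$unitigs$length))
})

test_that("circularity is detected and terminal repeats trimmed", {
  fx <- clean_assembly(len = 3000, k = 21, seed = 71, circular = TRUE)
  g <- simplify(fx$graph)
  expect_equal(nrow(g$unitigs), 1L)
  expect_true(detect_circular(g))
  expect_equal(g$unitigs$length, 3000L + 20L) # genome + (k-1) duplication
  tr <- trim_terminal_repeat(g$unitigs$seq, r_min = 20)
  expect_equal(tr$r, 20L)
  expect_equal(nchar(tr$seq), 3000L)
  # the contig starts wherever compaction started: equal up to rotation
  expect_true(same_up_to_rotation(tr$seq, fx$genome))

  # linear genomes are not circular
  fl <- clean_assembly(len = 1500, k = 21, seed = 72)
  expect_false(any(detect_circular(fl$graph)))
})

test_that("terminal repeat trimming follows the prefix/suffix definition", {
  expect_equal(trim_terminal_repeat("ACGTAC", r_min = 2),
               list(seq = "ACGT", r = 2L))
  expect_equal(trim_terminal_repeat("ACGTGA", r_min = 2),
               list(seq = "ACGTGA", r = 0L))
  expect_error(trim_terminal_repeat("ACG", r_min = 2), "shorter")
})

test_that("low-complexity coverage flags tandem-repeat windows", {
  expect_equal(low_complexity_fraction("AAAAAAAAAA"), 1.0)
  expect_equal(low_complexity_fraction("ATATATATATAT"), 1.0)
  # a window with no period <= 5 run reaching length 8
  expect_equal(low_complexity_fraction("TGTTGCCTAAGCTGGACGGTCGGGCGAATCC"), 0)
  expect_true(terminal_lowcomp_artifact(
    paste0("TGTTGCCTAAGCTGGACGGTCGGG", strrep("AT", 16))))
  expect_false(terminal_lowcomp_artifact(
    paste0(strrep("AT", 16), "TGTTGCCTAAGCTGGACGGTCGGGCGAATCC")))
})

test_that("emission rules follow the default and strict truth tables", {
  mk_rec <- function(id, len, ab = 10) {
    seedling <- simulate_genome(len, seed = 400 + id)
    data.frame(id = id, seq = seedling, length = len, mean_abund = ab,
               stringsAsFactors = FALSE)
  }
  # ids: 1 short isolated linear, 2 long isolated linear,
  #      3+4 short connected pair, 5 short isolated circular
  circ_fx <- clean_assembly(len = 80, k = 21, seed = 405, circular = TRUE)
  circ <- simplify(circ_fx$graph)
  stopifnot(nrow(circ$unitigs) == 1, detect_circular(circ))
  u <- rbind(mk_rec(1, 100), mk_rec(2, 200), mk_rec(3, 100), mk_rec(4, 100),
             data.frame(id = 5, seq = circ$unitigs$seq,
                        length = circ$unitigs$length, mean_abund = 10,
                        stringsAsFactors = FALSE))
  links <- rbind(
    data.frame(from = 3, from_end = "+", to = 4, to_end = "+",
               stringsAsFactors = FALSE),
    data.frame(from = 4, from_end = "-", to = 3, to_end = "-",
               stringsAsFactors = FALSE),
    data.frame(from = 5, from_end = "+", to = 5, to_end = "+",
               stringsAsFactors = FALSE),
    data.frame(from = 5, from_end = "-", to = 5, to_end = "-",
               stringsAsFactors = FALSE))
  g <- toy_graph(u, links, k = 21)
  # default: discard only short, non-circular, isolated contigs
  def <- emit_contigs(g, min_len = 150)
  expect_setequal(def$seq, u$seq[c(2, 3, 4, 5)])
  expect_true(def$circular[match(u$seq[5], def$seq)])
  # strict: keep only long AND connected contigs
  st <- emit_contigs(g, min_len = 150, strict = TRUE)
  expect_equal(nrow(st), 0L) # contig 2 is long but isolated
  # a long connected contig passes strict
  u2 <- rbind(mk_rec(1, 200), mk_rec(2, 100))
  links2 <- rbind(
    data.frame(from = 1, from_end = "+", to = 2, to_end = "+",
               stringsAsFactors = FALSE),
    data.frame(from = 2, from_end = "-", to = 1, to_end = "-",
               stringsAsFactors = FALSE))
  st2 <- emit_contigs(toy_graph(u2, links2, k = 21), min_len = 150,
                      strict = TRUE)
  expect_equal(st2$seq, u2$seq[1])
})

test_that("simplification agrees with exhaustive search on small graphs", {
  # exhaustive tip oracle: dead-end unitigs shorter than the cap whose
  # junction offers a strictly better-covered competing branch
  for (seed in c(81, 82, 83, 84)) {
    gg <- simulate_genome(1500, seed = seed)
    rr <- simulate_reads(gg, coverage = 25, read_length = 80,
                         error_rate = 0.008, seed = seed + 10)
    g <- assemble_unitigs(rr, k = 15)
    p <- simplify_params(15)
    u <- g$unitigs; L <- g$links
    deg <- function(id, e) sum(L$from == id & L$from_end == e)
    expected_tips <- Filter(function(id) {
      i <- match(id, u$id)
      dp <- deg(id, "+"); dm <- deg(id, "-")
      if (!xor(dp == 0, dm == 0) || u$length[i] > p$tip_len_max)
        return(FALSE)
      e <- if (dp > 0) "+" else "-"
      att <- L[L$from == id & L$from_end == e & L$to != id, , drop = FALSE]
      comp <- unlist(lapply(seq_len(nrow(att)), function(j) {
        ae <- ifelse(att$to_end[j] == "+", "-", "+")
        L$to[L$from == att$to[j] & L$from_end == ae & L$to != id]
      }))
      any(u$mean_abund[match(comp, u$id)] > u$mean_abund[i])
    }, u$id)
    gt <- clip_tips(g, p)
    kept <- unitigr:::cpp_count_canonical(gt$unitigs$seq, 15)$kmer
    removed_kmers <- unitigr:::cpp_count_canonical(
      u$seq[u$id %in% expected_tips], 15)$kmer
    expect_length(intersect(kept, removed_kmers), 0L)
    expect_setequal(kept, setdiff(
      unitigr:::cpp_count_canonical(u$seq, 15)$kmer, removed_kmers))
  }
})
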