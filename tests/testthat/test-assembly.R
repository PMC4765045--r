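test_that("N-runs are tracked and sequences validated", {
  cs <- contig_seq("c1", "ACGTNNNACGTNACGNNN")
  expect_equal(cs$n_runs$start, c(5L, 12L, 16L))
  expect_equal(cs$n_runs$len, c(3L, 1L, 3L))
  expect_equal(nrow(contig_seq("c2", "ACGT")$n_runs), 0)
  expect_error(contig_seq("c3", "ACGU"), "A, C, G, T, N")
})

test_that("locus classification distinguishes the three cases", {
  toy_i <- make_toy_locus(1, "i")
  plan_i <- classify_locus(solve_toy(toy_i), toy_i$hits)[["pg1"]]
  expect_equal(plan_i$case, "i")

  toy_ii <- make_toy_locus(2, "ii")
  plan_ii <- classify_locus(solve_toy(toy_ii), toy_ii$hits)[["pg1"]]
  expect_equal(plan_ii$case, "ii")
  expect_equal(plan_ii$order, c("cA", "cB"))

  # interleaving pattern: host carries all exons but one interior exon,
  # which sits on its own small contig
  toy_iii <- make_toy_locus(3, "iii")
  plan_iii <- classify_locus(solve_toy(toy_iii), toy_iii$hits)[["pg1"]]
  expect_equal(plan_iii$case, "iii")
  expect_equal(plan_iii$inserts$host[1], "cA")
  expect_equal(plan_iii$order, "cA")
})

test_that("out-of-order TCE hits are flagged, not planned", {
  toy <- make_toy_locus(4, "i")
  h <- toy$hits
  # swap the coordinates of exons 2 and 3 so the order along the contig
  # contradicts the TCE numbering
  i2 <- which(h$tce_type == 2); i3 <- which(h$tce_type == 3)
  tmp <- h[i2, c("contig_start", "contig_end")]
  h[i2, c("contig_start", "contig_end")] <- h[i3, c("contig_start", "contig_end")]
  h[i3, c("contig_start", "contig_end")] <- tmp
  plan <- classify_locus(solve_toy(toy), h)[["pg1"]]
  expect_equal(plan$case, "flagged")
  expect_match(plan$reason, "order")
  expect_error(assemble_locus(plan, list(), h), "manual review")
})

test_that("concatenation handles strand and spacers", {
  expect_equal(concat_fragments(c("ACGT", "TTAA"), spacer_n = 2),
               "ACGTNNTTAA")
  # hand reverse-complement of a 10-nt toy sequence
  expect_equal(concat_fragments(c("AAAA", "ACGTACGTTG"), c("+", "-"),
                                spacer_n = 0),
               paste0("AAAA", "CAACGTACGT"))
  expect_equal(concat_fragments("ACGT"), "ACGT")
  # length invariant: sum of fragments plus spacers
  s <- concat_fragments(c("ACGT", "TT", "GGG"), spacer_n = 5)
  expect_equal(nchar(s), 4 + 2 + 3 + 2 * 5)
})

test_that("interleaving substitutes N-runs of three or more", {
  host <- contig_seq("h", paste0("AAAA", "NNNNN", "TTTT"))
  r <- interleave_contigs(host, "CCC", window_start = 5, window_end = 9)
  expect_equal(r$mode, "n_run")
  expect_equal(r$seq, "AAAACCCTTTT")
  # the longest run wins, leftmost on ties
  host2 <- contig_seq("h", "AANNNAANNNNAA")
  r2 <- interleave_contigs(host2, "CC", 1, 13)
  expect_equal(r2$seq, "AANNNAACCAA")
  # runs shorter than 3 do not count
  host3 <- contig_seq("h", "AAANNAAA")
  r3 <- interleave_contigs(host3, "CC", 2, 7, flank_n = 3)
  expect_equal(r3$mode, "padded")
  expect_error(interleave_contigs(host, "C", 6, 5), "empty insertion window")
})

test_that("padded insertion lands at the window midpoint with N flanks", {
  host <- contig_seq("h", strrep("A", 20))
  r <- interleave_contigs(host, "GGG", window_start = 5, window_end = 15,
                          flank_n = 4)
  expect_equal(r$mode, "padded")
  expect_equal(r$offset$edit_start, 10)
  expect_equal(r$seq, paste0(strrep("A", 9), "NNNNGGGNNNN", strrep("A", 11)))
  expect_equal(nchar(r$seq), 20 + 3 + 8)
})

test_that("offset maps relocate outside coordinates exactly", {
  host <- contig_seq("h", "ACGTACNNNNNGTACGT")
  r <- interleave_contigs(host, "TTT", 6, 12)
  old <- host$seq; new <- r$seq
  for (pos in c(1, 3, 6)) {
    expect_equal(substr(new, map_offset(r$offset, pos),
                        map_offset(r$offset, pos)),
                 substr(old, pos, pos))
  }
  for (pos in c(12, 17)) {
    expect_equal(substr(new, map_offset(r$offset, pos),
                        map_offset(r$offset, pos)),
                 substr(old, pos, pos))
  }
  expect_error(map_offset(r$offset, 8), "edited window")
  # only the N-run was removed: merged is host prefix + insert + host suffix
  expect_equal(new, paste0(substr(old, 1, 6), "TTT", substr(old, 12, 17)))
})

test_that("assembled loci contain every planted exon exactly once in order", {
  for (seed in 1:12) {
    ct <- c("i", "ii", "iii")[(seed %% 3) + 1]
    toy <- make_toy_locus(seed + 100, ct,
                          n_gap_run = seed %% 2 == 0,
                          minus_strand = seed %% 4 == 0)
    plan <- classify_locus(solve_toy(toy), toy$hits)[["pg1"]]
    expect_equal(plan$case, ct, info = paste("seed", seed))
    merged <- assemble_locus(plan, toy$seqs, toy$hits)
    pos <- exon_positions(merged$seq, toy$exons)
    expect_true(all(pos > 0), info = paste("seed", seed))
    expect_true(!is.unsorted(pos, strictly = TRUE),
                info = paste("seed", seed))
  }
})
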