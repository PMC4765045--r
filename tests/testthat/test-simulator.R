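tiny_params <- function(...) sim_params(n_paralogs = 3, n_exons = 2,
                                        exon_len_meanlog = log(30), ...)

test_that("zero divergence reproduces the ancestor in every copy", {
  p <- tiny_params(paralog_branch = 0, exon_branch = 0, indel_rate = 0)
  fam <- simulate_family(p, seed = 9)
  anc <- fam$query_exons[[1]]
  for (pg in fam$paralog_ids) {
    expect_identical(fam$query_exons[[pg]], anc)
    expect_identical(fam$target_exons[[pg]], anc)
  }
})

test_that("families are deterministic under a fixed seed", {
  p <- sim_params()
  f1 <- simulate_family(p, seed = 5)
  f2 <- simulate_family(p, seed = 5)
  expect_identical(f1$query_proteins, f2$query_proteins)
  expect_identical(f1$target_exons, f2$target_exons)
  f3 <- simulate_family(p, seed = 6)
  expect_false(identical(f1$query_proteins, f3$query_proteins))
  # defaults: 8 paralogs x 12 exons = 96 target exons
  expect_equal(sum(lengths(f1$target_exons)), 96)
})

test_that("fragmentation hits the requested exons-per-fragment level", {
  p <- tiny_params()
  fam <- simulate_family(sim_params(), seed = 2)
  # level = n_exons: one fragment per paralog
  fr <- fragment_family(fam, 12, seed = 1)
  expect_equal(nrow(fr$fragments), 8)
  expect_equal(fr$realized_level, 12)
  # level = 1: every exon its own fragment
  fr1 <- fragment_family(fam, 1, seed = 1)
  expect_equal(nrow(fr1$fragments), 96)
  expect_true(all(fr1$fragments$exon_start == fr1$fragments$exon_end))
  # fragments of different paralogs are never merged; exon order preserved
  expect_true(all(fr1$fragments$paralog_id == fr1$truth))
  # expected exons per fragment converges to the level (12 exons, level 4)
  rl <- vapply(1:400, function(s)
    fragment_family(fam, 4, seed = s)$realized_level, numeric(1))
  expect_lt(abs(mean(rl) - 4) / 4, 0.1)
  expect_error(fragment_family(fam, 0), "level > 0")
})

test_that("self scores dominate cross-paralog scores at positive divergence", {
  for (seed in 1:25) {
    fam <- simulate_family(tiny_params(), seed = seed)
    fr <- fragment_family(fam, 2, seed = seed)
    hits <- score_hits(fam, fr, evalue_max = Inf)
    for (k in seq_len(fam$params$n_exons)) {
      h <- hits[hits$tce_type == k, , drop = FALSE]
      for (pg in fam$paralog_ids) {
        self <- h$bitscore[h$paralog_id == pg & grepl(pg, h$contig_id)]
        cross <- h$bitscore[h$paralog_id != pg & grepl(pg, h$contig_id)]
        if (length(self) == 1 && length(cross) > 0)
          expect_gte(self, max(cross))  # discrete scores allow exact ties
      }
    }
  }
})

test_that("scoring respects the E-value emulation and empty inputs", {
  fam <- simulate_family(tiny_params(), seed = 3)
  fr <- fragment_family(fam, 2, seed = 3)
  empty <- fr
  empty$fragments <- fr$fragments[0, , drop = FALSE]
  expect_equal(nrow(score_hits(fam, empty)), 0)
  all_hits <- score_hits(fam, fr, evalue_max = Inf)
  cut_hits <- score_hits(fam, fr, evalue_max = 1e-4)
  expect_true(nrow(cut_hits) <= nrow(all_hits))
  expect_true(all(cut_hits$evalue < 1e-4))
})

test_that("full-length scores are maximal for identical sequences", {
  p <- tiny_params(paralog_branch = 0, exon_branch = 0, indel_rate = 0)
  fam <- simulate_family(p, seed = 4)
  fr <- fragment_family(fam, p$n_exons, seed = 1)
  fl <- score_full_length(fam, fr)
  # zero divergence: every query aligns perfectly to every unit of the same
  # concatenated length, so all scores within a unit are equal and maximal
  for (u in unique(fl$unit_id)) {
    s <- fl$score[fl$unit_id == u]
    expect_equal(diff(range(s)), 0)
  }
})

test_that("a one-replicate benchmark is reproducible and well-formed", {
  p <- tiny_params()
  r1 <- run_benchmark(p, levels = c(2, 1), reps = 2, seed = 11)
  r2 <- run_benchmark(p, levels = c(2, 1), reps = 2, seed = 11)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  expect_setequal(r1$method, c("ilp", "greedy"))
  expect_equal(nrow(r1), 4)
  expect_true(all(r1$mean_accuracy >= 0 & r1$mean_accuracy <= 1))
})

test_that("simulated families export as FASTA plus truth table", {
  fam <- simulate_family(tiny_params(), seed = 8)
  fr <- fragment_family(fam, 1, seed = 8)
  qp <- withr::local_tempfile(fileext = ".fa")
  fp <- withr::local_tempfile(fileext = ".fa")
  tp <- withr::local_tempfile(fileext = ".tsv")
  write_family_fasta(fam, fr, query_path = qp, fragment_path = fp,
                     truth_path = tp)
  q <- Biostrings::readAAStringSet(qp)
  expect_equal(length(q), 3)
  f <- Biostrings::readAAStringSet(fp)
  expect_equal(length(f), nrow(fr$fragments))
  expect_equal(nrow(utils::read.table(tp, header = TRUE)), nrow(fr$fragments))
})
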