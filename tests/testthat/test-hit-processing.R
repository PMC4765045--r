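blast_line <- function(q = "ARRB1_3", s = "contig7", qs = 1, qe = 60,
                       ss = 100, se = 279, ev = "3e-20", bs = "85.1") {
  paste(q, s, "95.0", "60", "3", "0", qs, qe, ss, se, ev, bs, sep = "\t")
}

test_that("BLAST tabular parsing maps fields and converts coordinates", {
  expect_equal(nrow(parse_blast_tab(character(0))), 0)

  ht <- parse_blast_tab(blast_line(ev = "3e-20", bs = "85.1"))
  expect_equal(ht$paralog_id, "ARRB1")
  expect_equal(ht$tce_type, 3L)
  expect_equal(ht$evalue, 3e-20)
  expect_equal(ht$bitscore, 85.1)
  expect_equal(ht$strand, "+")
  expect_equal(ht$contig_start, 99L)   # 1-based 100 -> 0-based 99
  expect_equal(ht$contig_end, 279L)

  # minus strand: sstart > send
  htm <- parse_blast_tab(blast_line(ss = 900, se = 700))
  expect_equal(htm$strand, "-")
  expect_equal(htm$contig_start, 699L)
  expect_equal(htm$contig_end, 900L)
})

test_that("BLAST parsing errors name the offending line or query", {
  bad <- c(blast_line(), "only\tthree\tcolumns")
  expect_error(parse_blast_tab(bad), "line 2")
  expect_error(parse_blast_tab(blast_line(q = "noexonnumber")),
               "noexonnumber")
})

domtbl_line <- function(target = "contig7", model = "SAG_2", score = "55.2",
                        iev = "4.1e-17") {
  paste(target, "-", "300", model, "-", "60", "1e-20", "60.1", "0.1",
        "1", "2", "1e-18", iev, score, "0.1", "5", "58", "101", "155",
        "98", "160", "0.95", "-", sep = " ")
}

test_that("HMMER domain-table parsing keeps one hit per domain row", {
  expect_equal(nrow(parse_hmmer_domtbl(c("# comment", "#"))), 0)

  ht <- parse_hmmer_domtbl(domtbl_line())
  expect_equal(ht$paralog_id, "SAG")
  expect_equal(ht$tce_type, 2L)
  expect_equal(ht$bitscore, 55.2)      # per-domain score
  expect_equal(ht$evalue, 4.1e-17)     # independent E-value
  expect_equal(ht$contig_start, 100L)
  expect_equal(ht$contig_end, 155L)

  two <- parse_hmmer_domtbl(c("# hdr", domtbl_line(), domtbl_line(score = "12.0")))
  expect_equal(nrow(two), 2)
})

test_that("the E-value filter keeps rows strictly below the threshold", {
  ht <- hit_table(contig_id = c("c1", "c2"), paralog_id = c("p1", "p1"),
                  tce_type = c(1L, 1L), bitscore = c(50, 40),
                  evalue = c(1e-5, 0.5), contig_start = 0L, contig_end = 5L,
                  strand = "+", query_cov_len = 10L)
  expect_equal(nrow(filter_evalue(ht, 1e-4)), 1)
  expect_equal(filter_evalue(ht, 1e-4)$contig_id, "c1")
  expect_equal(nrow(filter_evalue(ht, 1)), 2)        # above all evalues
  expect_equal(nrow(filter_evalue(hit_table(), 1e-4)), 0)
  # E-value filtering commutes with concatenation
  a <- ht[1, , drop = FALSE]; b <- ht[2, , drop = FALSE]
  both <- filter_evalue(ht, 1e-3)
  expect_equal(nrow(both),
               nrow(filter_evalue(structure(a, class = class(ht),
                                            provenance = "simulated"), 1e-3)) +
               nrow(filter_evalue(structure(b, class = class(ht),
                                            provenance = "simulated"), 1e-3)))
})

test_that("singleton filtering drops only low-density lone hits", {
  mk <- function(contigs, scores, lens) {
    hit_table(contig_id = contigs, paralog_id = "p1",
              tce_type = seq_along(contigs), bitscore = scores,
              evalue = 1e-9, contig_start = 0L, contig_end = 5L,
              strand = "+", query_cov_len = lens)
  }
  # two weak hits sharing a contig are kept
  comp <- mk(c("c1", "c1"), c(10, 12), c(60L, 60L))
  expect_equal(nrow(filter_singletons(comp, 1.0)), 2)
  # lone hit at 30/60 = 0.5 bits/res dropped, 90/60 = 1.5 kept
  expect_equal(nrow(filter_singletons(mk("c1", 30, 60L), 1.0)), 0)
  expect_equal(nrow(filter_singletons(mk("c1", 90, 60L), 1.0)), 1)
  expect_error(filter_singletons(mk("c1", 30, 0L), 1.0), "query_cov_len")
})

test_that("TCE grouping thresholds on the same-paralog background", {
  # background scores {2,2,2,2} with z = 2: sd 0 so cutoff is exactly 2
  bg <- expand.grid(exon_a = 1:2, exon_b = 1:2)
  bg <- bg[bg$exon_a != bg$exon_b, ]
  mk_bg <- function(p) data.frame(paralog_a = p, exon_a = c(1, 2, 1, 2),
                                  paralog_b = p, exon_b = c(2, 1, 2, 1),
                                  score = 2)
  cross <- function(score_e1, score_e2) data.frame(
    paralog_a = "A", exon_a = 1:2, paralog_b = "B", exon_b = 1:2,
    score = c(score_e1, score_e2))
  lens <- expand.grid(paralog = c("A", "B"), exon = 1:2)
  lens$len <- 50

  g <- group_homologous_tces(rbind(mk_bg("A"), mk_bg("B"), cross(5, 1.5)),
                             z = 2, min_len = 10, exon_lens = lens)
  expect_equal(unname(g$cutoffs), c(2, 2))
  grp <- g$groups
  # score 5 > 2 links A1-B1; score 1.5 does not link A2-B2
  expect_equal(grp$tce_group[grp$paralog == "A" & grp$exon == 1],
               grp$tce_group[grp$paralog == "B" & grp$exon == 1])
  expect_false(grp$tce_group[grp$paralog == "A" & grp$exon == 2] ==
               grp$tce_group[grp$paralog == "B" & grp$exon == 2])
  # a partition: every retained exon in exactly one group
  expect_equal(nrow(grp), 4)
  expect_false(any(duplicated(grp[, c("paralog", "exon")])))

  # perfect homology: groups are the exon ordinals
  g2 <- group_homologous_tces(rbind(mk_bg("A"), mk_bg("B"), cross(9, 9)),
                              z = 2, min_len = 10, exon_lens = lens)
  expect_equal(g2$n_groups, 2)
  expect_equal(g2$groups$tce_group[g2$groups$exon == 1], c(1L, 1L))
  expect_equal(g2$groups$tce_group[g2$groups$exon == 2], c(2L, 2L))

  # short exons are excluded from every group
  lens3 <- lens; lens3$len[lens3$paralog == "B" & lens3$exon == 2] <- 4
  g3 <- group_homologous_tces(rbind(mk_bg("A"), mk_bg("B"), cross(9, 9)),
                              z = 2, min_len = 10, exon_lens = lens3)
  expect_false(any(g3$groups$paralog == "B" & g3$groups$exon == 2))

  # a background with fewer than two values is an error
  tiny <- data.frame(paralog_a = "A", exon_a = 1, paralog_b = "A",
                     exon_b = 2, score = 2)
  expect_error(group_homologous_tces(tiny, 2, 10, lens), "background")
})
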