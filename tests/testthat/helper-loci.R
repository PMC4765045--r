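# toy locus builder for assembly tests: plant known exon sequences on
# contigs with case i / ii / iii structure and return sequences + hits +
# the planted truth

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# build one paralog locus; `case_type` in c("i", "ii", "iii");
# for case iii, `n_gap_run` decides whether the host gap window carries an
# N-run of >= 3 (substitution mode) or not (padded mode)
make_toy_locus <- function(seed, case_type, n_exons = 6, exon_len = 40,
                           n_gap_run = TRUE, minus_strand = FALSE) {
  set.seed(seed)
  exons <- vapply(seq_len(n_exons), function(i) rand_dna(exon_len), "")
  pid <- "pg1"
  hit_rows <- list(); seqs <- list()
  add_hits <- function(contig_id, tces, starts, strand = "+") {
    for (t in seq_along(tces)) {
      hit_rows[[length(hit_rows) + 1L]] <<- data.frame(
        contig_id = contig_id, paralog_id = pid, tce_type = tces[t],
        bitscore = 50, evalue = 1e-20,
        contig_start = starts[t], contig_end = starts[t] + exon_len,
        strand = strand, query_cov_len = exon_len)
    }
  }
  place <- function(tces, spacer_len = 10) {
    # plus-strand virtual contig carrying `tces` separated by spacers
    parts <- character(); starts <- integer(); pos <- 0L
    for (k in tces) {
      sp <- rand_dna(spacer_len)
      parts <- c(parts, sp, exons[k])
      starts <- c(starts, pos + spacer_len)
      pos <- pos + spacer_len + exon_len
    }
    list(seq = paste(parts, collapse = ""), starts = starts)
  }

  if (case_type == "i") {
    p <- place(seq_len(n_exons))
    seqs[["cA"]] <- p$seq
    add_hits("cA", seq_len(n_exons), p$starts)
  } else if (case_type == "ii") {
    cut <- sample(2:(n_exons - 1), 1)
    runs <- list(1:cut, (cut + 1):n_exons)
    ids <- c("cA", "cB")
    for (ci in 1:2) {
      p <- place(runs[[ci]])
      if (minus_strand && ci == 2) {
        L <- nchar(p$seq)
        seqs[[ids[ci]]] <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(p$seq)))
        add_hits(ids[ci], runs[[ci]],
                 L - (p$starts + exon_len), strand = "-")
      } else {
        seqs[[ids[ci]]] <- p$seq
        add_hits(ids[ci], runs[[ci]], p$starts)
      }
    }
  } else { # case iii: host misses one interior exon, carried by the insert
    gap <- sample(2:(n_exons - 1), 1)
    host_tces <- setdiff(seq_len(n_exons), gap)
    parts <- character(); pos <- 0L; starts <- integer()
    for (k in host_tces) {
      sp <- rand_dna(10)
      parts <- c(parts, sp, exons[k]); starts <- c(starts, pos + 10L)
      pos <- pos + 10L + exon_len
      if (k == gap - 1L) { # the gap window follows this exon
        win <- if (n_gap_run) paste0(rand_dna(10), strrep("N", 6), rand_dna(10))
               else rand_dna(20)
        parts <- c(parts, win); pos <- pos + nchar(win)
      }
    }
    seqs[["cA"]] <- paste(parts, collapse = "")
    add_hits("cA", host_tces, starts)
    p <- place(gap)
    seqs[["cH"]] <- p$seq
    add_hits("cH", gap, p$starts)
  }
  hits <- do.call(rbind, hit_rows)
  hits <- do.call(hit_table, c(as.list(hits), provenance = "simulated"))
  list(exons = exons, seqs = seqs, hits = hits, paralog = pid,
       case_type = case_type)
}

# positions (or -1) of each planted exon in a merged sequence
exon_positions <- function(merged, exons) {
  vapply(exons, function(e) {
    m <- gregexpr(e, merged, fixed = TRUE)[[1]]
    if (m[1] == -1) -1L else if (length(m) > 1) -2L else as.integer(m[1])
  }, integer(1))
}

solve_toy <- function(toy) {
  inst <- build_instance(toy$hits, 1, max(toy$hits$tce_type))
  solve_pcap(inst)
}
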