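# fixtures built in code: random PCAP instances and the spec'd toy cases

# small random instance; guaranteed to contain at least one positive score
random_instance <- function(seed, max_contigs = 4, max_paralogs = 3,
                            max_tces = 4, density = 0.45) {
  set.seed(seed)
  n <- sample(2:max_contigs, 1)
  P <- sample(2:max_paralogs, 1)
  m <- sample(2:max_tces, 1)
  repeat {
    theta <- array(0, dim = c(n, P, m))
    pos <- stats::runif(n * P * m) < density
    theta[pos] <- round(stats::runif(sum(pos), 1, 20), 2)
    if (all(apply(theta > 0, 1, any))) break  # every contig has a hit
  }
  pcap_instance(theta)
}

# the 2x2 "diagonal" instance: one TCE type, diagonal scores 5, off 4
diagonal_instance <- function() {
  th <- array(0, c(2, 2, 1))
  th[1, 1, 1] <- 5; th[1, 2, 1] <- 4
  th[2, 1, 1] <- 4; th[2, 2, 1] <- 5
  pcap_instance(th)
}

simple_hits <- function(...) {
  rows <- list(...)
  do.call(hit_table, c(
    list(contig_id = vapply(rows, `[[`, "", 1),
         paralog_id = vapply(rows, `[[`, "", 2),
         tce_type = as.integer(vapply(rows, function(r) r[[3]], 1)),
         bitscore = vapply(rows, function(r) r[[4]], 1),
         evalue = 1e-10, contig_start = 0L, contig_end = 10L,
         strand = "+", query_cov_len = 10L),
    provenance = "simulated"))
}

edges_complete <- function(n) t(utils::combn(n, 2))
edges_cycle <- function(n) cbind(seq_len(n), c(seq_len(n)[-1], 1))
edges_petersen <- function() {
  outer <- cbind(1:5, c(2:5, 1))
  inner <- cbind(6:10, c(8, 9, 10, 6, 7))
  spokes <- cbind(1:5, 6:10)
  rbind(outer, inner, spokes)
}
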