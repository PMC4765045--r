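# Synthetic paralogous-family generator and fragmentation benchmark.
#
# A random ancestral protein is decomposed into exons; paralogs arise on a
# star tree by per-exon substitution + indel evolution; each paralog's exons
# then diverge independently into a "query" and a "target" species copy.
# Target exons are distributed over fragments (units) at a chosen
# fragmentation level and scored against the query TCEs, producing the input
# of the assignment problem with a known truth map.

# BLOSUM-style amino acid background frequencies
aa_alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
aa_freqs <- c(0.078, 0.051, 0.045, 0.054, 0.019, 0.043, 0.063, 0.074,
              0.022, 0.051, 0.091, 0.057, 0.022, 0.039, 0.052, 0.071,
              0.058, 0.013, 0.032, 0.065)
aa_freqs <- aa_freqs / sum(aa_freqs)

# evaluate expr under a local RNG state seeded with `seed`
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulation parameters for the fragmentation benchmark
#'
#' Branch lengths are in PAM-like units: along a branch of length `b` each
#' site receives `Poisson(b / 100)` substitution events (replacement drawn
#' from the background frequencies, so a small fraction of events is
#' silent), and each site independently hosts an indel event with
#' probability `indel_rate * b` (insertion or deletion with equal
#' probability, length 1 + Geometric(1/2) residues). With the defaults the
#' paralog-generation phase (branch 50, rate 5e-4) realises about 2.5%
#' indels per sequence, and the species-divergence phase applied to each
#' exon independently (branch 20) about 1% — the regimes the benchmark is
#' designed around. Exon lengths (in residues) are drawn from a log-normal
#' (median ~40 aa, i.e. ~120 nt) truncated to `[min_exon_len,
#' max_exon_len]`; micro-exons below 15 aa are excluded because
#' similarity search cannot retrieve them reliably and they would measure
#' search sensitivity, not assignment quality.
#'
#' @param n_paralogs number of paralogs (default 8).
#' @param n_exons exons per paralog (default 12).
#' @param paralog_branch star-tree branch length to each paralog.
#' @param exon_branch per-exon branch length to each species copy.
#' @param indel_rate indel events per site per unit branch length.
#' @param exon_len_meanlog,exon_len_sdlog log-normal exon length (aa).
#' @param min_exon_len,max_exon_len truncation bounds (aa).
#' @param evalue_max E-value ceiling when scoring TCEs against fragments.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(n_paralogs = 8, n_exons = 12,
                       paralog_branch = 50, exon_branch = 20,
                       indel_rate = 5e-4,
                       exon_len_meanlog = log(40), exon_len_sdlog = 0.5,
                       min_exon_len = 15, max_exon_len = 300,
                       evalue_max = 1e-4) {
  stopifnot(n_paralogs >= 1, n_exons >= 1, paralog_branch >= 0,
            exon_branch >= 0, indel_rate >= 0, min_exon_len >= 1,
            max_exon_len >= min_exon_len, evalue_max > 0)
  structure(as.list(environment()), class = "sim_params")
}

sample_aa <- function(n) sample(aa_alphabet, n, replace = TRUE, prob = aa_freqs)

# substitution + indel evolution of one sequence (character vector of
# residues) along a branch
evolve_seq <- function(seq, branch, indel_rate) {
  n <- length(seq)
  if (n == 0 || branch == 0) return(seq)
  nev <- stats::rpois(n, branch / 100)
  hit <- which(nev > 0)
  seq[hit] <- sample_aa(length(hit))
  p_indel <- min(1, indel_rate * branch)
  ev <- which(stats::runif(n) < p_indel)
  if (length(ev) > 0) {
    out <- as.list(seq)
    for (pos in ev) {
      len <- 1L + stats::rgeom(1, 0.5)
      if (stats::runif(1) < 0.5) {
        out[[pos]] <- c(seq[pos], sample_aa(len))          # insertion after
      } else {
        for (d in pos:min(n, pos + len - 1L)) out[[d]] <- character(0)
      }
    }
    seq <- unlist(out)
  }
  if (length(seq) == 0) sample_aa(1) else seq
}

#' Simulate a paralogous gene family in two species
#'
#' Generates a random ancestral protein as a list of exons, evolves it into
#' `n_paralogs` paralogs on a star tree (`paralog_branch` per tip), and then
#' evolves every paralog exon independently into a query-species and a
#' target-species copy (`exon_branch` each). Deterministic for a fixed
#' seed.
#'
#' @param params a [sim_params()] object.
#' @param seed integer seed.
#' @return object of class `sim_family`: list with `params`, `exon_lens`
#'   (ancestral exon lengths), `paralog_ids`, `query_exons` and
#'   `target_exons` (list\[paralog\]\[\[exon\]\] of residue vectors),
#'   `query_proteins` (named character vector of concatenated query
#'   sequences), and a score cache used by [score_hits()] /
#'   [score_full_length()].
#' @export
simulate_family <- function(params, seed = 1) {
  stopifnot(inherits(params, "sim_params"))
  with_local_seed(seed, {
    lens <- integer(params$n_exons)
    for (k in seq_len(params$n_exons)) {
      repeat {
        l <- round(stats::rlnorm(1, params$exon_len_meanlog,
                                 params$exon_len_sdlog))
        if (l >= params$min_exon_len && l <= params$max_exon_len) break
      }
      lens[k] <- as.integer(l)
    }
    ancestor <- lapply(lens, sample_aa)
    pid <- sprintf("P%02d", seq_len(params$n_paralogs))
    paralog_exons <- lapply(pid, function(p)
      lapply(ancestor, evolve_seq, branch = params$paralog_branch,
             indel_rate = params$indel_rate))
    query_exons <- lapply(paralog_exons, function(ex)
      lapply(ex, evolve_seq, branch = params$exon_branch,
             indel_rate = params$indel_rate))
    target_exons <- lapply(paralog_exons, function(ex)
      lapply(ex, evolve_seq, branch = params$exon_branch,
             indel_rate = params$indel_rate))
    names(query_exons) <- names(target_exons) <- pid
    qprot <- vapply(query_exons, function(ex)
      paste(unlist(ex), collapse = ""), character(1))
    structure(list(params = params, seed = seed, exon_lens = lens,
                   paralog_ids = pid, query_exons = query_exons,
                   target_exons = target_exons, query_proteins = qprot,
                   cache = new.env(parent = emptyenv())),
              class = "sim_family")
  })
}

#' @export
print.sim_family <- function(x, ...) {
  cat(sprintf("sim_family: %d paralogs x %d exons (ancestral lengths %s aa)\n",
              x$params$n_paralogs, x$params$n_exons,
              paste(x$exon_lens, collapse = ",")))
  invisible(x)
}

#' Fragment a simulated family into genomic units
#'
#' Cuts each target paralog's ordered exon list into contiguous runs by
#' dropping a breakpoint between consecutive exons independently with
#' probability `p = (n_exons / level - 1) / (n_exons - 1)`, so the expected
#' number of exons per fragment equals `level`. `level = n_exons` gives one
#' fragment per paralog, `level = 1` puts every exon on its own fragment.
#' Fragments of different paralogs are never merged.
#'
#' @param family a [simulate_family()] result.
#' @param level target average exons per fragment, in `(0, n_exons]`.
#' @param seed integer seed.
#' @return list with `fragments` (data frame `fragment_id`, `paralog_id`,
#'   `exon_start`, `exon_end`), `truth` (named vector `fragment_id ->
#'   paralog_id`) and `realized_level`.
#' @export
fragment_family <- function(family, level, seed = 1) {
  stopifnot(inherits(family, "sim_family"))
  ne <- family$params$n_exons
  stopifnot(level > 0, level <= ne)
  p <- if (ne == 1) 0 else (ne / level - 1) / (ne - 1)
  p <- min(1, max(0, p))
  with_local_seed(seed, {
    rows <- list()
    for (pg in family$paralog_ids) {
      breaks <- if (ne > 1) which(stats::runif(ne - 1) < p) else integer(0)
      starts <- c(1L, breaks + 1L)
      ends <- c(breaks, ne)
      for (f in seq_along(starts)) {
        rows[[length(rows) + 1L]] <- data.frame(
          fragment_id = sprintf("%s_f%02d_%02d", pg, starts[f], ends[f]),
          paralog_id = pg, exon_start = starts[f], exon_end = ends[f],
          stringsAsFactors = FALSE)
      }
    }
    fragments <- do.call(rbind, rows)
    list(fragments = fragments,
         truth = stats::setNames(fragments$paralog_id, fragments$fragment_id),
         realized_level = ne * family$params$n_paralogs / nrow(fragments))
  })
}

# lazily computed 3d arrays of TCE-vs-TCE bitscores and E-values:
# dims (query paralog, target paralog, exon)
tce_score_tensor <- function(family) {
  if (!is.null(family$cache$tce_bits)) return(invisible(family$cache))
  P <- family$params$n_paralogs; ne <- family$params$n_exons
  pid <- family$paralog_ids
  bits <- array(NA_real_, dim = c(P, P, ne), dimnames = list(pid, pid, NULL))
  ev <- bits
  for (t in seq_len(P)) {
    for (k in seq_len(ne)) {
      qs <- vapply(family$query_exons, function(ex)
        paste(ex[[k]], collapse = ""), character(1))
      res <- align_bits(qs, paste(family$target_exons[[t]][[k]],
                                  collapse = ""))
      bits[, t, k] <- res$bits
      ev[, t, k] <- res$evalue
    }
  }
  family$cache$tce_bits <- bits
  family$cache$tce_evalue <- ev
  invisible(family$cache)
}

#' Score query TCEs against fragments
#'
#' For every exon carried by a fragment and every query paralog, the query
#' TCE of the same homology group is locally aligned against the fragment's
#' copy of that exon ([align_bits()]); matches with E-value at or above
#' `evalue_max` are omitted, emulating the search tool's E-value cut.
#' Scores depend only on the (query paralog, target paralog, exon) triple
#' and are cached in the family object, so repeated fragmentations of one
#' family are cheap.
#'
#' @param family a [simulate_family()] result.
#' @param fragmentation a [fragment_family()] result.
#' @param evalue_max E-value ceiling; defaults to the family's parameter.
#' @return a [hit_table()] with provenance `"simulated"`; coordinates are
#'   residue positions of the exon within the fragment.
#' @export
score_hits <- function(family, fragmentation,
                       evalue_max = family$params$evalue_max) {
  stopifnot(inherits(family, "sim_family"))
  cache <- tce_score_tensor(family)
  frags <- fragmentation$fragments
  pid <- family$paralog_ids
  tlen <- vapply(family$target_exons, function(ex)
    vapply(ex, length, 1L), integer(family$params$n_exons))
  qlen <- vapply(family$query_exons, function(ex)
    vapply(ex, length, 1L), integer(family$params$n_exons))
  # tlen, qlen: exons x paralogs
  out <- vector("list", nrow(frags))
  for (r in seq_len(nrow(frags))) {
    t <- frags$paralog_id[r]
    ks <- frags$exon_start[r]:frags$exon_end[r]
    off <- c(0L, cumsum(tlen[ks, t]))
    bits <- cache$tce_bits[, t, ks, drop = FALSE]
    ev <- cache$tce_evalue[, t, ks, drop = FALSE]
    keep <- which(ev < evalue_max & bits > 0, arr.ind = TRUE)
    if (nrow(keep) == 0) next
    out[[r]] <- data.frame(
      contig_id = frags$fragment_id[r],
      paralog_id = pid[keep[, 1]],
      tce_type = ks[keep[, 3]],
      bitscore = bits[keep],
      evalue = ev[keep],
      contig_start = off[keep[, 3]],
      contig_end = off[keep[, 3] + 1L],
      strand = "+",
      query_cov_len = qlen[cbind(ks[keep[, 3]], keep[, 1])],
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(hit_table(provenance = "simulated"))
  df <- do.call(rbind, out)
  do.call(hit_table, c(as.list(df), provenance = "simulated"))
}

#' Score full-length query proteins against fragments
#'
#' Best local alignment bitscore of each whole query protein against each
#' fragment's concatenated exon sequence - the scores the greedy baseline
#' assigns from. Because fragments are contiguous exon runs, scores are
#' memoised per (target paralog, run) in the family cache.
#'
#' @inheritParams score_hits
#' @return data frame `unit_id`, `paralog_id`, `score` (bits).
#' @export
score_full_length <- function(family, fragmentation) {
  stopifnot(inherits(family, "sim_family"))
  if (is.null(family$cache$full)) family$cache$full <- new.env(parent = emptyenv())
  frags <- fragmentation$fragments
  pid <- family$paralog_ids
  out <- vector("list", nrow(frags))
  for (r in seq_len(nrow(frags))) {
    key <- sprintf("%s:%d:%d", frags$paralog_id[r],
                   frags$exon_start[r], frags$exon_end[r])
    sc <- family$cache$full[[key]]
    if (is.null(sc)) {
      subject <- paste(unlist(
        family$target_exons[[frags$paralog_id[r]]][
          frags$exon_start[r]:frags$exon_end[r]]), collapse = "")
      sc <- align_bits(family$query_proteins, subject)$bits
      family$cache$full[[key]] <- sc
    }
    out[[r]] <- data.frame(unit_id = frags$fragment_id[r], paralog_id = pid,
                           score = sc, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Run the fragmentation benchmark
#'
#' Simulates one family, then for each fragmentation level draws `reps`
#' independent fragmentations of the same family; every replicate is scored
#' once and handed to both the exact assignment solver and the greedy
#' full-length baseline, and per-unit accuracies against the truth map are
#' aggregated per method and level. Fully seeded and deterministic.
#'
#' @param params a [sim_params()] object.
#' @param levels numeric vector of fragmentation levels (average exons per
#'   fragment).
#' @param reps fragmentation replicates per level.
#' @param seed integer master seed (family and all replicates derive from
#'   it).
#' @param relaxed_eq7 passed to [solve_pcap()].
#' @param family optionally reuse an existing [simulate_family()] result.
#' @return data frame of class `benchmark_result` with columns `level`,
#'   `method` (`"ilp"` / `"greedy"`), `mean_accuracy`, `sd_accuracy`,
#'   `reps`, `mean_realized_level`; the per-replicate accuracy matrix is
#'   attached as attribute `per_rep`.
#' @export
run_benchmark <- function(params = sim_params(), levels = c(12, 8, 4, 2, 1),
                          reps = 200, seed = 1, relaxed_eq7 = FALSE,
                          family = NULL) {
  stopifnot(reps >= 1)
  if (is.null(family)) family <- simulate_family(params, seed = seed)
  params <- family$params
  rep_seeds <- with_local_seed(seed + 1L,
    matrix(sample.int(.Machine$integer.max - 1L, length(levels) * reps),
           nrow = reps))
  rows <- list(); per_rep <- list()
  for (li in seq_along(levels)) {
    lv <- levels[li]
    acc <- matrix(NA_real_, reps, 2, dimnames = list(NULL, c("ilp", "greedy")))
    rlv <- numeric(reps)
    for (r in seq_len(reps)) {
      fr <- fragment_family(family, lv, seed = rep_seeds[r, li])
      rlv[r] <- fr$realized_level
      hits <- score_hits(family, fr)
      acc[r, "ilp"] <- if (nrow(hits) == 0) 0 else {
        inst <- build_instance(hits, params$n_paralogs, params$n_exons,
                               paralog_ids = family$paralog_ids)
        sol <- solve_pcap(inst, relaxed_eq7 = relaxed_eq7)
        assignment_accuracy(sol, fr$truth)
      }
      fl <- score_full_length(family, fr)
      acc[r, "greedy"] <- greedy_accuracy(greedy_assign(fl), fr$truth)
    }
    per_rep[[as.character(lv)]] <- acc
    for (mth in colnames(acc)) {
      rows[[length(rows) + 1L]] <- data.frame(
        level = lv, method = mth, mean_accuracy = mean(acc[, mth]),
        sd_accuracy = stats::sd(acc[, mth]), reps = reps,
        mean_realized_level = mean(rlv), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  attr(res, "per_rep") <- per_rep
  class(res) <- c("benchmark_result", "data.frame")
  res
}

#' Write simulated queries and fragments as FASTA
#'
#' @param family a [simulate_family()] result.
#' @param fragmentation a [fragment_family()] result (for fragments).
#' @param query_path,fragment_path,truth_path output paths (`NULL` to skip).
#' @export
write_family_fasta <- function(family, fragmentation = NULL,
                               query_path = NULL, fragment_path = NULL,
                               truth_path = NULL) {
  if (!is.null(query_path)) {
    qs <- Biostrings::AAStringSet(family$query_proteins)
    Biostrings::writeXStringSet(qs, query_path)
  }
  if (!is.null(fragment_path) && !is.null(fragmentation)) {
    frags <- fragmentation$fragments
    seqs <- vapply(seq_len(nrow(frags)), function(r)
      paste(unlist(family$target_exons[[frags$paralog_id[r]]][
        frags$exon_start[r]:frags$exon_end[r]]), collapse = ""), character(1))
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(stats::setNames(seqs, frags$fragment_id)),
      fragment_path)
  }
  if (!is.null(truth_path) && !is.null(fragmentation)) {
    utils::write.table(fragmentation$fragments, truth_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}
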