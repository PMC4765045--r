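#' Contig sequence with tracked N-runs
#'
#' Wraps a nucleotide sequence (alphabet A, C, G, T, N) together with the
#' positions of its runs of consecutive `N`s, which mark missing sequence at
#' the scaffold level and are the preferred insertion points when contigs
#' are interleaved.
#'
#' @param id contig identifier.
#' @param seq character string over A/C/G/T/N (case-insensitive).
#' @return object of class `contig_seq`: list with `id`, `seq`, and
#'   `n_runs` (data frame `start`, `end`, `len`, 1-based inclusive).
#' @export
contig_seq <- function(id, seq) {
  seq <- toupper(as.character(seq))
  if (!grepl("^[ACGTN]*$", seq))
    stop("contig sequence must be over A, C, G, T, N")
  structure(list(id = id, seq = seq, n_runs = find_n_runs(seq)),
            class = "contig_seq")
}

find_n_runs <- function(seq) {
  m <- gregexpr("N+", seq)[[1]]
  if (m[1] == -1)
    return(data.frame(start = integer(), end = integer(), len = integer()))
  len <- attr(m, "match.length")
  data.frame(start = as.integer(m), end = as.integer(m) + len - 1L,
             len = as.integer(len))
}

#' @export
print.contig_seq <- function(x, ...) {
  cat(sprintf("contig_seq %s: %d nt, %d N-run(s)\n", x$id, nchar(x$seq),
              nrow(x$n_runs)))
  invisible(x)
}

revcomp <- function(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))

# flip 0-based half-open hit coordinates onto the reverse complement
revcomp_hit_coords <- function(start, end, contig_len) {
  list(start = contig_len - end, end = contig_len - start)
}

#' Classify the contig structure of each assigned paralog
#'
#' After solving the assignment, each paralog's set of contigs falls into
#' one of three cases: (i) a single contig; (ii) several contigs, each
#' carrying a consecutive run of TCEs, with pairwise non-overlapping
#' ranges - these can be concatenated unambiguously in TCE order; (iii)
#' some contig carries an ordered but non-consecutive TCE set whose gap is
#' covered by another assigned contig - that contig must be interleaved
#' (inserted) into the gap. Contigs whose hits are out of TCE order along
#' the sequence, or overlapping TCE ranges that fit no case, are flagged
#' for manual review and no plan is emitted for that paralog.
#'
#' @param assignment a `pcap_assignment`.
#' @param hits the [hit_table()] the instance was built from (nucleotide
#'   coordinates, 0-based half-open).
#' @return named list (per assigned paralog) of locus plans: list with
#'   `paralog_id`, `case` (`"i"`, `"ii"`, `"iii"` or `"flagged"`),
#'   `contigs` (data frame `contig_id`, `strand`, `tce_min`, `tce_max`,
#'   `tces`), `order` (concatenation order of top-level contigs),
#'   `inserts` (data frame `host`, `insert`, `after_tce`, `before_tce`),
#'   and `reason` when flagged.
#' @export
classify_locus <- function(assignment, hits) {
  stopifnot(inherits(hits, "hit_table"))
  plans <- list()
  for (i in which(!is.na(assignment$C))) {
    pid <- assignment$paralog_ids[assignment$C[i]]
    plans[[pid]] <- c(plans[[pid]], assignment$contig_ids[i])
  }
  out <- list()
  for (pid in names(plans)) {
    h <- hits[hits$paralog_id == pid & hits$contig_id %in% plans[[pid]], ,
              drop = FALSE]
    out[[pid]] <- plan_one_locus(pid, plans[[pid]], h)
  }
  out
}

plan_one_locus <- function(pid, contigs, h) {
  flag <- function(reason)
    list(paralog_id = pid, case = "flagged", contigs = NULL, order = NULL,
         inserts = NULL, reason = reason)
  info <- lapply(contigs, function(cid) {
    hc <- h[h$contig_id == cid, , drop = FALSE]
    strand <- names(sort(table(hc$strand), decreasing = TRUE))[1]
    o <- order(if (strand == "+") hc$contig_start else -hc$contig_start)
    list(contig_id = cid, strand = strand, tces = hc$tce_type[o])
  })
  for (ci in info) {
    if (is.unsorted(ci$tces, strictly = TRUE))
      return(flag(sprintf("TCE order violated on contig %s", ci$contig_id)))
  }
  all_tces <- unlist(lapply(info, `[[`, "tces"))
  if (anyDuplicated(all_tces))
    return(flag("a TCE appears on more than one assigned contig"))
  df <- data.frame(
    contig_id = vapply(info, `[[`, "", "contig_id"),
    strand = vapply(info, `[[`, "", "strand"),
    tce_min = vapply(info, function(x) min(x$tces), 1),
    tce_max = vapply(info, function(x) max(x$tces), 1),
    stringsAsFactors = FALSE)
  df$tces <- lapply(info, `[[`, "tces")
  df <- df[order(df$tce_min), , drop = FALSE]

  if (nrow(df) == 1) {
    return(list(paralog_id = pid, case = "i", contigs = df,
                order = df$contig_id, inserts = NULL, reason = NULL))
  }
  consecutive <- vapply(df$tces, function(ts)
    all(diff(ts) == 1), logical(1))
  disjoint <- all(df$tce_min[-1] > df$tce_max[-nrow(df)])
  if (all(consecutive) && disjoint) {
    return(list(paralog_id = pid, case = "ii", contigs = df,
                order = df$contig_id, inserts = NULL, reason = NULL))
  }
  # case iii: fit contigs into the gaps of hosts, innermost-first
  inserts <- list(); is_insert <- rep(FALSE, nrow(df))
  for (ci in seq_len(nrow(df))) {
    gaps <- tce_gaps(df$tces[[ci]])
    for (g in gaps) {
      inside <- which(df$tce_min >= g[1] & df$tce_max <= g[2])
      if (length(inside) == 0)
        next  # gap not covered here: TCEs may be missing entirely
      covered <- sort(unlist(df$tces[inside]))
      inserts[[length(inserts) + 1L]] <- data.frame(
        host = df$contig_id[ci], insert_first = df$contig_id[inside[1]],
        after_tce = g[1] - 1L, before_tce = g[2] + 1L,
        inserts = I(list(df$contig_id[inside])))
      is_insert[inside] <- TRUE
    }
  }
  if (length(inserts) == 0)
    return(flag("overlapping TCE ranges that fit no assembly case"))
  # an insert nested inside an insert would need recursion; flag cycles
  hosts <- vapply(inserts, function(x) x$host[1], "")
  if (any(hosts %in% unlist(lapply(inserts, function(x) x$inserts[[1]]))))
    return(flag("nested/cyclic interleaving; resolve manually"))
  ins_df <- do.call(rbind, inserts)
  top <- df$contig_id[!is_insert]
  list(paralog_id = pid, case = "iii", contigs = df, order = top,
       inserts = ins_df, reason = NULL)
}

tce_gaps <- function(ts) {
  gaps <- list()
  d <- diff(ts)
  for (w in which(d > 1))
    gaps[[length(gaps) + 1L]] <- c(ts[w] + 1L, ts[w + 1L] - 1L)
  gaps
}

#' Concatenate oriented fragments with N spacers
#'
#' Joins fragment sequences in the given order, reverse-complementing
#' minus-strand fragments first, separated by a run of `spacer_n` Ns.
#'
#' @param seqs character vector of nucleotide sequences (in final order).
#' @param strands matching vector of `"+"`/`"-"`.
#' @param spacer_n number of Ns inserted between consecutive fragments.
#' @return single merged sequence string.
#' @export
concat_fragments <- function(seqs, strands = rep("+", length(seqs)),
                             spacer_n = 100) {
  stopifnot(length(seqs) == length(strands))
  oriented <- ifelse(strands == "-", vapply(seqs, revcomp, ""), seqs)
  paste(oriented, collapse = strrep("N", spacer_n))
}

#' Interleave an insert sequence into a host contig
#'
#' Places `insert` into the host window between the closest flanking TCE
#' hits (`window_start`..`window_end`, 1-based inclusive). If the window
#' contains a run of three or more consecutive Ns, the longest such run
#' (leftmost on ties) is substituted by the insert; otherwise the insert,
#' padded with `flank_n` Ns on both sides, is placed at the window
#' midpoint. The returned offset map relocates host coordinates outside the
#' edited region.
#'
#' @param host a [contig_seq()] (or sequence string).
#' @param insert insert sequence string (already oriented).
#' @param window_start,window_end 1-based inclusive insertion window on the
#'   host (between the end of the upstream hit and the start of the
#'   downstream hit).
#' @param flank_n N-padding used when no N-run is available.
#' @return list with `seq` (merged sequence), `offset` (list
#'   `edit_start`, `removed_len`, `inserted_len`) and `mode`
#'   (`"n_run"` or `"padded"`); use [map_offset()] to relocate positions.
#' @export
interleave_contigs <- function(host, insert, window_start, window_end,
                               flank_n = 100) {
  if (!inherits(host, "contig_seq")) host <- contig_seq("host", host)
  if (window_start > window_end)
    stop("empty insertion window (adjacent hits touch); manual review needed")
  runs <- host$n_runs
  runs <- runs[runs$len >= 3 & runs$start >= window_start &
               runs$end <= window_end, , drop = FALSE]
  if (nrow(runs) > 0) {
    r <- runs[order(-runs$len, runs$start)[1], ]
    edit_start <- r$start; removed <- r$len; new_seq <- insert
    mode <- "n_run"
  } else {
    edit_start <- floor((window_start + window_end) / 2)
    removed <- 0L
    new_seq <- paste0(strrep("N", flank_n), insert, strrep("N", flank_n))
    mode <- "padded"
  }
  merged <- paste0(substr(host$seq, 1, edit_start - 1), new_seq,
                   substr(host$seq, edit_start + removed, nchar(host$seq)))
  list(seq = merged,
       offset = list(edit_start = edit_start, removed_len = removed,
                     inserted_len = nchar(new_seq)),
       mode = mode)
}

#' Relocate a host position through an interleaving offset map
#'
#' @param offset the `offset` element returned by [interleave_contigs()].
#' @param pos 1-based position(s) on the original host, outside the edited
#'   window.
#' @return relocated position(s) on the merged sequence.
#' @export
map_offset <- function(offset, pos) {
  shift <- offset$inserted_len - offset$removed_len
  out <- ifelse(pos < offset$edit_start, pos,
                ifelse(pos >= offset$edit_start + offset$removed_len,
                       pos + shift, NA_integer_))
  if (anyNA(out)) stop("position inside the edited window cannot be mapped")
  out
}

#' Assemble the merged locus of one paralog
#'
#' Executes a locus plan from [classify_locus()]: minus-strand contigs are
#' orientation-normalised (reverse complemented, hit coordinates flipped),
#' case-iii inserts are interleaved into their host windows, and the
#' resulting top-level fragments are concatenated in TCE order with N
#' spacers.
#'
#' @param plan one element of the [classify_locus()] result.
#' @param sequences named list/vector of contig sequences (strings or
#'   [contig_seq()]).
#' @param hits the [hit_table()] with the paralog's hits.
#' @param spacer_n,flank_n see [concat_fragments()] and
#'   [interleave_contigs()].
#' @return list with `seq` (merged locus) and `case`.
#' @export
assemble_locus <- function(plan, sequences, hits, spacer_n = 100,
                           flank_n = 100) {
  if (plan$case == "flagged")
    stop("locus flagged for manual review: ", plan$reason)
  getseq <- function(cid) {
    s <- sequences[[cid]]
    if (is.null(s)) stop("missing contig sequence: ", cid)
    if (inherits(s, "contig_seq")) s$seq else as.character(s)
  }
  pid <- plan$paralog_id
  h <- hits[hits$paralog_id == pid, , drop = FALSE]
  # orientation-normalise every contig once
  oriented <- list(); hcoord <- list()
  for (ci in seq_len(nrow(plan$contigs))) {
    cid <- plan$contigs$contig_id[ci]
    s <- getseq(cid)
    hh <- h[h$contig_id == cid, , drop = FALSE]
    if (plan$contigs$strand[ci] == "-") {
      L <- nchar(s)
      s <- revcomp(s)
      cc <- revcomp_hit_coords(hh$contig_start, hh$contig_end, L)
      hh$contig_start <- cc$start; hh$contig_end <- cc$end
    }
    oriented[[cid]] <- s
    hcoord[[cid]] <- hh
  }
  if (!is.null(plan$inserts)) {
    for (r in seq_len(nrow(plan$inserts))) {
      host_id <- plan$inserts$host[r]
      hh <- hcoord[[host_id]]
      up <- hh[hh$tce_type == plan$inserts$after_tce[r], , drop = FALSE]
      dn <- hh[hh$tce_type == plan$inserts$before_tce[r], , drop = FALSE]
      if (nrow(up) == 0 || nrow(dn) == 0)
        stop("flanking hits for interleaving window not found on ", host_id)
      ws <- up$contig_end[1] + 1L          # 0-based end -> first 1-based pos after
      we <- dn$contig_start[1]             # 0-based start == last 1-based pos before
      insert_seq <- paste(vapply(plan$inserts$inserts[[r]],
                                 function(x) oriented[[x]], ""),
                          collapse = strrep("N", spacer_n))
      res <- interleave_contigs(contig_seq(host_id, oriented[[host_id]]),
                                insert_seq, ws, we, flank_n = flank_n)
      oriented[[host_id]] <- res$seq
      ok <- hh$contig_end <= res$offset$edit_start - 1L |
        hh$contig_start >= res$offset$edit_start + res$offset$removed_len - 1L
      hh$contig_start[ok] <- map_offset(res$offset, hh$contig_start[ok] + 1L) - 1L
      hh$contig_end[ok] <- map_offset(res$offset, hh$contig_end[ok])
      hcoord[[host_id]] <- hh
    }
  }
  merged <- paste(vapply(plan$order, function(cid) oriented[[cid]], ""),
                  collapse = strrep("N", spacer_n))
  list(seq = merged, case = plan$case)
}
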