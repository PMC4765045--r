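#' Construct a hit table
#'
#' A hit table is an ordered data frame of similarity matches of query TCEs
#' (translated coding exons) against genomic contigs, the raw material of a
#' paralog-to-contig assignment instance. One row is one scored match of TCE
#' type `tce_type` of paralog `paralog_id` on contig `contig_id`.
#'
#' Coordinates are stored 0-based half-open on the contig; parsers convert
#' from the 1-based inclusive conventions of the input formats.
#'
#' @param contig_id,paralog_id character identifiers.
#' @param tce_type integer TCE (homologous exon group) number, >= 1.
#' @param bitscore non-negative similarity score (bits).
#' @param evalue expectation value of the match.
#' @param contig_start,contig_end 0-based half-open match coordinates.
#' @param strand `"+"` or `"-"`.
#' @param query_cov_len number of query residues covered by the match.
#' @param provenance one of `"blast_tab"`, `"hmmer_domtbl"`, `"simulated"`.
#' @return A `data.frame` of class `hit_table` with the columns above and a
#'   `provenance` attribute.
#' @export
hit_table <- function(contig_id = character(), paralog_id = character(),
                      tce_type = integer(), bitscore = numeric(),
                      evalue = numeric(), contig_start = integer(),
                      contig_end = integer(), strand = character(),
                      query_cov_len = integer(),
                      provenance = c("simulated", "blast_tab", "hmmer_domtbl")) {
  provenance <- match.arg(provenance)
  df <- data.frame(
    contig_id = as.character(contig_id),
    paralog_id = as.character(paralog_id),
    tce_type = as.integer(tce_type),
    bitscore = as.numeric(bitscore),
    evalue = as.numeric(evalue),
    contig_start = as.integer(contig_start),
    contig_end = as.integer(contig_end),
    strand = as.character(strand),
    query_cov_len = as.integer(query_cov_len),
    stringsAsFactors = FALSE
  )
  if (nrow(df) > 0) {
    if (any(df$bitscore < 0)) stop("bitscore must be non-negative")
    if (any(df$contig_start > df$contig_end))
      stop("contig_start must not exceed contig_end")
    if (!all(df$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'")
  }
  structure(df, provenance = provenance,
            class = c("hit_table", "data.frame"))
}

#' @export
print.hit_table <- function(x, ...) {
  cat(sprintf("hit_table: %d hits (%s)\n", nrow(x), attr(x, "provenance")))
  if (nrow(x) > 0) print.data.frame(utils::head(x, 10), ...)
  if (nrow(x) > 10) cat(sprintf("... and %d more rows\n", nrow(x) - 10))
  invisible(x)
}

# keep class + provenance through subsetting done by the filters
restore_hit_table <- function(df, template) {
  structure(as.data.frame(df), provenance = attr(template, "provenance"),
            class = c("hit_table", "data.frame"))
}

# split "<paralog>_<tce>" at the LAST underscore; regex override possible
split_query_name <- function(qname, pattern = "^(.*)_([0-9]+)$") {
  m <- regmatches(qname, regexec(pattern, qname))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("cannot parse query name(s) into <paralog>_<tce>: ",
         paste(unique(qname[bad]), collapse = ", "))
  list(paralog = vapply(m, `[`, "", 2L),
       tce = as.integer(vapply(m, `[`, "", 3L)))
}

#' Parse BLAST tabular output into a hit table
#'
#' Reads the 12-column tab-separated BLAST format (as produced by
#' `tblastn -outfmt 6`): query, subject, identity, alignment length,
#' mismatches, gap opens, qstart, qend, sstart, send, evalue, bitscore.
#' Query names must encode the paralog and the TCE number as
#' `<paralog>_<tce>`, split at the last underscore (override with
#' `query_pattern`). Minus-strand matches are recognised by
#' `sstart > send`; coordinates are converted to the internal 0-based
#' half-open convention.
#'
#' @param path file path, connection, or character vector of lines.
#' @param query_pattern regex with two capture groups (paralog, tce).
#' @return A [hit_table()] with provenance `"blast_tab"`.
#' @export
parse_blast_tab <- function(path, query_pattern = "^(.*)_([0-9]+)$") {
  lines <- read_input_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(hit_table(provenance = "blast_tab"))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (any(nf != 12L))
    stop(sprintf("malformed BLAST tabular line %d: expected 12 columns, got %d",
                 which(nf != 12L)[1], nf[nf != 12L][1]))
  tab <- do.call(rbind, fields)
  qn <- split_query_name(tab[, 1], query_pattern)
  sstart <- as.integer(tab[, 9]); send <- as.integer(tab[, 10])
  minus <- sstart > send
  hit_table(
    contig_id = tab[, 2],
    paralog_id = qn$paralog,
    tce_type = qn$tce,
    bitscore = as.numeric(tab[, 12]),
    evalue = as.numeric(tab[, 11]),
    contig_start = ifelse(minus, send, sstart) - 1L,
    contig_end = ifelse(minus, sstart, send),
    strand = ifelse(minus, "-", "+"),
    query_cov_len = abs(as.integer(tab[, 8]) - as.integer(tab[, 7])) + 1L,
    provenance = "blast_tab"
  )
}

#' Parse a HMMER3 per-domain table into a hit table
#'
#' Reads `hmmsearch --domtblout` output (whitespace-separated, `#` comment
#' lines ignored). The model (query) name must encode `<paralog>_<tce>`.
#' Each domain row becomes one hit, using the per-domain bitscore and the
#' independent E-value; alignment coordinates on the target are taken from
#' the `ali from`/`ali to` columns.
#'
#' @inheritParams parse_blast_tab
#' @return A [hit_table()] with provenance `"hmmer_domtbl"`.
#' @export
parse_hmmer_domtbl <- function(path, query_pattern = "^(.*)_([0-9]+)$") {
  lines <- read_input_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0) return(hit_table(provenance = "hmmer_domtbl"))
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- vapply(fields, length, 1L)
  if (any(nf < 22L))
    stop(sprintf("malformed HMMER domain table line %d: expected >= 22 columns, got %d",
                 which(nf < 22L)[1], nf[nf < 22L][1]))
  tab <- do.call(rbind, lapply(fields, `[`, 1:22))
  qn <- split_query_name(tab[, 4], query_pattern)
  ali_from <- as.integer(tab[, 18]); ali_to <- as.integer(tab[, 19])
  hit_table(
    contig_id = tab[, 1],
    paralog_id = qn$paralog,
    tce_type = qn$tce,
    bitscore = as.numeric(tab[, 14]),
    evalue = as.numeric(tab[, 13]),
    contig_start = ali_from - 1L,
    contig_end = ali_to,
    strand = "+",
    query_cov_len = as.integer(tab[, 17]) - as.integer(tab[, 16]) + 1L,
    provenance = "hmmer_domtbl"
  )
}

read_input_lines <- function(path) {
  if (inherits(path, "connection")) return(readLines(path))
  if (is.character(path) && length(path) == 1 && file.exists(path))
    return(readLines(path))
  as.character(path)
}

#' Filter hits by E-value
#'
#' Retains exactly the hits with `evalue` strictly below `threshold`,
#' preserving row order. This is the first spurious-hit filter applied to a
#' raw search-tool hit list.
#'
#' @param table a [hit_table()].
#' @param threshold positive E-value cutoff (default `1e-5`).
#' @return the filtered `hit_table`.
#' @export
filter_evalue <- function(table, threshold = 1e-5) {
  stopifnot(inherits(table, "hit_table"), threshold > 0)
  restore_hit_table(table[table$evalue < threshold, , drop = FALSE], table)
}

#' Filter lone hits by length-normalised bitscore
#'
#' A TCE hit found alone on a contig, without any accompanying hit of any
#' paralog or TCE type, is more likely spurious than a hit in company. Such
#' singletons are dropped unless their length-normalised score,
#' `bitscore / query_cov_len` (bits per aligned query residue), reaches
#' `min_norm_score`. Hits on contigs carrying more than one hit pass
#' unconditionally.
#'
#' @param table a [hit_table()].
#' @param min_norm_score minimum bits per aligned residue for lone hits.
#' @return the filtered `hit_table`.
#' @export
filter_singletons <- function(table, min_norm_score = 1.0) {
  stopifnot(inherits(table, "hit_table"), min_norm_score >= 0)
  if (nrow(table) == 0) return(table)
  if (any(table$query_cov_len == 0))
    stop("query_cov_len of 0 in hit table; cannot length-normalise")
  n_on_contig <- table(table$contig_id)[table$contig_id]
  lone <- n_on_contig == 1L
  keep <- !lone | (table$bitscore / table$query_cov_len >= min_norm_score)
  restore_hit_table(table[keep, , drop = FALSE], table)
}

#' Group query exons into homologous TCE groups
#'
#' Before assignment, the exons of the query paralogs must be numbered
#' consistently so that homologous exons share a TCE group number. Given
#' pairwise similarity scores among query exons, a per-paralog background
#' distribution is computed from the scores of each paralog's exons against
#' the *other exons of the same paralog* (which are non-homologous by
#' construction). A cutoff `theta_hat_j = mean + z * sd` of that background
#' separates genuine cross-paralog homology from promiscuous matches:
#' cross-paralog exon pairs scoring strictly above the cutoff of either
#' member's paralog are linked, and connected components of the link graph
#' become TCE groups. Exons shorter than `min_len` are excluded from
#' grouping altogether.
#'
#' Components that would merge two exons of the same paralog are flagged
#' (`flagged` column, plus a warning) for manual review rather than being
#' trusted silently.
#'
#' @param self_scores data frame with columns `paralog_a`, `exon_a`,
#'   `paralog_b`, `exon_b`, `score`: pairwise similarity scores among query
#'   exons (exon indices are per-paralog ordinals). Same-paralog pairs with
#'   `exon_a != exon_b` form the background; cross-paralog pairs are the
#'   candidate homology links.
#' @param z z-score defining the per-paralog cutoff.
#' @param min_len minimum exon length (residues) for inclusion.
#' @param exon_lens data frame with columns `paralog`, `exon`, `len`.
#' @return list with `groups` (data frame `paralog`, `exon`, `tce_group`,
#'   `flagged`), `cutoffs` (named numeric, per paralog) and `n_groups`.
#' @export
group_homologous_tces <- function(self_scores, z = 2, min_len = 10, exon_lens) {
  stopifnot(all(c("paralog_a", "exon_a", "paralog_b", "exon_b", "score")
                %in% names(self_scores)),
            all(c("paralog", "exon", "len") %in% names(exon_lens)))
  self_scores$paralog_a <- as.character(self_scores$paralog_a)
  self_scores$paralog_b <- as.character(self_scores$paralog_b)
  exon_lens$paralog <- as.character(exon_lens$paralog)
  keep_exons <- exon_lens[exon_lens$len >= min_len, c("paralog", "exon")]
  if (nrow(keep_exons) == 0)
    return(list(groups = data.frame(paralog = character(), exon = integer(),
                                    tce_group = integer(), flagged = logical()),
                cutoffs = numeric(), n_groups = 0L))
  key <- function(p, e) paste(p, e, sep = "\r")
  keep_key <- key(keep_exons$paralog, keep_exons$exon)

  same <- self_scores$paralog_a == self_scores$paralog_b &
    self_scores$exon_a != self_scores$exon_b
  cutoffs <- vapply(split(self_scores$score[same], self_scores$paralog_a[same]),
                    function(s) {
                      if (length(s) < 2)
                        stop("background distribution with < 2 values for a paralog; ",
                             "provide TCE homology directly (custom input)")
                      mean(s) + z * stats::sd(s)
                    }, numeric(1))

  cross <- self_scores[self_scores$paralog_a != self_scores$paralog_b, , drop = FALSE]
  cross <- cross[key(cross$paralog_a, cross$exon_a) %in% keep_key &
                 key(cross$paralog_b, cross$exon_b) %in% keep_key, , drop = FALSE]
  linked <- cross$score > cutoffs[cross$paralog_a] &
            cross$score > cutoffs[cross$paralog_b]
  edges <- cross[linked, , drop = FALSE]

  # order vertices by (paralog order of appearance, exon ordinal) so that
  # group numbering follows query exon order
  keep_exons <- keep_exons[order(match(keep_exons$paralog,
                                       unique(exon_lens$paralog)),
                                 keep_exons$exon), , drop = FALSE]
  verts <- key(keep_exons$paralog, keep_exons$exon)
  g <- igraph::make_empty_graph(n = length(verts), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = verts)
  if (nrow(edges) > 0)
    g <- igraph::add_edges(g, rbind(match(key(edges$paralog_a, edges$exon_a), verts),
                                    match(key(edges$paralog_b, edges$exon_b), verts)))
  comp <- igraph::components(g)$membership
  # renumber components 1..m by first (query-exon-order) member
  first_of <- tapply(seq_along(comp), comp, min)
  renum <- rank(first_of)[as.character(comp)]

  groups <- data.frame(paralog = keep_exons$paralog, exon = keep_exons$exon,
                       tce_group = as.integer(renum), stringsAsFactors = FALSE)
  dup <- stats::aggregate(exon ~ paralog + tce_group, groups, length)
  bad_groups <- unique(dup$tce_group[dup$exon > 1])
  groups$flagged <- groups$tce_group %in% bad_groups
  if (length(bad_groups) > 0)
    warning("TCE group(s) ", paste(bad_groups, collapse = ", "),
            " merge two exons of the same paralog; flagged for manual review")
  list(groups = groups, cutoffs = cutoffs,
       n_groups = length(unique(groups$tce_group)))
}

#' Write a TCE grouping as a tab-separated table
#'
#' @param grouping result of [group_homologous_tces()].
#' @param path output file path.
#' @export
write_tce_groups <- function(grouping, path) {
  utils::write.table(grouping$groups, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
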