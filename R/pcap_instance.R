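#' Build a PCAP instance from a filtered hit table
#'
#' The paralog-to-contig assignment problem (PCAP) is defined on a score
#' tensor `theta[i, j, k]`: the bitscore of the best hit of TCE type `k` of
#' paralog `j` on contig `i`, with 0 meaning "no (or undesirable) match".
#' When several hits share an `(i, j, k)` cell (repeated local matches of
#' the same exon), the maximum bitscore is retained, matching the working
#' assumption that each exon type occurs at most once per contig. Contigs
#' without any hit are absent from the instance.
#'
#' For each contig the instance also stores
#' `mu[i] = |{k : exists j' with theta[i, j', k] > 0}|`, the number of
#' distinct TCE groups with a positive score on contig `i` (independent of
#' the paralog). `mu` weights the ILP objective so that assignments placing
#' many exons on the same contig are preferred.
#'
#' @param hits a [hit_table()] (already filtered).
#' @param n_paralogs number of query paralogs `N`.
#' @param n_tce_types number of homologous TCE groups `m`.
#' @param paralog_ids optional character vector giving the paralog order;
#'   defaults to the sorted unique ids in `hits`.
#' @return object of class `pcap_instance`: list with `theta` (dense
#'   `n_contigs x n_paralogs x n_tce_types` array, dimnames = ids), `mu`
#'   (named integer vector), `contig_ids`, `paralog_ids`, `n_tce_types`.
#' @export
build_instance <- function(hits, n_paralogs, n_tce_types, paralog_ids = NULL) {
  stopifnot(inherits(hits, "hit_table"))
  if (nrow(hits) == 0) stop("nothing to assign: empty hit table")
  if (is.null(paralog_ids)) paralog_ids <- sort(unique(hits$paralog_id))
  if (length(paralog_ids) > n_paralogs)
    stop("more distinct paralog ids in hits than n_paralogs")
  paralog_ids <- c(paralog_ids,
                   sprintf("unused_paralog_%d",
                           seq_len(n_paralogs - length(paralog_ids))))
  unknown <- !(hits$paralog_id %in% paralog_ids)
  if (any(unknown))
    stop("unknown paralog in hit: ",
         paste(utils::head(unique(hits$paralog_id[unknown])), collapse = ", "))
  if (any(hits$tce_type < 1 | hits$tce_type > n_tce_types)) {
    bad <- which(hits$tce_type < 1 | hits$tce_type > n_tce_types)[1]
    stop(sprintf("hit %d has tce_type %d outside 1..%d (contig %s, paralog %s)",
                 bad, hits$tce_type[bad], n_tce_types,
                 hits$contig_id[bad], hits$paralog_id[bad]))
  }
  contig_ids <- unique(hits$contig_id)
  theta <- array(0, dim = c(length(contig_ids), n_paralogs, n_tce_types),
                 dimnames = list(contig_ids, paralog_ids, NULL))
  i <- match(hits$contig_id, contig_ids)
  j <- match(hits$paralog_id, paralog_ids)
  k <- hits$tce_type
  # max-retention per (i, j, k)
  o <- order(hits$bitscore)  # later (larger) writes win
  theta[cbind(i, j, k)[o, , drop = FALSE]] <- hits$bitscore[o]
  new_pcap_instance(theta)
}

new_pcap_instance <- function(theta) {
  mu <- apply(theta > 0, c(1, 3), any)
  mu <- as.integer(rowSums(mu))
  names(mu) <- rownames(theta)
  structure(list(theta = theta, mu = mu,
                 contig_ids = rownames(theta),
                 paralog_ids = colnames(theta),
                 n_contigs = dim(theta)[1],
                 n_paralogs = dim(theta)[2],
                 n_tce_types = dim(theta)[3]),
            class = "pcap_instance")
}

#' Create a PCAP instance directly from a score tensor
#'
#' Mostly useful for tests and for hard instances built by the 3-coloring
#' reduction. `mu` is always recomputed from `theta`.
#'
#' @param theta numeric array `contigs x paralogs x tce_types`; entries
#'   `<= 0` mean no match.
#' @return a `pcap_instance`.
#' @export
pcap_instance <- function(theta) {
  stopifnot(is.array(theta), length(dim(theta)) == 3)
  if (is.null(rownames(theta)))
    rownames(theta) <- sprintf("contig%d", seq_len(dim(theta)[1]))
  if (is.null(colnames(theta)))
    colnames(theta) <- sprintf("paralog%d", seq_len(dim(theta)[2]))
  theta[theta < 0] <- 0
  new_pcap_instance(theta)
}

#' @export
print.pcap_instance <- function(x, ...) {
  cat(sprintf("pcap_instance: %d contigs x %d paralogs x %d TCE types, %d positive scores\n",
              x$n_contigs, x$n_paralogs, x$n_tce_types, sum(x$theta > 0)))
  invisible(x)
}

#' Read / write a PCAP instance as a tab-separated table
#'
#' The serialisation is one row per positive score: columns `contig`,
#' `paralog`, `tce`, `theta`. Dimensions are recovered from the data
#' unless given.
#'
#' @param x a `pcap_instance`.
#' @param path file path.
#' @param n_paralogs,n_tce_types optional explicit dimensions.
#' @return `read_instance` returns a `pcap_instance`.
#' @export
write_instance <- function(x, path) {
  stopifnot(inherits(x, "pcap_instance"))
  idx <- which(x$theta > 0, arr.ind = TRUE)
  df <- data.frame(contig = x$contig_ids[idx[, 1]],
                   paralog = x$paralog_ids[idx[, 2]],
                   tce = idx[, 3],
                   theta = x$theta[idx])
  df <- df[order(df$contig, df$paralog, df$tce), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_instance
#' @export
read_instance <- function(path, n_paralogs = NULL, n_tce_types = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("contig", "paralog", "tce", "theta") %in% names(df)))
  paralog_ids <- sort(unique(df$paralog))
  if (is.null(n_paralogs)) n_paralogs <- length(paralog_ids)
  if (is.null(n_tce_types)) n_tce_types <- max(df$tce)
  ht <- hit_table(contig_id = df$contig, paralog_id = df$paralog,
                  tce_type = df$tce, bitscore = df$theta,
                  evalue = 0, contig_start = 0L, contig_end = 1L,
                  strand = "+", query_cov_len = 1L,
                  provenance = "simulated")
  build_instance(ht, n_paralogs, n_tce_types, paralog_ids = paralog_ids)
}
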