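#' Greedy full-length assignment baseline
#'
#' The comparison method for the exon-aware solver: each paralog is assigned
#' to the single unit (contig/fragment) on which its *full-length* query
#' protein achieves the best bitscore, ignoring exon structure entirely.
#' Several paralogs may pick the same unit (greedy imposes no exclusivity),
#' and units not picked by anybody stay unassigned. Ties are broken towards
#' the lexicographically smallest unit identifier.
#'
#' @param scores data frame with columns `unit_id`, `paralog_id`, `score`
#'   (best full-length bitscore of that paralog on that unit), or a numeric
#'   matrix with units as rows and paralogs as columns.
#' @return object of class `greedy_assignment`: data frame `paralog_id`,
#'   `unit_id`, `score` (one row per paralog).
#' @export
greedy_assign <- function(scores) {
  if (is.matrix(scores)) {
    scores <- data.frame(
      unit_id = rep(rownames(scores), times = ncol(scores)),
      paralog_id = rep(colnames(scores), each = nrow(scores)),
      score = as.vector(scores))
  }
  stopifnot(all(c("unit_id", "paralog_id", "score") %in% names(scores)),
            nrow(scores) > 0)
  picks <- lapply(split(scores, scores$paralog_id), function(d) {
    d <- d[order(-d$score, d$unit_id), , drop = FALSE]
    d[1, c("paralog_id", "unit_id", "score")]
  })
  out <- do.call(rbind, picks)
  rownames(out) <- NULL
  structure(out, class = c("greedy_assignment", "data.frame"))
}

#' Per-unit accuracy of a greedy assignment
#'
#' The fraction of truth units that were picked by their owning paralog. A
#' unit picked by a wrong paralog, or not picked at all, counts as
#' incorrect; units a paralog picks beyond its true ones are not additionally
#' penalised (only truth units enter the denominator).
#'
#' @param assignment a [greedy_assign()] result.
#' @param truth named character vector `unit_id -> paralog_id` (or data
#'   frame with columns `unit_id`, `paralog_id`) covering every unit that
#'   carries at least one exon.
#' @return accuracy in `[0, 1]`.
#' @export
greedy_accuracy <- function(assignment, truth) {
  truth <- as_truth_vector(truth)
  if (length(truth) == 0) stop("empty truth map")
  picked_by <- stats::setNames(assignment$unit_id, assignment$paralog_id)
  correct <- vapply(seq_along(truth), function(u) {
    p <- truth[u]
    !is.na(picked_by[p]) && picked_by[p] == names(truth)[u]
  }, logical(1))
  mean(correct)
}

#' Per-unit accuracy of a solver assignment
#'
#' The fraction of truth units whose assigned paralog (in a
#' [solve_pcap()] result) equals the true one; unassigned units count as
#' incorrect. This is the same unit-level metric as [greedy_accuracy()],
#' making the two methods directly comparable.
#'
#' @param assignment a `pcap_assignment`.
#' @param truth named character vector `unit_id -> paralog_id` or data frame
#'   with columns `unit_id`, `paralog_id`.
#' @return accuracy in `[0, 1]`.
#' @export
assignment_accuracy <- function(assignment, truth) {
  truth <- as_truth_vector(truth)
  if (length(truth) == 0) stop("empty truth map")
  got <- rep(NA_character_, length(truth))
  idx <- match(names(truth), assignment$contig_ids)
  has <- !is.na(idx) & !is.na(assignment$C[idx])
  got[has] <- assignment$paralog_ids[assignment$C[idx[has]]]
  mean(!is.na(got) & got == truth)
}

as_truth_vector <- function(truth) {
  if (is.data.frame(truth)) {
    stopifnot(all(c("unit_id", "paralog_id") %in% names(truth)))
    truth <- stats::setNames(as.character(truth$paralog_id),
                             as.character(truth$unit_id))
  }
  truth
}
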