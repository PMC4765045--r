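#' Reduce graph 3-coloring to a PCAP instance
#'
#' The construction behind the NP-completeness of the assignment problem,
#' usable as a hard-instance generator. Given a simple graph, build an
#' instance with three identical queries ("colors"), one TCE type per edge,
#' and one target per vertex carrying the types of its incident edges with
#' score 1 (type mismatches are simply absent, which the solver's
#' constraints treat as forbidden). Two adjacent vertices share an edge
#' type, so no query can be assigned to both; an assignment covering every
#' (non-isolated) vertex is exactly a proper 3-coloring.
#'
#' @param edges two-column matrix or data frame of vertex pairs (character
#'   or integer), no self-loops; duplicate and reversed pairs are collapsed.
#' @param vertices optional vector of vertex ids (to include isolated
#'   vertices in the bookkeeping; they never enter the instance).
#' @return list with `instance` (a `pcap_instance` with `3 * |E|` query
#'   TCEs; `NULL` for an edgeless graph), `vertices`, `edges` (canonical
#'   form).
#' @export
graph_to_pcap <- function(edges, vertices = NULL) {
  edges <- canonical_edges(edges)
  verts <- unique(c(as.character(vertices),
                    as.character(edges[, 1]), as.character(edges[, 2])))
  if (nrow(edges) == 0)
    return(list(instance = NULL, vertices = verts, edges = edges))
  nE <- nrow(edges)
  touched <- unique(c(edges[, 1], edges[, 2]))
  theta <- array(0, dim = c(length(touched), 3, nE),
                 dimnames = list(touched,
                                 c("color1", "color2", "color3"), NULL))
  for (e in seq_len(nE)) {
    theta[edges[e, 1], , e] <- 1
    theta[edges[e, 2], , e] <- 1
  }
  list(instance = pcap_instance(theta), vertices = verts, edges = edges)
}

canonical_edges <- function(edges) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2) stop("edges must have two columns")
  edges <- matrix(as.character(edges), ncol = 2)
  if (nrow(edges) > 0) {
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    flip <- edges[, 1] > edges[, 2]
    edges[flip, ] <- edges[flip, 2:1]
    edges <- unique(edges)
  }
  edges
}

#' Decide 3-colorability through the assignment solver
#'
#' Solves the PCAP instance built by [graph_to_pcap()] (with the `mu`
#' objective weighting disabled, so that feasibility rather than weighting
#' decides) and reports whether the optimum assigns every vertex with at
#' least one incident edge to a query. By the reduction's correctness this
#' holds if and only if the graph is 3-colorable; a witness coloring is
#' returned when it exists (isolated vertices get color 1).
#'
#' @inheritParams graph_to_pcap
#' @return list with `colorable` (logical) and `coloring` (named integer
#'   vector in 1..3, or `NULL`).
#' @export
decide_3col_via_pcap <- function(edges, vertices = NULL) {
  red <- graph_to_pcap(edges, vertices)
  if (is.null(red$instance)) {
    col <- stats::setNames(rep(1L, length(red$vertices)), red$vertices)
    return(list(colorable = TRUE, coloring = col))
  }
  sol <- solve_pcap(red$instance, mu_weight = FALSE)
  C <- sol$C
  if (any(is.na(C))) return(list(colorable = FALSE, coloring = NULL))
  col <- stats::setNames(rep(1L, length(red$vertices)), red$vertices)
  col[red$instance$contig_ids] <- as.integer(C)
  list(colorable = TRUE, coloring = col)
}

#' Exhaustive 3-coloring by backtracking
#'
#' Straightforward vertex-by-vertex backtracking enumeration, independent of
#' the assignment machinery; intended as the reference oracle for
#' [decide_3col_via_pcap()] on small graphs.
#'
#' @inheritParams graph_to_pcap
#' @return list with `colorable` and `coloring` as in
#'   [decide_3col_via_pcap()].
#' @export
find_3coloring <- function(edges, vertices = NULL) {
  edges <- canonical_edges(edges)
  verts <- unique(c(as.character(vertices),
                    as.character(edges[, 1]), as.character(edges[, 2])))
  n <- length(verts)
  if (n == 0) return(list(colorable = TRUE, coloring = stats::setNames(integer(0), character(0))))
  adj <- vector("list", n)
  for (e in seq_len(nrow(edges))) {
    a <- match(edges[e, 1], verts); b <- match(edges[e, 2], verts)
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  col <- integer(n)
  rec <- function(v) {
    if (v > n) return(TRUE)
    for (c in 1:3) {
      if (!any(col[adj[[v]]] == c)) {
        col[v] <<- c
        if (rec(v + 1L)) return(TRUE)
        col[v] <<- 0L
      }
    }
    FALSE
  }
  if (rec(1L)) list(colorable = TRUE, coloring = stats::setNames(col, verts))
  else list(colorable = FALSE, coloring = NULL)
}

#' Read an edge list from a text file
#'
#' One edge per line, two whitespace-separated vertex ids; empty lines and
#' `#` comments ignored.
#'
#' @param path file path.
#' @return two-column character matrix.
#' @export
read_edge_list <- function(path) {
  lines <- read_input_lines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(matrix(character(0), ncol = 2))
  parts <- strsplit(lines, "[[:space:]]+")
  if (any(vapply(parts, length, 1L) != 2))
    stop("edge list lines must contain exactly two vertex ids")
  do.call(rbind, parts)
}
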