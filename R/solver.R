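#' Exact solver for the paralog-to-contig assignment problem
#'
#' Maximises the ILP objective
#' `sum_i sum_j sum_k mu[i] * theta[i,j,k] * E[i,j,k]`
#' over binary variables `C[i,j]` (paralog `j` assigned to contig `i`) and
#' `E[i,j,k]` (TCE `k` of paralog `j` assigned to contig `i`) subject to:
#' each TCE `(j, k)` assigned to at most one contig and each contig carrying
#' at most one paralog; `C[i,j] = 0` when paralog `j` has no positive hit on
#' contig `i`; `C` and `E` linked so that `C[i,j] = 1` iff some `E[i,j,k] = 1`;
#' `mu[i] * C[i,j] <= sum_{k: theta[i,j,k]>0} E[i,j,k]` (an assigned contig
#' takes all TCE groups present on it); and `E[i,j,k] = 0` for TCE types
#' without any positive score on contig `i`.
#'
#' Because the linking constraints force an all-or-nothing take of the
#' positive-score TCE set `K[i,j]` once `C[i,j] = 1`, the search reduces to
#' choosing at most one paralog per contig such that no two chosen contigs
#' consume the same `(j, k)`. The solver runs an exact depth-first
#' branch-and-bound over this space (the problem is NP-complete, so
#' worst-case exponential time is unavoidable); instances decompose into
#' independent components of contigs coupled through shared TCEs, which are
#' solved separately. Ties between equal-objective optima are broken towards
#' the lexicographically smallest assignment in `(contig, paralog)` index
#' order, so results are reproducible.
#'
#' With `relaxed_eq7 = TRUE` the all-take constraint counts only the TCE
#' groups for which *this* paralog has positive scores
#' (`|K[i,j]| * C[i,j] <= sum E`), instead of all groups present on the
#' contig; the default requires a candidate paralog to cover every TCE group
#' found on the contig. `mu_weight = FALSE` drops the `mu` objective
#' multiplier (used for decision-type instances such as the 3-coloring
#' reduction, where feasibility rather than weighting should decide).
#'
#' @param instance a `pcap_instance`.
#' @param mu_weight multiply each score by the contig's `mu` (default TRUE).
#' @param relaxed_eq7 per-paralog instead of per-contig all-take constraint.
#' @param banned list of C vectors (integer, NA = unassigned) that may not be
#'   returned; used for sub-optimal solution enumeration.
#' @return object of class `pcap_assignment`: list with `C` (named integer
#'   vector over contigs, value = paralog index or NA), `E` (data frame
#'   `contig`, `paralog`, `tce`), `objective`, `status`.
#' @seealso [brute_force_pcap()] for the exhaustive oracle,
#'   [enumerate_pcap()] for ranked sub-optimal solutions,
#'   [validate_assignment()] for the independent constraint checker.
#' @export
solve_pcap <- function(instance, mu_weight = TRUE, relaxed_eq7 = FALSE,
                       banned = list()) {
  stopifnot(inherits(instance, "pcap_instance"))
  if (all(instance$theta <= 0)) stop("nothing to assign: no positive score")
  cand <- candidate_sets(instance, mu_weight, relaxed_eq7)
  n <- instance$n_contigs
  if (length(banned) == 0) {
    # independent components can be solved separately
    comp <- contig_components(instance)
    C <- rep(NA_integer_, n)
    for (cc in split(seq_len(n), comp)) {
      r <- dfs_branch_bound(cand, cc, instance$n_paralogs,
                            instance$n_tce_types, banned = list())
      if (is.null(r)) stop("internal error: component search failed")
      C[cc] <- r$C[cc]
    }
  } else {
    r <- dfs_branch_bound(cand, seq_len(n), instance$n_paralogs,
                          instance$n_tce_types, banned = banned)
    if (is.null(r))
      return(structure(list(C = NULL, E = NULL, objective = NA_real_,
                            status = "infeasible"),
                       class = "pcap_assignment"))
    C <- r$C
  }
  assignment_from_C(instance, C, mu_weight, relaxed_eq7)
}

# per (contig, paralog): positive-score TCE set, candidate flag and value
candidate_sets <- function(instance, mu_weight, relaxed_eq7) {
  theta <- instance$theta
  mu <- instance$mu
  P <- instance$n_paralogs
  w <- if (mu_weight) mu else rep(1, length(mu))
  lapply(seq_len(instance$n_contigs), function(i) {
    js <- integer(); vals <- numeric(); ks <- list()
    for (j in seq_len(P)) {
      K <- which(theta[i, j, ] > 0)
      ok <- if (relaxed_eq7) length(K) >= 1 else length(K) == mu[i]
      if (ok && length(K) >= 1) {
        js <- c(js, j); ks[[length(ks) + 1L]] <- K
        vals <- c(vals, w[i] * sum(theta[i, j, K]))
      }
    }
    o <- order(-vals, js)
    list(js = js[o], vals = vals[o], ks = ks[o],
         max_val = if (length(vals)) max(vals) else 0)
  })
}

# contigs coupled through a shared (paralog, TCE) cell must be solved jointly
contig_components <- function(instance) {
  theta <- instance$theta
  n <- instance$n_contigs
  A <- matrix(theta > 0, nrow = n)  # contigs x (paralog, tce) incidence
  adj <- (A %*% t(A)) > 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$membership
}

# exact DFS with suffix-sum upper bound; explores objective ties to apply the
# lexicographic tie-break, skips banned complete C maps
dfs_branch_bound <- function(cand, contigs, n_paralogs, n_tce, banned) {
  tol <- 1e-9
  ord <- contigs[order(-vapply(cand[contigs], `[[`, 0, "max_val"))]
  suffix <- rev(cumsum(rev(vapply(cand[ord], `[[`, 0, "max_val"))))
  suffix <- c(suffix, 0)
  used <- matrix(FALSE, n_paralogs, n_tce)
  n_all <- length(cand)
  assign_now <- rep(NA_integer_, n_all)
  best <- new.env(parent = emptyenv())
  best$val <- -Inf
  best$C <- NULL
  banned_enc <- lapply(banned, encode_C, n_paralogs = n_paralogs)

  lex_better <- function(a, b) {
    ae <- encode_C(a, n_paralogs); be <- encode_C(b, n_paralogs)
    d <- which(ae != be)
    length(d) > 0 && ae[d[1]] < be[d[1]]
  }

  rec <- function(pos, cur) {
    if (pos > length(ord)) {
      if (length(banned_enc) > 0) {
        enc <- encode_C(assign_now, n_paralogs)
        for (b in banned_enc) if (identical(b, enc)) return(invisible())
      }
      if (cur > best$val + tol ||
          (cur >= best$val - tol &&
           (is.null(best$C) || lex_better(assign_now, best$C)))) {
        if (cur > best$val) best$val <- cur
        best$C <- assign_now
      }
      return(invisible())
    }
    if (cur + suffix[pos] < best$val - tol) return(invisible())
    i <- ord[pos]
    ci <- cand[[i]]
    for (t in seq_along(ci$js)) {
      j <- ci$js[t]; K <- ci$ks[[t]]
      if (!any(used[j, K])) {
        used[j, K] <<- TRUE
        assign_now[i] <<- j
        rec(pos + 1L, cur + ci$vals[t])
        used[j, K] <<- FALSE
        assign_now[i] <<- NA_integer_
      }
    }
    rec(pos + 1L, cur)  # leave contig unassigned
  }
  rec(1L, 0)
  if (is.null(best$C)) NULL else list(C = best$C, objective = best$val)
}

encode_C <- function(C, n_paralogs) {
  x <- as.integer(C)
  x[is.na(x)] <- n_paralogs + 1L
  x
}

# derive E (the full positive-score TCE set of every selected pair) and the
# objective from a C vector
assignment_from_C <- function(instance, C, mu_weight = TRUE,
                              relaxed_eq7 = FALSE) {
  theta <- instance$theta
  w <- if (mu_weight) instance$mu else rep(1, instance$n_contigs)
  E <- list(); obj <- 0
  for (i in seq_len(instance$n_contigs)) {
    j <- C[i]
    if (!is.na(j)) {
      K <- which(theta[i, j, ] > 0)
      E[[length(E) + 1L]] <- data.frame(contig = i, paralog = j, tce = K)
      obj <- obj + w[i] * sum(theta[i, j, K])
    }
  }
  E <- if (length(E)) do.call(rbind, E) else
    data.frame(contig = integer(), paralog = integer(), tce = integer())
  names(C) <- instance$contig_ids
  structure(list(C = C, E = E, objective = unname(obj), status = "optimal",
                 mu_weight = mu_weight, relaxed_eq7 = relaxed_eq7,
                 contig_ids = instance$contig_ids,
                 paralog_ids = instance$paralog_ids),
            class = "pcap_assignment")
}

#' @export
print.pcap_assignment <- function(x, ...) {
  cat(sprintf("pcap_assignment (%s), objective %.4g\n", x$status, x$objective))
  if (is.null(x$C)) return(invisible(x))
  for (i in which(!is.na(x$C))) {
    ks <- x$E$tce[x$E$contig == i]
    cat(sprintf("  %s -> %s [TCE %s]\n", x$contig_ids[i],
                x$paralog_ids[x$C[i]], paste(ks, collapse = ",")))
  }
  invisible(x)
}

#' Objective value of an assignment
#'
#' Computes `sum_{E set} mu[i] * theta[i,j,k]` (or unweighted with
#' `mu_weight = FALSE`). Errors if `E` contains a variable for a TCE type
#' with no positive score of any paralog on that contig, which the ILP
#' forbids outright.
#'
#' @param instance a `pcap_instance`.
#' @param assignment a `pcap_assignment` (or list with an `E` data frame).
#' @param mu_weight as in [solve_pcap()].
#' @return numeric objective value.
#' @export
pcap_objective <- function(instance, assignment, mu_weight = TRUE) {
  E <- assignment$E
  if (is.null(E) || nrow(E) == 0) return(0)
  theta <- instance$theta
  if (any(E$tce < 1 | E$tce > instance$n_tce_types) ||
      any(E$contig < 1 | E$contig > instance$n_contigs))
    stop("E set for a TCE type with no positive score on the contig")
  any_pos <- apply(theta > 0, c(1, 3), any)
  if (any(!any_pos[cbind(E$contig, E$tce)]))
    stop("E set for a TCE type with no positive score on the contig")
  w <- if (mu_weight) instance$mu else rep(1, instance$n_contigs)
  sum(w[E$contig] * theta[cbind(E$contig, E$paralog, E$tce)])
}

#' Exhaustive brute-force oracle for PCAP
#'
#' Enumerates every map of contigs to (paralog | unassigned), derives the
#' TCE variables for each map (an assigned contig takes the full
#' positive-score TCE set of its paralog), discards maps that violate any of
#' the ILP constraints, and returns the maximum-objective assignment. This
#' is a deliberately naive, solver-independent reference implementation used
#' to validate [solve_pcap()]; the search space `(n_paralogs + 1) ^
#' n_contigs` must stay below `max_space`.
#'
#' @inheritParams solve_pcap
#' @param max_space refuse to enumerate larger search spaces.
#' @return a `pcap_assignment`.
#' @export
brute_force_pcap <- function(instance, mu_weight = TRUE, relaxed_eq7 = FALSE,
                             max_space = 1e6) {
  stopifnot(inherits(instance, "pcap_instance"))
  if (all(instance$theta <= 0)) stop("nothing to assign: no positive score")
  n <- instance$n_contigs
  P <- instance$n_paralogs
  if ((P + 1)^n > max_space)
    stop(sprintf("search space (%d+1)^%d exceeds max_space", P, n))
  theta <- instance$theta
  mu <- instance$mu
  w <- if (mu_weight) mu else rep(1, n)
  Ksets <- lapply(seq_len(n), function(i)
    lapply(seq_len(P), function(j) which(theta[i, j, ] > 0)))
  best_val <- -Inf; best_C <- NULL
  counter <- rep(0L, n)  # 0 = unassigned, 1..P = paralog
  repeat {
    val <- 0; ok <- TRUE
    seen <- matrix(FALSE, P, instance$n_tce_types)
    for (i in seq_len(n)) {
      j <- counter[i]
      if (j == 0L) next
      K <- Ksets[[i]][[j]]
      need <- if (relaxed_eq7) length(K) >= 1 else length(K) == mu[i]
      if (!need || any(seen[j, K])) { ok <- FALSE; break }
      seen[j, K] <- TRUE
      val <- val + w[i] * sum(theta[i, j, K])
    }
    if (ok && val > best_val) { best_val <- val; best_C <- counter }
    # increment base-(P+1) counter
    pos <- 1L
    while (pos <= n) {
      counter[pos] <- counter[pos] + 1L
      if (counter[pos] <= P) break
      counter[pos] <- 0L
      pos <- pos + 1L
    }
    if (pos > n) break
  }
  C <- ifelse(best_C == 0L, NA_integer_, best_C)
  assignment_from_C(instance, C, mu_weight, relaxed_eq7)
}

#' Enumerate ranked (sub-)optimal assignments
#'
#' Repeatedly re-solves the instance, each time adding a no-good cut that
#' excludes the complete `C` pattern of every previously returned solution,
#' so alternatives differ in their paralog-to-contig structure. Stops after
#' `max_n` solutions or when no feasible unseen `C` map remains. Ranked
#' alternatives are useful to judge how reliable the optimal assignment is:
#' a large objective gap to the runner-up indicates a well-determined
#' solution.
#'
#' @inheritParams solve_pcap
#' @param max_n maximum number of solutions to return.
#' @return object of class `pcap_solutions`: list with `best`,
#'   `alternatives` (list of `pcap_assignment`, non-increasing objective,
#'   the first being `best`) and `status`.
#' @export
enumerate_pcap <- function(instance, max_n = 3, mu_weight = TRUE,
                           relaxed_eq7 = FALSE) {
  stopifnot(max_n >= 1)
  sols <- list(); banned <- list()
  status <- "optimal"
  for (s in seq_len(max_n)) {
    r <- solve_pcap(instance, mu_weight = mu_weight,
                    relaxed_eq7 = relaxed_eq7, banned = banned)
    if (r$status == "infeasible") { status <- "optimal"; break }
    sols[[length(sols) + 1L]] <- r
    banned[[length(banned) + 1L]] <- unname(r$C)
  }
  if (length(sols) == max_n) status <- "limit"
  structure(list(best = sols[[1]], alternatives = sols, status = status),
            class = "pcap_solutions")
}

#' Independent constraint checker for PCAP assignments
#'
#' Verifies all ILP constraints directly on the raw `C`/`E` variables,
#' without reusing any of the solver's machinery: per-TCE and per-contig
#' uniqueness, no assignment without hits, the C/E linking in both
#' directions, the all-take constraint (per-contig `mu` form by default,
#' per-paralog form with `relaxed_eq7 = TRUE`), and the exclusion of TCE
#' variables for types absent from the contig.
#'
#' @inheritParams pcap_objective
#' @param relaxed_eq7 which all-take variant to check.
#' @return `TRUE` if all constraints hold, otherwise a character vector
#'   describing every violation (with `valid = FALSE` semantics).
#' @export
validate_assignment <- function(instance, assignment, relaxed_eq7 = FALSE) {
  theta <- instance$theta
  n <- instance$n_contigs; P <- instance$n_paralogs; m <- instance$n_tce_types
  C <- matrix(0L, n, P)
  sel <- which(!is.na(assignment$C))
  C[cbind(sel, assignment$C[sel])] <- 1L
  E <- array(0L, dim = c(n, P, m))
  if (nrow(assignment$E) > 0)
    E[as.matrix(assignment$E[, c("contig", "paralog", "tce")])] <- 1L
  bad <- character()
  viol <- function(msg) bad <<- c(bad, msg)

  ejk <- apply(E, c(2, 3), sum)
  if (any(ejk > 1)) viol("a TCE (j,k) is assigned to more than one contig")
  if (any(rowSums(C) > 1)) viol("a contig carries more than one paralog")
  has_hit <- apply(theta > 0, c(1, 2), any)
  if (any(C == 1 & !has_hit)) viol("contig assigned to a paralog without hits on it")
  eij <- apply(E, c(1, 2), sum)
  if (any(C - eij > 0)) viol("C set without any E set (linking, lower)")
  if (any(eij - m * C > 0)) viol("E set without C set (linking, upper)")
  pos_cnt <- apply(theta > 0, c(1, 2), sum)
  epos <- apply(E * (theta > 0), c(1, 2), sum)
  muij <- if (relaxed_eq7) pos_cnt else matrix(instance$mu, n, P)
  if (any(muij * C - epos > 0))
    viol("assigned contig does not take all required TCE groups")
  any_pos <- apply(theta > 0, c(1, 3), any)
  e_ik <- apply(E, c(1, 3), sum)
  if (any(e_ik[!any_pos] > 0))
    viol("E set for a TCE type with no positive score on the contig")
  if (length(bad) == 0) TRUE else bad
}

#' Write an assignment list to a tab-separated file
#'
#' One row per assigned contig: contig id, paralog id, comma-separated TCE
#' list, contribution to the objective; a trailing comment records the total
#' objective.
#'
#' @param assignment a `pcap_assignment`.
#' @param instance the instance it was computed from.
#' @param path output path.
#' @export
write_assignment <- function(assignment, instance, path) {
  sel <- which(!is.na(assignment$C))
  w <- if (isTRUE(assignment$mu_weight)) instance$mu else
    rep(1, instance$n_contigs)
  rows <- vapply(sel, function(i) {
    j <- assignment$C[i]
    ks <- assignment$E$tce[assignment$E$contig == i]
    contrib <- w[i] * sum(instance$theta[i, j, ks])
    sprintf("%s\t%s\t%s\t%.6g", assignment$contig_ids[i],
            assignment$paralog_ids[j], paste(ks, collapse = ","), contrib)
  }, character(1))
  writeLines(c("contig\tparalog\ttce_list\tcontribution", rows,
               sprintf("# objective\t%.6g", assignment$objective)), path)
  invisible(path)
}
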