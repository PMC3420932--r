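#' Incremental objective cost of a candidate edge
#'
#' Evaluates, in constant time per source-target pair, the objective cost
#' of the network with one hypothetical edge `(from, to)` of cost `cost`
#' added, without mutating anything.  For the unrestricted variants the new
#' pair distance is `min(d(s,t), d(s,u) + w' + d(v,t))` from the
#' precomputed forward and reverse Dijkstra tables.  For the hop-restricted
#' variants the split of the hop budget across the two legs is enumerated:
#' `min(d_X(s,t), min_{a=0..X-1} d_a(s,u) + w' + d_{X-1-a}(v,t))`, where
#' `d_0(x,y)` is 0 iff `x == y` and unreachable otherwise — for `X = 5`
#' these are exactly the six cases (three interior splits, the two
#' endpoint cases, and the unchanged old distance).  Unreachable legs
#' propagate; the penalty is applied only at objective reduction time.
#'
#' @param tables Precomputed distance tables from
#'   [precompute_tables()] for the current graph.
#' @param from,to Candidate edge endpoints (must not be an existing edge).
#' @param cost Candidate traversal cost `w'` in \[0, 1\].
#' @return The objective cost of the graph with the candidate added.
#' @export
candidate_new_cost <- function(tables, from, to, cost = 0) {
  net <- tables$net
  spec <- tables$spec
  if (edge_key(from, to) %in% edge_key(net$edges$from, net$edges$to)) {
    stop(sprintf("candidate %s->%s is already an edge", from, to),
         call. = FALSE)
  }
  if (from == to) stop("candidate self-loop", call. = FALSE)
  if (!all(c(from, to) %in% net$nodes)) {
    stop("candidate endpoints must be nodes of the network", call. = FALSE)
  }
  D <- tables$D
  if (!spec$hop_restricted) {
    path <- outer(tables$Fwd[, from], tables$Bwd[, to], "+") + cost
  } else {
    X <- spec$hops
    path <- matrix(Inf, nrow(D), ncol(D))
    for (a in 0:(X - 1L)) {
      leg <- outer(tables$Fk[[a + 1L]][, from],
                   tables$Bk[[X - a]][, to], "+")
      path <- pmin(path, leg)
    }
    path <- path + cost
  }
  newD <- pmin(D, path)
  attr(newD, "n_nodes") <- tables$n
  objective_cost(newD, spec, tables$n)
}

#' Precompute the distance tables used by incremental candidate scoring
#'
#' Runs the per-source forward and per-target reverse distance kernels
#' (Dijkstra, or the bounded-hop Bellman-Ford tables for `-x` variants) on
#' the current graph and bundles them with the source-target pair distance
#' matrix.  One precomputation serves the evaluation of every candidate
#' edge at that greedy step.
#'
#' @param net A `pathway_network`.
#' @param ends A `pathway_endpoints`.
#' @param spec An `objective_spec`.
#' @return An opaque tables object for [candidate_new_cost()].
#' @export
precompute_tables <- function(net, ends, spec) {
  distance_tables(net, ends, spec)
}

# Dense scoring: new objective cost for EVERY ordered node pair at once.
# W is an n x n matrix of candidate costs (entries outside `mask` ignored);
# returns an n x n matrix of new objective costs with non-candidates = NA.
# Mathematically identical to candidate_new_cost() per cell; vectorized
# over pairs so a greedy step over ~n^2 candidates stays affordable.
score_all_candidates <- function(tables, W, mask) {
  spec <- tables$spec
  n <- tables$n
  D <- tables$D
  penalty <- resolve_penalty(spec, n)
  S <- seq_len(nrow(D))
  Tt <- seq_len(ncol(D))
  total <- matrix(0, n, n)
  for (tj in Tt) {
    per_target <- NULL
    for (si in S) {
      if (!spec$hop_restricted) {
        path <- outer(tables$Fwd[si, ], tables$Bwd[tj, ], "+")
      } else {
        X <- spec$hops
        path <- matrix(Inf, n, n)
        for (a in 0:(X - 1L)) {
          path <- pmin(path, outer(tables$Fk[[a + 1L]][si, ],
                                   tables$Bk[[X - a]][tj, ], "+"))
        }
      }
      P <- pmin(path + W, D[si, tj])
      P[is.infinite(P)] <- penalty
      if (spec$single_source) {
        per_target <- if (is.null(per_target)) P else pmin(per_target, P)
      } else {
        total <- total + P
      }
    }
    if (spec$single_source) total <- total + per_target
  }
  total[!mask] <- NA_real_
  total
}

# usage counts for the Betweenness baseline: number of source-target pairs
# (or targets, for -ss variants) whose distance the candidate reduces.
# strict = TRUE counts strict reductions; FALSE counts candidates lying on
# a (possibly tied) shortest path.
usage_counts <- function(tables, W, mask, strict = TRUE) {
  spec <- tables$spec
  n <- tables$n
  D <- tables$D
  cmp <- if (strict) {
    function(path, old) path < old - TIE_TOL
  } else {
    function(path, old) is.finite(path) & path <= old + TIE_TOL
  }
  counts <- matrix(0, n, n)
  for (tj in seq_len(ncol(D))) {
    if (spec$single_source) {
      old <- min(D[, tj])
      newmin <- NULL
    }
    for (si in seq_len(nrow(D))) {
      if (!spec$hop_restricted) {
        path <- outer(tables$Fwd[si, ], tables$Bwd[tj, ], "+")
      } else {
        X <- spec$hops
        path <- matrix(Inf, n, n)
        for (a in 0:(X - 1L)) {
          path <- pmin(path, outer(tables$Fk[[a + 1L]][si, ],
                                   tables$Bk[[X - a]][tj, ], "+"))
        }
      }
      path <- path + W
      if (spec$single_source) {
        P <- pmin(path, D[si, tj])
        newmin <- if (is.null(newmin)) P else pmin(newmin, P)
      } else {
        counts <- counts + cmp(path, D[si, tj])
      }
    }
    if (spec$single_source) counts <- counts + cmp(newmin, min(D[, tj]))
  }
  counts[!mask] <- NA_real_
  counts
}

# build the n x n candidate cost matrix and mask from a candidate frame
candidate_matrices <- function(net, candidates) {
  n <- n_nodes(net)
  W <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  mask <- matrix(FALSE, n, n, dimnames = list(net$nodes, net$nodes))
  idx <- cbind(match(candidates$from, net$nodes),
               match(candidates$to, net$nodes))
  W[idx] <- candidates$cost
  mask[idx] <- TRUE
  list(W = W, mask = mask)
}

new_prediction_list <- function(rows, method, spec, k, seed,
                                candidate_source, stop_reason, penalty) {
  df <- if (length(rows) == 0L) {
    data.frame(rank = integer(), from = character(), to = character(),
               cost = numeric(), objective_before = numeric(),
               objective_after = numeric(), delta = numeric(),
               tie_count = integer(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  rownames(df) <- NULL
  structure(df, class = c("prediction_list", "data.frame"),
            method = method, spec = spec, k = k, seed = seed,
            candidate_source = candidate_source, stop_reason = stop_reason,
            penalty = penalty)
}

#' @export
print.prediction_list <- function(x, ...) {
  at <- attributes(x)
  cat(sprintf("prediction_list (%s, %s): %d edge(s)%s\n",
              at$method, at$spec$variant %||% "no objective", nrow(x),
              if (!is.null(at$stop_reason) && at$stop_reason != "budget")
                sprintf(" [stopped early: %s]", at$stop_reason) else ""))
  print.data.frame(x, ...)
  invisible(x)
}

# Shared engine for Greedy and Direct-ST: repeatedly add the candidate
# minimizing the new objective cost, with seeded uniform tie-breaking.
run_objective_predictor <- function(net, ends, spec, k, candidates, seed,
                                    method, candidate_source) {
  validate_endpoints(ends, net)
  if (!is.numeric(k) || k < 1 || k != round(k)) {
    stop("`k` must be a positive integer", call. = FALSE)
  }
  candidates <- check_candidates(net, candidates)
  if (!is.null(seed)) set.seed(seed)
  penalty <- resolve_penalty(spec, n_nodes(net))
  rows <- list()
  stop_reason <- "budget"
  for (step in seq_len(k)) {
    if (nrow(candidates) == 0L) {
      stop_reason <- "candidate pool exhausted"
      break
    }
    tables <- distance_tables(net, ends, spec)
    current <- objective_cost(tables$D, spec, n_nodes(net))
    cm <- candidate_matrices(net, candidates)
    scores <- score_all_candidates(tables, cm$W, cm$mask)
    cand_idx <- cbind(match(candidates$from, net$nodes),
                      match(candidates$to, net$nodes))
    vals <- scores[cand_idx]
    best <- min(vals)
    if (current - best <= TIE_TOL) {
      stop_reason <- "no candidate strictly reduces the objective"
      break
    }
    ties <- which(vals <= best + TIE_TOL)
    pick <- ties[sample.int(length(ties), 1L)]
    chosen <- candidates[pick, , drop = FALSE]
    rows[[step]] <- data.frame(rank = step,
                               from = chosen$from, to = chosen$to,
                               cost = chosen$cost,
                               objective_before = current,
                               objective_after = vals[pick],
                               delta = current - vals[pick],
                               tie_count = length(ties),
                               stringsAsFactors = FALSE)
    net <- add_edges(net, chosen)
    candidates <- candidates[-pick, , drop = FALSE]
  }
  new_prediction_list(rows, method, spec, k, seed, candidate_source,
                      stop_reason, penalty)
}

#' Greedy prediction of missing pathway edges
#'
#' The core predictor: repeat `k` times — recompute all forward/reverse
#' distance tables on the current graph, score every remaining candidate
#' edge with the incremental rule of [candidate_new_cost()], add the
#' candidate minimizing the new objective cost (exact ties, within 1e-12,
#' broken uniformly at random with the seeded generator), and record the
#' step.  Stops early when the candidate pool is exhausted or no candidate
#' strictly reduces the objective.
#'
#' @param net A `pathway_network`.
#' @param ends A `pathway_endpoints`.
#' @param spec An `objective_spec`.
#' @param k Positive integer edge budget.
#' @param candidates Data frame `from`, `to`, `cost` of candidate edges
#'   disjoint from existing edges, or `NULL` for all missing edges at
#'   `default_cost`.
#' @param default_cost Cost for auto-enumerated candidates (default 0).
#' @param seed Integer seed for tie-breaking; `NULL` uses the current RNG
#'   state.
#' @return A `prediction_list`: data frame with columns `rank`, `from`,
#'   `to`, `cost`, `objective_before`, `objective_after`, `delta`,
#'   `tie_count`, plus run metadata in attributes (`method`, `spec`, `k`,
#'   `seed`, `candidate_source`, `stop_reason`, `penalty`).
#' @examples
#' g <- pathway_network(data.frame(from = c("s", "a", "b"),
#'                                 to = c("a", "b", "t"), cost = 0.2))
#' ends <- pathway_endpoints("s", "t")
#' greedy_predict(g, ends, objective_spec("shortcuts"), k = 1, seed = 1)
#' @export
greedy_predict <- function(net, ends, spec, k, candidates = NULL,
                           default_cost = 0, seed = NULL) {
  source_desc <- if (is.null(candidates)) {
    candidates <- missing_edges(net, default_cost)
    "all-missing"
  } else "supplied"
  run_objective_predictor(net, ends, spec, k, candidates, seed,
                          method = "greedy", candidate_source = source_desc)
}

#' Naive best-edge oracle (full recomputation)
#'
#' For every candidate, materializes the graph with that edge added and
#' recomputes [pair_distances()] and [objective_cost()] from scratch.
#' Returns the full tied set of minimizing candidates and the minimum
#' cost.  Quadratically slower than the incremental rule; used as the
#' independent correctness oracle for [greedy_predict()].
#'
#' @inheritParams greedy_predict
#' @param candidates Data frame of candidate edges.
#' @return A list with `best` (data frame of all candidates tied, within
#'   1e-12, at the minimum), `cost` (the minimum new objective cost), and
#'   `costs` (per-candidate new objective costs, in candidate order).
#' @export
naive_best_edge <- function(net, ends, spec, candidates) {
  validate_endpoints(ends, net)
  candidates <- check_candidates(net, candidates)
  costs <- vapply(seq_len(nrow(candidates)), function(i) {
    grown <- add_edges(net, candidates[i, , drop = FALSE])
    network_objective(grown, ends, spec)
  }, numeric(1))
  best <- min(costs)
  list(best = candidates[costs <= best + TIE_TOL, , drop = FALSE],
       cost = best, costs = costs)
}
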