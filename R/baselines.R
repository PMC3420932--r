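#' Direct source-to-target baseline predictor
#'
#' Restricts the candidate pool to missing direct `(source, target)` edges
#' and otherwise runs the same objective-minimizing machinery as
#' [greedy_predict()]: at each step the direct edge giving the largest
#' objective reduction is added.
#'
#' @inheritParams greedy_predict
#' @param default_cost Cost assigned to each direct candidate (default 0).
#' @return A `prediction_list`.
#' @export
direct_st_predict <- function(net, ends, spec, k, default_cost = 0,
                              seed = NULL) {
  validate_endpoints(ends, net)
  cand <- expand.grid(from = ends$sources, to = ends$targets,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cand$cost <- default_cost
  exists <- edge_key(cand$from, cand$to) %in%
    edge_key(net$edges$from, net$edges$to)
  cand <- cand[!exists, , drop = FALSE]
  if (nrow(cand) == 0L) {
    stop("every source-target edge already exists", call. = FALSE)
  }
  run_objective_predictor(net, ends, spec, k, cand, seed,
                          method = "direct-st",
                          candidate_source = "source-target")
}

#' Candidate usage counts for the Betweenness baseline
#'
#' For each candidate edge, counts the source-target pairs (or, for `-ss`
#' variants, the targets) whose distance the candidate would strictly
#' reduce if added — a pair's usage is binary, ignoring the magnitude of
#' the reduction.  With `strict = FALSE` a candidate lying on a tied
#' shortest path also counts as used.
#'
#' @inheritParams greedy_predict
#' @param candidates Data frame of candidate edges (`NULL` for all missing
#'   edges at cost 0).
#' @param strict Count only strict distance reductions (default) or also
#'   ties.
#' @return Numeric vector of counts, one per candidate row, with the
#'   candidate frame attached as attribute `candidates`.
#' @export
betweenness_usage <- function(net, ends, spec, candidates = NULL,
                              strict = TRUE) {
  validate_endpoints(ends, net)
  if (is.null(candidates)) candidates <- missing_edges(net, 0)
  candidates <- check_candidates(net, candidates)
  tables <- distance_tables(net, ends, spec)
  cm <- candidate_matrices(net, candidates)
  U <- usage_counts(tables, cm$W, cm$mask, strict = strict)
  counts <- U[cbind(match(candidates$from, net$nodes),
                    match(candidates$to, net$nodes))]
  attr(counts, "candidates") <- candidates
  counts
}

#' Betweenness baseline predictor
#'
#' At each step adds the candidate used by the most source-target shortest
#' paths (the usage count of [betweenness_usage()]), with seeded uniform
#' tie-breaking.  Objective before/after values are recorded for the chosen
#' edge so cost-reduction curves remain comparable with the other methods,
#' but the selection itself ignores the magnitude of cost reduction.
#'
#' @inheritParams betweenness_usage
#' @param k Positive integer edge budget.
#' @param seed Integer seed for tie-breaking.
#' @return A `prediction_list`.
#' @export
betweenness_predict <- function(net, ends, spec, k, candidates = NULL,
                                seed = NULL, strict = TRUE) {
  validate_endpoints(ends, net)
  if (!is.numeric(k) || k < 1 || k != round(k)) {
    stop("`k` must be a positive integer", call. = FALSE)
  }
  source_desc <- if (is.null(candidates)) "all-missing" else "supplied"
  if (is.null(candidates)) candidates <- missing_edges(net, 0)
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
    U <- usage_counts(tables, cm$W, cm$mask, strict = strict)
    idx <- cbind(match(candidates$from, net$nodes),
                 match(candidates$to, net$nodes))
    counts <- U[idx]
    ties <- which(counts >= max(counts) - 0.5)
    pick <- ties[sample.int(length(ties), 1L)]
    chosen <- candidates[pick, , drop = FALSE]
    after <- candidate_new_cost(tables, chosen$from, chosen$to, chosen$cost)
    rows[[step]] <- data.frame(rank = step, from = chosen$from,
                               to = chosen$to, cost = chosen$cost,
                               objective_before = current,
                               objective_after = after,
                               delta = current - after,
                               tie_count = length(ties),
                               stringsAsFactors = FALSE)
    net <- add_edges(net, chosen)
    candidates <- candidates[-pick, , drop = FALSE]
  }
  new_prediction_list(rows, "betweenness", spec, k, seed, source_desc,
                      stop_reason, penalty)
}

# dense weighted-Jaccard scores for every unordered non-adjacent pair
jaccard_matrix <- function(net) {
  C <- confidence_matrix(net)
  A <- (C > 0) * 1
  ncommon <- A %*% A
  numsum <- C %*% A + A %*% C
  strength <- rowSums(C)
  denom <- outer(strength, strength, "+")
  score <- ncommon * numsum / denom
  score[!is.finite(score)] <- 0
  score
}

#' Weighted Jaccard score of a non-adjacent node pair
#'
#' A common-neighbor link score over undirected neighborhoods (the union
#' of in- and out-neighbors; a neighbor adjacent in both directions
#' contributes its maximum-confidence incidence once).  With common
#' neighborhood `C = N(u) n N(v)` and confidences `c`:
#' `|C| * sum_{x in C} (c(u,x) + c(v,x)) / (sum_{x in N(u)} c(u,x) +
#' sum_{x in N(v)} c(v,x))` — the shared-neighbor weight mass normalized by
#' each protein's total neighbor weight, biased toward pairs with more
#' common neighbors.
#'
#' @param net A `pathway_network`.
#' @param u,v Distinct node identifiers, non-adjacent in either direction.
#' @return Nonnegative scalar score.
#' @export
jaccard_score <- function(net, u, v) {
  if (u == v) stop("u and v must differ", call. = FALSE)
  if (!all(c(u, v) %in% net$nodes)) {
    stop("u and v must be nodes of the network", call. = FALSE)
  }
  A <- adjacency_mask(net)
  if (A[u, v] || A[v, u]) {
    stop(sprintf("%s and %s are adjacent", u, v), call. = FALSE)
  }
  jaccard_matrix(net)[u, v]
}

fill_objective_columns <- function(rows, nets, ends, spec) {
  # recompute the objective along the replayed sequence of grown graphs
  for (i in seq_along(rows)) {
    rows[[i]]$objective_before <- network_objective(nets[[i]], ends, spec)
    rows[[i]]$objective_after <- network_objective(nets[[i + 1L]], ends, spec)
    rows[[i]]$delta <- rows[[i]]$objective_before - rows[[i]]$objective_after
  }
  rows
}

#' Weighted Jaccard baseline predictor
#'
#' A global (endpoint-agnostic) predictor: at each step adds an edge
#' between the two non-adjacent nodes with the highest [jaccard_score()],
#' with seeded uniform tie-breaking.  The emitted directed edge is oriented
#' lexicographically; evaluation matches unordered pairs, so the
#' orientation cannot change accuracy numbers.  Scores are recomputed after
#' each addition.
#'
#' @param net A `pathway_network`.
#' @param k Positive integer edge budget.
#' @param seed Integer seed for tie-breaking.
#' @param default_cost Cost of each added edge (default 0).
#' @param ends,spec Optional endpoints and objective; when supplied the
#'   objective columns are filled by recomputation so the prediction list
#'   is curve-comparable with the objective-driven methods.
#' @return A `prediction_list`.
#' @export
jaccard_predict <- function(net, k, seed = NULL, default_cost = 0,
                            ends = NULL, spec = NULL) {
  if (!is.numeric(k) || k < 1 || k != round(k)) {
    stop("`k` must be a positive integer", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  nets <- list(net)
  stop_reason <- "budget"
  for (step in seq_len(k)) {
    S <- jaccard_matrix(net)
    A <- adjacency_mask(net)
    eligible <- upper.tri(S) | lower.tri(S)
    eligible[A | t(A)] <- FALSE
    eligible[lower.tri(eligible)] <- FALSE   # unordered: one cell per pair
    cand <- which(eligible, arr.ind = TRUE)
    if (nrow(cand) == 0L) {
      stop_reason <- "no non-adjacent pair left"
      break
    }
    vals <- S[cand]
    ties <- which(vals >= max(vals) - TIE_TOL)
    pick <- ties[sample.int(length(ties), 1L)]
    a <- net$nodes[cand[pick, 1L]]
    b <- net$nodes[cand[pick, 2L]]
    edge <- data.frame(from = min(a, b), to = max(a, b), cost = default_cost,
                       stringsAsFactors = FALSE)
    rows[[step]] <- data.frame(rank = step, from = edge$from, to = edge$to,
                               cost = edge$cost,
                               objective_before = NA_real_,
                               objective_after = NA_real_, delta = NA_real_,
                               tie_count = length(ties),
                               score = vals[pick], stringsAsFactors = FALSE)
    net <- add_edges(net, edge)
    nets[[step + 1L]] <- net
  }
  if (!is.null(ends) && !is.null(spec)) {
    rows <- fill_objective_columns(rows, nets, ends, spec)
  }
  new_prediction_list(rows, "jaccard", spec %||% list(variant = NULL),
                      k, seed, "all-non-adjacent", stop_reason,
                      penalty = NULL)
}

#' Shortest-path baseline predictor
#'
#' A global (endpoint-agnostic) predictor: at each step adds the ordered
#' non-adjacent pair `(u, v)` with the smallest directed shortest-path
#' distance `d(u, v)` (unreachable pairs are ineligible), with seeded
#' uniform tie-breaking; distances are recomputed on the grown graph after
#' each addition.
#'
#' @inheritParams jaccard_predict
#' @return A `prediction_list`.
#' @export
short_path_predict <- function(net, k, seed = NULL, default_cost = 0,
                               ends = NULL, spec = NULL) {
  if (!is.numeric(k) || k < 1 || k != round(k)) {
    stop("`k` must be a positive integer", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  nets <- list(net)
  stop_reason <- "budget"
  for (step in seq_len(k)) {
    Dall <- igraph::distances(as_igraph(net), mode = "out",
                              algorithm = "dijkstra")[net$nodes, net$nodes]
    A <- adjacency_mask(net)
    Dall[A] <- Inf
    diag(Dall) <- Inf
    if (!any(is.finite(Dall))) {
      stop_reason <- "no finite-distance non-adjacent pair left"
      break
    }
    best <- min(Dall)
    ties <- which(Dall <= best + TIE_TOL)
    pick <- ties[sample.int(length(ties), 1L)]
    ij <- arrayInd(pick, dim(Dall))
    edge <- data.frame(from = net$nodes[ij[1L]], to = net$nodes[ij[2L]],
                       cost = default_cost, stringsAsFactors = FALSE)
    rows[[step]] <- data.frame(rank = step, from = edge$from, to = edge$to,
                               cost = edge$cost,
                               objective_before = NA_real_,
                               objective_after = NA_real_, delta = NA_real_,
                               tie_count = length(ties),
                               score = best, stringsAsFactors = FALSE)
    net <- add_edges(net, edge)
    nets[[step + 1L]] <- net
  }
  if (!is.null(ends) && !is.null(spec)) {
    rows <- fill_objective_columns(rows, nets, ends, spec)
  }
  new_prediction_list(rows, "short-path", spec %||% list(variant = NULL),
                      k, seed, "all-non-adjacent", stop_reason,
                      penalty = NULL)
}
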