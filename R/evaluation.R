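#' Cost-reduction curve
#'
#' Replays a prediction list's edges in rank order on the original graph,
#' recomputing the objective cost from scratch after each addition, and
#' reports the cost as a percent of the original cost.  A warning is
#' emitted when the original cost contains unreachable-pair penalty terms,
#' since percent-of-original is then penalty-dominated.
#'
#' @param net The original `pathway_network` (predicted edges must be
#'   absent from it).
#' @param ends A `pathway_endpoints`.
#' @param spec An `objective_spec`.
#' @param predictions A `prediction_list` or data frame with `from`, `to`,
#'   `cost` in rank order.
#' @return A `cost_curve` data frame with columns `edges_added` (0-based),
#'   `cost`, `percent_of_original`.
#' @export
cost_curve <- function(net, ends, spec, predictions) {
  validate_endpoints(ends, net)
  predictions <- as.data.frame(predictions, stringsAsFactors = FALSE)
  if (nrow(predictions) > 0L &&
      any(edge_key(predictions$from, predictions$to) %in%
          edge_key(net$edges$from, net$edges$to))) {
    stop("a predicted edge is already present in the network", call. = FALSE)
  }
  pd0 <- pair_distances(net, ends, spec)
  if (any(is.infinite(pd0))) {
    warning(sprintf(
      "%d source-target pair(s) unreachable at rank 0; curve is penalty-substituted",
      sum(is.infinite(pd0))), call. = FALSE)
  }
  original <- objective_cost(pd0, spec, n_nodes(net))
  cost <- numeric(nrow(predictions) + 1L)
  cost[1L] <- original
  for (i in seq_len(nrow(predictions))) {
    net <- add_edges(net, predictions[i, c("from", "to", "cost")])
    cost[i + 1L] <- network_objective(net, ends, spec)
  }
  out <- data.frame(edges_added = 0:nrow(predictions), cost = cost,
                    percent_of_original = 100 * cost / original)
  class(out) <- c("cost_curve", "data.frame")
  out
}

#' Accuracy of the top-k predictions against a reference set
#'
#' A rank `<= k` prediction `(u, v)` counts as correct when its unordered
#' pair lies in the reference set (reference databases are undirected, so
#' direction is ignored) and, when `node_filter` is given, both endpoints
#' belong to the filter set (e.g. known pathway members).  The denominator
#' is the number of evaluated predictions.
#'
#' @param predictions A `prediction_list` or data frame with `from`, `to`.
#' @param reference A `reference_edge_set`.
#' @param k Number of top predictions to evaluate; `NULL` (default) or a
#'   value exceeding the list length uses all predictions (with a warning
#'   in the latter case).
#' @param node_filter Optional character vector of allowed node
#'   identifiers.
#' @return Fraction in \[0, 1\].
#' @export
accuracy_at_k <- function(predictions, reference, k = NULL,
                          node_filter = NULL) {
  predictions <- as.data.frame(predictions, stringsAsFactors = FALSE)
  if (nrow(reference$pairs) == 0L) {
    stop("reference set is empty", call. = FALSE)
  }
  if (is.null(k)) k <- nrow(predictions)
  if (k > nrow(predictions)) {
    warning(sprintf("only %d prediction(s) available; evaluating all",
                    nrow(predictions)), call. = FALSE)
    k <- nrow(predictions)
  }
  if (k == 0L) return(NaN)
  top <- predictions[seq_len(k), , drop = FALSE]
  hit <- in_reference(reference, top$from, top$to)
  if (!is.null(node_filter)) {
    hit <- hit & top$from %in% node_filter & top$to %in% node_filter
  }
  sum(hit) / k
}

#' Held-out-edge cross-validation
#'
#' Partitions `cv_edges` (a subset of existing edges) into `folds` random
#' folds with the seeded generator.  Per fold: the fold's edges are removed,
#' the configured predictor is run for `top_k` predictions on the reduced
#' graph — with the removed edges eligible again as candidates at
#' `candidate_cost` — and predictions matching a removed edge (ignoring
#' direction) are counted as hits.  Folds that receive no edges are
#' skipped.  If fold removal disconnects source-target pairs the run
#' proceeds under the penalty, with a warning.
#'
#' @param net A `pathway_network`.
#' @param ends A `pathway_endpoints`.
#' @param spec An `objective_spec`.
#' @param cv_edges Data frame `from`, `to` of existing edges to hold out.
#' @param folds Integer number of folds (>= 2).
#' @param top_k Predictions counted per fold.
#' @param method Predictor: `"greedy"`, `"direct-st"` or `"betweenness"`.
#' @param candidate_cost Cost given to candidates in the reduced graph.
#' @param restrict_to Optional `reference_edge_set`; when given, the
#'   candidate pool is restricted to missing edges whose unordered pair
#'   lies in the set (both orientations are offered).
#' @param seed Integer seed controlling the fold partition and tie-breaks.
#' @return A `crossval_report`: list with `folds`, per-fold data frame
#'   `fold_detail` (removed edge count, top_k, hits) and
#'   `recovery_percent` = 100 * total hits / total evaluated predictions.
#' @export
cross_validate <- function(net, ends, spec, cv_edges, folds = 5L,
                           top_k = 10L, method = c("greedy", "direct-st",
                                                   "betweenness"),
                           candidate_cost = 0, restrict_to = NULL,
                           seed = NULL) {
  method <- match.arg(method)
  validate_endpoints(ends, net)
  if (folds < 2L) stop("`folds` must be at least 2", call. = FALSE)
  cv_edges <- as.data.frame(cv_edges, stringsAsFactors = FALSE)
  have <- edge_key(net$edges$from, net$edges$to)
  if (!all(edge_key(cv_edges$from, cv_edges$to) %in% have)) {
    stop("`cv_edges` must be a subset of existing edges", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  assignment <- sample(rep(seq_len(folds), length.out = nrow(cv_edges)))
  detail <- data.frame(fold = seq_len(folds),
                       removed = 0L, top_k = 0L, hits = 0L)
  for (f in seq_len(folds)) {
    held <- cv_edges[assignment == f, , drop = FALSE]
    detail$removed[f] <- nrow(held)
    if (nrow(held) == 0L) next
    reduced <- remove_edges(net, held)
    if (any(is.infinite(pair_distances(reduced, ends, spec)))) {
      warning(sprintf(
        "fold %d: some source-target pairs disconnected after removal; penalty applies",
        f), call. = FALSE)
    }
    cand <- missing_edges(reduced, candidate_cost)
    if (!is.null(restrict_to)) {
      cand <- cand[in_reference(restrict_to, cand$from, cand$to), ,
                   drop = FALSE]
      if (!is.null(restrict_to$pairs$confidence) &&
          !all(is.na(restrict_to$pairs$confidence))) {
        key <- edge_key(pmin(cand$from, cand$to), pmax(cand$from, cand$to))
        refkey <- edge_key(restrict_to$pairs$a, restrict_to$pairs$b)
        conf <- restrict_to$pairs$confidence[match(key, refkey)]
        cand$cost <- ifelse(is.na(conf), candidate_cost,
                            confidence_to_cost(conf))
      }
    }
    pred <- switch(method,
      "greedy" = greedy_predict(reduced, ends, spec, k = top_k,
                                candidates = cand, seed = NULL),
      "direct-st" = direct_st_predict(reduced, ends, spec, k = top_k,
                                      default_cost = candidate_cost,
                                      seed = NULL),
      "betweenness" = betweenness_predict(reduced, ends, spec, k = top_k,
                                          candidates = cand, seed = NULL))
    heldkey <- edge_key(pmin(held$from, held$to), pmax(held$from, held$to))
    predkey <- edge_key(pmin(pred$from, pred$to), pmax(pred$from, pred$to))
    detail$top_k[f] <- nrow(pred)
    detail$hits[f] <- sum(predkey %in% heldkey)
  }
  evaluated <- sum(detail$top_k)
  structure(list(folds = folds, fold_detail = detail,
                 recovery_percent = if (evaluated > 0)
                   100 * sum(detail$hits) / evaluated else NaN,
                 method = method, top_k = top_k, seed = seed),
            class = "crossval_report")
}

#' @export
print.crossval_report <- function(x, ...) {
  cat(sprintf("crossval_report (%s, %d folds): %.3g%% recovery (%d/%d)\n",
              x$method, x$folds, x$recovery_percent,
              sum(x$fold_detail$hits), sum(x$fold_detail$top_k)))
  print.data.frame(x$fold_detail, row.names = FALSE)
  invisible(x)
}

#' Hypergeometric overlap enrichment
#'
#' Upper-tail probability of drawing at least `hits` annotated items in a
#' size-`k` draw, without replacement, from a universe containing
#' `annotated` annotated items — equivalent to a one-sided Fisher's exact
#' test on the 2x2 overlap table.
#'
#' @param hits Observed overlap count.
#' @param k Number of predictions drawn.
#' @param annotated Number of annotated items in the universe.
#' @param universe Universe size.
#' @return One-sided p-value in \[0, 1\].
#' @examples
#' overlap_enrichment(hits = 2, k = 2, annotated = 5, universe = 10)
#' @export
overlap_enrichment <- function(hits, k, annotated, universe) {
  counts <- c(hits = hits, k = k, annotated = annotated,
              universe = universe)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (hits > k || k > universe || hits > annotated ||
      annotated > universe) {
    stop("inconsistent counts: need hits <= k <= universe and hits <= annotated <= universe",
         call. = FALSE)
  }
  if (hits == 0) return(1)
  phyper(hits - 1, annotated, universe - annotated, k, lower.tail = FALSE)
}

#' Baseline hit rate of a random prediction
#'
#' The percent chance that a uniformly random prediction lands in a
#' reference set of `reference_count` items out of `universe_count`
#' possibilities.
#'
#' @param reference_count Size of the reference set (may be fractional,
#'   e.g. an expected count).
#' @param universe_count Number of possible predictions (> 0).
#' @return Percent in \[0, 100\].
#' @examples
#' random_hit_rate(659719, 4371 * 4370)  # ~3.5%
#' @export
random_hit_rate <- function(reference_count, universe_count) {
  if (universe_count <= 0) stop("universe must be positive", call. = FALSE)
  if (reference_count < 0 || reference_count > universe_count) {
    stop("need 0 <= reference_count <= universe_count", call. = FALSE)
  }
  100 * reference_count / universe_count
}
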