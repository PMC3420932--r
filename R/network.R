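#' Convert edge confidence to traversal cost
#'
#' Edges carry a confidence in \[0, 1\]; distance computations use the
#' complementary cost `1 - confidence`, so that high-confidence edges imply
#' short paths.
#'
#' @param confidence Numeric vector of confidences in \[0, 1\].
#' @return Numeric vector of costs, `1 - confidence`.
#' @examples
#' confidence_to_cost(c(1, 0, 0.872))
#' @export
confidence_to_cost <- function(confidence) {
  if (!is.numeric(confidence)) {
    stop("`confidence` must be numeric", call. = FALSE)
  }
  bad <- which(is.na(confidence) | confidence < 0 | confidence > 1)
  if (length(bad) > 0L) {
    stop(sprintf("confidence out of [0, 1]: %s",
                 paste(format(confidence[bad[seq_len(min(5L, length(bad)))]]),
                       collapse = ", ")),
         call. = FALSE)
  }
  1 - confidence
}

#' @rdname confidence_to_cost
#' @param cost Numeric vector of costs in \[0, 1\].
#' @export
cost_to_confidence <- function(cost) confidence_to_cost(cost)

#' Construct a confidence-weighted directed network
#'
#' The central container: a directed graph whose edges carry a traversal
#' cost in \[0, 1\] (already transformed from confidence via
#' [confidence_to_cost()]).  Self-loops and duplicate ordered pairs are
#' rejected; use [read_network()] for the permissive file-reading path that
#' applies the deduplication and self-loop policies.
#'
#' @param edges A data frame with character columns `from`, `to` and numeric
#'   column `cost` (each in \[0, 1\]).
#' @param nodes Optional character vector of node identifiers; the union
#'   with edge endpoints is used, so isolated nodes can be declared here.
#' @return An object of class `pathway_network` with elements `nodes`
#'   (character) and `edges` (data frame `from`, `to`, `cost`).
#' @examples
#' g <- pathway_network(data.frame(from = "a", to = "b", cost = 0.1))
#' g
#' @export
pathway_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        cost = numeric(), stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("from", "to", "cost") %in% names(edges))) {
    stop("`edges` needs columns from, to, cost", call. = FALSE)
  }
  edges <- edges[, c("from", "to", "cost")]
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$cost <- as.numeric(edges$cost)
  if (any(edges$from == edges$to)) {
    stop("self-loop edges are not allowed", call. = FALSE)
  }
  if (any(is.na(edges$cost) | edges$cost < 0 | edges$cost > 1)) {
    stop("edge costs must lie in [0, 1]", call. = FALSE)
  }
  key <- edge_key(edges$from, edges$to)
  if (anyDuplicated(key)) {
    stop("duplicate ordered edge pairs in `edges`", call. = FALSE)
  }
  nodes <- unique(c(as.character(nodes %||% character()),
                    edges$from, edges$to))
  if (length(nodes) < 1L) {
    stop("a network needs at least one node", call. = FALSE)
  }
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "pathway_network")
}

edge_key <- function(from, to) paste(from, to, sep = "\t")

#' @export
print.pathway_network <- function(x, ...) {
  cat(sprintf("pathway_network: %d nodes, %d directed edges\n",
              n_nodes(x), n_edges(x)))
  if (n_edges(x) > 0L) {
    cat(sprintf("  edge cost range [%.3g, %.3g]\n",
                min(x$edges$cost), max(x$edges$cost)))
  }
  invisible(x)
}

#' Node and edge counts
#' @param net A `pathway_network`.
#' @return Integer count.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

#' Add edges to a network
#'
#' @param net A `pathway_network`.
#' @param edges Data frame with `from`, `to`, `cost`; endpoints must already
#'   be nodes of `net` and the ordered pairs must not be existing edges.
#' @return The grown `pathway_network`.
#' @export
add_edges <- function(net, edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c(edges$from, edges$to) %in% net$nodes)) {
    stop("edge endpoints must be existing nodes", call. = FALSE)
  }
  if (any(edge_key(edges$from, edges$to) %in%
          edge_key(net$edges$from, net$edges$to))) {
    stop("edge already present in network", call. = FALSE)
  }
  pathway_network(rbind(net$edges,
                        edges[, c("from", "to", "cost")]),
                  nodes = net$nodes)
}

#' Remove edges from a network
#'
#' @param net A `pathway_network`.
#' @param edges Data frame with `from`, `to` identifying existing edges.
#' @return The reduced `pathway_network` (node set unchanged).
#' @export
remove_edges <- function(net, edges) {
  drop <- edge_key(as.character(edges$from), as.character(edges$to))
  have <- edge_key(net$edges$from, net$edges$to)
  missing <- setdiff(drop, have)
  if (length(missing) > 0L) {
    stop(sprintf("cannot remove unknown edge(s): %s",
                 paste(gsub("\t", "->", head(missing, 3L)), collapse = ", ")),
         call. = FALSE)
  }
  pathway_network(net$edges[!(have %in% drop), , drop = FALSE],
                  nodes = net$nodes)
}

#' Reverse every edge of a network
#' @param net A `pathway_network`.
#' @return A `pathway_network` with all edge directions flipped.
#' @export
reverse_network <- function(net) {
  pathway_network(data.frame(from = net$edges$to, to = net$edges$from,
                             cost = net$edges$cost,
                             stringsAsFactors = FALSE),
                  nodes = net$nodes)
}

as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                     vertices = net$nodes)
  igraph::E(g)$weight <- net$edges$cost
  g
}

# n x n logical adjacency in net$nodes order
adjacency_mask <- function(net) {
  n <- n_nodes(net)
  A <- matrix(FALSE, n, n, dimnames = list(net$nodes, net$nodes))
  if (n_edges(net) > 0L) {
    A[cbind(match(net$edges$from, net$nodes),
            match(net$edges$to, net$nodes))] <- TRUE
  }
  A
}

# symmetric confidence matrix; for a pair adjacent in both directions the
# maximum-confidence incidence is kept (used by the Jaccard baseline)
confidence_matrix <- function(net) {
  n <- n_nodes(net)
  C <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  if (n_edges(net) > 0L) {
    i <- match(net$edges$from, net$nodes)
    j <- match(net$edges$to, net$nodes)
    conf <- 1 - net$edges$cost
    for (e in seq_along(i)) {
      C[i[e], j[e]] <- max(C[i[e], j[e]], conf[e])
      C[j[e], i[e]] <- max(C[j[e], i[e]], conf[e])
    }
  }
  C
}

#' Pathway endpoints: source and target sets
#'
#' @param sources,targets Character vectors of node identifiers; must be
#'   nonempty and disjoint.
#' @return An object of class `pathway_endpoints`.
#' @examples
#' pathway_endpoints(c("s1", "s2"), "t")
#' @export
pathway_endpoints <- function(sources, targets) {
  sources <- unique(as.character(sources))
  targets <- unique(as.character(targets))
  if (length(sources) < 1L || length(targets) < 1L) {
    stop("source and target sets must be nonempty", call. = FALSE)
  }
  both <- intersect(sources, targets)
  if (length(both) > 0L) {
    stop(sprintf("sources and targets overlap: %s",
                 paste(head(both, 5L), collapse = ", ")), call. = FALSE)
  }
  structure(list(sources = sources, targets = targets),
            class = "pathway_endpoints")
}

#' @export
print.pathway_endpoints <- function(x, ...) {
  cat(sprintf("pathway_endpoints: %d sources, %d targets (%d ordered pairs)\n",
              length(x$sources), length(x$targets),
              length(x$sources) * length(x$targets)))
  invisible(x)
}

#' Validate endpoints against a network
#'
#' @param ends A `pathway_endpoints`.
#' @param net A `pathway_network` whose node set must contain every
#'   endpoint identifier.
#' @return `ends`, invisibly, on success.
#' @export
validate_endpoints <- function(ends, net) {
  absent <- setdiff(c(ends$sources, ends$targets), net$nodes)
  if (length(absent) > 0L) {
    stop(sprintf("endpoint identifiers absent from network: %s",
                 paste(head(absent, 5L), collapse = ", ")), call. = FALSE)
  }
  invisible(ends)
}

#' Reference edge set (unordered pairs with optional confidences)
#'
#' Holds evaluation or candidate material such as "potential" (non-physical)
#' association edges: unordered node pairs, optionally confidence-weighted.
#'
#' @param pairs Data frame with character columns `a`, `b` and optional
#'   numeric `confidence` in \[0, 1\].
#' @param label Free-text label for reporting.
#' @return An object of class `reference_edge_set`; pairs are stored with
#'   `a < b` (lexicographically) and deduplicated keeping the maximum
#'   confidence.
#' @export
reference_edge_set <- function(pairs, label = "reference") {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L) {
    pairs <- data.frame(a = character(), b = character(),
                        confidence = numeric(), stringsAsFactors = FALSE)
  } else {
    if (!all(c("a", "b") %in% names(pairs))) {
      stop("`pairs` needs columns a, b", call. = FALSE)
    }
    pairs$a <- as.character(pairs$a)
    pairs$b <- as.character(pairs$b)
    if (is.null(pairs$confidence)) pairs$confidence <- NA_real_
    conf <- pairs$confidence
    if (any(!is.na(conf) & (conf < 0 | conf > 1))) {
      stop("reference confidences must lie in [0, 1]", call. = FALSE)
    }
    self <- pairs$a == pairs$b
    if (any(self)) {
      warning(sprintf("dropping %d self-pair row(s)", sum(self)),
              call. = FALSE)
      pairs <- pairs[!self, , drop = FALSE]
    }
    lo <- pmin(pairs$a, pairs$b)
    hi <- pmax(pairs$a, pairs$b)
    pairs$a <- lo
    pairs$b <- hi
    key <- edge_key(pairs$a, pairs$b)
    if (anyDuplicated(key)) {
      best <- tapply(pairs$confidence, key, function(z) {
        if (all(is.na(z))) NA_real_ else max(z, na.rm = TRUE)
      })
      keep <- !duplicated(key)
      pairs <- pairs[keep, , drop = FALSE]
      pairs$confidence <- as.numeric(best[edge_key(pairs$a, pairs$b)])
    }
    pairs <- pairs[order(pairs$a, pairs$b), , drop = FALSE]
  }
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, label = label), class = "reference_edge_set")
}

#' @export
print.reference_edge_set <- function(x, ...) {
  cat(sprintf("reference_edge_set '%s': %d unordered pairs\n",
              x$label, nrow(x$pairs)))
  invisible(x)
}

#' Unordered-pair membership in a reference set
#'
#' @param ref A `reference_edge_set`.
#' @param u,v Character vectors of node identifiers (recycled pairwise).
#' @return Logical vector: is the unordered pair `{u, v}` in the set?
#' @export
in_reference <- function(ref, u, v) {
  edge_key(pmin(u, v), pmax(u, v)) %in% edge_key(ref$pairs$a, ref$pairs$b)
}

#' Enumerate all missing directed edges as candidates
#'
#' Yields every ordered node pair `(u, v)` with `u != v` that is not an
#' existing edge, each assigned `default_cost` as its traversal cost.
#' Reverse orientations of existing edges are included: a predictor may
#' legitimately propose the reverse of an oriented interaction.
#'
#' @param net A `pathway_network`.
#' @param default_cost Traversal cost assigned to each candidate (default 0,
#'   which maximally encourages usage of the hypothesized edge).
#' @return Data frame `from`, `to`, `cost` with `n(n-1) - m` rows.
#' @examples
#' g <- pathway_network(data.frame(from = c("a", "b", "c"),
#'                                 to = c("b", "c", "a"), cost = 0.1))
#' nrow(missing_edges(g))  # 3 * 2 - 3
#' @export
missing_edges <- function(net, default_cost = 0) {
  stopifnot(is.numeric(default_cost), default_cost >= 0, default_cost <= 1)
  n <- n_nodes(net)
  from <- rep(net$nodes, each = n)
  to <- rep(net$nodes, times = n)
  keep <- from != to
  from <- from[keep]
  to <- to[keep]
  key <- edge_key(from, to)
  exists <- key %in% edge_key(net$edges$from, net$edges$to)
  data.frame(from = from[!exists], to = to[!exists],
             cost = rep(default_cost, sum(!exists)),
             stringsAsFactors = FALSE)
}

# validate a candidate data frame against a network
check_candidates <- function(net, candidates) {
  candidates <- as.data.frame(candidates, stringsAsFactors = FALSE)
  if (nrow(candidates) == 0L) {
    stop("candidate pool is empty", call. = FALSE)
  }
  if (is.null(candidates$cost)) candidates$cost <- 0
  candidates$from <- as.character(candidates$from)
  candidates$to <- as.character(candidates$to)
  if (any(candidates$from == candidates$to)) {
    stop("candidate self-loops are not allowed", call. = FALSE)
  }
  if (any(candidates$cost < 0 | candidates$cost > 1)) {
    stop("candidate costs must lie in [0, 1]", call. = FALSE)
  }
  if (!all(c(candidates$from, candidates$to) %in% net$nodes)) {
    stop("candidate endpoints must be nodes of the network", call. = FALSE)
  }
  if (any(edge_key(candidates$from, candidates$to) %in%
          edge_key(net$edges$from, net$edges$to))) {
    stop("candidate coincides with an existing edge", call. = FALSE)
  }
  key <- edge_key(candidates$from, candidates$to)
  candidates[!duplicated(key), c("from", "to", "cost")]
}
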