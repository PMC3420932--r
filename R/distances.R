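#' Single-origin shortest-path distances
#'
#' `shortest_distances_from()` returns the minimum total edge cost of a
#' directed path from `origin` to every node (Dijkstra; all costs are
#' nonnegative, zero-cost edges are legal).  `shortest_distances_to()` is
#' the mirror image: the cost of reaching `destination` from every node,
#' computed on the edge-reversed graph.  Unreachable nodes carry `Inf`,
#' which is a sentinel: any substitution by a finite penalty happens in the
#' objective layer, never here.
#'
#' @param net A `pathway_network`.
#' @param origin,destination A node identifier of `net`.
#' @return Named numeric vector over all nodes (in `net$nodes` order);
#'   `Inf` marks unreachable nodes.
#' @examples
#' g <- pathway_network(data.frame(from = c("s", "a", "b"),
#'                                 to = c("a", "b", "t"), cost = 0.2))
#' shortest_distances_from(g, "s")[["t"]]
#' @export
shortest_distances_from <- function(net, origin) {
  if (!origin %in% net$nodes) {
    stop(sprintf("unknown origin node '%s'", origin), call. = FALSE)
  }
  d <- igraph::distances(as_igraph(net), v = origin, mode = "out",
                         algorithm = "dijkstra")
  setNames(as.numeric(d[1L, net$nodes]), net$nodes)
}

#' @rdname shortest_distances_from
#' @export
shortest_distances_to <- function(net, destination) {
  if (!destination %in% net$nodes) {
    stop(sprintf("unknown destination node '%s'", destination), call. = FALSE)
  }
  d <- igraph::distances(as_igraph(net), v = destination, mode = "in",
                         algorithm = "dijkstra")
  setNames(as.numeric(d[1L, net$nodes]), net$nodes)
}

#' Bounded-hop distance tables (modified Bellman-Ford)
#'
#' `hop_distances_from()` computes, for every `k = 0..hops`, the least-cost
#' directed path from `origin` using at most `k` edges.  Each relaxation
#' round reads only the previous round's values (double buffering), so row
#' `k` means "at most k hops" exactly, even in the presence of zero-cost
#' edges.  `hop_distances_to()` runs the same kernel on the edge-reversed
#' graph, giving per-hop costs of reaching `destination`.
#'
#' @param net A `pathway_network`.
#' @param origin,destination A node identifier of `net`.
#' @param hops Positive integer: the maximum hop count (table rows are
#'   `0..hops`).
#' @return A `(hops + 1) x n` numeric matrix; row names `"0".."hops"`,
#'   column names the nodes.  `Inf` marks node/hop combinations with no
#'   satisfying path.
#' @examples
#' g <- pathway_network(data.frame(from = c("s", "a", "b"),
#'                                 to = c("a", "b", "t"), cost = 0.2))
#' hop_distances_from(g, "s", 3)["3", "t"]
#' @export
hop_distances_from <- function(net, origin, hops) {
  if (!origin %in% net$nodes) {
    stop(sprintf("unknown origin node '%s'", origin), call. = FALSE)
  }
  if (!is.numeric(hops) || length(hops) != 1L || hops < 1 ||
      hops != round(hops)) {
    stop("`hops` must be a positive integer", call. = FALSE)
  }
  n <- n_nodes(net)
  tab <- matrix(Inf, nrow = hops + 1L, ncol = n,
                dimnames = list(as.character(0:hops), net$nodes))
  tab[1L, origin] <- 0
  ei <- match(net$edges$from, net$nodes)
  ej <- match(net$edges$to, net$nodes)
  w <- net$edges$cost
  prev <- tab[1L, ]
  for (k in seq_len(hops)) {
    cur <- prev
    if (length(ei) > 0L) {
      relaxed <- prev[ei] + w
      upd <- tapply(relaxed, ej, min)
      idx <- as.integer(names(upd))
      cur[idx] <- pmin(cur[idx], as.numeric(upd))
    }
    tab[k + 1L, ] <- cur
    prev <- cur
  }
  tab
}

#' @rdname hop_distances_from
#' @export
hop_distances_to <- function(net, destination, hops) {
  hop_distances_from(reverse_network(net), destination, hops)
}
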