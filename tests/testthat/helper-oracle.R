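# Independent brute-force oracles, deliberately naive: depth-first
# enumeration of simple paths.  Removing a cycle from a walk never
# increases cost (nonnegative) or hops, so the minimum over simple paths
# equals the minimum over all walks under a hop bound.

brute_min_cost <- function(net, from, to, max_hops) {
  out <- split(seq_len(nrow(net$edges)), net$edges$from)
  best <- Inf
  walk <- function(node, used, cost, hops) {
    if (cost >= best) return()
    if (node == to && hops > 0L) best <<- min(best, cost)
    if (node == to || hops >= max_hops) return()
    for (e in out[[node]]) {
      nxt <- net$edges$to[e]
      if (nxt %in% used) next
      walk(nxt, c(used, nxt), cost + net$edges$cost[e], hops + 1L)
    }
  }
  if (from == to) return(0)
  walk(from, from, 0, 0L)
  best
}

# brute-force objective: enumerate paths per pair, substitute penalty,
# reduce per variant
brute_objective <- function(net, ends, spec) {
  max_hops <- if (spec$hop_restricted) spec$hops else n_nodes(net) - 1L
  penalty <- spec$penalty %||% n_nodes(net)
  pd <- outer(ends$sources, ends$targets,
              Vectorize(function(s, t) brute_min_cost(net, s, t, max_hops)))
  pd[is.infinite(pd)] <- penalty
  if (spec$single_source) sum(apply(pd, 2, min)) else sum(pd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
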