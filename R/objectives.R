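#' Objective specification
#'
#' The four objective variants over source-target distances:
#' * `"shortcuts"` — total shortest-path cost over all |S| x |T| ordered
#'   pairs;
#' * `"shortcuts-x"` — the same, with every path restricted to at most
#'   `hops` edges;
#' * `"shortcuts-ss"` — per target, only the distance to its single closest
#'   source is summed;
#' * `"shortcuts-x-ss"` — single-source and hop-restricted.
#'
#' The default hop bound is 5, matching pathway-database statistics (on
#' average about five edges between a target and its closest source).
#' Unreachable pairs enter the objective as a finite `penalty`; the default
#' (`NULL`) resolves to the node count `n` of the graph being scored, which
#' strictly exceeds any simple-path cost (at most `n - 1` edges of cost at
#' most 1) and any hop-bounded cost (at most `hops`), so connecting a
#' disconnected pair is always rewarded first.
#'
#' @param variant One of `"shortcuts"`, `"shortcuts-x"`, `"shortcuts-ss"`,
#'   `"shortcuts-x-ss"`.
#' @param hops Positive integer hop bound; used only by the `-x` variants.
#' @param penalty Positive real substituted for unreachable pair distances,
#'   or `NULL` to use the node count of the scored graph.
#' @return An object of class `objective_spec`.
#' @examples
#' objective_spec("shortcuts-x", hops = 5)
#' @export
objective_spec <- function(variant = c("shortcuts", "shortcuts-x",
                                       "shortcuts-ss", "shortcuts-x-ss"),
                           hops = 5L, penalty = NULL) {
  variant <- match.arg(variant)
  if (!is.numeric(hops) || hops < 1 || hops != round(hops)) {
    stop("`hops` must be a positive integer", call. = FALSE)
  }
  if (!is.null(penalty) && (!is.numeric(penalty) || penalty <= 0)) {
    stop("`penalty` must be a positive real or NULL", call. = FALSE)
  }
  structure(list(variant = variant,
                 hop_restricted = grepl("-x", variant, fixed = TRUE),
                 single_source = grepl("-ss$", variant),
                 hops = as.integer(hops),
                 penalty = penalty),
            class = "objective_spec")
}

#' @export
print.objective_spec <- function(x, ...) {
  cat(sprintf("objective_spec: %s%s, penalty %s\n", x$variant,
              if (x$hop_restricted) sprintf(" (hops = %d)", x$hops) else "",
              if (is.null(x$penalty)) "= node count" else format(x$penalty)),
      ...)
  invisible(x)
}

resolve_penalty <- function(spec, n) {
  p <- spec$penalty %||% as.numeric(n)
  limit <- if (spec$hop_restricted) spec$hops else n - 1
  if (p <= limit) {
    warning(sprintf(
      "penalty %g does not exceed the maximum achievable path cost %g",
      p, limit), call. = FALSE)
  }
  p
}

#' Source-target pair distance matrix
#'
#' Computes the |S| x |T| matrix of directed source-to-target distances
#' under an objective specification: unrestricted Dijkstra distances for
#' the plain variants, or row `hops` of the bounded-hop tables for the
#' `-x` variants.  Unreachable pairs are `Inf`.
#'
#' @param net A `pathway_network`.
#' @param ends A `pathway_endpoints`, valid against `net`.
#' @param spec An `objective_spec`.
#' @return Numeric matrix with sources as rows and targets as columns;
#'   attribute `n_nodes` records the graph size for penalty resolution.
#' @export
pair_distances <- function(net, ends, spec) {
  validate_endpoints(ends, net)
  tabs <- distance_tables(net, ends, spec)
  tabs$D
}

# Precompute every table the incremental candidate evaluation needs:
#  - unrestricted: Fwd[s, u] = d(s, u), Bwd[t, v] = d(v, t), D[s, t]
#  - hop-bounded:  Fk[[k+1]][s, u] = d_k(s, u), Bk[[k+1]][t, v] = d_k(v, t)
#    for k = 0..hops, and D[s, t] = d_hops(s, t)
distance_tables <- function(net, ends, spec) {
  validate_endpoints(ends, net)
  S <- ends$sources
  Tt <- ends$targets
  n <- n_nodes(net)
  if (!spec$hop_restricted) {
    g <- as_igraph(net)
    Fwd <- igraph::distances(g, v = S, mode = "out",
                             algorithm = "dijkstra")[, net$nodes,
                                                     drop = FALSE]
    Bwd <- igraph::distances(g, v = Tt, mode = "in",
                             algorithm = "dijkstra")[, net$nodes,
                                                     drop = FALSE]
    D <- Fwd[, Tt, drop = FALSE]
    dimnames(D) <- list(S, Tt)
    out <- list(Fwd = Fwd, Bwd = Bwd, D = D)
  } else {
    X <- spec$hops
    Fk <- lapply(0:X, function(k)
      matrix(Inf, length(S), n, dimnames = list(S, net$nodes)))
    Bk <- lapply(0:X, function(k)
      matrix(Inf, length(Tt), n, dimnames = list(Tt, net$nodes)))
    for (i in seq_along(S)) {
      tab <- hop_distances_from(net, S[i], X)
      for (k in 0:X) Fk[[k + 1L]][i, ] <- tab[k + 1L, ]
    }
    rnet <- reverse_network(net)
    for (j in seq_along(Tt)) {
      tab <- hop_distances_from(rnet, Tt[j], X)
      for (k in 0:X) Bk[[k + 1L]][j, ] <- tab[k + 1L, ]
    }
    D <- t(Bk[[X + 1L]][, S, drop = FALSE])
    dimnames(D) <- list(S, Tt)
    out <- list(Fk = Fk, Bk = Bk, D = D)
  }
  attr(out$D, "n_nodes") <- n
  out$spec <- spec
  out$net <- net
  out$ends <- ends
  out$n <- n
  out
}

#' Objective cost of a pair distance matrix
#'
#' Applies the unreachable-pair penalty and reduces the matrix according to
#' the variant: the plain variants sum every pair; the single-source (`-ss`)
#' variants sum, per target, the minimum over sources (the minimum is taken
#' after penalty substitution, so an all-unreachable target contributes one
#' penalty).
#'
#' @param pd A pair distance matrix from [pair_distances()] (sources as
#'   rows, `Inf` for unreachable pairs).
#' @param spec The `objective_spec` the matrix was computed under.
#' @param n_nodes Node count used to resolve a `NULL` penalty; defaults to
#'   the matrix's `n_nodes` attribute.
#' @return Nonnegative scalar cost.
#' @export
objective_cost <- function(pd, spec, n_nodes = attr(pd, "n_nodes")) {
  if (is.null(n_nodes) && is.null(spec$penalty)) {
    stop("supply `n_nodes` (or a matrix carrying it) to resolve the penalty",
         call. = FALSE)
  }
  penalty <- resolve_penalty(spec, n_nodes)
  pd[is.infinite(pd)] <- penalty
  if (spec$single_source) {
    sum(apply(pd, 2L, min))
  } else {
    sum(pd)
  }
}

# objective cost directly from a network (convenience used throughout)
network_objective <- function(net, ends, spec) {
  objective_cost(pair_distances(net, ends, spec), spec, n_nodes(net))
}
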