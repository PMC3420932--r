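#' Specification for a synthetic layered pathway network
#'
#' Describes a benchmark instance shaped like an oriented signaling
#' network: a layer of sources (sensors), `n_layers` intermediate layers,
#' and a layer of targets (transcription factors), with forward edges
#' between consecutive layers and a few planted long-range "shortcut"
#' edges routed through well-connected hub nodes.  Defaults emulate the
#' endpoint counts of the yeast study system (5 sources, 11 targets) with
#' four intermediate layers of 32 nodes, so the canonical source-to-target
#' path has 5 hops — matching the default hop bound of
#' [objective_spec()] — for a 144-node instance.
#'
#' @param n_sources,n_targets,n_layers,nodes_per_layer Positive integers.
#' @param p_forward Edge probability between consecutive layers, in (0, 1].
#' @param beta_shape Length-2 shape parameters of the Beta confidence
#'   sampler; the default `c(8, 2)` skews toward high confidence, like
#'   curated physical interactions.
#' @param n_planted Number of planted layer-skipping shortcut edges
#'   (confidence at least 0.95, spanning at least 2 layers).
#' @param seed Integer seed; the instance is fully determined by it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_sources = 5L, n_targets = 11L, n_layers = 4L,
                           nodes_per_layer = 32L, p_forward = 0.15,
                           beta_shape = c(8, 2), n_planted = 3L,
                           seed = 1L) {
  stopifnot(n_sources >= 1, n_targets >= 1, n_layers >= 2,
            nodes_per_layer >= 1, p_forward > 0, p_forward <= 1,
            length(beta_shape) == 2L, all(beta_shape > 0), n_planted >= 0)
  structure(list(n_sources = as.integer(n_sources),
                 n_targets = as.integer(n_targets),
                 n_layers = as.integer(n_layers),
                 nodes_per_layer = as.integer(nodes_per_layer),
                 p_forward = p_forward, beta_shape = beta_shape,
                 n_planted = as.integer(n_planted),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a layered pathway benchmark network
#'
#' Builds `sources -> layer 1 -> ... -> layer L -> targets` with forward
#' edges sampled at `p_forward` and confidences from the Beta sampler.
#' Reachability is then repaired: for every source-target pair not
#' reachable within `L + 1` hops, a chain through one random node per layer
#' is completed, so every pair is reachable within the canonical hop count
#' before any hiding.  Finally `n_planted` high-confidence (>= 0.95)
#' shortcut edges are planted between nodes at least two layers apart,
#' each placed sequentially at the missing pair whose addition most
#' reduces the total source-target shortest-path cost — i.e. on as many
#' source-target routes as possible, the role a true undiscovered pathway
#' shortcut would play.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `net` (`pathway_network`, planted edges included),
#'   `ends` (`pathway_endpoints`), `planted` (data frame `from`, `to`,
#'   `cost` of the planted edges) and `layers` (named list of layer
#'   membership).
#' @export
generate_pathway_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  L <- spec$n_layers
  layers <- c(list(sprintf("s%02d", seq_len(spec$n_sources))),
              lapply(seq_len(L), function(i)
                sprintf("v%d_%02d", i, seq_len(spec$nodes_per_layer))),
              list(sprintf("t%02d", seq_len(spec$n_targets))))
  names(layers) <- c("sources", sprintf("layer%d", seq_len(L)), "targets")
  nodes <- unlist(layers, use.names = FALSE)
  rconf <- function(m) rbeta(m, spec$beta_shape[1L], spec$beta_shape[2L])

  from <- character(); to <- character(); conf <- numeric()
  for (i in seq_len(L + 1L)) {
    a <- layers[[i]]; b <- layers[[i + 1L]]
    grid <- expand.grid(from = a, to = b, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    keep <- runif(nrow(grid)) < spec$p_forward
    from <- c(from, grid$from[keep])
    to <- c(to, grid$to[keep])
    conf <- c(conf, rconf(sum(keep)))
  }
  edges <- data.frame(from = from, to = to,
                      cost = confidence_to_cost(conf),
                      stringsAsFactors = FALSE)
  net <- pathway_network(edges, nodes = nodes)

  # repair: complete a random chain for every pair outside the hop budget
  for (s in layers$sources) {
    hop <- hop_distances_from(net, s, L + 1L)
    for (t in layers$targets[!is.finite(hop[L + 2L, layers$targets])]) {
      chain <- c(s, vapply(seq_len(L), function(i)
        sample(layers[[i + 1L]], 1L), character(1)), t)
      for (e in seq_len(L + 1L)) {
        if (!edge_key(chain[e], chain[e + 1L]) %in%
            edge_key(net$edges$from, net$edges$to)) {
          net <- add_edges(net, data.frame(from = chain[e],
                                           to = chain[e + 1L],
                                           cost = confidence_to_cost(rconf(1L)),
                                           stringsAsFactors = FALSE))
        }
      }
      hop <- hop_distances_from(net, s, L + 1L)
    }
  }

  # plant shortcuts where they sit on the most source-target routes: among
  # missing pairs whose endpoints are >= 2 layers apart, sequentially pick
  # the pair whose (zero-cost) addition most reduces the total
  # source-target shortest-path cost, so each planted edge shortcuts many
  # pairs at once
  ends <- pathway_endpoints(layers$sources, layers$targets)
  layer_of <- rep(seq_along(layers) - 1L, lengths(layers))
  names(layer_of) <- nodes
  span_ok <- outer(layer_of[nodes], layer_of[nodes],
                   function(a, b) b - a >= 2L)
  plant_spec <- objective_spec("shortcuts")
  planted <- data.frame(from = character(), to = character(),
                        cost = numeric(), stringsAsFactors = FALSE)
  W0 <- matrix(0, length(nodes), length(nodes),
               dimnames = list(nodes, nodes))
  for (j in seq_len(spec$n_planted)) {
    mask <- span_ok & !adjacency_mask(net)
    if (!any(mask)) break
    tables <- distance_tables(net, ends, plant_spec)
    sc <- score_all_candidates(tables, W0, mask)
    pick <- arrayInd(which.min(sc), dim(sc))
    e <- data.frame(from = nodes[pick[1L]], to = nodes[pick[2L]],
                    cost = confidence_to_cost(runif(1L, 0.95, 1)),
                    stringsAsFactors = FALSE)
    net <- add_edges(net, e)
    planted <- rbind(planted, e)
  }
  list(net = net, ends = ends, planted = planted, layers = layers)
}

#' Hide edges to create a recovery benchmark
#'
#' Removes `to_hide` from the network and returns the reduced graph plus
#' the hidden set as a [reference_edge_set()] whose confidences retain the
#' original edge evidence (usable as candidate costs via
#' `1 - confidence`).
#'
#' @param net A `pathway_network`.
#' @param to_hide Data frame `from`, `to` of existing edges.
#' @return A list with `net` (reduced graph) and `hidden`
#'   (`reference_edge_set` labeled `"hidden"`).
#' @export
hide_edges <- function(net, to_hide) {
  to_hide <- as.data.frame(to_hide, stringsAsFactors = FALSE)
  have <- edge_key(net$edges$from, net$edges$to)
  idx <- match(edge_key(to_hide$from, to_hide$to), have)
  if (anyNA(idx)) {
    stop("cannot hide an edge that is not in the network", call. = FALSE)
  }
  hidden <- reference_edge_set(
    data.frame(a = to_hide$from, b = to_hide$to,
               confidence = 1 - net$edges$cost[idx],
               stringsAsFactors = FALSE),
    label = "hidden")
  list(net = remove_edges(net, to_hide), hidden = hidden)
}

#' Generate an instance whose hidden shortcut strictly dominates
#'
#' A small constructed benchmark: three sources feed a gateway hub, a
#' second hub feeds three targets, and the only existing route between the
#' hubs is a slow moderate-confidence chain.  The planted high-confidence
#' hub-to-hub edge is hidden; once all missing edges are offered at cost
#' 0, re-adding it reduces every source-target pair at once and therefore
#' strictly dominates every other candidate, so an objective-driven
#' predictor must recover it at rank 1.
#'
#' @param seed Integer seed (jitters the confidences).
#' @return A list with `net` (hub edge hidden), `ends`, `hidden_edge`
#'   (data frame of the one hidden edge) and `full_net` (hub edge
#'   present).
#' @export
generate_dominant_instance <- function(seed = 1L) {
  set.seed(seed)
  S <- sprintf("s%d", 1:3)
  Tt <- sprintf("t%d", 1:3)
  rim <- function(m, lo, hi) runif(m, lo, hi)
  edges <- rbind(
    data.frame(from = S, to = "ha",
               cost = confidence_to_cost(rim(3, 0.95, 0.995))),
    data.frame(from = "hb", to = Tt,
               cost = confidence_to_cost(rim(3, 0.95, 0.995))),
    data.frame(from = c("ha", "c1", "c2"), to = c("c1", "c2", "hb"),
               cost = confidence_to_cost(rim(3, 0.45, 0.55))))
  hidden_edge <- data.frame(from = "ha", to = "hb",
                            cost = confidence_to_cost(rim(1, 0.95, 1)),
                            stringsAsFactors = FALSE)
  full <- pathway_network(rbind(edges, hidden_edge))
  list(net = remove_edges(full, hidden_edge),
       ends = pathway_endpoints(S, Tt),
       hidden_edge = hidden_edge,
       full_net = full)
}

#' Write a synthetic instance to the standard file formats
#'
#' Emits the network TSV, the endpoint node lists, the hidden-edge
#' reference TSV (when edges were hidden) and a YAML manifest recording
#' the generator spec and seed.
#'
#' @param instance Result of [generate_pathway_network()].
#' @param dir Output directory (created if needed).
#' @param spec The `synthetic_spec` used (stored in the manifest).
#' @param hidden Optional `reference_edge_set` of hidden edges.
#' @return `dir`, invisibly.
#' @export
write_instance <- function(instance, dir, spec = NULL, hidden = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_network(instance$net, file.path(dir, "network.tsv"))
  write_endpoints(instance$ends, file.path(dir, "sources.txt"),
                  file.path(dir, "targets.txt"))
  if (!is.null(hidden)) {
    p <- hidden$pairs
    writeLines(c("# node_a\tnode_b\tconfidence",
                 sprintf("%s\t%s\t%.17g", p$a, p$b, p$confidence)),
               file.path(dir, "hidden.tsv"))
  }
  if (!is.null(spec)) {
    yaml::write_yaml(unclass(spec), file.path(dir, "manifest.yaml"))
  }
  invisible(dir)
}
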