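# Shared toy graphs.
#
# chain_net:  s -> a -> b -> t, each edge cost 0.2
# fork_net:   s1 -> a (0.1), s2 -> a (0.3), a -> t (0.4)
# funnel_net: s1,s2 -> a (0.5), a -> b (0.5), b -> t1,t2 (0.5)

chain_net <- function() {
  pathway_network(data.frame(from = c("s", "a", "b"),
                             to = c("a", "b", "t"),
                             cost = 0.2, stringsAsFactors = FALSE))
}

fork_net <- function() {
  pathway_network(data.frame(from = c("s1", "s2", "a"),
                             to = c("a", "a", "t"),
                             cost = c(0.1, 0.3, 0.4),
                             stringsAsFactors = FALSE))
}

funnel_net <- function() {
  pathway_network(data.frame(from = c("s1", "s2", "a", "b", "b"),
                             to = c("a", "a", "b", "t1", "t2"),
                             cost = 0.5, stringsAsFactors = FALSE))
}

# Random graph with costs on a 0.05 grid and random disjoint endpoints.
# Used by oracle-equivalence and property tests.
random_instance <- function(seed, n = 8L, p = 0.3, n_sources = 2L,
                            n_targets = 2L) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  grid <- expand.grid(from = nodes, to = nodes, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$from != grid$to, ]
  grid <- grid[runif(nrow(grid)) < p, ]
  grid$cost <- sample(seq(0, 1, by = 0.05), nrow(grid), replace = TRUE)
  net <- pathway_network(grid, nodes = nodes)
  picks <- sample(nodes, n_sources + n_targets)
  list(net = net,
       ends = pathway_endpoints(picks[seq_len(n_sources)],
                                picks[n_sources + seq_len(n_targets)]))
}

all_variants <- c("shortcuts", "shortcuts-x", "shortcuts-ss",
                  "shortcuts-x-ss")

# local ordered-pair key for test assertions
ek <- function(u, v) paste(u, v, sep = "\t")

# A sparse source-target chain plus a dense high-confidence module that is
# disconnected from the pathway.  Common-neighbor and closest-pair picks
# land inside the module, away from every source-target path.
off_pathway_instance <- function() {
  chain <- data.frame(from = c("s", "a", "b"), to = c("a", "b", "t"),
                      cost = 0.5, stringsAsFactors = FALSE)
  x <- sprintf("x%d", 1:5)
  clique <- expand.grid(from = x, to = x, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  clique <- clique[clique$from != clique$to, ]
  gap <- with(clique, (from == "x1" & to == "x2") |
                (from == "x2" & to == "x1") |
                (from == "x3" & to == "x4") |
                (from == "x4" & to == "x3"))
  clique <- clique[!gap, ]
  clique$cost <- 0.01
  list(net = pathway_network(rbind(chain, clique)),
       ends = pathway_endpoints("s", "t"))
}
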