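test_that("Direct-ST optimizes over the direct source-target pool", {
  g <- fork_net()
  ends <- pathway_endpoints(c("s1", "s2"), "t")
  p <- direct_st_predict(g, ends, objective_spec("shortcuts"), k = 1,
                         seed = 1)
  expect_equal(c(p$from, p$to), c("s2", "t"))
  expect_equal(p$objective_after, 0.5)

  pss <- direct_st_predict(g, ends, objective_spec("shortcuts-ss"), k = 1,
                           seed = 1)
  expect_equal(pss$objective_after, 0.0)
  expect_equal(pss$tie_count, 2L)

  chain <- chain_net()
  pc <- direct_st_predict(chain, pathway_endpoints("s", "t"),
                          objective_spec("shortcuts"), k = 1, seed = 1)
  expect_equal(c(pc$from, pc$to), c("s", "t"))

  full <- pathway_network(data.frame(from = "s", to = "t", cost = 0.5))
  expect_error(direct_st_predict(full, pathway_endpoints("s", "t"),
                                 objective_spec("shortcuts"), k = 1),
               "already exists")
})

test_that("betweenness usage counts pairs with strictly reduced distance", {
  g <- funnel_net()
  ends <- pathway_endpoints(c("s1", "s2"), c("t1", "t2"))
  sp <- objective_spec("shortcuts")
  cand <- data.frame(from = c("a", "s1", "t1"), to = c("t1", "t2", "t2"),
                     cost = 0)
  u <- betweenness_usage(g, ends, sp, cand)
  expect_equal(as.numeric(u), c(2, 1, 0))

  # non-strict counting also admits candidates tying a shortest path
  z <- pathway_network(data.frame(from = c("s", "m", "s"),
                                  to = c("m", "t", "x"),
                                  cost = c(0, 0, 0)),
                       nodes = c("s", "m", "t", "x"))
  zu <- betweenness_usage(z, pathway_endpoints("s", "t"), sp,
                          data.frame(from = "x", to = "t", cost = 0),
                          strict = FALSE)
  expect_equal(as.numeric(zu), 1)
  zs <- betweenness_usage(z, pathway_endpoints("s", "t"), sp,
                          data.frame(from = "x", to = "t", cost = 0),
                          strict = TRUE)
  expect_equal(as.numeric(zs), 0)
})

test_that("betweenness predictor picks the max-usage candidate", {
  g <- funnel_net()
  ends <- pathway_endpoints(c("s1", "s2"), c("t1", "t2"))
  p <- betweenness_predict(g, ends, objective_spec("shortcuts"), k = 2,
                           seed = 7)
  expect_equal(nrow(p), 2L)
  expect_true(all(diff(c(p$objective_before[1], p$objective_after)) <= 1e-12))
  # the SS variant counts targets, not pairs
  pss <- betweenness_predict(g, ends, objective_spec("shortcuts-ss"),
                             k = 1, seed = 7)
  expect_equal(nrow(pss), 1L)
})

test_that("weighted Jaccard score follows the common-neighbor formula", {
  g <- pathway_network(data.frame(
    from = c("u", "u", "v", "v", "v"),
    to = c("x", "y", "x", "y", "z"),
    cost = confidence_to_cost(c(0.8, 0.6, 0.4, 0.9, 0.5))))
  expect_equal(jaccard_score(g, "u", "v"), 2 * (1.2 + 1.5) / (1.4 + 1.8))

  none <- pathway_network(data.frame(from = c("u", "v"), to = c("x", "y"),
                                     cost = 0.5))
  expect_equal(jaccard_score(none, "u", "v"), 0)

  ident <- pathway_network(data.frame(from = c("u", "v"), to = c("h", "h"),
                                      cost = 0))
  expect_equal(jaccard_score(ident, "u", "v"), 1.0)

  adj <- pathway_network(data.frame(from = "u", to = "v", cost = 0.5))
  expect_error(jaccard_score(adj, "u", "v"), "adjacent")
  expect_error(jaccard_score(adj, "u", "u"), "must differ")
})

test_that("Jaccard predictor iterates over unordered non-adjacent pairs", {
  star <- pathway_network(data.frame(from = "h", to = c("p", "q", "r"),
                                     cost = 0))
  p <- jaccard_predict(star, k = 1, seed = 5)
  expect_equal(p$tie_count, 1L + 2L)  # three spoke pairs tie
  expect_true(all(c(p$from, p$to) %in% c("p", "q", "r")))
  expect_true(p$from < p$to)  # lexicographic orientation

  # unique maximum ranks first, and picked pairs leave the pool
  g <- pathway_network(data.frame(
    from = c("u", "u", "v", "v", "v", "p"),
    to = c("x", "y", "x", "y", "z", "x"),
    cost = confidence_to_cost(c(0.8, 0.6, 0.4, 0.9, 0.5, 0.1))))
  # (x, y) share u and v with little other neighborhood mass:
  # 2 * (0.8 + 0.4 + 0.6 + 0.9) / (1.3 + 1.5) is the unique maximum
  p2 <- jaccard_predict(g, k = 2, seed = 5)
  expect_equal(c(p2$from[1L], p2$to[1L]), c("x", "y"))
  expect_equal(p2$score[1L], 2 * 2.7 / 2.8)
  expect_false(any(duplicated(ek(pmin(p2$from, p2$to),
                                 pmax(p2$from, p2$to)))))
})

test_that("Short-Path adds the closest non-interacting ordered pair", {
  g <- chain_net()
  p <- short_path_predict(g, k = 1, seed = 2)
  expect_equal(p$tie_count, 2L)  # (s,b) and (a,t) tie at 0.4
  expect_true(paste(p$from, p$to) %in% c("s b", "a t"))

  two <- pathway_network(data.frame(from = c("a", "c"), to = c("b", "d"),
                                    cost = 0.5))
  p2 <- short_path_predict(two, k = 1, seed = 2)
  expect_equal(nrow(p2), 0L)
  expect_match(attr(p2, "stop_reason"), "no finite-distance")

  # after an addition the next minimum is recomputed on the grown graph
  p3 <- short_path_predict(g, k = 3, seed = 2)
  expect_equal(nrow(p3), 3L)
  expect_false(any(duplicated(ek(p3$from, p3$to))))
})

test_that("global predictors ignore the endpoint labeling", {
  inst <- random_instance(17, n = 12L, p = 0.3, n_sources = 2L,
                          n_targets = 2L)
  flipped <- pathway_endpoints(inst$ends$targets, inst$ends$sources)
  sp <- objective_spec("shortcuts")
  j1 <- jaccard_predict(inst$net, k = 3, seed = 4, ends = inst$ends,
                        spec = sp)
  j2 <- jaccard_predict(inst$net, k = 3, seed = 4, ends = flipped,
                        spec = sp)
  expect_identical(j1[, c("from", "to")], j2[, c("from", "to")])
  s1 <- short_path_predict(inst$net, k = 3, seed = 4, ends = inst$ends,
                           spec = sp)
  s2 <- short_path_predict(inst$net, k = 3, seed = 4, ends = flipped,
                           spec = sp)
  expect_identical(s1[, c("from", "to")], s2[, c("from", "to")])
})
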