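test_that("confidence/cost transform is complementary and validates input", {
  expect_equal(confidence_to_cost(1.0), 0.0)
  expect_equal(confidence_to_cost(0.0), 1.0)
  expect_equal(confidence_to_cost(0.872), 0.128)
  expect_error(confidence_to_cost(1.2), "out of \\[0, 1\\].*1\\.2")
  expect_error(confidence_to_cost(-0.1), "out of \\[0, 1\\]")
  # cost -> confidence -> cost round-trips exactly for any cost that arose
  # from a confidence
  conf <- seq(0, 1, by = 0.001)
  cost <- confidence_to_cost(conf)
  expect_identical(confidence_to_cost(cost_to_confidence(cost)), cost)
})

test_that("network TSV reading applies self-loop, dedup and dialect rules", {
  f <- withr::local_tempfile(lines = c("# comment", "a\tb\t0.9",
                                       "b\tc\t0.8", "c\tc\t0.5"))
  expect_warning(net <- read_network(f, directed = TRUE), "self-loop")
  expect_equal(n_nodes(net), 3L)
  expect_equal(n_edges(net), 2L)
  costs <- setNames(net$edges$cost, ek(net$edges$from, net$edges$to))
  expect_equal(unname(costs[ek("a", "b")]), 0.1)
  expect_equal(unname(costs[ek("b", "c")]), 0.2)

  expect_warning(undir <- read_network(f, directed = FALSE), "self-loop")
  expect_equal(n_edges(undir), 4L)

  f2 <- withr::local_tempfile(lines = "a\tb\t872")
  net2 <- read_network(f2, dialect = "string-score")
  expect_equal(net2$edges$cost, 0.128)

  # duplicate ordered pair keeps maximum confidence
  f3 <- withr::local_tempfile(lines = c("a\tb\t0.4", "a\tb\t0.6"))
  expect_equal(read_network(f3)$edges$cost, 0.4)

  f4 <- withr::local_tempfile(lines = c("a\tb\t0.9", "bad row"))
  expect_error(read_network(f4), "line 2")
  f5 <- withr::local_tempfile(lines = "a\tb\t1.7")
  expect_error(read_network(f5), "out of range at line 1")
})

test_that("networks round-trip through the TSV format unchanged", {
  for (seed in 1:5) {
    net <- random_instance(seed, n = 10L, p = 0.4)$net
    f <- withr::local_tempfile()
    write_network(net, f)
    back <- read_network(f)
    o1 <- order(net$edges$from, net$edges$to)
    o2 <- order(back$edges$from, back$edges$to)
    expect_equal(back$edges[o2, ], net$edges[o1, ],
                 ignore_attr = TRUE)
  }
})

test_that("endpoint files load and validate against the graph", {
  fs <- withr::local_tempfile(lines = c("# sources", sprintf("s%d", 1:5)))
  ft <- withr::local_tempfile(lines = sprintf("t%d", 1:11))
  ends <- read_endpoints(fs, ft)
  expect_length(ends$sources, 5L)
  expect_length(ends$targets, 11L)
  expect_equal(length(ends$sources) * length(ends$targets), 55L)

  f1 <- withr::local_tempfile(lines = "s")
  f2 <- withr::local_tempfile(lines = "t")
  single <- read_endpoints(f1, f2)
  expect_length(single$sources, 1L)

  fshared <- withr::local_tempfile(lines = c("s", "x"))
  fshared2 <- withr::local_tempfile(lines = c("x", "t"))
  expect_error(read_endpoints(fshared, fshared2), "overlap")

  expect_error(validate_endpoints(pathway_endpoints("s", "zz"),
                                  chain_net()), "absent")
  expect_silent(validate_endpoints(pathway_endpoints("s", "t"), chain_net()))
})

test_that("reference sets deduplicate unordered pairs keeping max confidence", {
  f <- withr::local_tempfile(lines = c("a\tb\t0.4", "b\ta\t0.6",
                                       "c\td", "a\tc\t0.2"))
  ref <- read_reference_set(f)
  expect_equal(nrow(ref$pairs), 3L)
  ab <- ref$pairs[ref$pairs$a == "a" & ref$pairs$b == "b", ]
  expect_equal(ab$confidence, 0.6)
  expect_true(all(in_reference(ref, c("b", "d"), c("a", "c"))))
  expect_false(in_reference(ref, "a", "d"))

  fe <- withr::local_tempfile(lines = "# nothing")
  expect_warning(empty <- read_reference_set(fe), "no pair rows")
  expect_equal(nrow(empty$pairs), 0L)

  expect_warning(reference_edge_set(data.frame(a = "x", b = "x")),
                 "self-pair")
})

test_that("missing-edge enumeration covers exactly the ordered non-edges", {
  tri <- pathway_network(data.frame(from = c("a", "b", "c"),
                                    to = c("b", "c", "a"), cost = 0.1))
  expect_equal(nrow(missing_edges(tri)), 3L)
  # reverse orientations of existing edges are included
  expect_true(ek("b", "a") %in%
                ek(missing_edges(tri)$from, missing_edges(tri)$to))

  both <- pathway_network(data.frame(from = c("a", "b"), to = c("b", "a"),
                                     cost = 0.5))
  expect_equal(nrow(missing_edges(both)), 0L)

  for (seed in 1:10) {
    net <- random_instance(seed, n = sample(3:12, 1L))$net
    n <- n_nodes(net)
    expect_equal(nrow(missing_edges(net)) + n_edges(net), n * (n - 1L))
  }
})

test_that("network construction enforces its invariants", {
  expect_error(pathway_network(data.frame(from = "a", to = "a", cost = 0.1)),
               "self-loop")
  expect_error(pathway_network(data.frame(from = "a", to = "b", cost = 1.2)),
               "\\[0, 1\\]")
  expect_error(pathway_network(data.frame(from = c("a", "a"),
                                          to = c("b", "b"),
                                          cost = 0.1)), "duplicate")
  net <- chain_net()
  expect_error(add_edges(net, data.frame(from = "s", to = "a", cost = 0)),
               "already present")
  expect_error(remove_edges(net, data.frame(from = "t", to = "s")),
               "unknown edge")
  rev <- reverse_network(net)
  expect_equal(shortest_distances_from(rev, "t")[["s"]], 0.6)
})
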