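test_that("shortest travel times on hand-checkable networks", {
  net <- line_network()
  expect_same_mapping(shortest_travel_times(net, "A"),
                      c(A = 0, B = 4, C = 9))
  expect_same_mapping(shortest_travel_times(net, "C"),
                      c(C = 0, B = 5, A = 9))
  # single isolated node
  solo <- travel_network(data.frame(from_id = character(),
                                    to_id = character(),
                                    minutes = numeric()),
                         municipality_ids = "Z")
  expect_equal(shortest_travel_times(solo, "Z"), c(Z = 0))
  expect_error(shortest_travel_times(net, "NOPE"),
               "unknown municipality id: 'NOPE'")
})

test_that("network construction rejects invalid edges", {
  expect_error(travel_network(data.frame(from_id = "A", to_id = "A",
                                         minutes = 1)), "self-loop")
  expect_error(travel_network(data.frame(from_id = "A", to_id = "B",
                                         minutes = 0)), "minutes > 0")
  expect_error(travel_network(data.frame(from_id = "A", to_id = "B",
                                         minutes = -3)), "minutes > 0")
  expect_error(travel_network(data.frame(from_id = "A", to_id = "B",
                                         minutes = Inf)), "minutes > 0")
})

test_that("shortest paths agree with the brute-force all-pairs oracle", {
  for (seed in 1:10) {
    n <- sample(5:25, 1)
    net <- random_network(seed * 100, n)
    D <- oracle_all_pairs(net$edges, net$nodes)
    for (origin in net$nodes) {
      got <- shortest_travel_times(net, origin)
      want <- D[origin, ]
      want <- want[is.finite(want)]
      expect_equal(got[order(names(got))], want[order(names(want))],
                   tolerance = 1e-12)
    }
  }
})

test_that("computed travel times are symmetric and satisfy the triangle property", {
  net <- random_network(42, 20)
  D <- do.call(rbind, lapply(net$nodes, function(o) {
    d <- shortest_travel_times(net, o)
    d[net$nodes]
  }))
  dimnames(D) <- list(net$nodes, net$nodes)
  expect_equal(D, t(D), tolerance = 1e-12)
  for (u in net$nodes) for (v in net$nodes)
    expect_true(all(D[u, ] <= D[u, v] + D[v, ] + 1e-9))
})

test_that("catchment membership follows the closed cutoff boundary", {
  net <- line_network()
  c5 <- compute_catchment(net, "A", 5)
  expect_equal(c5$members, c(A = 0, B = 4))
  c10 <- compute_catchment(net, "A", 10)
  expect_equal(c10$members, c(A = 0, B = 4, C = 9))
  # time exactly equal to the cutoff is inside
  c9 <- compute_catchment(net, "A", 9)
  expect_true("C" %in% names(c9$members))
  expect_equal(unname(c9$members["A"]), 0)
  expect_error(compute_catchment(net, "A", 0), "positive")
  expect_error(compute_catchment(net, "A", -5), "positive")
  expect_error(compute_catchment(net, "NOPE", 10), "unknown municipality")
})

test_that("catchments nest monotonically in the cutoff and ignore district borders", {
  co <- tiny_country()
  net <- co$network
  for (m in co$municipalities$municipality_id) {
    m10 <- names(compute_catchment(net, m, 10)$members)
    m15 <- names(compute_catchment(net, m, 15)$members)
    m20 <- names(compute_catchment(net, m, 20)$members)
    expect_true(all(m10 %in% m15))
    expect_true(all(m15 %in% m20))
  }
  # at least one catchment spans more than one district on this fixture
  spans <- vapply(co$municipalities$municipality_id, function(m) {
    ms <- names(compute_catchment(net, m, 20)$members)
    length(unique(co$municipalities$district_id[
      co$municipalities$municipality_id %in% ms]))
  }, numeric(1))
  expect_true(any(spans > 1))
})

test_that("nearest facility times cover host, remote and absent cases", {
  net <- line_network()
  fac <- data.frame(facility_id = c("F1", "F2"),
                    facility_type = c("hospital", "pharmacy"),
                    municipality_id = c("C", "A"),
                    stringsAsFactors = FALSE)
  expect_equal(nearest_facility_time(net, "C", fac, "hospital"), 0)
  expect_equal(nearest_facility_time(net, "A", fac, "hospital"), 9)
  expect_equal(nearest_facility_time(net, "B", fac, "pharmacy"), 4)
  expect_true(is.na(nearest_facility_time(net, "A", fac, "nursing_home")))
  expect_error(nearest_facility_time(net, "A", fac, "spaceport"),
               "unknown facility_type")
})

test_that("network files round-trip through CSV and GraphML", {
  net <- random_network(9, 12)
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(net$edges, csv, row.names = FALSE)
  back <- read_network(csv)
  expect_equal(sort(back$nodes), sort(net$nodes))
  expect_same_mapping(shortest_travel_times(back, net$nodes[1]),
                      shortest_travel_times(net, net$nodes[1]))
  gml <- withr::local_tempfile(fileext = ".graphml")
  igraph::write_graph(net$graph, gml, format = "graphml")
  back2 <- read_network(gml)
  expect_same_mapping(shortest_travel_times(back2, net$nodes[1]),
                      shortest_travel_times(net, net$nodes[1]))
})
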