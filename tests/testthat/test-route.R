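test_that("the mid-block grid route matches hand enumeration", {
  # 3x3 grid, school mid-block in the center: the access segment runs
  # between two interior 4-way intersections, each contributing its other
  # three incident streets
  net <- generate_grid_network(3, 3)
  route <- select_route(net)
  expect_equal(unname(count_route_units(route)), c(1L, 2L, 6L))
  expect_equal(route$access_segments, "h_1_1")
  expect_setequal(route$crossings, c("n_1_1", "n_2_1"))
  expect_setequal(route$other_segments$edge_id,
                  c("h_0_1", "h_2_1", "v_1_0", "v_1_1", "v_2_0", "v_2_1"))
  # every other segment hangs off a listed crossing (one-hop property)
  for (i in seq_len(nrow(route$other_segments))) {
    e <- net$edges[net$edges$id == route$other_segments$edge_id[i], ]
    expect_true(any(c(e$node_a, e$node_b) %in% route$crossings))
  }
  expect_equal(nrow(route$other_segments),
               length(unique(route$other_segments$edge_id)))
})

test_that("a single-block loop yields two corner crossings", {
  net <- generate_grid_network(1, 1, school_block = c(1, 1))
  route <- select_route(net)
  expect_equal(unname(count_route_units(route)), c(1L, 2L, 2L))
  expect_setequal(route$crossings, c("n_0_0", "n_1_0"))
  expect_setequal(route$other_segments$edge_id, c("v_0_0", "v_1_0"))
})

test_that("school driveways join the crossing list without splitting", {
  net0 <- generate_grid_network(3, 3, driveways = 0)
  net2 <- generate_grid_network(3, 3, driveways = 2)
  r0 <- select_route(net0)
  r2 <- select_route(net2)
  expect_equal(unname(count_route_units(r2)), c(1L, 4L, 6L))
  expect_setequal(setdiff(r2$crossings, r0$crossings), c("d_1", "d_2"))
  # driveways never split the access segment, and contribute no segments
  expect_equal(r2$access_segments, r0$access_segments)
  expect_equal(r2$other_segments, r0$other_segments)
})

test_that("a dead-end access segment contributes one crossing", {
  nodes <- data.frame(id = c("a", "b", "c", "d"), x = c(0, 1, 1, 2),
                      y = c(0, 0, 1, 0), kind = "intersection",
                      stringsAsFactors = FALSE)
  edges <- data.frame(id = c("e1", "e2", "e3"),
                      node_a = c("a", "b", "b"), node_b = c("b", "c", "d"),
                      stringsAsFactors = FALSE)
  # 'a' is a dead end: the only crossing with onward segments is 'b'
  net <- street_network(nodes, edges, list(access_edge_ids = "e1"))
  route <- select_route(net)
  expect_setequal(route$crossings, c("a", "b"))
  expect_setequal(route$other_segments$edge_id, c("e2", "e3"))
  expect_true(all(route$other_segments$via_crossing == "b"))
})

test_that("access segments come from the entrance node when not declared", {
  nodes <- data.frame(id = c("a", "b", "c", "lonely"), x = c(0, 1, 2, 9),
                      y = 0, kind = "intersection", stringsAsFactors = FALSE)
  edges <- data.frame(id = c("e1", "e2"), node_a = c("a", "b"),
                      node_b = c("b", "c"), stringsAsFactors = FALSE)
  net <- street_network(nodes, edges, list(entrance_node = "b"))
  expect_equal(identify_access_segments(net), c("e1", "e2"))
  expect_error(
    select_route(street_network(nodes, edges,
                                list(entrance_node = "lonely"))),
    "not adjacent to any street segment")
})

test_that("routes are deterministic under node and edge permutations", {
  net <- generate_grid_network(4, 3, school_block = c(2, 2), driveways = 1)
  base <- select_route(net)
  set.seed(8)
  for (i in 1:5) {
    shuffled <- street_network(
      net$nodes[sample(nrow(net$nodes)), ],
      net$edges[sample(nrow(net$edges)), ],
      net$school)
    expect_equal(select_route(shuffled), base)
  }
})

test_that("adding an incident street only grows the route", {
  net <- generate_grid_network(2, 2, school_block = c(1, 1))
  base <- select_route(net)
  # a new spur off one access-segment endpoint
  nodes2 <- rbind(net$nodes,
                  data.frame(id = "spur_end", x = -1, y = -1,
                             kind = "intersection",
                             on_edge = NA_character_))
  edges2 <- rbind(net$edges,
                  data.frame(id = "spur", node_a = "n_0_0",
                             node_b = "spur_end",
                             street_name = "Spur"))
  grown <- select_route(street_network(nodes2, edges2, net$school))
  expect_true(all(base$crossings %in% grown$crossings))
  expect_true(all(base$other_segments$edge_id %in%
                    grown$other_segments$edge_id))
  expect_true("spur" %in% grown$other_segments$edge_id)
})

test_that("street networks validate their structure", {
  nodes <- data.frame(id = c("a", "b"), x = 0:1, y = 0,
                      kind = "intersection", stringsAsFactors = FALSE)
  edges <- data.frame(id = "e1", node_a = "a", node_b = "ghost",
                      stringsAsFactors = FALSE)
  expect_error(street_network(nodes, edges, list(entrance_node = "a")),
               "not intersection nodes")
  d <- data.frame(id = "d1", x = 0.5, y = 0, kind = "driveway",
                  on_edge = "nope", stringsAsFactors = FALSE)
  nodes2 <- rbind(cbind(nodes, on_edge = NA_character_), d)
  edges2 <- data.frame(id = "e1", node_a = "a", node_b = "b",
                       stringsAsFactors = FALSE)
  expect_error(street_network(nodes2, edges2, list(entrance_node = "a")),
               "without a valid on_edge")
  expect_error(generate_grid_network(2, 2, school_block = c(5, 1)),
               "outside")
})

test_that("street networks round-trip through the directory format", {
  net <- generate_grid_network(2, 3, school_block = c(2, 1), driveways = 1)
  dir <- withr::local_tempdir()
  write_street_network(net, dir)
  back <- read_street_network(dir)
  expect_equal(select_route(back), select_route(net))
  expect_equal(back$nodes$id, net$nodes$id)
})
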