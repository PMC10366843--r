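test_that("a straight-line graph yields the unique path for every method", {
  a <- array(FALSE, c(5, 3, 3))
  a[1:5, 1, 1] <- TRUE
  g <- skeleton_to_graph(cow_mask(a, rep(0.6, 3)))
  for (m in c("dfs", "dijkstra", "astar")) {
    p <- find_path(g, c(0, 0, 0), c(4, 0, 0), m)
    expect_identical(nrow(p$voxels), 5L)
    expect_equal(p$length, 4 * 0.6, tolerance = 1e-12)
    expect_true(validate_path(p, g, c(0, 0, 0), c(4, 0, 0)))
  }
})

test_that("on a 16-node cycle DFS takes the long arc while Dijkstra takes the short one", {
  g <- ring_graph(spacing = 0.6)
  s <- c(2, 0, 0); goal <- c(0, 4, 0)
  pd <- dfs_path(g, s, goal)
  pj <- dijkstra_path(g, s, goal)
  pa <- astar_path(g, s, goal)
  pb <- brute_force_shortest(g, s, goal)
  expect_identical(nrow(pd$voxels), 13L)               # 12-edge arc
  expect_identical(nrow(pj$voxels), 5L)                # 4-edge arc
  short <- 2 * 0.6 + 2 * 0.6 * sqrt(2)
  long <- 6 * 0.6 + 6 * 0.6 * sqrt(2)
  expect_equal(pj$length, short, tolerance = 1e-12)
  expect_equal(pd$length, long, tolerance = 1e-12)
  expect_equal(pa$length, short, tolerance = 1e-12)
  expect_equal(pb$length, short, tolerance = 1e-12)
  expect_gt(pd$length, pj$length)
})

test_that("start == goal returns a zero-length single-node path", {
  g <- ring_graph()
  for (m in c("dfs", "dijkstra", "astar")) {
    p <- find_path(g, c(2, 0, 0), c(2, 0, 0), m)
    expect_identical(nrow(p$voxels), 1L)
    expect_identical(p$length, 0)
  }
  expect_identical(brute_force_shortest(g, c(2, 0, 0), c(2, 0, 0))$length, 0)
})

test_that("an unreachable goal raises a no-path error, not a snap or parse error", {
  a <- array(FALSE, c(9, 3, 3))
  a[1:3, 1, 1] <- TRUE
  a[7:9, 1, 1] <- TRUE                   # two separated line components
  g <- skeleton_to_graph(cow_mask(a, rep(1, 3)))
  for (m in c("dfs", "dijkstra", "astar"))
    expect_error(find_path(g, c(0, 0, 0), c(8, 0, 0), m), "no path",
                 class = "cow_nopath_error")
})

test_that("brute force solves the two-route analytic fixture", {
  # nodes (0,0,0)-(1,0,0)-(2,0,0) in line plus apex (1,1,0):
  # direct route cost 2, detour over the apex 2*sqrt(2)
  a <- array(FALSE, c(3, 2, 1))
  a[1:3, 1, 1] <- TRUE; a[2, 2, 1] <- TRUE
  g <- skeleton_to_graph(cow_mask(a, rep(1, 3)))
  p <- brute_force_shortest(g, c(0, 0, 0), c(2, 0, 0))
  expect_equal(p$length, 2, tolerance = 1e-12)
  expect_identical(nrow(p$voxels), 3L)
  # minimal 2-node graph
  b <- array(FALSE, c(2, 1, 1)); b[1:2, 1, 1] <- TRUE
  g2 <- skeleton_to_graph(cow_mask(b, rep(1, 3)))
  expect_equal(brute_force_shortest(g2, c(0, 0, 0), c(1, 0, 0))$length, 1)
})

test_that("the enumeration guard refuses oversized oracle queries", {
  fx <- phantom_fixture("complete")
  co <- fx$graph$coords
  expect_error(
    brute_force_shortest(fx$graph, co[1, ], co[nrow(co), ], max_expansions = 50),
    "guard", class = "cow_oracle_error")
})

test_that("Dijkstra, A* and the oracle agree and DFS never beats them on 200 random graphs", {
  for (s in 1:200) {
    g <- random_voxel_graph(s)
    st <- g$coords[1, ]
    go <- g$coords[nrow(g$coords), ]
    pj <- dijkstra_path(g, st, go)
    pa <- astar_path(g, st, go)
    pb <- brute_force_shortest(g, st, go)
    pd <- dfs_path(g, st, go)
    expect_equal(pj$length, pb$length, tolerance = 1e-9)
    expect_equal(pa$length, pb$length, tolerance = 1e-9)
    expect_gte(pd$length, pj$length - 1e-9)
    validate_path(pj, g, st, go)
    validate_path(pa, g, st, go)
    validate_path(pd, g, st, go)
  }
})

test_that("all methods are deterministic and shortest paths satisfy the triangle identity", {
  g <- random_voxel_graph(7, n_max = 12L, box = 5L)
  st <- g$coords[1, ]; go <- g$coords[nrow(g$coords), ]
  for (m in c("dfs", "dijkstra", "astar")) {
    p1 <- find_path(g, st, go, m)
    p2 <- find_path(g, st, go, m)
    expect_identical(p1$voxels, p2$voxels)
  }
  pj <- dijkstra_path(g, st, go)
  if (nrow(pj$voxels) > 2) {
    mid <- pj$voxels[ceiling(nrow(pj$voxels) / 2), ]
    expect_equal(dijkstra_path(g, st, mid)$length +
                   dijkstra_path(g, mid, go)$length,
                 pj$length, tolerance = 1e-9)
  }
})

test_that("Dijkstra distances match an independent graph library on the phantom", {
  skip_if_not_installed("igraph")
  fx <- phantom_fixture("complete")
  g <- fx$graph
  ig <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
  igraph::E(ig)$weight <- g$weights
  sp <- fx$ph$endpoints
  for (i in c(1, 6, 14)) {      # AComm, R-ICA, BA
    a <- snap_to_skeleton(c(sp$ax[i], sp$ay[i], sp$az[i]), g)
    b <- snap_to_skeleton(c(sp$bx[i], sp$by[i], sp$bz[i]), g)
    ia <- which(g$coords[, 1] == a[1] & g$coords[, 2] == a[2] & g$coords[, 3] == a[3])
    ib <- which(g$coords[, 1] == b[1] & g$coords[, 2] == b[2] & g$coords[, 3] == b[3])
    expect_equal(dijkstra_path(g, a, b)$length,
                 as.numeric(igraph::distances(ig, ia, ib)), tolerance = 1e-9)
  }
})

test_that("path validation rejects corrupted paths", {
  g <- ring_graph()
  p <- dijkstra_path(g, c(2, 0, 0), c(0, 4, 0))
  broken <- p; broken$length <- p$length + 1
  expect_error(validate_path(broken, g), "length", class = "cow_input_error")
  loopy <- p; loopy$voxels <- rbind(p$voxels, p$voxels[1, ])
  expect_error(validate_path(loopy, g), class = "cow_input_error")
})
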