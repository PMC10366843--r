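test_that("all 14 segments are found on the complete phantom within 1 voxel of truth", {
  fx <- phantom_fixture("complete")
  res <- label_segments(fx$graph, fx$ph$endpoints, "dijkstra")
  st <- vapply(res$records, `[[`, "", "status")
  expect_identical(unname(st), rep("found", 14))
  errs <- vapply(cow_segment_names(), function(nm)
    mean_centerline_error(res$records[[nm]]$path$voxels,
                          fx$ph$truth$centerlines[[nm]]), 0)
  expect_lt(max(errs), 1)
})

test_that("sentinel specs pass through as undetected while the rest are found", {
  fx <- phantom_fixture("complete")
  sp <- fx$ph$endpoints
  i <- match(c("R-PComm", "L-PComm"), sp$name)
  a <- as.matrix(sp[, c("ax", "ay", "az")]); b <- as.matrix(sp[, c("bx", "by", "bz")])
  a[i, ] <- 0L; b[i, ] <- 0L
  specs <- cow_endpoints(sp$name, a, b)
  res <- label_segments(fx$graph, specs, "dijkstra")
  st <- vapply(res$records, `[[`, "", "status")
  expect_identical(sum(st == "undetected"), 2L)
  expect_identical(names(st[st == "undetected"]), c("R-PComm", "L-PComm"))
  expect_identical(sum(st == "found"), 12L)
})

test_that("segments sharing a branch point produce overlapping termini", {
  fx <- phantom_fixture("complete")
  res <- label_segments(fx$graph, fx$ph$endpoints, "dijkstra")
  ra1 <- res$records[["R-A1"]]; rm1 <- res$records[["R-M1"]]
  expect_identical(ra1$status, "found")
  expect_identical(rm1$status, "found")
  # both specs start at the R-ICA top branch point; after snapping both
  # paths must begin at the same skeleton voxel
  expect_identical(ra1$path$voxels[1, ], rm1$path$voxels[1, ])
})

test_that("dijkstra and astar labelings agree segment-by-segment and are reproducible", {
  fx <- phantom_fixture("complete")
  r1 <- label_segments(fx$graph, fx$ph$endpoints, "dijkstra")
  r2 <- label_segments(fx$graph, fx$ph$endpoints, "astar")
  l1 <- vapply(r1$records, `[[`, 0, "length_mm")
  l2 <- vapply(r2$records, `[[`, 0, "length_mm")
  expect_equal(l1, l2, tolerance = 1e-9)
  r1b <- label_segments(fx$graph, fx$ph$endpoints, "dijkstra")
  expect_identical(lapply(r1$records, `[[`, "path"),
                   lapply(r1b$records, `[[`, "path"))
})

test_that("a snap failure on a present spec is classified undetected, disconnection as failed", {
  # two disconnected line skeletons; specs point at them and far away
  a <- array(FALSE, c(20, 5, 5))
  a[1:6, 3, 3] <- TRUE
  a[15:20, 3, 3] <- TRUE
  g <- skeleton_to_graph(cow_mask(a, rep(0.6, 3)))
  nm <- cow_segment_names()
  am <- matrix(0L, 14, 3); bm <- matrix(0L, 14, 3)
  am[1, ] <- c(0L, 2L, 2L);  bm[1, ] <- c(5L, 2L, 2L)    # AComm: connected
  am[2, ] <- c(0L, 2L, 2L);  bm[2, ] <- c(19L, 2L, 2L)   # R-A1: disconnected
  am[3, ] <- c(10L, 2L, 2L); bm[3, ] <- c(19L, 2L, 2L)   # L-A1: snap fails
  specs <- cow_endpoints(nm, am, bm)                     # rest are sentinels
  res <- label_segments(g, specs, "dijkstra")
  expect_identical(res$records[["AComm"]]$status, "found")
  expect_identical(res$records[["R-A1"]]$status, "failed")
  expect_identical(res$records[["L-A1"]]$status, "undetected")
  st <- vapply(res$records, `[[`, "", "status")
  expect_identical(sum(st == "undetected"), 12L)   # 11 sentinels + 1 snap failure
  expect_lte(sum(st == "undetected"), 14L)
})

test_that("CSV export round-trips coordinates and labels", {
  fx <- phantom_fixture("complete")
  res <- label_segments(fx$graph, fx$ph$endpoints, "dijkstra")
  f <- tempfile(fileext = ".csv")
  export_labeled_centerlines(res, f)
  back <- import_labeled_centerlines(f)
  orig <- as.data.frame(res)
  expect_identical(back$segment, orig$segment)
  expect_identical(back$x, orig$x)
  expect_identical(back$y, orig$y)
  expect_identical(back$z, orig$z)
})

test_that("an all-undetected labeling exports 14 status rows and no path rows", {
  nm <- cow_segment_names()
  specs <- cow_endpoints(nm, matrix(0L, 14, 3), matrix(0L, 14, 3))
  a <- array(FALSE, c(4, 4, 4)); a[1:2, 1, 1] <- TRUE
  g <- skeleton_to_graph(cow_mask(a, rep(1, 3)))
  res <- label_segments(g, specs, "dijkstra")
  f <- tempfile(fileext = ".csv")
  export_labeled_centerlines(res, f)
  back <- import_labeled_centerlines(f)
  expect_identical(nrow(back), 14L)
  expect_true(all(is.na(back$order)))
  expect_identical(unique(back$status), "undetected")
})

test_that("HTML export contains one named trace per found segment", {
  fx <- phantom_fixture("complete")
  res <- label_segments(fx$graph, fx$ph$endpoints, "dijkstra")
  f <- tempfile(fileext = ".html")
  export_labeled_centerlines(res, f)
  html <- paste(readLines(f), collapse = "\n")
  n_found <- sum(vapply(res$records, `[[`, "", "status") == "found")
  expect_identical(lengths(regmatches(html, gregexpr("data-segment=", html))),
                   n_found)
  for (nm in cow_segment_names())
    expect_match(html, sprintf('data-segment="%s"', nm), fixed = TRUE)
})

test_that("JSON export is valid and carries the voxel paths", {
  fx <- phantom_fixture("complete")
  res <- label_segments(fx$graph, fx$ph$endpoints, "dijkstra")
  f <- tempfile(fileext = ".json")
  export_labeled_centerlines(res, f)
  j <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_identical(j$method, "dijkstra")
  expect_identical(nrow(j$segments), 14L)
  expect_true(all(j$segments$status == "found"))
})
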