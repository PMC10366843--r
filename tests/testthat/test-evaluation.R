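test_that("accuracy and undetected percentages match their closed forms", {
  expect_identical(accuracy_percent(614, 121), 83.5)
  expect_identical(accuracy_percent(714, 21), 97.1)
  expect_identical(accuracy_percent(706, 29), 96.1)
  expect_identical(accuracy_percent(19, 25), 43.2)
  expect_error(accuracy_percent(0, 0), "undefined", class = "cow_input_error")
  expect_identical(undetected_percent(16, 60), 26.7)
  expect_identical(undetected_percent(46, 60), 76.7)
  expect_identical(undetected_percent(0, 60), 0)
  expect_error(undetected_percent(1, 0), class = "cow_input_error")
})

test_that("Fisher's exact test reproduces published two-sided p-values", {
  expect_equal(round(fisher_exact_two_sided(c(44, 0, 36, 8)), 3), 0.006)
  expect_equal(round(fisher_exact_two_sided(c(8, 6, 14, 0)), 3), 0.016)
  expect_equal(round(fisher_exact_two_sided(c(51, 9, 60, 0)), 3), 0.003)
  expect_equal(round(fisher_exact_two_sided(c(58, 2, 60, 0)), 3), 0.496)
  expect_equal(fisher_exact_two_sided(c(51, 9, 50, 10)), 1)
  expect_lt(fisher_exact_two_sided(c(19, 25, 44, 0)), 0.001)
  expect_equal(fisher_exact_two_sided(c(30, 5, 30, 5)), 1, tolerance = 1e-12)
})

test_that("Fisher p is symmetric under row and column swaps and lies in (0, 1]", {
  set.seed(31)
  for (i in 1:50) {
    t <- sample(0:25, 4, replace = TRUE)
    if (sum(t) == 0) next
    p <- fisher_exact_two_sided(t)
    expect_gt(p, 0)
    expect_lte(p, 1)
    expect_equal(p, fisher_exact_two_sided(t[c(3, 4, 1, 2)]), tolerance = 1e-12)
    expect_equal(p, fisher_exact_two_sided(t[c(2, 1, 4, 3)]), tolerance = 1e-12)
  }
})

test_that("Fisher implementation equals the enumeration oracle for all small tables", {
  for (N in c(5, 12, 20, 30)) {
    for (a in 0:N) for (b in 0:(N - a)) for (c in 0:(N - a - b)) {
      d <- N - a - b - c
      expect_equal(fisher_exact_two_sided(c(a, b, c, d)),
                   fisher_oracle(a, b, c, d), tolerance = 1e-12)
    }
  }
})

test_that("Fisher implementation matches stats::fisher.test on random tables", {
  set.seed(41)
  for (i in 1:60) {
    t <- sample(0:60, 4, replace = TRUE)
    if (sum(t) == 0 || sum(t[1:2]) == 0 || sum(t[3:4]) == 0) next
    ours <- fisher_exact_two_sided(t)
    ref <- stats::fisher.test(matrix(t, 2, byrow = TRUE))$p.value
    expect_equal(ours, min(ref, 1), tolerance = 1e-7)
  }
})

test_that("p-value formatting mirrors the published rendering", {
  expect_identical(format_p(c(0.0004, 0.0061, 0.4957983, 1, 0.9996)),
                   c("<0.001", "0.006", "0.496", "1", "1"))
})

test_that("the evaluation table reproduces the published totals and accuracies", {
  ev <- evaluation_table(cow_reference_counts())
  expect_identical(ev$totals$m1_correct, 614)
  expect_identical(ev$totals$m1_incorrect, 121)
  expect_identical(ev$totals$m2_correct, 714)
  expect_identical(ev$totals$m2_incorrect, 21)
  expect_identical(ev$totals$m3_correct, 706)
  expect_identical(ev$totals$m3_incorrect, 29)
  expect_identical(ev$totals$undetected, 105)
  expect_identical(unname(ev$accuracy), c(83.5, 97.1, 96.1))
  # conservation: correct + incorrect + undetected == total per segment
  t <- ev$table
  expect_true(all(t$m1_correct + t$m1_incorrect + t$undetected == t$total))
  expect_true(all(t$total == 60))
  expect_identical(ev$totals$total, 840)
  # spot-checked pairwise p-values
  expect_equal(round(t$p23[t$segment == "AComm"], 3), 0.006)
  expect_equal(round(t$p12[t$segment == "R-PComm"], 3), 0.016)
  expect_equal(round(t$p12[t$segment == "L-M1"], 3), 0.496)
  expect_identical(t$p12[t$segment == "R-ICA"], 1)
})

test_that("evaluation table rejects inconsistent or single-method input", {
  counts <- cow_reference_counts()
  bad <- counts; bad$m2_correct[1] <- bad$m2_correct[1] + 1
  expect_error(evaluation_table(bad), "differ", class = "cow_input_error")
  expect_error(evaluation_table(counts[, 1:3]), class = "cow_input_error")
})

test_that("per-path run records tally into a conserved table", {
  set.seed(51)
  subjects <- sprintf("s%02d", 1:20)
  segs <- cow_segment_names()
  grid <- expand.grid(subject = subjects, segment = segs,
                      method = c("dfs", "dijkstra", "astar"),
                      stringsAsFactors = FALSE)
  # undetected is a property of (subject, segment), shared by all methods
  und <- matrix(runif(20 * 14) < 0.1, 20, 14)
  grid$status <- ifelse(und[cbind(match(grid$subject, subjects),
                                  match(grid$segment, segs))],
                        "undetected", "found")
  correctness <- grid[, c("subject", "segment", "method")]
  correctness$correct <- runif(nrow(grid)) > 0.2
  ev <- build_evaluation_table(grid, correctness)
  t <- ev$table
  expect_true(all(t$m1_correct + t$m1_incorrect + t$undetected == 20))
  expect_true(all(t$m2_correct + t$m2_incorrect + t$undetected == 20))
  expect_identical(ev$totals$total, 20 * 14)

  single <- grid[grid$method == "dfs", ]
  expect_error(build_evaluation_table(single, correctness),
               "three methods", class = "cow_input_error")
  mismatched <- grid[!(grid$method == "astar" & grid$segment == "BA"), ]
  expect_error(build_evaluation_table(mismatched, correctness),
               "segment set", class = "cow_input_error")
})

test_that("the timing harness reports positive timings and a bounded graph fraction", {
  fx <- phantom_fixture("complete")
  tm <- time_methods(fx$skel, fx$ph$endpoints, repetitions = 3L)
  expect_identical(nrow(tm$timings), 9L)
  expect_true(all(tm$timings$path_ms > 0))
  expect_true(all(tm$timings$graph_ms > 0))
  expect_true(all(tm$timings$graph_fraction > 0 & tm$timings$graph_fraction < 1))
  expect_identical(nrow(tm$summary), 3L)
})
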