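# Evaluation statistics: per-segment correct/incorrect/undetected tallies,
# accuracies, two-sided Fisher's exact tests between methods, and a timing
# harness.

#' Accuracy percentage
#'
#' `100 * correct / (correct + incorrect)`, reported to one decimal.
#' Undetected segments are excluded from the denominator.
#'
#' @param correct,incorrect Non-negative counts.
#' @return Percentage rounded to one decimal.
#' @export
accuracy_percent <- function(correct, incorrect) {
  if (correct < 0 || incorrect < 0)
    cow_input_error("counts must be non-negative")
  if (correct + incorrect == 0)
    cow_input_error("accuracy undefined: correct + incorrect is zero")
  round(100 * correct / (correct + incorrect), 1)
}

#' Undetected-path percentage
#'
#' `100 * undetected / subjects` to one decimal.
#'
#' @param undetected,subjects Counts; `subjects > 0`.
#' @return Percentage rounded to one decimal.
#' @export
undetected_percent <- function(undetected, subjects) {
  if (subjects <= 0) cow_input_error("subjects must be > 0")
  if (undetected < 0) cow_input_error("undetected must be >= 0")
  round(100 * undetected / subjects, 1)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact p-value from the hypergeometric distribution with fixed margins,
#' using the minimum-likelihood two-sided convention: the p-value is the sum
#' of the point probabilities of all tables (with the same margins) whose
#' probability does not exceed that of the observed table, within a relative
#' tolerance of 1e-7 to absorb floating-point noise.
#'
#' @param t 2x2 matrix of non-negative counts, or a length-4 vector
#'   `c(a, b, c, d)` read row-wise (row = method, column = correct/incorrect).
#' @return p-value in (0, 1].
#' @export
fisher_exact_two_sided <- function(t) {
  if (is.matrix(t)) t <- c(t[1, 1], t[1, 2], t[2, 1], t[2, 2])
  t <- as.numeric(t)
  if (length(t) != 4L || anyNA(t) || any(t < 0) || any(t != round(t)))
    cow_input_error("t: expected four non-negative integer counts")
  if (sum(t) == 0) cow_input_error("t: at least one entry must be > 0")
  a <- t[1]; b <- t[2]; c <- t[3]; d <- t[4]
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || b + d == 0) return(1)
  k <- max(0, c1 - r2):min(r1, c1)      # support of the a-cell
  probs <- dhyper(k, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Format a p-value for reporting
#'
#' Three decimals, with `"<0.001"` for p below 0.0005 and `"1"` for values
#' rounding to one.
#'
#' @param p Numeric p-value(s).
#' @return Character vector.
#' @export
format_p <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 0.0005) return("<0.001")
    s <- sprintf("%.3f", pi)
    if (s == "1.000") "1" else s
  }, character(1))
}

#' Build the method-comparison evaluation table from per-segment counts
#'
#' Takes per-segment correct/incorrect counts for the three path-finding
#' methods plus the per-segment undetected count, and produces the full
#' evaluation table: per-segment pairwise Fisher p-values (method 1 vs 2,
#' 1 vs 3, 2 vs 3), a totals row, and per-method overall accuracies.
#' Undetected segments are excluded from accuracy denominators, so
#' `correct + incorrect + undetected == total` per segment.
#'
#' @param counts Data frame with columns `segment`, `m1_correct`,
#'   `m1_incorrect`, `m2_correct`, `m2_incorrect`, `m3_correct`,
#'   `m3_incorrect`, `undetected`.
#' @return An object of class `cow_eval`: list with `table` (the per-segment
#'   data frame augmented with `p12`, `p13`, `p23`, `total`), `totals`
#'   (summed counts) and `accuracy` (named vector, percent, for
#'   `dfs`/`dijkstra`/`astar`).
#' @export
evaluation_table <- function(counts) {
  need <- c("segment", "m1_correct", "m1_incorrect", "m2_correct",
            "m2_incorrect", "m3_correct", "m3_incorrect", "undetected")
  if (!is.data.frame(counts) || !all(need %in% names(counts)))
    cow_input_error(sprintf("counts: expected columns %s",
                            paste(need, collapse = ", ")))
  cnt <- counts[, need]
  att1 <- cnt$m1_correct + cnt$m1_incorrect
  att2 <- cnt$m2_correct + cnt$m2_incorrect
  att3 <- cnt$m3_correct + cnt$m3_incorrect
  if (any(att1 != att2) || any(att1 != att3))
    cow_input_error("counts: attempted-path totals differ across methods")
  cnt$total <- att1 + cnt$undetected
  cnt$p12 <- mapply(function(a, b, c, d) fisher_exact_two_sided(c(a, b, c, d)),
                    cnt$m1_correct, cnt$m1_incorrect,
                    cnt$m2_correct, cnt$m2_incorrect)
  cnt$p13 <- mapply(function(a, b, c, d) fisher_exact_two_sided(c(a, b, c, d)),
                    cnt$m1_correct, cnt$m1_incorrect,
                    cnt$m3_correct, cnt$m3_incorrect)
  cnt$p23 <- mapply(function(a, b, c, d) fisher_exact_two_sided(c(a, b, c, d)),
                    cnt$m2_correct, cnt$m2_incorrect,
                    cnt$m3_correct, cnt$m3_incorrect)
  totals <- colSums(cnt[, c("m1_correct", "m1_incorrect", "m2_correct",
                            "m2_incorrect", "m3_correct", "m3_incorrect",
                            "undetected", "total")])
  accuracy <- c(
    dfs      = accuracy_percent(totals[["m1_correct"]], totals[["m1_incorrect"]]),
    dijkstra = accuracy_percent(totals[["m2_correct"]], totals[["m2_incorrect"]]),
    astar    = accuracy_percent(totals[["m3_correct"]], totals[["m3_incorrect"]]))
  structure(list(table = cnt, totals = as.list(totals), accuracy = accuracy),
            class = "cow_eval")
}

#' @export
print.cow_eval <- function(x, ...) {
  t <- x$table
  cat("<cow_eval> per-segment path-finding evaluation\n")
  cat(sprintf("%-8s %5s %5s %5s %5s %5s %5s %7s %7s %7s %6s %6s\n",
              "segment", "m1_c", "m1_i", "m2_c", "m2_i", "m3_c", "m3_i",
              "p12", "p13", "p23", "undet", "total"))
  for (i in seq_len(nrow(t)))
    cat(sprintf("%-8s %5d %5d %5d %5d %5d %5d %7s %7s %7s %6d %6d\n",
                t$segment[i], t$m1_correct[i], t$m1_incorrect[i],
                t$m2_correct[i], t$m2_incorrect[i], t$m3_correct[i],
                t$m3_incorrect[i], format_p(t$p12[i]), format_p(t$p13[i]),
                format_p(t$p23[i]), t$undetected[i], t$total[i]))
  with(x$totals, cat(sprintf(
    "%-8s %5d %5d %5d %5d %5d %5d %23s %6d %6d\n", "Total",
    m1_correct, m1_incorrect, m2_correct, m2_incorrect,
    m3_correct, m3_incorrect, "", undetected, total)))
  cat(sprintf("accuracy: dfs %.1f%%, dijkstra %.1f%%, astar %.1f%%\n",
              x$accuracy[["dfs"]], x$accuracy[["dijkstra"]],
              x$accuracy[["astar"]]))
  invisible(x)
}

#' Build the evaluation table from per-path run records
#'
#' Tallies per-subject, per-segment labeling outcomes for the three methods
#' into the counts consumed by [evaluation_table()]. A path counts as
#' correct when the supplied judgment says so; a `failed` status (snapped
#' endpoints in disconnected components) counts as incorrect; `undetected`
#' statuses must agree across methods, since detection is a property of the
#' shared vessel mask, not of the path finder.
#'
#' @param runs Data frame with columns `subject`, `segment`, `method`
#'   (`"dfs"`, `"dijkstra"`, `"astar"`) and `status`
#'   (`found`/`undetected`/`failed`).
#' @param correctness Data frame with columns `subject`, `segment`, `method`,
#'   `correct` (logical) supplying the judgment for every `found` path —
#'   ground-truth distance on phantoms, reviewer consensus on real data.
#' @return A `cow_eval`, as from [evaluation_table()].
#' @export
build_evaluation_table <- function(runs, correctness) {
  need_r <- c("subject", "segment", "method", "status")
  if (!is.data.frame(runs) || !all(need_r %in% names(runs)))
    cow_input_error(sprintf("runs: expected columns %s",
                            paste(need_r, collapse = ", ")))
  methods <- c("dfs", "dijkstra", "astar")
  if (!setequal(unique(runs$method), methods))
    cow_input_error("runs: need exactly the three methods dfs, dijkstra, astar (pairwise tests are undefined otherwise)")
  segs <- sort(unique(runs$segment))
  for (m in methods) {
    sm <- runs[runs$method == m, ]
    if (!setequal(unique(sm$segment), segs))
      cow_input_error(sprintf("runs: segment set for method %s differs", m))
  }
  key <- function(d) paste(d$subject, d$segment, d$method, sep = "\r")
  runs$correct <- correctness$correct[match(key(runs), key(correctness))]
  if (any(runs$status == "found" & is.na(runs$correct)))
    cow_input_error("correctness: missing judgment for a found path")
  # undetected must agree across methods for each (subject, segment)
  und <- runs[runs$status == "undetected", c("subject", "segment")]
  und_key <- unique(paste(und$subject, und$segment, sep = "\r"))
  for (m in methods) {
    sm <- runs[runs$method == m & runs$status == "undetected", ]
    if (!setequal(paste(sm$subject, sm$segment, sep = "\r"), und_key))
      cow_input_error("runs: undetected statuses differ across methods")
  }
  tally <- function(m, seg) {
    sm <- runs[runs$method == m & runs$segment == seg, ]
    c(correct = sum(sm$status == "found" & sm$correct),
      incorrect = sum(sm$status == "found" & !sm$correct) +
                  sum(sm$status == "failed"),
      undetected = sum(sm$status == "undetected"))
  }
  rows <- lapply(segs, function(seg) {
    t1 <- tally("dfs", seg); t2 <- tally("dijkstra", seg); t3 <- tally("astar", seg)
    data.frame(segment = seg,
               m1_correct = t1[["correct"]], m1_incorrect = t1[["incorrect"]],
               m2_correct = t2[["correct"]], m2_incorrect = t2[["incorrect"]],
               m3_correct = t3[["correct"]], m3_incorrect = t3[["incorrect"]],
               undetected = t1[["undetected"]], stringsAsFactors = FALSE)
  })
  evaluation_table(do.call(rbind, rows))
}

#' Write an evaluation table as CSV and/or JSON
#'
#' @param eval A `cow_eval`.
#' @param path Output path; format from the extension (`.csv` or `.json`).
#' @return The path, invisibly.
#' @export
write_evaluation <- function(eval, path) {
  if (!inherits(eval, "cow_eval")) cow_input_error("eval: expected a cow_eval")
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(list(table = eval$table, totals = eval$totals,
                              accuracy = as.list(eval$accuracy)),
                         path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  } else {
    t <- eval$table
    t$p12 <- format_p(t$p12); t$p13 <- format_p(t$p13); t$p23 <- format_p(t$p23)
    write.csv(t, path, row.names = FALSE)
  }
  invisible(path)
}

#' Published 60-subject method-comparison counts
#'
#' Per-segment correct/incorrect/undetected tallies from a published
#' 60-subject TOF-MRA comparison of the three path-finding methods on the 14
#' circle-of-Willis segments, shipped with the package as a worked example
#' for the evaluation statistics.
#'
#' @return Data frame in the format accepted by [evaluation_table()].
#' @export
cow_reference_counts <- function() {
  path <- system.file("extdata", "cow_method_comparison.csv",
                      package = "cowpath", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Time the path-finding methods
#'
#' Measures, per repetition, the wall-clock time of skeleton-to-graph
#' conversion and of running each method over all endpoint specs, mirroring
#' the reporting split in which graph construction dominates the total.
#' Timings are reported, never asserted: they are hardware-dependent.
#'
#' @param skel A skeleton [cow_mask()].
#' @param specs A [cow_endpoints()] table.
#' @param methods Methods to time.
#' @param repetitions Number of repetitions (default 3).
#' @return List with `timings` (data frame: method, rep, path_ms, graph_ms,
#'   graph_fraction) and `summary` (per-method mean/sd of path and graph
#'   times in ms).
#' @export
time_methods <- function(skel, specs, methods = c("dfs", "dijkstra", "astar"),
                         repetitions = 3L) {
  elapsed_ms <- function(expr) {
    t0 <- Sys.time()
    force(expr)
    as.numeric(difftime(Sys.time(), t0, units = "secs")) * 1000
  }
  rows <- list()
  for (rep in seq_len(repetitions)) {
    g <- NULL
    graph_ms <- elapsed_ms(g <- skeleton_to_graph(skel))
    for (m in methods) {
      path_ms <- elapsed_ms(label_segments(g, specs, m))
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, rep = rep, path_ms = path_ms, graph_ms = graph_ms,
        graph_fraction = graph_ms / (graph_ms + path_ms),
        stringsAsFactors = FALSE)
    }
  }
  timings <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(methods, function(m) {
    sm <- timings[timings$method == m, ]
    data.frame(method = m,
               path_ms_mean = mean(sm$path_ms), path_ms_sd = sd(sm$path_ms),
               graph_ms_mean = mean(sm$graph_ms), graph_ms_sd = sd(sm$graph_ms),
               stringsAsFactors = FALSE)
  }))
  list(timings = timings, summary = summ)
}
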