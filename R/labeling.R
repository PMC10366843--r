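# Running a path-finding method over all 14 annotated segments and exporting
# the labeled centerlines.

#' Label all annotated vessel segments
#'
#' For each non-sentinel endpoint specification, snaps both endpoints onto
#' the skeleton graph and runs the chosen path-finding method. Per-segment
#' failures are recorded, never raised, so one bad segment cannot abort a
#' subject. Statuses: `found` (path returned), `undetected` (sentinel spec,
#' or an endpoint with no skeleton voxel within the snap radius — the vessel
#' is absent from the mask), `failed` (both endpoints snapped but lie in
#' disconnected skeleton components). Shared endpoints between segments
#' (e.g. the A1/M1 branch point) are legal and produce overlapping termini.
#'
#' @param graph A `cow_skeleton_graph`.
#' @param specs A [cow_endpoints()] table covering the 14 canonical names.
#' @param method `"dijkstra"` (default), `"astar"` or `"dfs"`.
#' @param snap_radius Maximum endpoint snap distance in voxels (default 3).
#' @return An object of class `cow_labels`: a list with `records` (one per
#'   canonical segment: `name`, `status`, `path`, `length_mm`), `method` and
#'   `spacing`.
#' @export
label_segments <- function(graph, specs, method = c("dijkstra", "astar", "dfs"),
                           snap_radius = 3) {
  method <- match.arg(method)
  if (!inherits(specs, "cow_endpoints"))
    cow_input_error("specs: expected a cow_endpoints table")
  absent <- setdiff(cow_segment_names(), specs$name)
  if (length(absent))
    cow_input_error(sprintf("specs: missing segment(s): %s",
                            paste(absent, collapse = ", ")))
  records <- lapply(cow_segment_names(), function(nm) {
    row <- specs[specs$name == nm, ]
    rec <- list(name = nm, status = "undetected", path = NULL, length_mm = NA_real_)
    if (row$missing) return(rec)
    a <- c(row$ax, row$ay, row$az)
    b <- c(row$bx, row$by, row$bz)
    snapped <- tryCatch(
      list(a = snap_to_skeleton(a, graph, snap_radius),
           b = snap_to_skeleton(b, graph, snap_radius)),
      cow_snap_error = function(e) NULL)
    if (is.null(snapped)) return(rec)
    p <- tryCatch(find_path(graph, snapped$a, snapped$b, method),
                  cow_nopath_error = function(e) NULL)
    if (is.null(p)) {
      rec$status <- "failed"
    } else {
      rec$status <- "found"
      rec$path <- p
      rec$length_mm <- p$length
    }
    rec
  })
  names(records) <- cow_segment_names()
  structure(list(records = records, method = method, spacing = graph$spacing),
            class = "cow_labels")
}

#' @export
print.cow_labels <- function(x, ...) {
  st <- vapply(x$records, `[[`, "", "status")
  cat(sprintf("<cow_labels> method %s: %d found, %d undetected, %d failed\n",
              x$method, sum(st == "found"), sum(st == "undetected"),
              sum(st == "failed")))
  for (r in x$records)
    cat(sprintf("  %-8s %-10s %s\n", r$name, r$status,
                if (r$status == "found") sprintf("%7.2f mm", r$length_mm) else ""))
  invisible(x)
}

#' @export
as.data.frame.cow_labels <- function(x, ...) {
  rows <- lapply(x$records, function(r) {
    if (r$status == "found") {
      v <- r$path$voxels
      data.frame(segment = r$name, status = r$status,
                 order = seq_len(nrow(v)),
                 x = v[, 1], y = v[, 2], z = v[, 3],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(segment = r$name, status = r$status, order = NA_integer_,
                 x = NA_integer_, y = NA_integer_, z = NA_integer_,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fixed color palette for the 14 segments
#'
#' @return Named character vector of hex colors keyed by canonical name.
#' @export
segment_palette <- function() {
  cols <- hcl.colors(14, "Dark 3")
  names(cols) <- cow_segment_names()
  cols
}

#' Export labeled centerlines
#'
#' CSV: one row per path voxel (`segment, status, order, x, y, z`); segments
#' without a path contribute a single status row with empty coordinates.
#' JSON: one record per segment with status, length and the voxel list.
#' HTML: a self-contained static 3D scatter (oblique projection rendered as
#' SVG) with one named trace per found segment, colored by
#' [segment_palette()].
#'
#' @param result A `cow_labels`.
#' @param path Output file path.
#' @param format `"csv"`, `"json"` or `"html"`; inferred from the file
#'   extension when omitted.
#' @return The path, invisibly.
#' @export
export_labeled_centerlines <- function(result, path,
                                       format = c("csv", "json", "html")) {
  if (!inherits(result, "cow_labels"))
    cow_input_error("result: expected a cow_labels")
  if (missing(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("csv", "json", "html")) ext else "csv"
  }
  format <- match.arg(format)
  switch(format,
    csv = {
      df <- as.data.frame(result)
      write.csv(df, path, row.names = FALSE, na = "")
    },
    json = {
      recs <- lapply(result$records, function(r) {
        out <- list(name = r$name, status = r$status)
        if (r$status == "found") {
          out$length_mm <- r$length_mm
          out$voxels <- unname(apply(r$path$voxels, 1, as.integer,
                                     simplify = FALSE))
        }
        out
      })
      jsonlite::write_json(list(method = result$method,
                                spacing = result$spacing,
                                segments = unname(recs)),
                           path, auto_unbox = TRUE, digits = NA)
    },
    html = .write_html_scatter(result, path))
  invisible(path)
}

# Minimal self-contained HTML: two oblique 2D projections of the 3D
# centerlines as SVG polylines, one trace per found segment.
.write_html_scatter <- function(result, path) {
  pal <- segment_palette()
  found <- Filter(function(r) r$status == "found", result$records)
  proj <- function(v) {
    # oblique projection: x' = x + 0.35 z, y' = y + 0.35 z
    cbind(v[, 1] + 0.35 * v[, 3], v[, 2] + 0.35 * v[, 3])
  }
  traces <- vapply(found, function(r) {
    p <- proj(r$path$voxels)
    pts <- paste(sprintf("%.1f,%.1f", p[, 1], 300 - p[, 2]), collapse = " ")
    sprintf(paste0('<polyline class="trace" data-segment="%s" fill="none" ',
                   'stroke="%s" stroke-width="2" points="%s"><title>%s</title>',
                   '</polyline>'),
            r$name, pal[[r$name]], pts, r$name)
  }, character(1))
  legend <- vapply(result$records, function(r)
    sprintf('<li style="color:%s">%s: %s</li>', pal[[r$name]], r$name, r$status),
    character(1))
  html <- c("<!DOCTYPE html>",
            "<html><head><meta charset='utf-8'>",
            "<title>Labeled circle-of-Willis centerlines</title></head><body>",
            sprintf("<h1>Labeled centerlines (%s)</h1>", result$method),
            '<svg viewBox="-20 -20 400 360" width="800" height="720">',
            traces,
            "</svg>",
            "<ul>", legend, "</ul>",
            "</body></html>")
  writeLines(html, path)
  invisible(path)
}

#' Re-read an exported centerline CSV
#'
#' @param path CSV written by [export_labeled_centerlines()].
#' @return Data frame with columns `segment, status, order, x, y, z`.
#' @export
import_labeled_centerlines <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("segment", "status", "order", "x", "y", "z")
  if (!all(need %in% names(df)))
    cow_parse_error(sprintf("%s: expected columns %s", path,
                            paste(need, collapse = ", ")))
  df
}
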