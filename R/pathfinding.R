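# The three path-finding methods compared by the pipeline, plus an exhaustive
# brute-force oracle used in tests. All operate on a cow_skeleton_graph and
# are deterministic: depth-first search visits neighbors in the fixed
# lexicographic (dz, dy, dx) offset order baked into the adjacency lists, and
# Dijkstra / A* break priority ties by the lexicographically smallest node
# coordinate.

.resolve_node <- function(graph, coord, what) {
  coord <- as.integer(coord)
  if (length(coord) != 3L || anyNA(coord))
    cow_input_error(sprintf("%s: expected 3 integer voxel indices", what))
  id <- which(graph$coords[, 1] == coord[1] &
              graph$coords[, 2] == coord[2] &
              graph$coords[, 3] == coord[3])
  if (!length(id))
    cow_input_error(sprintf("%s (%s) is not a graph node", what,
                            paste(coord, collapse = ", ")))
  id[1]
}

.path_from_ids <- function(graph, ids, method) {
  vox <- graph$coords[ids, , drop = FALSE]
  len <- 0
  if (length(ids) > 1) {
    d <- (vox[-1, , drop = FALSE] - vox[-nrow(vox), , drop = FALSE]) *
      rep(graph$spacing, each = nrow(vox) - 1)
    len <- sum(sqrt(rowSums(d^2)))
  }
  structure(list(voxels = vox, length = len, method = method),
            class = "cow_path")
}

#' @export
print.cow_path <- function(x, ...) {
  cat(sprintf("<cow_path> %s, %d voxels, %.3f mm\n",
              x$method, nrow(x$voxels), x$length))
  invisible(x)
}

#' Validate a path against its graph
#'
#' Checks the structural invariants of a returned path: consecutive voxels
#' are 26-adjacent graph nodes, no voxel repeats, the stored length equals
#' the sum of Euclidean inter-voxel distances (to 1e-9), and the path
#' terminates at the queried endpoints.
#'
#' @param path A `cow_path`.
#' @param graph The `cow_skeleton_graph` the path was found on.
#' @param start,goal Optional endpoint coordinates to check against.
#' @return `TRUE`, invisibly; raises an input error otherwise.
#' @export
validate_path <- function(path, graph, start = NULL, goal = NULL) {
  if (!inherits(path, "cow_path")) cow_input_error("path: expected a cow_path")
  vox <- path$voxels
  n <- nrow(vox)
  if (n < 1L) cow_input_error("path: empty")
  ids <- apply(vox, 1, function(p) .resolve_node(graph, p, "path voxel"))
  if (anyDuplicated(ids)) cow_input_error("path: repeated voxel")
  if (n > 1) {
    step <- abs(vox[-1, , drop = FALSE] - vox[-n, , drop = FALSE])
    if (any(step > 1L) || any(rowSums(step) == 0L))
      cow_input_error("path: consecutive voxels must be distinct and 26-adjacent")
  }
  ref <- .path_from_ids(graph, ids, path$method)
  if (abs(ref$length - path$length) > 1e-9)
    cow_input_error("path: stored length disagrees with voxel sequence")
  if (!is.null(start) && any(vox[1, ] != as.integer(start)))
    cow_input_error("path: does not start at the queried start point")
  if (!is.null(goal) && any(vox[n, ] != as.integer(goal)))
    cow_input_error("path: does not end at the queried goal point")
  invisible(TRUE)
}

#' Depth-first-search path finding (Method 1)
#'
#' Maze-solver traversal: from the start voxel, repeatedly push the first
#' unvisited neighbor (in the fixed lexicographic offset order) onto a stack;
#' when no unvisited neighbor exists, backtrack by popping. The stack
#' contents on reaching the goal are returned as the path. The result is a
#' valid simple path but is not guaranteed shortest: on looped anatomy such
#' as the communicating arteries it can detour the long way around a cycle.
#'
#' @param graph A `cow_skeleton_graph`.
#' @param start,goal Voxel coordinates of graph nodes.
#' @return A `cow_path` with `method = "dfs"`.
#' @export
dfs_path <- function(graph, start, goal) {
  s <- .resolve_node(graph, start, "start")
  g <- .resolve_node(graph, goal, "goal")
  if (s == g) return(.path_from_ids(graph, s, "dfs"))
  n <- nrow(graph$coords)
  visited <- logical(n)
  visited[s] <- TRUE
  stack <- integer(n)
  ptr <- integer(n)                       # per-depth neighbor cursor
  stack[1] <- s
  depth <- 1L
  while (depth > 0L) {
    u <- stack[depth]
    nbrs <- graph$adj[[u]]
    k <- ptr[depth] + 1L
    nxt <- 0L
    while (k <= length(nbrs)) {
      if (!visited[nbrs[k]]) { nxt <- nbrs[k]; break }
      k <- k + 1L
    }
    ptr[depth] <- k
    if (nxt == 0L) {
      depth <- depth - 1L                 # backtrack
    } else {
      visited[nxt] <- TRUE
      depth <- depth + 1L
      stack[depth] <- nxt
      ptr[depth] <- 0L
      if (nxt == g) break
    }
  }
  if (depth == 0L)
    cow_nopath_error(sprintf("no path from (%s) to (%s)",
                             paste(as.integer(start), collapse = ", "),
                             paste(as.integer(goal), collapse = ", ")))
  .path_from_ids(graph, stack[seq_len(depth)], "dfs")
}

#' Dijkstra shortest-path finding (Method 2)
#'
#' Returns the path of globally minimal total edge weight (mm) between two
#' skeleton voxels. Priority ties are broken by the lexicographically
#' smallest node coordinate, making the returned path deterministic.
#'
#' @inheritParams dfs_path
#' @return A `cow_path` with `method = "dijkstra"`.
#' @export
dijkstra_path <- function(graph, start, goal) {
  s <- .resolve_node(graph, start, "start")
  g <- .resolve_node(graph, goal, "goal")
  if (s == g) return(.path_from_ids(graph, s, "dijkstra"))
  n <- nrow(graph$coords)
  dist <- rep(Inf, n); dist[s] <- 0
  prev <- integer(n)
  done <- logical(n)
  repeat {
    d2 <- dist; d2[done] <- Inf
    m <- min(d2)
    if (!is.finite(m))
      cow_nopath_error(sprintf("no path from (%s) to (%s)",
                               paste(as.integer(start), collapse = ", "),
                               paste(as.integer(goal), collapse = ", ")))
    cand <- which(d2 <= m + 1e-12)
    u <- cand[which.min(graph$lexrank[cand])]
    if (u == g) break
    done[u] <- TRUE
    js <- graph$adj[[u]]; ws <- graph$adjw[[u]]
    nd <- dist[u] + ws
    upd <- nd < dist[js] - 1e-12
    if (any(upd)) {
      dist[js[upd]] <- nd[upd]
      prev[js[upd]] <- u
    }
  }
  ids <- g
  while (ids[1] != s) ids <- c(prev[ids[1]], ids)
  .path_from_ids(graph, ids, "dijkstra")
}

#' A* shortest-path finding (Method 3)
#'
#' Best-first search expanding nodes by minimal `f = g + h`, where `g` is the
#' accumulated path cost and the heuristic `h` is the Euclidean distance (mm)
#' from the node to the destination. Because edge weights are themselves
#' Euclidean inter-voxel distances, `h` never overestimates the remaining
#' cost (admissible and consistent), so the returned path cost equals the
#' Dijkstra cost.
#'
#' @inheritParams dfs_path
#' @return A `cow_path` with `method = "astar"`.
#' @export
astar_path <- function(graph, start, goal) {
  s <- .resolve_node(graph, start, "start")
  g <- .resolve_node(graph, goal, "goal")
  if (s == g) return(.path_from_ids(graph, s, "astar"))
  n <- nrow(graph$coords)
  gc <- graph$coords[g, ]
  dmm <- sweep(graph$coords, 2, gc) * rep(graph$spacing, each = n)
  h <- sqrt(rowSums(dmm^2))
  gs <- rep(Inf, n); gs[s] <- 0
  prev <- integer(n)
  closed <- logical(n)
  repeat {
    f <- gs + h
    f[closed] <- Inf
    m <- min(f)
    if (!is.finite(m))
      cow_nopath_error(sprintf("no path from (%s) to (%s)",
                               paste(as.integer(start), collapse = ", "),
                               paste(as.integer(goal), collapse = ", ")))
    cand <- which(f <= m + 1e-12)
    u <- cand[which.min(graph$lexrank[cand])]
    if (u == g) break
    closed[u] <- TRUE
    js <- graph$adj[[u]]; ws <- graph$adjw[[u]]
    open <- !closed[js]                  # consistent heuristic: closed is final
    js <- js[open]; ws <- ws[open]
    nd <- gs[u] + ws
    upd <- nd < gs[js] - 1e-12
    if (any(upd)) {
      gs[js[upd]] <- nd[upd]
      prev[js[upd]] <- u
    }
  }
  ids <- g
  while (ids[1] != s) ids <- c(prev[ids[1]], ids)
  .path_from_ids(graph, ids, "astar")
}

#' Exhaustive shortest-path oracle
#'
#' Enumerates every simple path between two nodes and returns the cheapest;
#' exponential, intended only as an independent reference in tests. Refuses
#' graphs whose enumeration exceeds `max_expansions` partial paths.
#'
#' @inheritParams dfs_path
#' @param max_expansions Guard on the number of partial simple paths explored
#'   (default 1e6).
#' @return A `cow_path` with `method = "brute"`.
#' @export
brute_force_shortest <- function(graph, start, goal, max_expansions = 1e6) {
  s <- .resolve_node(graph, start, "start")
  g <- .resolve_node(graph, goal, "goal")
  if (s == g) return(.path_from_ids(graph, s, "brute"))
  n <- nrow(graph$coords)
  env <- new.env(parent = emptyenv())
  env$best <- Inf
  env$best_ids <- NULL
  env$count <- 0
  visited <- logical(n)
  recurse <- function(u, ids, cost) {
    env$count <- env$count + 1
    if (env$count > max_expansions)
      cow_oracle_error(sprintf("enumeration guard exceeded (%g partial paths)",
                               max_expansions))
    if (u == g) {
      if (cost < env$best - 1e-12) {
        env$best <- cost
        env$best_ids <- ids
      }
      return(invisible(NULL))
    }
    visited[u] <<- TRUE
    nbrs <- graph$adj[[u]]; ws <- graph$adjw[[u]]
    for (k in seq_along(nbrs)) {
      j <- nbrs[k]
      if (!visited[j]) recurse(j, c(ids, j), cost + ws[k])
    }
    visited[u] <<- FALSE
    invisible(NULL)
  }
  recurse(s, s, 0)
  if (is.null(env$best_ids))
    cow_nopath_error(sprintf("no path from (%s) to (%s)",
                             paste(as.integer(start), collapse = ", "),
                             paste(as.integer(goal), collapse = ", ")))
  .path_from_ids(graph, env$best_ids, "brute")
}

#' Run one path-finding method by name
#'
#' @inheritParams dfs_path
#' @param method One of `"dfs"`, `"dijkstra"`, `"astar"`.
#' @return A `cow_path`.
#' @export
find_path <- function(graph, start, goal, method = c("dijkstra", "astar", "dfs")) {
  method <- match.arg(method)
  switch(method,
         dfs = dfs_path(graph, start, goal),
         dijkstra = dijkstra_path(graph, start, goal),
         astar = astar_path(graph, start, goal))
}
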