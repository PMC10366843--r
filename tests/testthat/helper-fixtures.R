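# Shared fixtures and independent oracles. Expensive phantom pipelines are
# built once per test run and cached here.

.fixtures <- new.env(parent = emptyenv())

# Full pipeline on a CoW phantom: segment -> skeletonize -> graph, cached by
# (variant, seed).
phantom_fixture <- function(variant = "complete", seed = 1L) {
  key <- paste(variant, seed, sep = "/")
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  ph <- make_cow_phantom(seed = seed, variant = variant)
  mask <- segment_vessels(ph$volume, ph$seeds)
  skel <- skeletonize_3d(mask)
  graph <- skeleton_to_graph(skel)
  fx <- list(ph = ph, mask = mask, skel = skel, graph = graph)
  .fixtures[[key]] <- fx
  fx
}

# Chord-free 16-node octagonal ring (sides of three) in the z = 0 plane.
# From start (2,0,0), the fixed (dz, dy, dx) neighbor order makes DFS take
# the +x neighbor first, i.e. the 12-edge arc to goal (0,4,0); the short arc
# has 4 edges (two straight, two diagonal).
ring_graph <- function(spacing = 0.6) {
  ring <- rbind(c(2, 0), c(3, 0), c(4, 0), c(5, 1), c(6, 2), c(6, 3),
                c(6, 4), c(5, 5), c(4, 6), c(3, 6), c(2, 6), c(1, 5),
                c(0, 4), c(0, 3), c(0, 2), c(1, 1))
  a <- array(FALSE, c(7, 7, 1))
  for (i in seq_len(nrow(ring))) a[ring[i, 1] + 1, ring[i, 2] + 1, 1] <- TRUE
  skeleton_to_graph(cow_mask(a, rep(spacing, 3)))
}

# Random connected voxel-cluster graph with <= n_max nodes in a 4^3 box and
# random isotropic spacing (so edge weights vary across {s, s*sqrt(2),
# s*sqrt(3)} with random s).
random_voxel_graph <- function(seed, n_max = 12L, box = 4L) {
  set.seed(seed)
  repeat {
    n <- sample(4:n_max, 1)
    lin <- sample(box^3, n)
    a <- array(FALSE, rep(box, 3))
    a[lin] <- TRUE
    m <- cow_mask(a, rep(runif(1, 0.3, 1.2), 3))
    if (mask_components(m) == 1L) return(skeleton_to_graph(m))
  }
}

# Independent flood-fill oracle for region growing in the constant-mean
# regime: the set of voxels reachable from the seed through voxels with
# |I - ref| <= tol, via plain R breadth-first search.
flood_oracle <- function(vol, seed, ref, tol, connectivity = 6L) {
  dims <- dim(vol$data)
  offs <- if (connectivity == 6L) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
          c(0, 0, 1), c(0, 0, -1))
  } else {
    as.matrix(expand.grid(-1:1, -1:1, -1:1))[-14, ]
  }
  inside <- function(p) all(p >= 0) && all(p <= dims - 1)
  keep <- abs(vol$data - ref) <= tol
  out <- array(FALSE, dims)
  q <- list(as.integer(seed))
  out[seed[1] + 1, seed[2] + 1, seed[3] + 1] <- TRUE
  while (length(q)) {
    p <- q[[1]]; q <- q[-1]
    for (k in seq_len(nrow(offs))) {
      v <- p + offs[k, ]
      if (!inside(v)) next
      i <- v[1] + 1; j <- v[2] + 1; l <- v[3] + 1
      if (!out[i, j, l] && keep[i, j, l]) {
        out[i, j, l] <- TRUE
        q[[length(q) + 1]] <- as.integer(v)
      }
    }
  }
  out
}

# Independent two-sided Fisher oracle: explicit binomial-coefficient
# enumeration over the support, minimum-likelihood convention.
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || b + d == 0) return(1)
  ks <- max(0, c1 - r2):min(r1, c1)
  pr <- exp(lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(r1 + r2, c1))
  min(sum(pr[pr <= pr[ks == a] * (1 + 1e-7)]), 1)
}

# Mean distance (voxels) from each path voxel to the nearest ground-truth
# centerline voxel.
mean_centerline_error <- function(path_voxels, truth_voxels) {
  mean(apply(path_voxels, 1, function(v)
    sqrt(min(colSums((t(truth_voxels) - v)^2)))))
}

# Straight tube volume (no noise) used by several segmentation tests.
straight_tube_volume <- function(dims = c(24, 9, 9), radius = 2,
                                 fg = 300, bg = 50, axis_yz = c(4, 4)) {
  a <- array(bg, dims)
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2]))
    for (z in seq_len(dims[3]))
      if ((y - 1 - axis_yz[1])^2 + (z - 1 - axis_yz[2])^2 <= radius^2)
        a[x, y, z] <- fg
  cow_volume(a, c(1, 1, 1))
}

tube_truth_mask <- function(vol, fg = 300) vol$data == fg
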