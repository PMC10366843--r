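# Vessel segmentation: Otsu thresholding plus 3D seeded region growing from
# user seeds, with the per-seed masks combined by set union.

#' Seed point for region growing
#'
#' @param coordinate Integer length-3 voxel index (0-based x, y, z).
#' @param label Free-text vessel name, e.g. `"R-ICA"`.
#' @return A list of class `cow_seed`.
#' @export
seed_point <- function(coordinate, label = "") {
  coordinate <- as.integer(coordinate)
  if (length(coordinate) != 3L || anyNA(coordinate))
    cow_input_error("coordinate: expected 3 integer voxel indices")
  structure(list(coordinate = coordinate, label = as.character(label)),
            class = "cow_seed")
}

.check_seed_inside <- function(coordinate, dims) {
  if (any(coordinate < 0L) || any(coordinate > dims - 1L))
    cow_input_error(sprintf("seed (%s) lies outside the %s grid",
                            paste(coordinate, collapse = ", "),
                            paste(dims, collapse = "x")))
}

#' Otsu intensity threshold
#'
#' Returns the threshold maximizing the between-class variance of the
#' intensity histogram: vessels in TOF-MRA are bright on a dark background,
#' so the high class is vascular. Deterministic for fixed input.
#'
#' @param vol A [cow_volume()] or numeric array.
#' @param n_bins Number of histogram bins (default 256).
#' @return The threshold intensity; voxels with intensity strictly above it
#'   form the bright class.
#' @export
otsu_threshold <- function(vol, n_bins = 256L) {
  x <- if (inherits(vol, "cow_volume")) vol$data else vol
  rng <- range(x)
  if (rng[1] == rng[2])
    cow_degenerate_error("constant volume: Otsu threshold is undefined")
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) cow_input_error("n_bins: need at least 2 bins")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- findInterval(x, edges, rightmost.closed = TRUE)
  counts <- as.numeric(tabulate(bin, nbins = n_bins))
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  w <- cumsum(counts)
  m <- cumsum(counts * mids)
  n <- w[n_bins]
  mt <- m[n_bins]
  # between-class variance for each cut after bin k, k = 1 .. n_bins-1
  k <- seq_len(n_bins - 1L)
  w0 <- w[k]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  sb <- rep(-Inf, n_bins - 1L)
  sb[valid] <- (n * m[k][valid] - mt * w0[valid])^2 / (w0[valid] * w1[valid])
  best <- which.max(sb)
  edges[best + 1L]
}

#' 3D seeded region growing
#'
#' Floods outward from a seed voxel through neighbors whose intensity stays
#' within `max_deviation` of the running mean of the accepted region; the
#' mean is updated after every acceptance and candidates are visited in a
#' fixed FIFO order, so the result is deterministic. The returned mask is
#' connected under the chosen connectivity and contains the seed.
#'
#' @param vol A [cow_volume()].
#' @param seed A [seed_point()] or integer length-3 voxel coordinate.
#' @param max_deviation Intensity tolerance, `>= 0`. Defaults to
#'   [default_grow_tolerance()].
#' @param connectivity 6 (face-adjacent, default; limits leakage across thin
#'   gaps) or 26.
#' @return A [cow_mask()].
#' @export
region_grow_3d <- function(vol, seed, max_deviation = NULL, connectivity = 6L) {
  if (!inherits(vol, "cow_volume")) cow_input_error("vol: expected a cow_volume")
  coord <- if (inherits(seed, "cow_seed")) seed$coordinate else as.integer(seed)
  if (length(coord) != 3L || anyNA(coord))
    cow_input_error("seed: expected 3 integer voxel indices")
  dims <- dim(vol$data)
  .check_seed_inside(coord, dims)
  if (!connectivity %in% c(6L, 26L))
    cow_input_error("connectivity: must be 6 or 26")
  if (is.null(max_deviation)) max_deviation <- default_grow_tolerance(vol, coord)
  if (!is.finite(max_deviation) || max_deviation < 0)
    cow_input_error("max_deviation: must be >= 0")
  res <- cpp_region_grow(as.numeric(vol$data), as.integer(dims), coord,
                         as.numeric(max_deviation), as.integer(connectivity))
  cow_mask(array(res, dim = dims), vol$spacing)
}

#' Default region-growing tolerance
#'
#' Links the thresholding and growing stages: the tolerance is the seed
#' intensity minus the Otsu threshold, floored at 10% of the seed intensity,
#' so a seed well inside the bright vascular class grows down to (but not
#' across) the global background/vessel separation.
#'
#' @param vol A [cow_volume()].
#' @param seed Seed coordinate or [seed_point()].
#' @param threshold Otsu threshold; computed from `vol` if missing.
#' @return Intensity tolerance.
#' @export
default_grow_tolerance <- function(vol, seed, threshold = NULL) {
  coord <- if (inherits(seed, "cow_seed")) seed$coordinate else as.integer(seed)
  .check_seed_inside(coord, dim(vol$data))
  if (is.null(threshold)) threshold <- otsu_threshold(vol)
  seed_i <- vol$data[coord[1] + 1L, coord[2] + 1L, coord[3] + 1L]
  max(seed_i - threshold, 0.1 * abs(seed_i))
}

#' Union of binary masks
#'
#' Voxelwise logical OR of masks on the same grid; used to combine the three
#' per-seed segmentations into the final vessel mask.
#'
#' @param masks List of [cow_mask()] objects sharing shape and spacing.
#' @return A [cow_mask()].
#' @export
union_masks <- function(masks) {
  if (inherits(masks, "cow_mask")) masks <- list(masks)
  if (!length(masks)) cow_input_error("masks: need at least one mask")
  d0 <- dim(masks[[1]]$data); s0 <- masks[[1]]$spacing
  for (m in masks) {
    if (!inherits(m, "cow_mask")) cow_input_error("masks: expected cow_mask objects")
    if (!identical(dim(m$data), d0))
      cow_input_error("masks: grid shapes differ")
    if (max(abs(m$spacing - s0)) > 1e-9)
      cow_input_error("masks: spacings differ")
  }
  out <- Reduce(`|`, lapply(masks, `[[`, "data"))
  cow_mask(array(out, dim = d0), s0)
}

#' Segment vessels from seeds
#'
#' Convenience wrapper for the full segmentation stage: Otsu threshold, one
#' region growing per seed (tolerance defaulting per seed via
#' [default_grow_tolerance()]), then the union of the per-seed masks.
#'
#' @param vol A [cow_volume()].
#' @param seeds List of [seed_point()]s (typically three: R-ICA, L-ICA, BA).
#' @param max_deviation Optional shared tolerance overriding the default.
#' @param connectivity Growing connectivity, 6 or 26.
#' @return A [cow_mask()].
#' @export
segment_vessels <- function(vol, seeds, max_deviation = NULL, connectivity = 6L) {
  if (inherits(seeds, "cow_seed")) seeds <- list(seeds)
  if (!length(seeds)) cow_input_error("seeds: need at least one seed")
  thr <- otsu_threshold(vol)
  masks <- lapply(seeds, function(s) {
    tol <- if (is.null(max_deviation)) default_grow_tolerance(vol, s, thr)
           else max_deviation
    region_grow_3d(vol, s, tol, connectivity)
  })
  union_masks(masks)
}
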