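# Synthetic TOF-MRA-like vascular phantoms: bright tubes with circle-of-
# Willis topology on a dark background, with ground-truth centerlines, so
# segmentation, skeletonization, path finding, labeling and evaluation are
# all testable without imaging data. Geometry is schematic — the path-finding
# algorithms consume only the skeleton topology.

#' Phantom specification
#'
#' @param shape Integer length-3 grid size in voxels.
#' @param spacing Isotropic voxel size in mm (default 0.6).
#' @param vessels List of vessels, each a list with `name`, `points` (k x 3
#'   matrix of 0-based voxel-space control points of a piecewise-linear
#'   curve), `radius` (voxels, >= 1) and `intensity`.
#' @param background Background intensity (default 50).
#' @param noise_sd Additive Gaussian noise standard deviation (default 10).
#'   Every vessel intensity must exceed `background + 5 * noise_sd` so that
#'   Otsu thresholding separates the classes.
#' @param bridges List of spurious bridges, each a list with `from`, `to`
#'   (length-3 points) and `radius`; rasterized like vessels at the maximum
#'   vessel intensity but excluded from the ground truth.
#' @param seed Integer RNG seed; identical seeds give identical volumes.
#' @return A list of class `cow_phantom_spec`.
#' @export
phantom_spec <- function(shape, vessels, spacing = 0.6, background = 50,
                         noise_sd = 10, bridges = list(), seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 4L))
    cow_input_error("shape: expected 3 axis lengths >= 4")
  if (!length(vessels)) cow_input_error("vessels: need at least one vessel")
  for (v in vessels) {
    if (is.null(v$name) || is.null(v$points) || is.null(v$radius) ||
        is.null(v$intensity))
      cow_input_error("vessels: each needs name, points, radius, intensity")
    if (v$radius < 1) cow_input_error(
      sprintf("vessels: radius of %s must be >= 1 voxel", v$name))
    if (v$intensity <= background + 5 * noise_sd) cow_input_error(
      sprintf("vessels: intensity of %s must exceed background + 5 * noise_sd",
              v$name))
    p <- v$points
    if (any(p < v$radius) ||
        any(sweep(p, 2, shape - 1 - v$radius) > 0))
      cow_input_error(sprintf(
        "vessels: control points of %s must lie inside the grid with margin >= radius",
        v$name))
  }
  for (b in bridges)
    if (is.null(b$from) || is.null(b$to) || is.null(b$radius) || b$radius < 1)
      cow_input_error("bridges: each needs from, to and radius >= 1")
  structure(list(shape = shape, spacing = rep(as.numeric(spacing), 3),
                 vessels = vessels, background = background,
                 noise_sd = noise_sd, bridges = bridges,
                 seed = as.integer(seed)),
            class = "cow_phantom_spec")
}

# Rasterize the set of voxels within `radius` of the segment p-q into `arr`.
.rasterize_segment <- function(arr, p, q, radius) {
  dims <- dim(arr)
  lo <- pmax(floor(pmin(p, q) - radius - 1), 0)
  hi <- pmin(ceiling(pmax(p, q) + radius + 1), dims - 1)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  g <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  d <- q - p
  L2 <- sum(d^2)
  if (L2 == 0) {
    t <- rep(0, nrow(g))
  } else {
    t <- pmin(pmax((sweep(g, 2, p) %*% d) / L2, 0), 1)
  }
  proj <- sweep(t %*% t(d), 2, p, "+")     # p + t*d per row
  dist2 <- rowSums((g - proj)^2)
  hit <- g[dist2 <= radius^2, , drop = FALSE]
  if (nrow(hit))
    arr[hit[, 1] + 1L + dims[1] * (hit[, 2] + dims[2] * hit[, 3])] <- TRUE
  arr
}

.rasterize_polyline <- function(dims, points, radius) {
  arr <- array(FALSE, dim = dims)
  for (i in seq_len(nrow(points) - 1))
    arr <- .rasterize_segment(arr, points[i, ], points[i + 1, ], radius)
  if (nrow(points) == 1)
    arr <- .rasterize_segment(arr, points[1, ], points[1, ], radius)
  arr
}

# Densely sample a polyline (arc-length step 0.25 voxel), round to voxels,
# drop consecutive duplicates: the ground-truth centerline.
.centerline_voxels <- function(points) {
  pts <- list()
  for (i in seq_len(nrow(points) - 1)) {
    p <- points[i, ]; q <- points[i + 1, ]
    L <- sqrt(sum((q - p)^2))
    n <- max(2L, ceiling(L / 0.25) + 1L)
    t <- seq(0, 1, length.out = n)
    pts[[i]] <- round(outer(1 - t, p) + outer(t, q))
  }
  m <- do.call(rbind, pts)
  keep <- c(TRUE, rowSums(abs(m[-1, , drop = FALSE] -
                              m[-nrow(m), , drop = FALSE])) > 0)
  m <- m[keep, , drop = FALSE]
  storage.mode(m) <- "integer"
  colnames(m) <- c("x", "y", "z")
  m
}

.polyline_length_mm <- function(points, spacing) {
  d <- (points[-1, , drop = FALSE] - points[-nrow(points), , drop = FALSE]) *
    rep(spacing, each = nrow(points) - 1)
  sum(sqrt(rowSums(d^2)))
}

#' Rasterize a phantom specification into a volume
#'
#' Each vessel becomes the set of voxels within its radius of the
#' piecewise-linear curve through its control points; vessel voxels take the
#' vessel intensity (overlaps take the maximum), all others the background;
#' Gaussian noise with the spec's seed is added on top. Ground truth is the
#' dense sampling of each curve rounded to voxels.
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume` (a [cow_volume()]), `centerlines` (named list
#'   of ground-truth voxel matrices, vessels only), `masks` (named list of
#'   per-structure logical arrays, bridges included) and `lengths_mm` (named
#'   vector of ground-truth curve lengths).
#' @export
make_tube_volume <- function(spec) {
  if (!inherits(spec, "cow_phantom_spec"))
    cow_input_error("spec: expected a cow_phantom_spec")
  dims <- spec$shape
  base <- array(spec$background, dim = dims)
  masks <- list()
  centerlines <- list()
  lengths <- numeric(0)
  for (v in spec$vessels) {
    m <- .rasterize_polyline(dims, v$points, v$radius)
    base[m] <- pmax(base[m], v$intensity)
    masks[[v$name]] <- m
    centerlines[[v$name]] <- .centerline_voxels(v$points)
    lengths[[v$name]] <- .polyline_length_mm(v$points, spec$spacing)
  }
  if (length(spec$bridges)) {
    bint <- max(vapply(spec$vessels, `[[`, 0, "intensity"))
    for (i in seq_along(spec$bridges)) {
      b <- spec$bridges[[i]]
      m <- .rasterize_polyline(dims, rbind(b$from, b$to), b$radius)
      base[m] <- pmax(base[m], bint)
      masks[[sprintf("bridge-%d", i)]] <- m
    }
  }
  if (spec$noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(spec$seed)
    base <- base + array(rnorm(prod(dims), 0, spec$noise_sd), dim = dims)
  }
  list(volume = cow_volume(base, spec$spacing), centerlines = centerlines,
       masks = masks, lengths_mm = lengths)
}

# Control-point geometry of the schematic circle of Willis on a reference
# 128-voxel grid; x is lateral (right side x < 64), y grows posteriorly,
# z grows superiorly. Coordinates are scaled by grid_size / 128.
.cow_geometry <- function(variant) {
  P <- function(...) matrix(c(...), ncol = 3, byrow = TRUE)
  ica_r <- P(40, 70, 24,  43, 66, 32,  39, 69, 40,  44, 65, 48,
             41, 67, 56,  42, 63, 64,  44, 62, 72)
  if (variant == "bridged")
    ica_r <- P(40, 70, 24,  40, 68, 28,  52, 74, 36,  40, 68, 44,
               41, 66, 54,  42, 63, 64,  44, 62, 72)
  mirror <- function(p) { p[, 1] <- 128 - p[, 1]; p }
  g <- list(
    `R-ICA`   = ica_r,
    `L-ICA`   = mirror(P(40, 70, 24,  43, 66, 32,  39, 69, 40,  44, 65, 48,
                         41, 67, 56,  42, 63, 64,  44, 62, 72)),
    `R-A1`    = P(44, 62, 72,  52, 52, 74,  58, 46, 76),
    `L-A1`    = P(84, 62, 72,  76, 52, 74,  70, 46, 76),
    AComm     = P(58, 46, 76,  64, 45, 76,  70, 46, 76),
    `R-M1`    = P(44, 62, 72,  34, 60, 73,  22, 56, 74),
    `L-M1`    = P(84, 62, 72,  94, 60, 73,  106, 56, 74),
    BA        = P(64, 96, 28,  63, 95, 40,  65, 94, 52,  64, 93, 62),
    `R-P1`    = P(64, 93, 62,  57, 91, 65,  50, 88, 68),
    `L-P1`    = P(64, 93, 62,  71, 91, 65,  78, 88, 68),
    `R-P2`    = P(50, 88, 68,  42, 96, 70,  34, 104, 72),
    `L-P2`    = P(78, 88, 68,  86, 96, 70,  94, 104, 72),
    `R-PComm` = P(44, 62, 72,  46, 74, 70,  50, 88, 68),
    `L-PComm` = P(84, 62, 72,  82, 74, 70,  78, 88, 68))
  extras <- list()
  if (variant == "looped")
    extras$`A2-loop` <- P(58, 46, 76,  60, 42, 84,  64, 40, 88,
                          68, 42, 84,  70, 46, 76)
  bridges <- list()
  if (variant == "bridged")
    bridges <- list(list(from = c(40, 68, 28), to = c(40, 68, 44), radius = 1.5))
  if (variant == "missing_pcomms")
    g[c("R-PComm", "L-PComm")] <- NULL
  list(segments = g, extras = extras, bridges = bridges)
}

#' Generate a circle-of-Willis phantom
#'
#' Builds a volume containing tubes for the 14 canonical segments wired with
#' circle-of-Willis topology: each internal carotid bifurcates into A1 and
#' M1; the basilar artery bifurcates into the two P1 segments; the anterior
#' communicating artery closes the anterior loop between the A1 termini and
#' the posterior communicating arteries close the loops between the carotid
#' tops and the P1/P2 junctions. Endpoint specifications are placed on the
#' ground-truth centerline termini.
#'
#' Variants: `complete` — all 14 segments; `missing_pcomms` — both PComms
#' absent, with sentinel endpoint lines, as in hypoplastic anatomy;
#' `looped` — adds an A2-A2 arc over the AComm so the depth-first search can
#' detour the long way around a cycle; `bridged` — makes the right ICA
#' strongly tortuous and adds a short spurious bridge between its bends, so
#' the shortest path is anatomically wrong while the long way around the
#' bend is the true course.
#'
#' @param seed Integer RNG seed for the noise.
#' @param variant `"complete"`, `"missing_pcomms"`, `"looped"` or
#'   `"bridged"`.
#' @param grid_size Cubic grid edge length in voxels (default 128).
#' @param spacing Isotropic voxel size in mm (default 0.6).
#' @param vessel_intensity,background,noise_sd Intensity model (defaults
#'   300 / 50 / 10, i.e. bright arteries on dark background with moderate
#'   noise).
#' @param radius Tube radius in voxels (default 2).
#' @return List with `volume`, `endpoints` (a [cow_endpoints()] table),
#'   `truth` (`centerlines`, `masks`, `lengths_mm`), `seeds` (three
#'   [seed_point()]s at the R-ICA, L-ICA and BA inflows), `spec`, `variant`
#'   and `seed`.
#' @export
make_cow_phantom <- function(seed = 1L,
                             variant = c("complete", "missing_pcomms",
                                         "looped", "bridged"),
                             grid_size = 128L, spacing = 0.6,
                             vessel_intensity = 300, background = 50,
                             noise_sd = 10, radius = 2) {
  variant <- match.arg(variant)
  sc <- grid_size / 128
  geo <- .cow_geometry(variant)
  mk <- function(nm, pts) list(name = nm, points = pts * sc, radius = radius,
                               intensity = vessel_intensity)
  vessels <- c(
    lapply(names(geo$segments), function(nm) mk(nm, geo$segments[[nm]])),
    lapply(names(geo$extras), function(nm) mk(nm, geo$extras[[nm]])))
  bridges <- lapply(geo$bridges, function(b)
    list(from = b$from * sc, to = b$to * sc, radius = b$radius))
  spec <- phantom_spec(shape = rep(as.integer(grid_size), 3),
                       vessels = vessels, spacing = spacing,
                       background = background, noise_sd = noise_sd,
                       bridges = bridges, seed = seed)
  built <- make_tube_volume(spec)
  nm14 <- cow_segment_names()
  a <- b <- matrix(0L, nrow = 14, ncol = 3)
  for (i in seq_along(nm14)) {
    nm <- nm14[i]
    if (!nm %in% names(geo$segments)) next       # sentinel row
    pts <- round(geo$segments[[nm]] * sc)
    a[i, ] <- as.integer(pts[1, ])
    b[i, ] <- as.integer(pts[nrow(pts), ])
  }
  endpoints <- cow_endpoints(nm14, a, b)
  first_vox <- function(nm) as.integer(round(geo$segments[[nm]][1, ] * sc))
  seeds <- list(seed_point(first_vox("R-ICA"), "R-ICA"),
                seed_point(first_vox("L-ICA"), "L-ICA"),
                seed_point(first_vox("BA"), "BA"))
  list(volume = built$volume, endpoints = endpoints,
       truth = list(centerlines = built$centerlines, masks = built$masks,
                    lengths_mm = built$lengths_mm),
       seeds = seeds, spec = spec, variant = variant, seed = as.integer(seed))
}

#' Write phantom outputs to a directory
#'
#' Writes the intensity volume and a ground-truth label volume as NIfTI, the
#' endpoint annotation text file, and a JSON manifest recording the
#' generation parameters, from which [phantom_from_manifest()] regenerates
#' the phantom bit-identically.
#'
#' @param phantom Result of [make_cow_phantom()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    cow_input_error(sprintf("cannot create directory %s", dir))
  dims <- dim(phantom$volume$data)
  lab <- array(0L, dim = dims)
  structure_names <- names(phantom$truth$masks)
  for (i in seq_along(structure_names))
    lab[phantom$truth$masks[[i]]] <- i
  paths <- c(volume = file.path(dir, "volume.nii.gz"),
             labels = file.path(dir, "labels.nii.gz"),
             endpoints = file.path(dir, "endpoints.txt"),
             manifest = file.path(dir, "manifest.json"))
  write_volume(phantom$volume, paths[["volume"]], datatype = "double")
  lab_num <- lab; storage.mode(lab_num) <- "double"
  write_volume(cow_volume(lab_num, phantom$volume$spacing),
               paths[["labels"]], datatype = "int16")
  write_endpoints(phantom$endpoints, paths[["endpoints"]])
  s <- phantom$spec
  jsonlite::write_json(
    list(seed = phantom$seed, variant = phantom$variant,
         grid_size = s$shape[1], spacing = s$spacing[1],
         vessel_intensity = max(vapply(s$vessels, `[[`, 0, "intensity")),
         background = s$background, noise_sd = s$noise_sd,
         radius = s$vessels[[1]]$radius,
         labels = as.list(setNames(seq_along(structure_names), structure_names))),
    paths[["manifest"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Regenerate a phantom from its manifest
#'
#' @param path Path to a `manifest.json` written by [write_phantom()].
#' @return The regenerated phantom, identical voxel-for-voxel to the one the
#'   manifest was written from.
#' @export
phantom_from_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  make_cow_phantom(seed = m$seed, variant = m$variant,
                   grid_size = m$grid_size, spacing = m$spacing,
                   vessel_intensity = m$vessel_intensity,
                   background = m$background, noise_sd = m$noise_sd,
                   radius = m$radius)
}
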