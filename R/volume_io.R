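# Volume containers and NIfTI / annotation-file input-output.
#
# Voxel coordinates are 0-based integer (x, y, z) indices in the NIfTI array
# layout; all modules share this convention.

#' Intensity volume container
#'
#' A 3D scalar grid with per-axis physical voxel spacing in millimetres.
#'
#' @param data 3D numeric array of intensities (all finite).
#' @param spacing Numeric length-3 vector of voxel sizes in mm, all strictly
#'   positive and finite.
#' @return An object of class `cow_volume`: a list with elements `data` and
#'   `spacing`.
#' @export
cow_volume <- function(data, spacing) {
  if (!is.array(data) || length(dim(data)) != 3L)
    cow_input_error("data: expected 3D volume")
  if (any(dim(data) < 1L))
    cow_input_error("data: every axis must have length >= 1")
  if (!all(is.finite(data)))
    cow_input_error("data: intensities must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    cow_input_error("spacing: expected 3 strictly positive finite values (mm)")
  structure(list(data = data, spacing = spacing), class = "cow_volume")
}

#' @export
print.cow_volume <- function(x, ...) {
  cat(sprintf("<cow_volume> %s voxels, spacing %s mm, intensity [%g, %g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, digits = 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Binary mask container
#'
#' A 3D logical grid on the same voxel lattice as the volume it was derived
#' from (segmentation result or skeleton).
#'
#' @param data 3D logical array.
#' @param spacing Numeric length-3 voxel size in mm.
#' @return An object of class `cow_mask`.
#' @export
cow_mask <- function(data, spacing) {
  if (!is.array(data) || length(dim(data)) != 3L)
    cow_input_error("data: expected 3D mask")
  if (!is.logical(data))
    storage.mode(data) <- "logical"
  if (anyNA(data))
    cow_input_error("data: mask must not contain NA")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    cow_input_error("spacing: expected 3 strictly positive finite values (mm)")
  structure(list(data = data, spacing = spacing), class = "cow_mask")
}

#' @export
print.cow_mask <- function(x, ...) {
  cat(sprintf("<cow_mask> %s voxels, %d foreground, spacing %s mm\n",
              paste(dim(x$data), collapse = "x"), sum(x$data),
              paste(format(x$spacing, digits = 4), collapse = "x")))
  invisible(x)
}

#' Read a 3D NIfTI volume
#'
#' Reads a NIfTI-1 file and returns the scalar grid together with the
#' per-axis voxel spacing taken from the header (`pixdim`).
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [cow_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    cow_input_error(sprintf("path: file not found: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    cow_input_error(sprintf("expected 3D volume, got %dD image in %s",
                            length(d), path))
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0))
    cow_input_error(sprintf("spacing: non-positive pixdim in %s", path))
  cow_volume(array(as.numeric(img), dim = d), sp[1:3])
}

#' Write a volume or mask as NIfTI
#'
#' @param vol A [cow_volume()] or [cow_mask()]. Masks are written as 0/1.
#' @param path Output file path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type; `"double"` (default) round-trips
#'   arbitrary numeric data losslessly, `"float"` halves file size, `"uint8"`
#'   suits masks.
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path, datatype = "double") {
  dat <- vol$data
  if (is.logical(dat)) {
    storage.mode(dat) <- "integer"
    if (identical(datatype, "double")) datatype <- "uint8"
  }
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, file = path, datatype = datatype)
  invisible(path)
}

#' Resample a volume to isotropic resolution
#'
#' Resamples each axis whose spacing differs from `target_spacing` with cubic
#' spline interpolation, preserving the physical extent of the grid: along a
#' resampled axis the output has `round((n - 1) * s_in / s_out) + 1` samples
#' at positions `k * s_out`, with edge handling by clamping. Axes already at
#' the target spacing are passed through unchanged.
#'
#' @param vol A [cow_volume()].
#' @param target_spacing Target isotropic voxel size in mm (default 0.6, the
#'   working resolution of the pipeline).
#' @return A [cow_volume()] with spacing `c(t, t, t)`.
#' @export
resample_isotropic <- function(vol, target_spacing = 0.6) {
  if (!inherits(vol, "cow_volume")) cow_input_error("vol: expected a cow_volume")
  t <- as.numeric(target_spacing)
  if (length(t) != 1L || !is.finite(t) || t <= 0)
    cow_input_error("target_spacing: expected one strictly positive value (mm)")
  if (any(t > 10 * vol$spacing))
    warning(sprintf(
      "target spacing %g mm is >10x coarser than an input axis spacing (%s mm)",
      t, paste(format(vol$spacing), collapse = ", ")))
  arr <- vol$data
  sp <- vol$spacing
  for (a in 1:3) {
    if (abs(sp[a] - t) <= 1e-9) next
    arr <- .resample_axis(arr, a, sp[a], t)
    sp[a] <- t
  }
  cow_volume(arr, rep(t, 3))
}

# Cubic-spline interpolation of one axis of a 3D array. splinefun's "fmm"
# end conditions reproduce polynomials up to degree 3 exactly.
.resample_axis <- function(arr, axis, s_in, s_out) {
  n_in <- dim(arr)[axis]
  n_out <- round((n_in - 1) * s_in / s_out) + 1
  x_in <- (seq_len(n_in) - 1) * s_in
  x_out <- pmin(pmax((seq_len(n_out) - 1) * s_out, 0), x_in[n_in])
  if (n_in == 1L) {
    # degenerate axis: constant along it
    out <- array(rep(arr, n_out), dim = c(dim(arr)[-axis], n_out))
    return(aperm(out, order(c(setdiff(1:3, axis), axis))))
  }
  res <- apply(arr, setdiff(1:3, axis), function(line)
    splinefun(x_in, line, method = "fmm")(x_out))
  dim(res) <- c(n_out, dim(arr)[-axis])
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(2, 3, 1))
  aperm(res, perm)
}

# ---- endpoint annotation files ----------------------------------------------

.sentinel <- c(0L, 0L, 0L)

#' Construct a vessel segment endpoint specification table
#'
#' @param name Character vector of canonical segment names.
#' @param a,b Integer matrices (one row per segment, columns x,y,z) of the two
#'   endpoint voxel coordinates, 0-based. The sentinel `0 0 0` for both
#'   endpoints marks a segment with no centerline (`missing = TRUE`).
#' @return A data frame of class `cow_endpoints` with columns `name`, `ax`,
#'   `ay`, `az`, `bx`, `by`, `bz`, `missing`.
#' @export
cow_endpoints <- function(name, a, b) {
  a <- matrix(as.integer(a), ncol = 3)
  b <- matrix(as.integer(b), ncol = 3)
  if (length(name) != nrow(a) || length(name) != nrow(b))
    cow_input_error("name, a, b must have matching lengths")
  bad <- setdiff(name, cow_segment_names())
  if (length(bad))
    cow_input_error(sprintf("unknown segment name(s): %s",
                            paste(bad, collapse = ", ")))
  if (anyDuplicated(name))
    cow_input_error("duplicate segment name(s)")
  miss_a <- rowSums(a == 0L) == 3L
  miss_b <- rowSums(b == 0L) == 3L
  if (any(miss_a != miss_b))
    cow_parse_error("one endpoint is the 0 0 0 sentinel but the other is not")
  missing <- miss_a & miss_b
  same <- !missing & rowSums(a == b) == 3L
  if (any(same))
    cow_input_error(sprintf("endpoints coincide for segment(s): %s",
                            paste(name[same], collapse = ", ")))
  structure(
    data.frame(name = name, ax = a[, 1], ay = a[, 2], az = a[, 3],
               bx = b[, 1], by = b[, 2], bz = b[, 3], missing = missing,
               stringsAsFactors = FALSE),
    class = c("cow_endpoints", "data.frame"))
}

#' Parse an endpoint annotation file
#'
#' Plain-text dialect: one segment per line, `NAME x1 y1 z1 x2 y2 z2`,
#' whitespace-separated, `#` starts a comment; coordinates are 0-based voxel
#' indices on the isotropic grid. All six coordinates zero is the sentinel
#' for a segment with no centerline. The file must contain exactly one line
#' per canonical segment name.
#'
#' @param path Path to the annotation text file.
#' @return A [cow_endpoints()] table with 14 rows.
#' @export
parse_endpoints <- function(path) {
  if (!file.exists(path))
    cow_input_error(sprintf("path: file not found: %s", path))
  raw <- readLines(path, warn = FALSE)
  stripped <- sub("#.*$", "", raw)
  keep <- which(nzchar(trimws(stripped)))
  names_seen <- character(0)
  a <- b <- matrix(integer(0), ncol = 3)
  for (ln in keep) {
    tok <- strsplit(trimws(stripped[ln]), "\\s+")[[1]]
    if (length(tok) != 7L)
      cow_parse_error(sprintf("line %d: expected 'NAME x1 y1 z1 x2 y2 z2', got %d token(s)",
                              ln, length(tok)))
    if (!tok[1] %in% cow_segment_names())
      cow_parse_error(sprintf("line %d: unknown segment name '%s'", ln, tok[1]))
    if (tok[1] %in% names_seen)
      cow_parse_error(sprintf("line %d: duplicate segment '%s'", ln, tok[1]))
    co <- suppressWarnings(as.integer(tok[2:7]))
    if (anyNA(co) || any(co < 0))
      cow_parse_error(sprintf("line %d: coordinates must be non-negative integers", ln))
    names_seen <- c(names_seen, tok[1])
    a <- rbind(a, co[1:3])
    b <- rbind(b, co[4:6])
  }
  absent <- setdiff(cow_segment_names(), names_seen)
  if (length(absent))
    cow_parse_error(sprintf("missing segment(s): %s", paste(absent, collapse = ", ")))
  cow_endpoints(names_seen, a, b)
}

#' Write an endpoint annotation file
#'
#' Emits segments in canonical order (AComm first, BA last) in the dialect
#' read by [parse_endpoints()].
#'
#' @param specs A [cow_endpoints()] table.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_endpoints <- function(specs, path) {
  if (!inherits(specs, "cow_endpoints"))
    cow_input_error("specs: expected a cow_endpoints table")
  ord <- match(cow_segment_names(), specs$name)
  ord <- ord[!is.na(ord)]
  s <- specs[ord, , drop = FALSE]
  lines <- sprintf("%s %d %d %d %d %d %d", s$name,
                   s$ax, s$ay, s$az, s$bx, s$by, s$bz)
  writeLines(lines, path)
  invisible(path)
}
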