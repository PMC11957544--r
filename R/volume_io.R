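#' Read a volumetric TIFF stack
#'
#' Reads a multi-page TIFF (or a directory of per-slice TIFFs, sorted by file
#' name) into a [VoxelGrid-class]. Physical metadata is resolved in order of
#' precedence: explicit arguments, a YAML sidecar (`<path>.yml`, written by
#' [writeVolume()]), OME-style `PhysicalSize*` keys found in the TIFF
#' description tag, and finally a fallback of 1 um isotropic with a warning.
#' When explicit arguments contradict stored metadata the explicit value wins
#' and a warning reports the conflict. Integer-valued files are read bit
#' exactly.
#'
#' @param path a TIFF file or a directory of single-slice TIFFs.
#' @param spacing optional explicit voxel spacing `(dz, dy, dx)` in um.
#' @param expansion optional explicit linear expansion factor.
#' @return A [VoxelGrid-class] with `data[z, y, x]`.
#' @seealso [writeVolume()]
#' @export
readVolume <- function(path, spacing = NULL, expansion = NULL) {
  if (!file.exists(path)) stop("no such file or directory: ", path)
  sidecar <- .read_sidecar(path)
  # integer files are read as stored (bit-exact); float files carry their
  # affine rescaling in the sidecar and must be read as plain floats
  as_is <- !identical(sidecar$bits, 32L)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (!length(files)) stop("directory contains no TIFF slices: ", path)
    slices <- lapply(files, function(f) tiff::readTIFF(f, as.is = as_is))
    info <- attributes(tiff::readTIFF(files[1], info = TRUE))
  } else {
    slices <- tiff::readTIFF(path, all = TRUE, as.is = as_is, info = TRUE)
    if (is.array(slices) && !is.list(slices)) slices <- list(slices)
    info <- attributes(slices[[1]])
  }
  if (length(dim(slices[[1]])) > 2L)
    stop("multi-channel slices are not supported; expected one sample per pixel")
  ny <- nrow(slices[[1]]); nx <- ncol(slices[[1]]); nz <- length(slices)
  data <- array(0, c(nz, ny, nx))
  for (z in seq_len(nz)) data[z, , ] <- slices[[z]]

  meta_spacing <- sidecar$spacing %||% .spacing_from_description(info)
  meta_expansion <- sidecar$expansion
  if (!is.null(spacing) && !is.null(meta_spacing) &&
      !isTRUE(all.equal(as.numeric(spacing), as.numeric(meta_spacing))))
    warning("explicit spacing overrides stored metadata (",
            paste(meta_spacing, collapse = ", "), ")")
  spacing <- spacing %||% meta_spacing
  if (is.null(spacing)) {
    warning("no voxel spacing available; assuming 1 um isotropic")
    spacing <- c(1, 1, 1)
  }
  expansion <- expansion %||% meta_expansion %||% 1
  if (!is.null(sidecar$offset) && !is.null(sidecar$range)) {
    data <- data / sidecar$maxval * sidecar$range + sidecar$offset
  }
  VoxelGrid(data, spacing = spacing, expansion = expansion)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.sidecar_path <- function(path) paste0(path, ".yml")

.read_sidecar <- function(path) {
  sc <- .sidecar_path(path)
  if (!file.exists(sc)) return(list())
  yaml::read_yaml(sc)
}

.spacing_from_description <- function(info) {
  desc <- info$description
  if (is.null(desc) || !nzchar(desc)) return(NULL)
  grab <- function(key) {
    m <- regmatches(desc, regexpr(paste0(key, "\\s*=?\\s*\"?[0-9.eE+-]+"),
                                  desc))
    if (!length(m)) return(NA_real_)
    as.numeric(regmatches(m, regexpr("[0-9.eE+-]+$", m)))
  }
  px <- grab("PhysicalSizeX"); py <- grab("PhysicalSizeY")
  pz <- grab("PhysicalSizeZ")
  if (any(is.na(c(px, py, pz)))) return(NULL)
  c(pz, py, px)
}

#' Write a volumetric TIFF stack with physical metadata
#'
#' Emits a multi-page TIFF plus a YAML sidecar (`<path>.yml`) carrying the
#' voxel spacing, expansion factor and the sample encoding, so that
#' [readVolume()] round-trips the grid. Integer-valued grids are stored at
#' their native bit depth (8 or 16 bit, no type promotion) and round-trip bit
#' exactly; other grids are stored as 32-bit float after affine rescaling to
#' \[0, 1\] (the affine coefficients go to the sidecar).
#'
#' @param grid a [VoxelGrid-class].
#' @param path output file path (`.tif`).
#' @param bits force 8, 16 or 32 bits per sample; default chooses the
#'   smallest lossless integer depth, else 32.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(grid, path, bits = NULL) {
  stopifnot(is(grid, "VoxelGrid"))
  data <- grid@data
  if (is.logical(data)) data <- data + 0
  intlike <- all(data == round(data)) && min(data) >= 0
  if (is.null(bits)) {
    bits <- if (intlike && max(data) <= 255) 8L
            else if (intlike && max(data) <= 65535) 16L
            else 32L
  }
  sidecar <- list(spacing = as.numeric(grid@spacing),
                  expansion = as.numeric(grid@expansion),
                  bits = as.integer(bits))
  nz <- dim(data)[1]
  if (bits %in% c(8L, 16L)) {
    maxval <- 2^bits - 1
    slices <- lapply(seq_len(nz), function(z) data[z, , ] / maxval)
  } else {
    r <- range(data)
    offset <- r[1]
    rng <- if (r[2] > r[1]) r[2] - r[1] else 1
    sidecar$offset <- offset
    sidecar$range <- rng
    sidecar$maxval <- 1
    slices <- lapply(seq_len(nz), function(z) (data[z, , ] - offset) / rng)
  }
  ok <- tryCatch(
    tiff::writeTIFF(slices, path, bits.per.sample = as.integer(bits)),
    error = function(e) stop("cannot write TIFF at ", path, ": ",
                             conditionMessage(e)))
  yaml::write_yaml(sidecar, .sidecar_path(path))
  invisible(path)
}

#' Downsample a volume to a target spacing or below a byte budget
#'
#' Linear-interpolation resampling (downsampling only). In budget mode an
#' isotropic voxel-count scale factor `f = max(1, (bytes/budget)^(1/3))` is
#' applied, with `bytes = 4 * n_voxels` (32-bit storage convention), and per
#' axis extents are rounded down so the realised factor is the nearest
#' rational at or above `f` that yields integer extents. Output spacing is
#' updated so physical extents are preserved. Constant volumes are preserved
#' exactly (linear interpolation reproduces constants).
#'
#' @param grid a [VoxelGrid-class].
#' @param spacing target spacing in um `(dz, dy, dx)` (each >= input spacing),
#'   or `NULL` to use `budget`.
#' @param budget maximum byte size of the output at 4 bytes per voxel.
#' @return The resampled [VoxelGrid-class].
#' @export
resampleVolume <- function(grid, spacing = NULL, budget = NULL) {
  stopifnot(is(grid, "VoxelGrid"))
  d <- dim(grid@data)
  if (is.null(spacing) && is.null(budget))
    stop("supply either a target spacing or a byte budget")
  if (is.null(spacing)) {
    if (budget <= 0) stop("budget must be positive")
    bytes <- 4 * prod(d)
    f <- max(1, (bytes / budget)^(1 / 3))
    n_new <- pmax(1L, as.integer(floor(d / f)))
  } else {
    if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
    if (any(spacing < grid@spacing - 1e-9))
      stop("resample is downsampling-only: target spacing below input spacing")
    n_new <- pmax(1L, as.integer(floor((d - 1) * grid@spacing / spacing + 1 + 1e-9)))
  }
  if (any(n_new < 1L)) stop("requested resampling yields an empty volume")
  arr <- grid@data + 0
  for (ax in 1:3) {
    if (n_new[ax] == d[ax]) next
    arr <- .resample_axis(arr, ax, n_new[ax])
  }
  new_spacing <- grid@spacing * d / n_new
  VoxelGrid(arr, spacing = new_spacing, expansion = grid@expansion,
            meta = c(grid@meta, list(resampled_from = d)))
}

# linear interpolation along one axis; output sample j (0-based) at input
# coordinate j * (n_old / n_new) voxels
.resample_axis <- function(arr, axis, n_new) {
  d <- dim(arr)
  n_old <- d[axis]
  pos <- (seq_len(n_new) - 1) * (n_old / n_new)
  pos <- pmin(pos, n_old - 1)
  i0 <- pmin(floor(pos), n_old - 2); i0 <- pmax(i0, 0)
  t <- pos - i0
  W <- matrix(0, n_new, n_old)
  W[cbind(seq_len(n_new), i0 + 1)] <- 1 - t
  W[cbind(seq_len(n_new), i0 + 2)] <- W[cbind(seq_len(n_new), i0 + 2)] + t
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- W %*% matrix(a, nrow = n_old)
  out <- array(m, c(n_new, d[perm[2]], d[perm[3]]))
  aperm(out, order(perm))
}

#' Crop a volume to a physical region
#'
#' Keeps the voxels whose centres fall in the half-open box
#' `[lower, upper)` (um). Spacing is unchanged; the crop offset is recorded
#' in `meta$crop_offset_um`.
#'
#' @param grid a [VoxelGrid-class].
#' @param box a [RegionBox-class].
#' @return The cropped [VoxelGrid-class].
#' @examples
#' g <- VoxelGrid(array(runif(8e3), c(20, 20, 20)))
#' dim(cropVolume(g, RegionBox(c(0, 0, 0), c(10, 5, 20))))
#' @export
cropVolume <- function(grid, box) {
  stopifnot(is(grid, "VoxelGrid"), is(box, "RegionBox"))
  d <- dim(grid@data)
  keep <- lapply(1:3, function(ax) {
    co <- .axis_coords(d[ax], grid@spacing[ax])
    which(co >= box@lower[ax] - 1e-9 & co < box@upper[ax] - 1e-9)
  })
  if (any(vapply(keep, length, 1L) == 0L))
    stop("crop box does not intersect the volume")
  off <- vapply(1:3, function(ax) (keep[[ax]][1] - 1) * grid@spacing[ax],
                numeric(1))
  VoxelGrid(grid@data[keep[[1]], keep[[2]], keep[[3]], drop = FALSE],
            spacing = grid@spacing, expansion = grid@expansion,
            meta = c(grid@meta, list(crop_offset_um = off)))
}

#' Pre-expansion (biological) resolution of an expanded acquisition
#'
#' Physical expansion magnifies the sample, so the effective biological
#' resolution is the optical resolution divided by the linear expansion
#' factor. With the 1x air objective used for cellular imaging (optical
#' resolution 2 x 2 x 5 um) and 4x isotropic expansion this gives
#' 0.5 x 0.5 x 1.25 um.
#'
#' @param optical per-axis optical resolution in um (any length).
#' @param expansion linear expansion factor, > 0.
#' @return `optical / expansion`, the same shape as `optical`.
#' @examples
#' effectiveResolution(c(2, 2, 5), 4)  # 0.5 0.5 1.25
#' @export
effectiveResolution <- function(optical, expansion) {
  if (any(optical <= 0) || any(expansion <= 0))
    stop("optical resolution and expansion factor must be positive")
  optical / expansion
}
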