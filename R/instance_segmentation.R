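#' Threshold a volume into a binary mask
#'
#' Foreground is the set `value >= threshold`. In `"auto"` mode the threshold
#' maximises Otsu's between-class variance on a 256-bin histogram; the chosen
#' value is reported with a message and recorded in `meta$threshold` — the
#' reproducible stand-in for the interactive thresholding checkpoint of the
#' original workflow.
#'
#' @param grid a [VoxelGrid-class] with finite values.
#' @param threshold a numeric cutoff, or `"auto"` for Otsu's method.
#' @return A binary [VoxelGrid-class] (logical data).
#' @export
binarize <- function(grid, threshold = "auto") {
  stopifnot(is(grid, "VoxelGrid"))
  if (!all(is.finite(grid@data))) stop("grid contains non-finite values")
  if (identical(threshold, "auto")) {
    threshold <- .otsu(grid@data)
    message(sprintf("binarize: auto (Otsu) threshold = %.6g", threshold))
  }
  VoxelGrid(grid@data >= threshold, grid@spacing, grid@expansion,
            meta = c(grid@meta, list(threshold = threshold)))
}

# Otsu's criterion on a 256-bin histogram; returns the threshold intensity
# (lower edge of the first above-threshold bin, mapped back to data units)
.otsu <- function(x, nbins = 256L) {
  r <- range(x)
  if (r[1] == r[2])
    stop("constant volume: automatic thresholding is undefined")
  h <- tabulate(pmin(as.integer((x - r[1]) / (r[2] - r[1]) * nbins) + 1L,
                     nbins), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mu_t <- mu[nbins]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- 0
  k <- which.max(sb2)      # foreground = bins > k
  r[1] + (k / nbins) * (r[2] - r[1])
}

#' Remove small connected components from a mask
#'
#' Deletes connected foreground components with fewer than `min_voxels`
#' voxels; components of exactly `min_voxels` are retained.
#'
#' @param binary a binary [VoxelGrid-class].
#' @param min_voxels minimum component size to keep (voxels).
#' @param connectivity 6 or 26 (default 26).
#' @return The cleaned binary [VoxelGrid-class].
#' @export
removeSmallSpots <- function(binary, min_voxels, connectivity = 26) {
  stopifnot(is(binary, "VoxelGrid"))
  mask <- .binary_array(binary)
  lab <- .cpp_label_components(as.logical(mask), .dims(binary),
                               as.integer(connectivity))
  K <- attr(lab, "n_labels")
  if (K > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = K)
    keep <- sizes >= min_voxels
    mask <- array(lab > 0 & keep[pmax(lab, 1L)], dim(mask))
  }
  VoxelGrid(mask, binary@spacing, binary@expansion, binary@meta)
}

#' Fill small interior holes in a mask
#'
#' Background components (6-connected, the conservative hole definition) that
#' do not touch the volume border and contain fewer than `max_voxels` voxels
#' become foreground.
#'
#' @param binary a binary [VoxelGrid-class].
#' @param max_voxels holes strictly smaller than this are filled.
#' @param connectivity background connectivity (default 6).
#' @return The filled binary [VoxelGrid-class].
#' @export
fillSmallHoles <- function(binary, max_voxels, connectivity = 6) {
  stopifnot(is(binary, "VoxelGrid"))
  mask <- .binary_array(binary)
  d <- dim(mask)
  lab <- .cpp_label_components(as.logical(!mask), .dims(binary),
                               as.integer(connectivity))
  K <- attr(lab, "n_labels")
  if (K > 0) {
    lab <- array(lab, d)
    border <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                       lab[, , c(1, d[3])]))
    sizes <- tabulate(lab[lab > 0], nbins = K)
    fill <- setdiff(which(sizes < max_voxels), border)
    if (length(fill)) mask[lab %in% fill] <- TRUE
  }
  VoxelGrid(mask, binary@spacing, binary@expansion, binary@meta)
}

#' Watershed instance labelling
#'
#' Splits a binary mask into labelled instances by flooding a landscape from
#' markers. By default the landscape is the negated Euclidean distance
#' transform of the mask (so instance centres are basins) and markers are the
#' regional minima after h-minima suppression with depth `h`, i.e. the
#' classic marker-based watershed used to separate touching nuclei. Explicit
#' landscapes (e.g. a negated enhancement response) or marker grids may be
#' supplied instead. Labels are renumbered consecutively `1..K` in scan
#' order, and label supports partition the foreground.
#'
#' @param binary a nonempty binary [VoxelGrid-class].
#' @param landscape `"auto"` or a co-registered [VoxelGrid-class] flooded from
#'   its minima.
#' @param markers `"auto"` or a [LabelGrid-class] of seed labels.
#' @param h h-minima suppression depth for auto markers (landscape units;
#'   default 1, one voxel of distance).
#' @param connectivity flooding connectivity (default 6; marker detection uses
#'   26 so plateau minima merge).
#' @return A [LabelGrid-class].
#' @export
watershedLabel <- function(binary, landscape = "auto", markers = "auto",
                           h = 1, connectivity = 6) {
  stopifnot(is(binary, "VoxelGrid"))
  mask <- .binary_array(binary)
  if (!any(mask)) stop("empty mask: nothing to label")
  dims <- .dims(binary)
  if (identical(landscape, "auto")) {
    if (all(mask)) {
      land <- array(0, dim(mask))   # no background: flat landscape
    } else {
      land <- -array(.cpp_edt(as.logical(mask), dims,
                              as.numeric(binary@spacing)), dim(mask))
    }
  } else {
    stopifnot(is(landscape, "VoxelGrid"))
    land <- landscape@data + 0
  }
  if (identical(markers, "auto")) {
    mk <- .auto_markers(land, mask, dims, h)
  } else {
    stopifnot(is(markers, "LabelGrid"))
    mk <- markers@data
  }
  lab <- .cpp_watershed(as.numeric(land), as.integer(mk), as.logical(mask),
                        dims, as.integer(connectivity))
  # renumber consecutively in scan order
  lab <- as.integer(lab)
  u <- unique(lab[lab > 0])
  remap <- integer(max(u, 0L))
  remap[u] <- seq_along(u)
  lab[lab > 0] <- remap[lab[lab > 0]]
  new("LabelGrid", data = array(lab, dim(mask)), spacing = binary@spacing,
      expansion = binary@expansion, nLabels = length(u))
}

.auto_markers <- function(land, mask, dims, h) {
  # h-minima: reconstruction-by-erosion of (f + h) over f, via the dual
  # reconstruction-by-dilation of the negated landscape
  f <- as.numeric(land)
  f[!mask] <- max(f) + h + 1   # keep background out of the basins
  rec <- -.cpp_reconstruct_dilation(-(f + h), -f, dims)
  .cpp_regional_minima(rec, as.logical(mask), dims, 26L)
}

#' Census of labelled instances
#'
#' One row per label with voxel count, physical volume and centroid; when
#' regions are supplied each instance is assigned to the region containing
#' its centroid (half-open boxes). Overlapping regions raise an error unless
#' `priority = TRUE`, in which case the first-listed region wins. Per-region
#' totals are attached as `attr(, "region_totals")`.
#'
#' @param labels a [LabelGrid-class].
#' @param regions optional list of [RegionBox-class] objects.
#' @param priority resolve region overlap by list order instead of erroring.
#' @return `data.frame` with columns `label, voxels, volume_um3, cz, cy, cx,
#'   region`.
#' @export
countLabels <- function(labels, regions = NULL, priority = FALSE) {
  stopifnot(is(labels, "LabelGrid"))
  K <- labels@nLabels
  voxvol <- prod(labels@spacing)
  if (K == 0L) {
    out <- data.frame(label = integer(), voxels = integer(),
                      volume_um3 = numeric(), cz = numeric(), cy = numeric(),
                      cx = numeric(), region = character())
    attr(out, "region_totals") <- NULL
    return(out)
  }
  sizes <- tabulate(labels@data[labels@data > 0], nbins = K)
  cent <- .label_centroids(labels@data, K, labels@spacing)
  region <- rep("all", K)
  if (!is.null(regions)) {
    if (!priority && length(regions) > 1) {
      for (i in seq_along(regions)[-1]) for (j in seq_len(i - 1)) {
        a <- regions[[i]]; b <- regions[[j]]
        if (all(a@lower < b@upper & b@lower < a@upper))
          stop("regions overlap; pass priority = TRUE to resolve by order")
      }
    }
    region <- rep(NA_character_, K)
    for (r in rev(seq_along(regions))) {
      box <- regions[[r]]
      inside <- cent[, 1] >= box@lower[1] & cent[, 1] < box@upper[1] &
                cent[, 2] >= box@lower[2] & cent[, 2] < box@upper[2] &
                cent[, 3] >= box@lower[3] & cent[, 3] < box@upper[3]
      nm <- if (is.na(box@name)) paste0("region", r) else box@name
      region[inside] <- nm
    }
  }
  out <- data.frame(label = seq_len(K), voxels = sizes,
                    volume_um3 = sizes * voxvol,
                    cz = cent[, 1], cy = cent[, 2], cx = cent[, 3],
                    region = region)
  totals <- aggregate(list(n = out$label), by = list(region = out$region),
                      FUN = length)
  attr(out, "region_totals") <- totals
  out
}
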