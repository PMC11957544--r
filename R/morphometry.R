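#' Whole-body mask from a nuclei-stained volume
#'
#' Builds a single connected body mask: optional budget resampling, strong
#' anisotropic diffusion (many iterations flatten texture while the body
#' outline survives), thresholding, interior hole filling, contour smoothing
#' by morphological closing with a ball (the deterministic counterpart of
#' ambient-occlusion surface regularisation: both suppress pits in the
#' surface), and finally retention of the largest connected component.
#'
#' @param grid a nuclei-stained [VoxelGrid-class].
#' @param budget optional byte budget for initial resampling (see
#'   [resampleVolume()]); `NULL` skips resampling.
#' @param threshold threshold for [binarize()] (`"auto"` = Otsu).
#' @param diffusion_iterations,kappa diffusion strength (defaults 15
#'   iterations at 10% of the dynamic range).
#' @param closing_radius ball radius in voxels for contour smoothing
#'   (default 5, at the working resolution).
#' @param max_hole_voxels holes below this size are filled (default 1e5).
#' @return A binary [VoxelGrid-class] body mask.
#' @export
bodyMask <- function(grid, budget = NULL, threshold = "auto",
                     diffusion_iterations = 15, kappa = NULL,
                     closing_radius = 5, max_hole_voxels = 1e5) {
  stopifnot(is(grid, "VoxelGrid"))
  if (!is.null(budget)) grid <- resampleVolume(grid, budget = budget)
  if (is.null(kappa)) kappa <- 0.1 * diff(range(grid@data))
  sm <- anisotropicDiffusion(grid, n_iterations = diffusion_iterations,
                             kappa = kappa)
  bin <- binarize(sm, threshold)
  if (!any(bin@data)) stop("empty mask after thresholding")
  bin <- fillSmallHoles(bin, max_hole_voxels)
  mask <- .closing(.binary_array(bin), bin@spacing, closing_radius)
  lab <- .cpp_label_components(as.logical(mask), .dims(bin), 26L)
  K <- attr(lab, "n_labels")
  if (K > 1) {
    sizes <- tabulate(lab[lab > 0], nbins = K)
    mask <- array(lab == which.max(sizes), dim(mask))
  }
  VoxelGrid(mask, bin@spacing, bin@expansion,
            meta = c(bin@meta, list(closing_radius = closing_radius)))
}

# morphological closing with a Euclidean ball of `radius` voxels (isotropic
# in voxel units), dilation and erosion via two distance transforms; the
# volume is padded by radius + 1 background voxels so the border acts as open
# space rather than clipping the ball
.closing <- function(mask, spacing, radius) {
  if (radius <= 0) return(mask)
  d <- dim(mask)
  pad <- as.integer(ceiling(radius) + 1L)
  big <- array(FALSE, d + 2L * pad)
  ix <- lapply(d, function(n) pad + seq_len(n))
  big[ix[[1]], ix[[2]], ix[[3]]] <- mask
  dims <- as.integer(dim(big))
  iso <- c(1, 1, 1)
  # dilation: background voxels within `radius` of the mask join it
  dist_to_fg <- array(.cpp_edt(as.logical(!big), dims, iso), dim(big))
  dil <- big | (dist_to_fg <= radius)
  # erosion: keep voxels deeper than `radius` inside the dilated mask
  depth <- array(.cpp_edt(as.logical(dil), dims, iso), dim(big))
  closed <- dil & (depth > radius)
  closed[ix[[1]], ix[[2]], ix[[3]]]
}

#' Measure a body mask
#'
#' Length, width and depth are the extents of the mask along the principal
#' axes of its voxel-coordinate covariance (longest first); volume is voxel
#' count times voxel volume; surface area is measured on an isosurface at
#' level 0.5 of the Gaussian-smoothed mask (marching tetrahedra), which
#' removes the ~50% overestimate a voxel-face count would give. Measurements
#' are reported in expanded-sample um by default; `scale = "biological"`
#' divides lengths by the expansion factor (volume by its cube, area by its
#' square).
#'
#' @param mask a nonempty binary [VoxelGrid-class].
#' @param scale `"expanded"` (default) or `"biological"`.
#' @param smooth_sigma mask smoothing before meshing, in voxels (default 0.7).
#' @return A [MorphometryResult-class].
#' @export
measureBody <- function(mask, scale = c("expanded", "biological"),
                        smooth_sigma = 0.7) {
  stopifnot(is(mask, "VoxelGrid"))
  scale <- match.arg(scale)
  m <- .binary_array(mask)
  if (!any(m)) stop("empty mask")
  sp <- mask@spacing
  idx <- which(m)
  d <- dim(m)
  co <- cbind(((idx - 1) %% d[1]) * sp[1],
              (((idx - 1) %/% d[1]) %% d[2]) * sp[2],
              ((idx - 1) %/% (d[1] * d[2])) * sp[3])
  ctr <- colMeans(co)
  cc <- sweep(co, 2, ctr)
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)$vectors
  proj <- cc %*% ev
  # half-open voxel support: add one voxel pitch along each principal axis
  pitch <- sqrt(colSums((diag(sp) %*% ev)^2))
  extents <- apply(proj, 2, function(p) diff(range(p))) + pitch
  volume <- length(idx) * prod(sp)
  area <- .mask_surface_area(m, sp, smooth_sigma)
  f <- if (scale == "biological") mask@expansion else 1
  new("MorphometryResult",
      length = extents[1] / f, width = extents[2] / f, depth = extents[3] / f,
      volume = volume / f^3, surfaceArea = area / f^2,
      saVRatio = sqrt(area) / volume^(1 / 3), scale = scale)
}

.mask_surface_area <- function(m, sp, smooth_sigma) {
  pad <- as.integer(ceiling(3 * smooth_sigma) + 1)
  d <- dim(m)
  big <- array(0, d + 2L * pad)
  big[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- m
  if (smooth_sigma > 0) {
    k <- .gauss_kernel(smooth_sigma)
    big <- .sep_filter(big, k, k, k)
  }
  .cpp_isosurface_area(as.numeric(big), as.integer(dim(big)),
                       as.numeric(sp), 0.5)
}

#' Dimensionless surface/volume shape index
#'
#' `sqrt(surface area) / cbrt(volume)`: invariant under isotropic scaling
#' (hence independent of the expansion factor), minimised by the sphere at
#' `sqrt(4 pi) / (4 pi / 3)^(1/3) = 2.199`; a cube gives `sqrt(6) = 2.449`.
#' Constancy of this ratio across animals of different sizes indicates shape
#' is preserved during growth.
#'
#' @param result a [MorphometryResult-class].
#' @return the ratio, numeric(1).
#' @export
saVRatio <- function(result) {
  stopifnot(is(result, "MorphometryResult"))
  result@saVRatio
}

#' Angle between two brain lobes
#'
#' The angle (degrees, in \[0, 90\]) between the first principal axes of two
#' 3D point clouds (e.g. centroids of octopaminergic neurons per lobe),
#' projected onto the organism's coronal plane. The coronal plane is taken
#' orthogonal to the smallest-variance principal axis of the pooled cloud
#' (the dorsoventral direction) unless an explicit plane normal is given.
#'
#' @param lobe_a,lobe_b matrices (n x 3, um) of points, each with at least 3
#'   non-collinear rows.
#' @param normal optional unit normal of the projection plane `(z, y, x)`.
#' @return angle in degrees.
#' @export
brainLobeAngle <- function(lobe_a, lobe_b, normal = NULL) {
  lobe_a <- as.matrix(lobe_a); lobe_b <- as.matrix(lobe_b)
  if (nrow(lobe_a) < 3 || nrow(lobe_b) < 3)
    stop("each lobe needs at least 3 points")
  axis_of <- function(p) {
    pc <- prcomp(p)
    if (pc$sdev[1] < 1e-12 || pc$sdev[2] < 1e-9 * pc$sdev[1])
      stop("degenerate (collinear) point cloud")
    pc$rotation[, 1]
  }
  a <- axis_of(lobe_a)
  b <- axis_of(lobe_b)
  if (is.null(normal)) {
    pooled <- prcomp(rbind(lobe_a, lobe_b))
    normal <- pooled$rotation[, 3]
  }
  normal <- normal / sqrt(sum(normal^2))
  proj <- function(v) {
    w <- v - sum(v * normal) * normal
    n <- sqrt(sum(w^2))
    if (n < 1e-9) stop("lobe axis is orthogonal to the projection plane")
    w / n
  }
  ca <- abs(sum(proj(a) * proj(b)))
  acos(pmin(1, ca)) * 180 / pi
}
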