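#' VoxelGrid: a 3D intensity volume with physical geometry
#'
#' The central data container: a 3D scalar field indexed `[z, y, x]` together
#' with the per-axis voxel spacing in micrometres and the linear expansion
#' factor of the sample (1 for unexpanded tissue). Voxel centres sit at
#' `(i - 1) * spacing` on each axis (1-based R indices), so physical
#' coordinates start at 0. Binary masks are represented as a `VoxelGrid`
#' holding a `logical` array.
#'
#' @slot data 3D `numeric` (or `logical`, for masks) array, dim `(nz, ny, nx)`.
#' @slot spacing numeric(3), voxel pitch in um per axis `(dz, dy, dx)`; all
#'   strictly positive and finite.
#' @slot expansion numeric(1), dimensionless linear expansion factor, >= 1.
#'   Measurements taken on the grid are in expanded-sample um; divide lengths
#'   by this factor (volumes by its cube) for biological scale.
#' @slot meta list of provenance entries (e.g. the threshold chosen by an
#'   automatic binarization); never interpreted by the algorithms.
#'
#' @seealso [VoxelGrid()], [readVolume()], [LabelGrid-class]
#' @export
setClass("VoxelGrid",
  representation(data = "array", spacing = "numeric", expansion = "numeric",
                 meta = "list"),
  prototype(spacing = c(1, 1, 1), expansion = 1, meta = list()))

setValidity("VoxelGrid", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L || any(d < 1L))
    msg <- c(msg, "data must be a 3D array with every extent >= 1")
  if (length(object@spacing) != 3L || !all(is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive finite values (um)")
  if (length(object@expansion) != 1L || !is.finite(object@expansion) ||
      object@expansion < 1)
    msg <- c(msg, "expansion factor must be a single finite value >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a VoxelGrid
#'
#' @param data 3D array indexed `[z, y, x]`.
#' @param spacing voxel pitch in um, `(dz, dy, dx)`; a scalar is recycled.
#' @param expansion linear expansion factor (>= 1).
#' @param meta optional provenance list.
#' @return A [VoxelGrid-class] object.
#' @examples
#' g <- VoxelGrid(array(0, c(8, 8, 8)), spacing = c(2.5, 0.8, 0.8))
#' voxelSpacing(g)
#' @export
VoxelGrid <- function(data, spacing = c(1, 1, 1), expansion = 1,
                      meta = list()) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("VoxelGrid", data = data, spacing = as.numeric(spacing),
      expansion = as.numeric(expansion), meta = meta)
}

#' LabelGrid: integer instance labels sharing a VoxelGrid's geometry
#'
#' Voxel value 0 is background; instances carry consecutive positive integer
#' labels `1..K`.
#'
#' @slot data 3D integer array.
#' @slot spacing,expansion as in [VoxelGrid-class].
#' @slot nLabels number of instances `K`.
#' @export
setClass("LabelGrid",
  representation(data = "array", spacing = "numeric", expansion = "numeric",
                 nLabels = "integer"),
  prototype(spacing = c(1, 1, 1), expansion = 1, nLabels = 0L))

setValidity("LabelGrid", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (any(object@data < 0, na.rm = TRUE))
    msg <- c(msg, "labels must be non-negative")
  if (length(object@nLabels) != 1L || object@nLabels < 0L)
    msg <- c(msg, "nLabels must be a single non-negative integer")
  if (length(msg)) msg else TRUE
})

#' RegionBox: an axis-aligned physical region
#'
#' Half-open box `[lower, upper)` in physical um per axis `(z, y, x)`, used to
#' crop volumes and to assign labelled instances or fiber midpoints to
#' anatomical compartments (e.g. the 500 x 250 x 300 um^3 census box used for
#' per-region fiber counts).
#'
#' @slot lower,upper numeric(3) corners in um; `lower < upper` on every axis.
#' @slot name optional label.
#' @export
setClass("RegionBox",
  representation(lower = "numeric", upper = "numeric", name = "character"),
  prototype(name = NA_character_))

setValidity("RegionBox", function(object) {
  if (length(object@lower) != 3L || length(object@upper) != 3L)
    return("lower and upper must each have 3 components (z, y, x)")
  if (!all(object@lower < object@upper))
    return("lower must be strictly below upper on every axis")
  TRUE
})

#' @param lower,upper box corners in um, `(z, y, x)`.
#' @param name optional region name.
#' @rdname RegionBox-class
#' @examples
#' RegionBox(c(0, 0, 0), c(500, 250, 300), name = "census")
#' @export
RegionBox <- function(lower, upper, name = NA_character_) {
  new("RegionBox", lower = as.numeric(lower), upper = as.numeric(upper),
      name = as.character(name))
}

#' HessianEigenvalues: per-voxel eigen decomposition of the Hessian
#'
#' Eigenvalues of the gamma-normalised (gamma = 2) Gaussian-derivative Hessian,
#' sorted by absolute value `|l1| <= |l2| <= |l3|` (Frangi convention), plus
#' the eigenvector of the smallest-|lambda| eigenvalue, which points along the
#' axis of tube-like structures.
#'
#' @slot l1,l2,l3 3D arrays of sorted eigenvalues.
#' @slot vz,vy,vx 3D arrays holding the components of the tube-axis
#'   eigenvector (may be empty if not requested).
#' @slot sigma the scale (in voxels) at which the Hessian was computed.
#' @export
setClass("HessianEigenvalues",
  representation(l1 = "array", l2 = "array", l3 = "array",
                 vz = "array", vy = "array", vx = "array", sigma = "numeric"))

#' CylinderTemplate: parameters of the matched cylinder
#'
#' Geometry of the solid-cylinder template used by [cylinderCorrelate()]:
#' all lengths in voxels of the processed grid. The annulus between
#' `outerRadius` and `maskRadius` serves as the local background reference;
#' voxels beyond `maskRadius` are ignored. The anterior-pole muscle recipe of
#' the source workflow uses length 18, outer radius 2.8, mask radius 3 and
#' 5 degree angular sampling.
#'
#' @slot length,outerRadius,maskRadius template geometry in voxels.
#' @slot angularStep orientation sampling step in degrees, in (0, 90].
#' @export
setClass("CylinderTemplate",
  representation(length = "numeric", outerRadius = "numeric",
                 maskRadius = "numeric", angularStep = "numeric"))

setValidity("CylinderTemplate", function(object) {
  msg <- character()
  if (object@length <= 2 * object@outerRadius)
    msg <- c(msg, "length must exceed twice the outer radius")
  if (object@angularStep <= 0 || object@angularStep > 90)
    msg <- c(msg, "angularStep must be in (0, 90] degrees")
  if (object@maskRadius < object@outerRadius)
    msg <- c(msg, "maskRadius must be >= outerRadius")
  if (length(msg)) msg else TRUE
})

#' @param length,outerRadius,maskRadius cylinder geometry in voxels.
#' @param angularStep orientation sampling step in degrees.
#' @rdname CylinderTemplate-class
#' @examples
#' CylinderTemplate(18, 2.8, 3, 5)  # the anterior-pole muscle setting
#' @export
CylinderTemplate <- function(length, outerRadius, maskRadius,
                             angularStep = 5) {
  new("CylinderTemplate", length = as.numeric(length),
      outerRadius = as.numeric(outerRadius),
      maskRadius = as.numeric(maskRadius),
      angularStep = as.numeric(angularStep))
}

#' CorrelationField: best cylinder match per voxel
#'
#' Per-voxel best zero-normalised correlation in \[-1, 1\] and the index of the
#' best-matching orientation from a fixed orientation set (antipodally
#' identified unit axes, rows of `axes` in `(z, y, x)` order). Index 0 marks
#' voxels where no orientation was evaluated or the correlation floor was not
#' reached.
#'
#' @slot corr 3D array of best correlations.
#' @slot axisIndex 3D integer array, 1-based row into `axes` (0 = none).
#' @slot axes matrix of sampled unit axes, one row per orientation.
#' @slot spacing voxel spacing of the source grid (um).
#' @slot template the [CylinderTemplate-class] used.
#' @export
setClass("CorrelationField",
  representation(corr = "array", axisIndex = "array", axes = "matrix",
                 spacing = "numeric", template = "CylinderTemplate"))

#' FiberSet: traced fiber polylines with orientation classes
#'
#' Ordered 3D polylines in physical um (`(z, y, x)` columns), each with arc
#' length, mean orientation (unit axis), and an anatomical orientation class
#' among circular, diagonal, longitudinal, dorsoventral, unclassified.
#'
#' @slot traces list of n x 3 matrices of points in um.
#' @slot orientations matrix (one row per fiber) of mean unit axes.
#' @slot lengths numeric arc lengths in um.
#' @slot classes factor of orientation classes.
#' @slot params provenance list (template, thresholds, seed).
#' @export
setClass("FiberSet",
  representation(traces = "list", orientations = "matrix",
                 lengths = "numeric", classes = "factor", params = "list"))

setValidity("FiberSet", function(object) {
  n <- length(object@traces)
  if (length(object@lengths) != n || length(object@classes) != n ||
      (n > 0 && nrow(object@orientations) != n))
    return("traces, orientations, lengths and classes must agree in length")
  if (n > 0 && any(vapply(object@traces, nrow, 1L) < 2L))
    return("every trace needs at least 2 points")
  TRUE
})

#' MorphometryResult: whole-body physical measurements
#'
#' Extents along the principal axes of the body mask, voxel-count volume,
#' isosurface area, and the dimensionless shape index sqrt(SA)/cbrt(V)
#' (>= 2.199, the spherical minimum, for convex bodies). `scale` records
#' whether values are in expanded-sample or biological units.
#'
#' @slot length,width,depth um along the first/second/third principal axes.
#' @slot volume um^3. @slot surfaceArea um^2.
#' @slot saVRatio dimensionless sqrt(surfaceArea)/volume^(1/3).
#' @slot scale `"expanded"` or `"biological"`.
#' @export
setClass("MorphometryResult",
  representation(length = "numeric", width = "numeric", depth = "numeric",
                 volume = "numeric", surfaceArea = "numeric",
                 saVRatio = "numeric", scale = "character"))

setValidity("MorphometryResult", function(object) {
  vals <- c(object@length, object@width, object@depth, object@volume,
            object@surfaceArea, object@saVRatio)
  if (any(!is.finite(vals)) || any(vals <= 0))
    return("all measurements must be positive and finite")
  if (!object@scale %in% c("expanded", "biological"))
    return("scale must be 'expanded' or 'biological'")
  TRUE
})

#' ScalingFit: allometric scaling fit with optional breakpoint
#'
#' One or two least-squares segments relating e.g. neuron count to total cell
#' count. For two segments the breakpoint is chosen by exhaustive grid search
#' over observed x, minimising total residual sum of squares.
#'
#' @slot slopes,intercepts per-segment coefficients (length 1 or 2).
#' @slot breakpoint x value splitting the segments, `NA` if unsupported.
#' @slot residualSD residual standard deviation of the chosen model.
#' @slot n number of points fitted.
#' @export
setClass("ScalingFit",
  representation(slopes = "numeric", intercepts = "numeric",
                 breakpoint = "numeric", residualSD = "numeric",
                 n = "integer"))
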