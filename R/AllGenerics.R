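#' @name accessors
#' @title Accessors for voxcensus data objects
#' @param object a voxcensus S4 object.
#' @description Slot access goes through these accessors rather than `@`.
NULL

#' @describeIn accessors the raw 3D array of a grid.
#' @export
setGeneric("voxelData", function(object) standardGeneric("voxelData"))

#' @describeIn accessors voxel spacing in um, `(dz, dy, dx)`.
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))

#' @describeIn accessors linear expansion factor of the sample.
#' @export
setGeneric("expansionFactor",
           function(object) standardGeneric("expansionFactor"))

#' @describeIn accessors number of instance labels in a [LabelGrid-class].
#' @export
setGeneric("nLabels", function(object) standardGeneric("nLabels"))

#' @export
setMethod("voxelData", "VoxelGrid", function(object) object@data)
#' @export
setMethod("voxelData", "LabelGrid", function(object) object@data)
#' @export
setMethod("voxelSpacing", "VoxelGrid", function(object) object@spacing)
#' @export
setMethod("voxelSpacing", "LabelGrid", function(object) object@spacing)
#' @export
setMethod("voxelSpacing", "CorrelationField", function(object) object@spacing)
#' @export
setMethod("expansionFactor", "VoxelGrid", function(object) object@expansion)
#' @export
setMethod("expansionFactor", "LabelGrid", function(object) object@expansion)
#' @export
setMethod("nLabels", "LabelGrid", function(object) object@nLabels)

#' @export
setMethod("dim", "VoxelGrid", function(x) dim(x@data))
#' @export
setMethod("dim", "LabelGrid", function(x) dim(x@data))

setMethod("show", "VoxelGrid", function(object) {
  d <- dim(object@data)
  cat(sprintf("VoxelGrid %d x %d x %d (z,y,x), spacing %s um, expansion %gx\n",
              d[1], d[2], d[3],
              paste(signif(object@spacing, 4), collapse = " x "),
              object@expansion))
  r <- range(object@data)
  cat(sprintf("  values in [%g, %g]%s\n", r[1], r[2],
              if (is.logical(object@data)) " (binary mask)" else ""))
})

setMethod("show", "LabelGrid", function(object) {
  d <- dim(object@data)
  cat(sprintf("LabelGrid %d x %d x %d (z,y,x), %d labels, spacing %s um\n",
              d[1], d[2], d[3], object@nLabels,
              paste(signif(object@spacing, 4), collapse = " x ")))
})

setMethod("show", "RegionBox", function(object) {
  cat(sprintf("RegionBox%s [%s) -> [%s) um (z,y,x)\n",
              if (is.na(object@name)) "" else paste0(" '", object@name, "'"),
              paste(object@lower, collapse = ", "),
              paste(object@upper, collapse = ", ")))
})

setMethod("show", "CorrelationField", function(object) {
  d <- dim(object@corr)
  cat(sprintf(
    "CorrelationField %d x %d x %d, %d orientations, best corr %.3f\n",
    d[1], d[2], d[3], nrow(object@axes), max(object@corr)))
})

setMethod("show", "FiberSet", function(object) {
  cat(sprintf("FiberSet of %d traces\n", length(object@traces)))
  if (length(object@traces)) {
    cat(sprintf("  total length %.1f um; classes: %s\n",
                sum(object@lengths),
                paste(sprintf("%s=%d", levels(object@classes),
                              tabulate(object@classes,
                                       nbins = nlevels(object@classes))),
                      collapse = ", ")))
  }
})

setMethod("show", "MorphometryResult", function(object) {
  cat(sprintf(paste0(
    "MorphometryResult (%s scale)\n",
    "  length x width x depth: %.1f x %.1f x %.1f um\n",
    "  volume %.4g um^3, surface area %.4g um^2, sqrt(SA)/cbrt(V) = %.3f\n"),
    object@scale, object@length, object@width, object@depth,
    object@volume, object@surfaceArea, object@saVRatio))
})

setMethod("show", "ScalingFit", function(object) {
  k <- length(object@slopes)
  cat(sprintf("ScalingFit: %d segment%s, n = %d\n", k,
              if (k > 1) "s" else "", object@n))
  for (i in seq_len(k))
    cat(sprintf("  segment %d: slope %.4g, intercept %.4g\n", i,
                object@slopes[i], object@intercepts[i]))
  if (!is.na(object@breakpoint))
    cat(sprintf("  breakpoint at x = %.4g\n", object@breakpoint))
  cat(sprintf("  residual sd %.4g\n", object@residualSD))
})

#' Fibers as a data frame
#'
#' One row per fiber: id, arc length (um), mean orientation components,
#' class, and midpoint coordinates.
#'
#' @param x a [FiberSet-class].
#' @param ... ignored.
#' @return `data.frame` with one row per trace.
#' @export
as.data.frame.FiberSet <- function(x, ...) {
  n <- length(x@traces)
  if (n == 0L) {
    return(data.frame(id = integer(), length_um = numeric(),
                      oz = numeric(), oy = numeric(), ox = numeric(),
                      class = character(), mz = numeric(), my = numeric(),
                      mx = numeric()))
  }
  mid <- t(vapply(x@traces, .trace_midpoint, numeric(3)))
  data.frame(id = seq_len(n), length_um = x@lengths,
             oz = x@orientations[, 1], oy = x@orientations[, 2],
             ox = x@orientations[, 3],
             class = as.character(x@classes),
             mz = mid[, 1], my = mid[, 2], mx = mid[, 3])
}
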