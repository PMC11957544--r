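#' Quasi-uniform orientation sampling of the hemisphere
#'
#' Deterministic set of unit axes (antipodally identified: every axis has
#' z >= 0, or y >= 0 on the equator) such that any direction lies within
#' `angular_step` degrees of a sample. Axes are arranged on rings of constant
#' polar angle spaced by `angular_step`, with azimuthal spacing at most
#' `angular_step` of arc on each ring, giving a worst-case covering radius of
#' about `0.71 * angular_step`.
#'
#' @param angular_step sampling step in degrees, in (0, 90].
#' @return matrix of unit axes, one row per orientation, columns `(z, y, x)`.
#' @examples
#' nrow(makeOrientationSet(90))  # the 3 coordinate axes
#' @export
makeOrientationSet <- function(angular_step) {
  if (angular_step <= 0 || angular_step > 90)
    stop("angular_step must be in (0, 90] degrees")
  step <- angular_step * pi / 180
  thetas <- seq(0, pi / 2, by = step)
  if (abs(thetas[length(thetas)] - pi / 2) > 1e-9)
    thetas <- c(thetas, pi / 2)
  rows <- list()
  for (th in thetas) {
    if (th < 1e-12) {
      rows[[length(rows) + 1L]] <- c(1, 0, 0)   # pole: the z axis
      next
    }
    arc <- if (abs(th - pi / 2) < 1e-9) pi else 2 * pi  # equator: half-ring
    n_az <- max(1L, ceiling(arc * sin(th) / step))
    phis <- (seq_len(n_az) - 1) / n_az * arc
    for (ph in phis) {
      rows[[length(rows) + 1L]] <-
        c(cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
    }
  }
  axes <- do.call(rbind, rows)
  colnames(axes) <- c("z", "y", "x")
  axes
}

#' Cylinder correlation
#'
#' Zero-normalised cross-correlation of the volume against a solid-cylinder
#' template at every orientation of a quasi-uniform sample
#' ([makeOrientationSet()]); per voxel the best correlation and best
#' orientation are kept. The template interior (radius `outerRadius`,
#' anti-aliased over one voxel) has value 1; the annulus out to `maskRadius`
#' has value 0 and acts as the local background reference; beyond
#' `maskRadius` the neighbourhood is ignored. Voxels whose neighbourhood has
#' zero intensity variance get correlation 0 by convention.
#'
#' Correlation is evaluated at `candidates`: all voxels by default, or the
#' voxels at or above an intensity floor (`min_intensity`), which skips
#' empty background in large sparse volumes without changing results where
#' fibers live.
#'
#' @param grid a pre-enhanced [VoxelGrid-class] (unsharp masking and/or
#'   [rodness()] recommended).
#' @param template a [CylinderTemplate-class]; the anterior-pole muscle
#'   recipe is `CylinderTemplate(18, 2.8, 3, 5)`.
#' @param min_intensity optional candidate floor: only voxels with intensity
#'   `>=` this value are evaluated.
#' @return A [CorrelationField-class].
#' @export
cylinderCorrelate <- function(grid, template, min_intensity = NULL) {
  stopifnot(is(grid, "VoxelGrid"), is(template, "CylinderTemplate"))
  dims <- .dims(grid)
  if (any(template@length > dims))
    stop("template is larger than the grid")
  axes <- makeOrientationSet(template@angularStep)
  if (is.null(min_intensity)) {
    cand <- seq_len(prod(dims)) - 1L
  } else {
    cand <- which(grid@data >= min_intensity) - 1L
  }
  res <- .cpp_cylinder_correlate(.as_numeric_vec(grid), dims, axes,
                                 template@length, template@outerRadius,
                                 template@maskRadius, as.integer(cand))
  new("CorrelationField",
      corr = array(res$corr, dim(grid@data)),
      axisIndex = array(as.integer(res$axis), dim(grid@data)),
      axes = axes, spacing = grid@spacing, template = template)
}

#' Trace fibers through a correlation field
#'
#' Extracts fiber polylines by ridge following: local correlation maxima at
#' or above `seed_threshold` seed traces in descending correlation order;
#' each trace steps bidirectionally along the locally best orientation
#' (re-evaluated every step, per-step turning capped at `turn_limit`),
#' stopping when the interpolated correlation drops below
#' `continue_threshold`, the turn limit is exceeded, or already-claimed
#' territory is entered. Claimed voxels (a tube of the template's outer
#' radius around each accepted trace) can neither seed nor be traversed
#' again, which resolves crossings deterministically in favour of the
#' stronger fiber. Traces shorter than `min_length` are discarded.
#'
#' @param field a [CorrelationField-class].
#' @param seed_threshold minimum correlation to start a trace (default 0.5).
#' @param continue_threshold minimum correlation to keep stepping (default
#'   `0.6 * seed_threshold`).
#' @param step_size step in voxels (default 1).
#' @param min_length minimum accepted arc length in um (default 0).
#' @param turn_limit maximum direction change per step, degrees (default 30).
#' @return A [FiberSet-class] (classes all `"unclassified"`; see
#'   [classifyOrientation()]).
#' @export
traceCorrelationLines <- function(field, seed_threshold = 0.5,
                                  continue_threshold = 0.6 * seed_threshold,
                                  step_size = 1, min_length = 0,
                                  turn_limit = 30) {
  stopifnot(is(field, "CorrelationField"))
  if (abs(seed_threshold) > 1 || abs(continue_threshold) > 1)
    stop("thresholds must lie in [-1, 1]")
  if (continue_threshold > seed_threshold)
    stop("continue_threshold must not exceed seed_threshold")
  corr <- field@corr
  dims <- as.integer(dim(corr))
  axisIndex <- field@axisIndex
  axes <- field@axes
  cos_turn <- cos(turn_limit * pi / 180)
  claimed <- array(FALSE, dims)
  claim_off <- .claim_ball_offsets(max(1, field@template@outerRadius))

  above <- corr >= seed_threshold
  seeds <- integer(0)
  if (any(above)) {
    peaks <- .cpp_regional_minima(as.numeric(-corr), as.logical(above),
                                  dims, 26L)
    K <- attr(peaks, "n_labels")
    if (K > 0) {
      # one representative voxel per peak plateau
      seeds <- vapply(split(which(peaks > 0), peaks[peaks > 0]),
                      `[`, integer(1), 1L)
      seeds <- seeds[order(corr[seeds], decreasing = TRUE)]
    }
  }

  corr_v <- as.numeric(corr)
  vox <- function(p) {     # nearest voxel (1-based triplet) of position p
    pmin(pmax(round(p) + 1L, 1L), dims)
  }
  axis_at <- function(v) {
    ai <- axisIndex[v[1], v[2], v[3]]
    if (ai == 0L) return(NULL)
    axes[ai, ]
  }
  march <- function(start, dir) {
    pts <- list()
    p <- start
    d <- dir
    repeat {
      p_new <- p + d * step_size
      if (any(p_new < 0) || any(p_new > dims - 1)) break
      c_new <- .cpp_trilinear(corr_v, dims, matrix(p_new, 1))
      if (c_new < continue_threshold) break
      v <- vox(p_new)
      if (claimed[v[1], v[2], v[3]]) break
      o <- axis_at(v)
      if (is.null(o)) break
      if (sum(o * d) < 0) o <- -o
      if (sum(o * d) < cos_turn) break
      pts[[length(pts) + 1L]] <- p_new
      p <- p_new
      d <- o
    }
    pts
  }

  traces <- list()
  orients <- list()
  for (s in seeds) {
    v0 <- arrayInd(s, dims)
    if (claimed[v0[1], v0[2], v0[3]]) next
    p0 <- as.numeric(v0 - 1L)
    d0 <- axis_at(v0)
    if (is.null(d0)) next
    fwd <- march(p0, d0)
    bwd <- march(p0, -d0)
    pts <- c(rev(bwd), list(p0), fwd)
    if (length(pts) < 2L) next
    pmat <- do.call(rbind, pts)
    # claim a tube around the trace
    for (i in seq_len(nrow(pmat))) {
      vv <- sweep(claim_off, 2, round(pmat[i, ]) + 1L, `+`)
      ok <- vv[, 1] >= 1 & vv[, 1] <= dims[1] &
            vv[, 2] >= 1 & vv[, 2] <= dims[2] &
            vv[, 3] >= 1 & vv[, 3] <= dims[3]
      claimed[vv[ok, , drop = FALSE]] <- TRUE
    }
    pum <- sweep(pmat, 2, field@spacing, `*`)
    len <- sum(sqrt(rowSums((pum[-1, , drop = FALSE] -
                             pum[-nrow(pum), , drop = FALSE])^2)))
    if (len < min_length) next
    steps <- pum[-1, , drop = FALSE] - pum[-nrow(pum), , drop = FALSE]
    M <- crossprod(steps)
    o <- eigen(M, symmetric = TRUE)$vectors[, 1]
    if (o[1] < 0 || (o[1] == 0 && o[2] < 0)) o <- -o
    traces[[length(traces) + 1L]] <- pum
    orients[[length(orients) + 1L]] <- o
  }

  n <- length(traces)
  cls <- factor(rep("unclassified", n),
                levels = c("circular", "diagonal", "longitudinal",
                           "dorsoventral", "unclassified"))
  new("FiberSet", traces = traces,
      orientations = if (n) do.call(rbind, orients) else
        matrix(numeric(0), 0, 3),
      lengths = if (n) vapply(traces, function(p)
        sum(sqrt(rowSums((p[-1, , drop = FALSE] -
                          p[-nrow(p), , drop = FALSE])^2))), numeric(1))
        else numeric(0),
      classes = cls,
      params = list(seed_threshold = seed_threshold,
                    continue_threshold = continue_threshold,
                    step_size = step_size, min_length = min_length,
                    turn_limit = turn_limit, template = field@template))
}

#' Classify fiber orientations against a body frame
#'
#' Assigns each fiber to an anatomical orientation class from its mean axis
#' and an orthonormal body frame (rows AP, ML, DV in `(z, y, x)` components):
#' fibers within 30 degrees of the DV axis are dorsoventral; the rest are
#' classified by the angle phi of their projection onto the AP-ML tangent
#' plane to the AP axis — longitudinal below 30 degrees, diagonal in
#' [30, 60), circular at or above 60. Classes are invariant under axis flips
#' (AP and -AP are the same axis).
#'
#' @param fibers a [FiberSet-class].
#' @param body_frame 3x3 matrix with rows AP, ML, DV (orthonormal).
#' @return The [FiberSet-class] with classes filled in.
#' @export
classifyOrientation <- function(fibers, body_frame) {
  stopifnot(is(fibers, "FiberSet"))
  body_frame <- as.matrix(body_frame)
  if (max(abs(crossprod(t(body_frame)) - diag(3))) > 1e-6)
    stop("body_frame must be orthonormal (rows AP, ML, DV)")
  lv <- levels(fibers@classes)
  n <- length(fibers@traces)
  if (n == 0L) return(fibers)
  cls <- character(n)
  for (i in seq_len(n)) {
    o <- fibers@orientations[i, ]
    cdv <- abs(sum(o * body_frame[3, ]))
    if (acos(pmin(1, cdv)) * 180 / pi < 30) {
      cls[i] <- "dorsoventral"
    } else {
      ap <- abs(sum(o * body_frame[1, ]))
      ml <- abs(sum(o * body_frame[2, ]))
      phi <- atan2(ml, ap) * 180 / pi
      cls[i] <- if (phi < 30) "longitudinal"
                else if (phi < 60) "diagonal" else "circular"
    }
  }
  fibers@classes <- factor(cls, levels = lv)
  fibers
}

#' Per-region fiber census
#'
#' Counts fibers whose arc-length midpoint lies inside a region box and
#' reports count and proportion per orientation class (proportions are `NA`
#' when the region holds no fibers).
#'
#' @param fibers a [FiberSet-class] (classified).
#' @param region a [RegionBox-class], e.g. the 500 x 250 x 300 um census box.
#' @return `data.frame` with columns `class, count, proportion`.
#' @export
fiberRegionStats <- function(fibers, region) {
  stopifnot(is(fibers, "FiberSet"), is(region, "RegionBox"))
  lv <- levels(fibers@classes)
  n <- length(fibers@traces)
  inside <- logical(n)
  for (i in seq_len(n)) {
    m <- .trace_midpoint(fibers@traces[[i]])
    inside[i] <- all(m >= region@lower) && all(m < region@upper)
  }
  counts <- table(factor(as.character(fibers@classes[inside]), levels = lv))
  total <- sum(counts)
  data.frame(class = lv, count = as.integer(counts),
             proportion = if (total > 0) as.numeric(counts) / total
                          else rep(NA_real_, length(lv)))
}
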