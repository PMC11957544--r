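# Seeded synthetic phantoms with exact ground truth for every pipeline stage.
#
# Noise model (shared): signal rendered in \[0, 1\], Poisson shot noise at
# `photons` counts per unit intensity plus Gaussian read noise whose sd is set
# so the total background sd hits the requested SNR, where
# SNR = (object peak - background mean) / background sd.

.phantom_noise <- function(signal, snr, peak, photons = 50) {
  if (!is.finite(snr) || snr <= 0) return(signal)
  shot <- array(rpois(length(signal), signal * photons) / photons,
                dim(signal))
  bg_shot_sd <- 0   # background is dark; shot noise there is negligible
  target_sd <- peak / snr
  read_sd <- sqrt(max(target_sd^2 - bg_shot_sd^2, 1e-12))
  shot + array(rnorm(length(signal), 0, read_sd), dim(signal))
}

#' Synthetic nuclei volume with known ground truth
#'
#' Renders `n` spherical nuclei with Gaussian radial intensity profiles
#' (profile sd = radius / 2, so the visible blob diameter matches the nominal
#' radius) at random non-overlapping positions; a designated fraction of
#' nuclei is placed as touching pairs at a centre distance of 1.5 radii,
#' the hard case marker-based watershed must split. Poisson + Gaussian noise
#' is added to the requested SNR. Ground truth (centroids in um, radii, pair
#' membership) is returned alongside the volume.
#'
#' Defaults emulate a PI-stained planarian fragment at the cellular-imaging
#' working resolution: 1 um isotropic voxels, nucleus radii 3-5 um, SNR 10.
#'
#' @param n number of nuclei.
#' @param dim volume extents `(nz, ny, nx)` in voxels.
#' @param spacing voxel spacing in um.
#' @param radius_range min/max nucleus radius in um.
#' @param touching_fraction fraction of nuclei placed as touching pairs
#'   (an even count of nuclei is consumed by pairs).
#' @param snr peak signal-to-noise ratio; `Inf` for noise-free.
#' @param seed RNG seed (same seed and parameters give a bit-identical
#'   volume and truth).
#' @param max_tries rejection-sampling bound per object.
#' @return list with `grid` (a [VoxelGrid-class]) and `truth` (data.frame
#'   `z, y, x, radius, pair`) plus `pairs` (data.frame of pair ids).
#' @export
makeNucleiPhantom <- function(n = 500, dim = c(256, 256, 256),
                              spacing = c(1, 1, 1),
                              radius_range = c(3, 5),
                              touching_fraction = 0, snr = 10, seed = 1,
                              max_tries = 5000L) {
  stopifnot(touching_fraction >= 0, touching_fraction <= 1)
  set.seed(seed)
  d <- as.integer(dim)
  ext <- (d - 1) * spacing
  n_pair <- floor(n * touching_fraction / 2)
  n_single <- n - 2L * n_pair

  centers <- matrix(numeric(0), 0, 3)
  radii <- numeric(0)
  pair_id <- integer(0)
  margin <- max(radius_range) + 2

  too_close <- function(p, r) {
    if (nrow(centers) == 0L) return(FALSE)
    dd <- sqrt(colSums((t(centers) - p)^2))
    any(dd < radii + r + 2)
  }
  draw_point <- function(r) {
    runif(3, min = margin, max = ext - margin)
  }

  for (i in seq_len(n_single)) {
    r <- runif(1, radius_range[1], radius_range[2])
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      p <- draw_point(r)
      if (!too_close(p, r)) { ok <- TRUE; break }
    }
    if (!ok) stop("nuclei density infeasible after bounded rejection attempts")
    centers <- rbind(centers, p)
    radii <- c(radii, r)
    pair_id <- c(pair_id, 0L)
  }
  for (k in seq_len(n_pair)) {
    r <- runif(1, radius_range[1], radius_range[2])
    sep <- 1.5 * r
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      p1 <- draw_point(r)
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      p2 <- p1 + u * sep
      if (any(p2 < margin) || any(p2 > ext - margin)) next
      if (!too_close(p1, r + sep) && !too_close(p2, r + sep)) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop("nuclei density infeasible after bounded rejection attempts")
    centers <- rbind(centers, p1, p2)
    radii <- c(radii, r, r)
    pair_id <- c(pair_id, k, k)
  }

  signal <- .render_blobs(d, spacing, centers, radii)
  noisy <- .phantom_noise(signal, snr, peak = 1)
  truth <- data.frame(z = centers[, 1], y = centers[, 2], x = centers[, 3],
                      radius = radii, pair = pair_id)
  list(grid = VoxelGrid(noisy, spacing = spacing), truth = truth,
       pairs = data.frame(pair = seq_len(n_pair)))
}

# render Gaussian-profile blobs (peak 1, sd = radius/2) with local support,
# max-blended; a single function so the array is modified in place
.render_blobs <- function(d, spacing, centers, radii) {
  signal <- array(0, d)
  for (i in seq_len(nrow(centers))) {
    center <- centers[i, ]
    radius <- radii[i]
    s <- radius / 2
    reach <- ceiling((radius + 3 * s) / spacing)
    ci <- round(center / spacing)
    lo <- pmax(ci - reach, 0); hi <- pmin(ci + reach, d - 1)
    zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
    dz2 <- (zi * spacing[1] - center[1])^2
    dy2 <- (yi * spacing[2] - center[2])^2
    dx2 <- (xi * spacing[3] - center[3])^2
    blob <- exp(-(outer(outer(dz2, dy2, `+`), dx2, `+`)) / (2 * s^2))
    sub <- signal[zi + 1, yi + 1, xi + 1]
    signal[zi + 1, yi + 1, xi + 1] <- pmax(sub, blob)
  }
  signal
}

#' Synthetic fiber volume with known orientation classes
#'
#' Renders straight solid cylinders with anti-aliased edges (analytic voxel
#' coverage ramp over one voxel, matching the correlation template's edge
#' model) at orientations drawn uniformly inside each fiber's class bin with
#' respect to `body_frame`. Fibers are placed with a minimum pairwise
#' clearance between segments. Ground truth carries endpoints, axes and
#' classes.
#'
#' @param fibers data.frame with columns `class` (circular, diagonal,
#'   longitudinal, dorsoventral), `length` (um) and `radius` (um); or an
#'   integer, for that many default fibers with classes cycled.
#' @param dim,spacing volume geometry (voxels, um).
#' @param body_frame 3x3 orthonormal rows AP, ML, DV in `(z, y, x)`;
#'   default AP = x, ML = y, DV = z.
#' @param snr peak signal-to-noise ratio (`Inf` = noise-free).
#' @param min_separation minimum clearance between fiber centrelines in um
#'   (default 8).
#' @param seed RNG seed.
#' @param max_tries rejection bound per fiber.
#' @return list with `grid`, `truth` (data.frame of endpoints, axis, class).
#' @export
makeFiberPhantom <- function(fibers = 50, dim = c(160, 160, 160),
                             spacing = c(1, 1, 1), body_frame = NULL,
                             snr = 5, min_separation = 8, seed = 1,
                             max_tries = 2000L) {
  set.seed(seed)
  if (is.numeric(fibers) && length(fibers) == 1L) {
    cls <- rep(c("circular", "diagonal", "longitudinal", "dorsoventral"),
               length.out = fibers)
    fibers <- data.frame(class = cls, length = 60, radius = 2)
  }
  d <- as.integer(dim)
  ext <- (d - 1) * spacing
  if (is.null(body_frame))
    body_frame <- rbind(AP = c(0, 0, 1), ML = c(0, 1, 0), DV = c(1, 0, 0))

  segs <- list()
  draw_axis <- function(class) {
    repeat {
      # draw inside the class bin with a 5 degree margin so rendered truth is
      # unambiguous under the 30/60 degree boundaries
      if (class == "dorsoventral") {
        th <- runif(1, 0, 25)
        ph <- runif(1, 0, 360)
        base <- body_frame[3, ]; t1 <- body_frame[1, ]; t2 <- body_frame[2, ]
      } else {
        phi <- switch(class,
                      longitudinal = runif(1, 0, 25),
                      diagonal = runif(1, 35, 55),
                      circular = runif(1, 65, 90))
        th <- 90   # stay in the AP-ML tangent plane, away from DV
        ph <- phi
        base <- body_frame[3, ]; t1 <- body_frame[1, ]; t2 <- body_frame[2, ]
        a <- cos(phi * pi / 180) * t1 + sin(phi * pi / 180) * t2
        return(a / sqrt(sum(a^2)))
      }
      thr <- th * pi / 180; phr <- ph * pi / 180
      a <- cos(thr) * base +
        sin(thr) * (cos(phr) * t1 + sin(phr) * t2)
      return(a / sqrt(sum(a^2)))
    }
  }

  seg_dist <- function(p1, q1, p2, q2) {
    # minimum distance between segments [p1,q1] and [p2,q2]
    u <- q1 - p1; v <- q2 - p2; w <- p1 - p2
    a <- sum(u * u); b <- sum(u * v); cc <- sum(v * v)
    dd <- sum(u * w); e <- sum(v * w)
    den <- a * cc - b * b
    s <- if (den > 1e-12) (b * e - cc * dd) / den else 0
    t <- if (cc > 1e-12) (a * e - b * dd) / max(den, 1e-12) else 0
    s <- min(1, max(0, s)); t <- min(1, max(0, t))
    # refine clamped coordinates once
    t <- if (cc > 1e-12) min(1, max(0, (b * s + e) / cc)) else 0
    s <- if (a > 1e-12) min(1, max(0, (b * t - dd) / a)) else 0
    sqrt(sum((p1 + s * u - (p2 + t * v))^2))
  }

  truth <- NULL
  for (i in seq_len(nrow(fibers))) {
    len <- fibers$length[i]; rad <- fibers$radius[i]
    axis <- draw_axis(fibers$class[i])
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      mid <- runif(3, min = rad + 2, max = ext - rad - 2)
      p <- mid - axis * len / 2
      q <- mid + axis * len / 2
      if (any(p < rad + 1) || any(p > ext - rad - 1) ||
          any(q < rad + 1) || any(q > ext - rad - 1)) next
      clear <- TRUE
      for (sgm in segs) {
        if (seg_dist(p, q, sgm$p, sgm$q) < min_separation) {
          clear <- FALSE; break
        }
      }
      if (clear) { ok <- TRUE; break }
    }
    if (!ok) stop("fiber packing infeasible after bounded rejection attempts")
    segs[[length(segs) + 1L]] <- list(p = p, q = q, axis = axis, radius = rad)
    truth <- rbind(truth, data.frame(
      pz = p[1], py = p[2], px = p[3], qz = q[1], qy = q[2], qx = q[3],
      az = axis[1], ay = axis[2], ax = axis[3],
      length = len, radius = rad, class = fibers$class[i]))
  }

  signal <- .render_capsules(d, spacing, segs)
  noisy <- .phantom_noise(signal, snr, peak = 1)
  list(grid = VoxelGrid(noisy, spacing = spacing), truth = truth,
       body_frame = body_frame)
}

# render anti-aliased solid cylinders (radial coverage ramp of one voxel)
# along segments (lists with p, q, radius), max-blended in place;
# soft_axial = TRUE ramps the ends over one voxel exactly like the
# correlation template
.render_capsules <- function(d, spacing, segs, soft_axial = FALSE) {
  signal <- array(0, d)
  for (sgm in segs) {
    p <- sgm$p; q <- sgm$q; radius <- sgm$radius
    lo <- pmax(floor(pmin(p, q) / spacing) - ceiling(radius) - 1, 0)
    hi <- pmin(ceiling(pmax(p, q) / spacing) + ceiling(radius) + 1, d - 1)
    zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
    gz <- zi * spacing[1]; gy <- yi * spacing[2]; gx <- xi * spacing[3]
    co <- cbind(rep(gz, times = length(gy) * length(gx)),
                rep(rep(gy, each = length(gz)), times = length(gx)),
                rep(gx, each = length(gz) * length(gy)))
    u <- q - p
    L <- sqrt(sum(u^2))
    u <- u / L
    w <- sweep(co, 2, p)
    t <- as.numeric(w %*% u)
    r2 <- pmax(rowSums(w^2) - t^2, 0)
    # the linear coverage ramp carries an area excess of pi/12 per section;
    # shrinking the nominal radius to sqrt(r^2 - 1/12) cancels it exactly,
    # so rendered mass tracks pi r^2 L
    r_eff <- sqrt(max(radius^2 - 1 / 12, 1e-4))
    radial <- pmin(1, pmax(0, r_eff + 0.5 - sqrt(r2)))
    axial <- if (soft_axial) {
      pmin(1, pmax(0, L / 2 + 0.5 - abs(t - L / 2)))
    } else {
      as.numeric(t >= 0 & t <= L)
    }
    val <- array(radial * axial, c(length(zi), length(yi), length(xi)))
    sub <- signal[zi + 1, yi + 1, xi + 1]
    signal[zi + 1, yi + 1, xi + 1] <- pmax(sub, val)
  }
  signal
}

#' Synthetic body-shape volume with analytic morphometry truth
#'
#' Sphere, cube or capsule (cylinder with hemispherical caps) rendered solid
#' or as a dense field of nuclei dots filling the shape; ground truth carries
#' the closed-form volume, surface area and principal-axis length.
#'
#' @param shape `"sphere"`, `"cube"` or `"capsule"`.
#' @param dims shape parameters in um: sphere radius `r`; cube side `a`;
#'   capsule `c(r, h)` (cylinder length `h`, cap radius `r`).
#' @param dim,spacing volume geometry; defaults size the volume to fit.
#' @param fill `"solid"` or `"nuclei"`.
#' @param snr noise level for nuclei fill (`Inf` = clean).
#' @param seed RNG seed (nuclei fill only).
#' @return list with `grid` and `truth` (list `volume`, `surface_area`,
#'   `length`).
#' @export
makeBodyPhantom <- function(shape = c("sphere", "cube", "capsule"), dims,
                            dim = NULL, spacing = c(1, 1, 1),
                            fill = c("solid", "nuclei"), snr = Inf,
                            seed = 1) {
  shape <- match.arg(shape)
  fill <- match.arg(fill)
  set.seed(seed)
  pad <- 8
  truth <- switch(shape,
    sphere = {
      r <- dims[1]
      list(volume = 4 / 3 * pi * r^3, surface_area = 4 * pi * r^2,
           length = 2 * r)
    },
    cube = {
      a <- dims[1]
      list(volume = a^3, surface_area = 6 * a^2, length = a)
    },
    capsule = {
      r <- dims[1]; h <- dims[2]
      list(volume = pi * r^2 * h + 4 / 3 * pi * r^3,
           surface_area = 2 * pi * r * h + 4 * pi * r^2,
           length = h + 2 * r)
    })
  if (is.null(dim)) {
    span <- switch(shape, sphere = 2 * dims[1],
                   cube = dims[1], capsule = dims[2] + 2 * dims[1])
    dim <- as.integer(ceiling(span / spacing) + 2 * pad)
    if (shape != "capsule") dim <- rep(max(dim), 3)
    else dim <- c(max(2 * dims[1] / spacing[1] + 2 * pad),
                  max(2 * dims[1] / spacing[2] + 2 * pad),
                  dim[3]) |> ceiling() |> as.integer()
  }
  d <- as.integer(dim)
  ctr <- (d - 1) / 2 * spacing
  gz <- (seq_len(d[1]) - 1) * spacing[1] - ctr[1]
  gy <- (seq_len(d[2]) - 1) * spacing[2] - ctr[2]
  gx <- (seq_len(d[3]) - 1) * spacing[3] - ctr[3]
  # anti-aliased coverage: 1 deep inside, ramping to 0 across one voxel at
  # the surface, so rendered mass tracks the analytic volume closely
  cov01 <- function(signed_dist_inside) pmin(1, pmax(0, signed_dist_inside + 0.5))
  inside <- switch(shape,
    sphere = {
      rr <- sqrt(outer(outer(gz^2, gy^2, `+`), gx^2, `+`))
      cov01(dims[1] - rr)
    },
    cube = {
      a2 <- dims[1] / 2
      outer(outer(cov01(a2 - abs(gz) - 0.5 + 0.5),
                  cov01(a2 - abs(gy) - 0.5 + 0.5), `*`),
            cov01(a2 - abs(gx) - 0.5 + 0.5), `*`)
    },
    capsule = {
      r <- dims[1]; h <- dims[2]
      tx <- pmin(pmax(gx, -h / 2), h / 2)       # axis along x
      dx2 <- outer(rep(1, length(gz) * length(gy)), (gx - tx)^2)
      rr <- sqrt(outer(outer(gz^2, gy^2, `+`), rep(1, length(gx))) +
                 array(dx2, c(length(gz), length(gy), length(gx))))
      cov01(r - rr)
    })
  inside <- array(inside, d)
  if (fill == "solid") {
    grid <- VoxelGrid(inside, spacing = spacing)
  } else {
    # dense nuclei fill: a jittered 3 um lattice of Gaussian dots, emulating
    # the near space-filling packing of PI-stained tissue
    step <- 3
    lat <- expand.grid(z = seq(0, (d[1] - 1) * spacing[1], by = step),
                       y = seq(0, (d[2] - 1) * spacing[2], by = step),
                       x = seq(0, (d[3] - 1) * spacing[3], by = step))
    lat <- as.matrix(lat) + matrix(runif(3 * nrow(lat), -0.8, 0.8),
                                   ncol = 3)
    vi <- round(sweep(lat, 2, spacing, `/`)) + 1
    ok <- vi[, 1] >= 1 & vi[, 1] <= d[1] & vi[, 2] >= 1 & vi[, 2] <= d[2] &
          vi[, 3] >= 1 & vi[, 3] <= d[3]
    lat <- lat[ok, , drop = FALSE]; vi <- vi[ok, , drop = FALSE]
    # nucleus centres sit inside the tissue, at least one nucleus radius
    # deep, so the stained surface coincides with the nominal body surface
    depth <- array(.cpp_edt(as.logical(inside >= 0.5), d, spacing), d)
    keep <- depth[cbind(vi[, 1], vi[, 2], vi[, 3])] >= 1.5
    cpos <- lat[keep, , drop = FALSE]
    signal <- .render_blobs(d, spacing, cpos, rep(3, nrow(cpos)))
    noisy <- .phantom_noise(signal, snr, peak = 1)
    grid <- VoxelGrid(noisy, spacing = spacing)
  }
  list(grid = grid, truth = truth)
}

#' Synthetic allometry table with a known scaling law
#'
#' Generates per-animal (cell count, neuron count, brain-neuron count) rows
#' following a one- or two-segment linear relation between total cell count
#' and neuron count, with multiplicative log-normal-style noise. Used to
#' validate [fitScaling()] breakpoint recovery and ratio summaries.
#'
#' @param n_samples number of animals.
#' @param slopes per-segment neuron-per-cell slopes (length 1 or 2).
#' @param intercepts per-segment intercepts (recycled; default 0).
#' @param breakpoint cell count splitting the segments (`NULL` for a single
#'   segment); the second segment's intercept is adjusted for continuity at
#'   the breakpoint.
#' @param cell_range range of cell counts sampled (uniform).
#' @param brain_fraction brain neurons as a fraction of neurons (default 0.3).
#' @param noise_cv multiplicative coefficient of variation.
#' @param seed RNG seed.
#' @return `data.frame(cells, neurons, brain_neurons)` with
#'   `attr(, "truth")` recording the generating parameters.
#' @export
makeAllometryTable <- function(n_samples = 100, slopes = c(0.10, 0.05),
                               intercepts = 0, breakpoint = 5e5,
                               cell_range = c(5e4, 2e6),
                               brain_fraction = 0.3, noise_cv = 0.05,
                               seed = 1) {
  set.seed(seed)
  cells <- sort(runif(n_samples, cell_range[1], cell_range[2]))
  if (is.null(breakpoint) || length(slopes) == 1L) {
    mu <- intercepts[1] + slopes[1] * cells
    truth <- list(slopes = slopes[1], intercepts = intercepts[1],
                  breakpoint = NA_real_)
  } else {
    b2 <- intercepts[1] + slopes[1] * breakpoint - slopes[2] * breakpoint
    mu <- ifelse(cells <= breakpoint,
                 intercepts[1] + slopes[1] * cells,
                 b2 + slopes[2] * cells)
    truth <- list(slopes = slopes, intercepts = c(intercepts[1], b2),
                  breakpoint = breakpoint)
  }
  neurons <- mu * (1 + rnorm(n_samples, 0, noise_cv))
  brain <- neurons * brain_fraction * (1 + rnorm(n_samples, 0, noise_cv))
  out <- data.frame(cells = cells, neurons = neurons, brain_neurons = brain)
  attr(out, "truth") <- truth
  out
}
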