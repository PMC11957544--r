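# Internal helpers shared across modules.

.dims <- function(grid) as.integer(dim(grid@data))

.as_numeric_vec <- function(grid) as.numeric(grid@data)

# sampled Gaussian kernel (order 0, 1, 2 derivatives), normalised so that the
# 0th-order kernel sums to 1 and derivative kernels annihilate/reproduce the
# corresponding monomials exactly on the grid
.gauss_kernel <- function(sigma, order = 0L) {
  if (sigma <= 0) {
    if (order == 0L) return(1)
    stop("derivative kernels need sigma > 0")
  }
  r <- max(1L, ceiling(4 * sigma))
  k <- seq(-r, r)
  g <- exp(-k^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0L) return(g)
  if (order == 1L) {
    # correlation kernel for d/dx: response to the ramp f(x) = x is exactly 1
    d <- k / sigma^2 * g
    d <- d / sum(d * k)
    return(d)
  }
  if (order == 2L) {
    d <- (k^2 - sigma^2) / sigma^4 * g
    d <- d - mean(d)                  # zero response to constants
    d <- d / (sum(d * k^2) / 2)       # response 1 to x^2/2, i.e. f'' of x^2 is 2
    return(d)
  }
  stop("order must be 0, 1 or 2")
}

# separable correlation along the three axes with per-axis kernels (NULL or
# length-1 kernels skip the axis); reflective boundaries
.sep_filter <- function(arr, kz = NULL, ky = NULL, kx = NULL) {
  dims <- as.integer(dim(arr))
  v <- as.numeric(arr)
  kern <- list(kz, ky, kx)
  for (ax in 0:2) {
    k <- kern[[ax + 1L]]
    if (is.null(k) || length(k) == 1L && isTRUE(all.equal(as.numeric(k), 1)))
      next
    v <- .cpp_correlate_axis(v, dims, as.numeric(k), ax)
  }
  array(v, dims)
}

.norm01 <- function(x) {
  r <- range(x)
  if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else x * 0
}

# voxel-centre physical coordinates along one axis (1-based index i -> um)
.axis_coords <- function(n, sp) (seq_len(n) - 1) * sp

# centroids of labelled voxels in um; labels: integer array, K = label count
.label_centroids <- function(labels, K, spacing) {
  dims <- dim(labels)
  idx <- which(labels > 0)
  lab <- labels[idx]
  zi <- (idx - 1) %% dims[1]
  yi <- ((idx - 1) %/% dims[1]) %% dims[2]
  xi <- (idx - 1) %/% (dims[1] * dims[2])
  cbind(z = tapply(zi, lab, mean) * spacing[1],
        y = tapply(yi, lab, mean) * spacing[2],
        x = tapply(xi, lab, mean) * spacing[3])[seq_len(K), , drop = FALSE]
}

.trace_midpoint <- function(pts) {
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                       pts[-nrow(pts), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  half <- cum[length(cum)] / 2
  i <- findInterval(half, cum, rightmost.closed = TRUE)
  if (i >= nrow(pts)) return(pts[nrow(pts), ])
  t <- if (seg[i] > 0) (half - cum[i]) / seg[i] else 0
  pts[i, ] + t * (pts[i + 1, ] - pts[i, ])
}

# stable 31-bit string hash for per-stage seed fan-out
.stable_hash <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

.claim_ball_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  g <- g[g$dz^2 + g$dy^2 + g$dx^2 <= radius^2, , drop = FALSE]
  as.matrix(g)
}

.is_binary <- function(grid) {
  is.logical(grid@data) || all(grid@data %in% c(0, 1))
}

.binary_array <- function(grid) {
  # anti-aliased coverage fields voxelise at the half-coverage level
  if (is.logical(grid@data)) grid@data else grid@data >= 0.5
}
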