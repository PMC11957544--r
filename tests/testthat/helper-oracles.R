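# Shared fixtures and independent oracles used across the suite.

# digital ball mask: voxel centres within radius r of the volume centre
make_digital_sphere <- function(r, pad = 5) {
  n <- 2 * r + 2 * pad
  cc <- (n - 1) / 2
  co <- expand.grid(z = 0:(n - 1), y = 0:(n - 1), x = 0:(n - 1))
  array((co$z - cc)^2 + (co$y - cc)^2 + (co$x - cc)^2 <= r^2, c(n, n, n))
}

# isotropic Gaussian blob, peak 1, sd s voxels, centred mid-volume
make_gaussian_blob <- function(n, s) {
  c0 <- (n - 1) / 2
  co <- expand.grid(z = 0:(n - 1), y = 0:(n - 1), x = 0:(n - 1))
  array(exp(-((co$z - c0)^2 + (co$y - c0)^2 + (co$x - c0)^2) / (2 * s^2)),
        c(n, n, n))
}

label_at <- function(labels, p_um, spacing = c(1, 1, 1)) {
  v <- round(p_um / spacing) + 1
  voxelData(labels)[v[1], v[2], v[3]]
}

# fraction of designated touching pairs assigned two distinct nonzero labels
pair_split_fraction <- function(labels, truth) {
  pairs <- split(seq_len(nrow(truth)), truth$pair)
  pairs <- pairs[names(pairs) != "0"]
  ok <- vapply(pairs, function(ix) {
    l1 <- label_at(labels, as.numeric(truth[ix[1], 1:3]))
    l2 <- label_at(labels, as.numeric(truth[ix[2], 1:3]))
    l1 != 0 && l2 != 0 && l1 != l2
  }, logical(1))
  mean(ok)
}

# brute-force priority flood: an independent R implementation of
# marker-driven watershed (linear scans instead of a heap; same
# lowest-value-first rule with first-queued tie-breaking)
watershed_oracle <- function(landscape, markers, mask, connectivity = 6) {
  d <- dim(mask)
  nb <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, , drop = FALSE]
  if (connectivity == 6) nb <- nb[rowSums(abs(nb)) == 1, , drop = FALSE]
  labels <- array(0L, d)
  q_idx <- integer(0); q_val <- numeric(0); q_ord <- integer(0)
  ord <- 0L
  push <- function(i) {
    ord <<- ord + 1L
    q_idx <<- c(q_idx, i); q_val <<- c(q_val, landscape[i])
    q_ord <<- c(q_ord, ord)
  }
  for (i in which(markers > 0 & mask)) {
    labels[i] <- markers[i]
    push(i)
  }
  while (length(q_idx)) {
    pick <- order(q_val, q_ord)[1]
    i <- q_idx[pick]
    q_idx <- q_idx[-pick]; q_val <- q_val[-pick]; q_ord <- q_ord[-pick]
    v <- arrayInd(i, d)
    for (k in seq_len(nrow(nb))) {
      w <- v + nb[k, ]
      if (any(w < 1) || any(w > d)) next
      j <- w[1] + d[1] * ((w[2] - 1) + d[2] * (w[3] - 1))
      if (!mask[j] || labels[j] != 0L) next
      labels[j] <- labels[i]
      push(j)
    }
  }
  labels
}

# direct cylinder-template correlation at one voxel: explicit rotated
# coordinates and stats::cor, independent of the C++ accumulation path
cylinder_corr_oracle <- function(arr, v0, axes, length., outer_radius,
                                 mask_radius) {
  reach <- ceiling(sqrt((length. / 2)^2 + (mask_radius + 0.5)^2) + 0.5)
  g <- expand.grid(dz = -reach:reach, dy = -reach:reach, dx = -reach:reach)
  best <- 0
  for (a in seq_len(nrow(axes))) {
    t <- g$dz * axes[a, 1] + g$dy * axes[a, 2] + g$dx * axes[a, 3]
    r <- sqrt(pmax(0, g$dz^2 + g$dy^2 + g$dx^2 - t^2))
    keep <- abs(t) <= length. / 2 + 0.5 & r <= mask_radius + 0.5
    tv <- (pmin(1, pmax(0, outer_radius + 0.5 - r)) *
           pmin(1, pmax(0, length. / 2 + 0.5 - abs(t))))[keep]
    iv <- arr[cbind(v0[1] + g$dz[keep] + 1, v0[2] + g$dy[keep] + 1,
                    v0[3] + g$dx[keep] + 1)]
    if (stats::sd(iv) > 1e-10) best <- max(best, stats::cor(tv, iv))
  }
  best
}

expect_rel_error <- function(value, truth, tol) {
  expect_lt(abs(value - truth) / abs(truth), tol)
}
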