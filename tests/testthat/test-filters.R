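test_that("gaussian smoothing is mass-preserving and handles edge cases", {
  g <- VoxelGrid(array(0, c(21, 21, 21)))
  g@data[11, 11, 11] <- 1
  sm <- gaussianSmooth(g, 2)
  expect_lt(abs(sum(voxelData(sm)) - 1), 1e-6)  # discrete kernel mass

  cst <- VoxelGrid(array(3.7, c(10, 10, 10)))
  expect_equal(voxelData(gaussianSmooth(cst, 1.5)), voxelData(cst))

  a <- array(runif(1000), c(10, 10, 10))
  expect_identical(voxelData(gaussianSmooth(VoxelGrid(a), 0)), a)
  expect_error(gaussianSmooth(VoxelGrid(a), -1), ">= 0")
})

test_that("gaussian smoothing acts in physical units on anisotropic grids", {
  # an impulse smoothed with sigma 2 um on a (2, 1, 1) um grid must spread
  # half as many voxels along z as along y/x
  g <- VoxelGrid(array(0, c(21, 21, 21)), spacing = c(2, 1, 1))
  g@data[11, 11, 11] <- 1
  sm <- voxelData(gaussianSmooth(g, 2))
  prof_z <- sm[, 11, 11]; prof_y <- sm[11, , 11]
  sd_z <- sqrt(sum(prof_z * (seq_len(21) - 11)^2) / sum(prof_z))
  sd_y <- sqrt(sum(prof_y * (seq_len(21) - 11)^2) / sum(prof_y))
  expect_equal(sd_z, 1, tolerance = 0.05)
  expect_equal(sd_y, 2, tolerance = 0.05)
})

test_that("diffusion conserves intensity, rejects unstable steps, preserves edges", {
  set.seed(1)
  g <- VoxelGrid(array(runif(16^3), c(16, 16, 16)))
  out <- anisotropicDiffusion(g, n_iterations = 8, kappa = 0.2)
  expect_lt(abs(sum(voxelData(out)) - sum(voxelData(g))) / sum(voxelData(g)),
            1e-6)
  cst <- VoxelGrid(array(2, c(8, 8, 8)))
  expect_equal(voxelData(anisotropicDiffusion(cst, 5)), voxelData(cst))
  expect_error(anisotropicDiffusion(g, 5, kappa = 0.2, lambda = 0.5),
               "stability")
  expect_error(anisotropicDiffusion(g, 0), "n_iterations")

  # a step edge of height 10*kappa survives diffusion better than a Gaussian
  # blur matched to equal background variance reduction
  set.seed(2)
  kappa <- 0.05
  step <- array(0, c(20, 20, 20))
  step[, , 11:20] <- 10 * kappa     # edge across x between slabs 10 and 11
  noisy <- step + array(rnorm(8000, 0, 0.02), c(20, 20, 20))
  gd <- anisotropicDiffusion(VoxelGrid(noisy), 10, kappa = kappa)
  # against the most favourable Gaussian (the sigma minimising background
  # variance), diffusion both denoises at least as well and keeps the edge
  # sharper
  bg_var <- function(a) var(as.numeric(a[, , 1:8]))
  sigmas <- seq(0.2, 2, by = 0.2)
  vars <- vapply(sigmas, function(s)
    bg_var(voxelData(gaussianSmooth(VoxelGrid(noisy), s))), numeric(1))
  gb <- gaussianSmooth(VoxelGrid(noisy), sigmas[which.min(vars)])
  edge_grad <- function(a) mean(abs(a[, , 11] - a[, , 10]))
  expect_lte(bg_var(voxelData(gd)), min(vars))
  expect_gte(edge_grad(voxelData(gd)), edge_grad(voxelData(gb)))
})

test_that("unsharp masking boosts mid frequencies and respects its bounds", {
  a <- array(runif(1000), c(10, 10, 10))
  expect_identical(voxelData(unsharpMask3D(VoxelGrid(a), 2, 0)), a)
  cst <- VoxelGrid(array(1.5, c(10, 10, 10)))
  expect_equal(voxelData(unsharpMask3D(cst, 2, 1)), voxelData(cst))

  # sinusoid of period 8*sigma gains amplitude
  sigma <- 1.5
  n <- 48
  x <- sin(2 * pi * (0:(n - 1)) / (8 * sigma))
  a <- array(rep(x, each = 64), c(8, 8, n))
  out <- voxelData(unsharpMask3D(VoxelGrid(a), sigma, 1))
  core <- 13:36
  expect_gt(diff(range(out[4, 4, core])), diff(range(a[4, 4, core])) * 1.05)
})

test_that("edge enhancement is a clamped band-pass", {
  cst <- VoxelGrid(array(5, c(12, 12, 12)))
  expect_true(all(voxelData(edgeEnhance(cst, 1, 3)) == 0))
  set.seed(3)
  a <- array(runif(16^3), c(16, 16, 16))
  out <- voxelData(edgeEnhance(VoxelGrid(a), 1, 2.5))
  expect_true(all(out >= 0))
  expect_error(edgeEnhance(VoxelGrid(a), 2, 1), "outer_sigma")

  # a blob at the matched scale outranks an isolated hot voxel
  blob <- make_gaussian_blob(25, 2.5)
  img <- blob
  img[4, 4, 4] <- 1   # hot voxel
  r <- voxelData(edgeEnhance(VoxelGrid(img), 2.5, 5))
  expect_gt(max(r[9:17, 9:17, 9:17]), r[4, 4, 4] * 1.5)
})

test_that("smoothing filters are equivariant under 90-degree rotations", {
  set.seed(4)
  a <- array(runif(12^3), c(12, 12, 12))
  rot <- function(x) aperm(x[, , dim(x)[3]:1], c(3, 2, 1))  # 90 deg z<->x
  f1 <- voxelData(gaussianSmooth(VoxelGrid(rot(a)), 1.2))
  f2 <- rot(voxelData(gaussianSmooth(VoxelGrid(a), 1.2)))
  expect_equal(f1, f2, tolerance = 1e-12)
  d1 <- voxelData(anisotropicDiffusion(VoxelGrid(rot(a)), 4, kappa = 0.2))
  d2 <- rot(voxelData(anisotropicDiffusion(VoxelGrid(a), 4, kappa = 0.2)))
  expect_equal(d1, d2, tolerance = 1e-12)
})
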