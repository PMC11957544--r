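test_that("VoxelGrid enforces its geometric invariants", {
  expect_error(VoxelGrid(array(0, c(4, 4)), c(1, 1, 1)), "3D")
  expect_error(VoxelGrid(array(0, c(4, 4, 4)), c(0, 1, 1)), "positive")
  expect_error(VoxelGrid(array(0, c(4, 4, 4)), expansion = 0.5), "expansion")
  g <- VoxelGrid(array(1, c(2, 3, 4)), spacing = 0.5, expansion = 4)
  expect_equal(dim(g), c(2L, 3L, 4L))
  expect_equal(voxelSpacing(g), c(0.5, 0.5, 0.5))
})

test_that("integer volumes round-trip bit exactly with their metadata", {
  d <- c(7, 12, 9)
  for (bits in c(8, 16)) {
    vals <- array(sample.int(2^bits, prod(d), replace = TRUE) - 1L, d)
    g <- VoxelGrid(vals + 0, spacing = c(2.5, 0.8, 0.8), expansion = 4)
    f <- tempfile(fileext = ".tif")
    writeVolume(g, f)
    r <- readVolume(f)
    expect_identical(voxelData(r), vals + 0)
    expect_equal(voxelSpacing(r), c(2.5, 0.8, 0.8))
    expect_equal(expansionFactor(r), 4)
    sc <- yaml::read_yaml(paste0(f, ".yml"))
    expect_equal(sc$bits, bits)   # no silent type promotion
  }
})

test_that("float volumes round-trip through the 32-bit path", {
  g <- VoxelGrid(array(rnorm(8 * 9 * 10), c(8, 9, 10)))
  f <- tempfile(fileext = ".tif")
  writeVolume(g, f)
  r <- readVolume(f)
  expect_lt(max(abs(voxelData(r) - voxelData(g))),
            1e-6 * diff(range(voxelData(g))))
})

test_that("reading resolves metadata precedence and degenerate stacks", {
  g <- VoxelGrid(array(round(runif(100, 0, 99)), c(1, 10, 10)))
  f <- tempfile(fileext = ".tif")
  writeVolume(g, f)
  one <- readVolume(f, spacing = c(1, 1, 1))   # explicit == stored: silent
  expect_equal(dim(one)[1], 1L)
  expect_warning(r2 <- readVolume(f, spacing = c(2, 1, 1)), "overrides")
  expect_equal(voxelSpacing(r2), c(2, 1, 1))
  file.remove(paste0(f, ".yml"))
  expect_warning(r3 <- readVolume(f), "assuming 1 um")
  expect_equal(voxelSpacing(r3), c(1, 1, 1))
  expect_error(readVolume(tempfile()), "no such file")
})

test_that("a directory of per-slice TIFFs reads as one stack", {
  d <- tempfile("slices_")
  dir.create(d)
  vals <- lapply(1:4, function(z) matrix((z * 10 + 0:11) / 255, 3, 4))
  for (z in 1:4)
    tiff::writeTIFF(vals[[z]], file.path(d, sprintf("slice_%02d.tif", z)),
                    bits.per.sample = 8L)
  yaml::write_yaml(list(spacing = c(2.5, 0.8, 0.8), expansion = 4, bits = 8L),
                   paste0(d, ".yml"))
  g <- readVolume(d)
  expect_equal(dim(g), c(4L, 3L, 4L))
  expect_equal(voxelSpacing(g), c(2.5, 0.8, 0.8))
  expect_equal(g@data[2, 1, 1], round(vals[[2]][1, 1] * 255))
})

test_that("resampling halves a grid cleanly and respects byte budgets", {
  a <- array(runif(40^3), c(40, 40, 40))
  g <- VoxelGrid(a, spacing = 1)
  r <- resampleVolume(g, spacing = 2)
  expect_equal(dim(r), c(20L, 20L, 20L))
  expect_equal(voxelSpacing(r), c(2, 2, 2))
  expect_equal(voxelData(r)[1, 1, 1], a[1, 1, 1])  # grid-aligned samples

  cst <- resampleVolume(VoxelGrid(array(7, c(12, 12, 12))), spacing = 3)
  expect_true(all(voxelData(cst) == 7))   # linear interp preserves constants

  budget <- 4 * 40^3 / 2   # half the 32-bit byte size: f = 2^(1/3)
  rb <- resampleVolume(g, budget = budget)
  expect_equal(dim(rb), rep(floor(40 / 2^(1 / 3)), 3))
  expect_lte(4 * prod(dim(rb)), budget)
  expect_error(resampleVolume(g, spacing = 0.5), "downsampling")
})

test_that("crop keeps voxel centres in the half-open box", {
  a <- array(runif(20^3), c(20, 20, 20))
  g <- VoxelGrid(a)
  full <- cropVolume(g, RegionBox(c(0, 0, 0), c(20, 20, 20)))
  expect_identical(voxelData(full), a)

  sub <- cropVolume(g, RegionBox(c(0, 0, 0), c(10, 5, 20)))
  expect_equal(dim(sub), c(10L, 5L, 20L))

  b1 <- cropVolume(g, RegionBox(c(0, 0, 0), c(12, 20, 20)))
  b2 <- cropVolume(g, RegionBox(c(12, 0, 0), c(20, 20, 20)))
  expect_equal(prod(dim(b1)) + prod(dim(b2)), prod(dim(g)))
  expect_error(cropVolume(g, RegionBox(c(100, 0, 0), c(110, 5, 5))),
               "intersect")
})

test_that("crop of a unit-spaced grid realises the census-box dimensions", {
  g <- VoxelGrid(array(0, c(40, 30, 20)))
  box <- RegionBox(c(0, 0, 0), c(30, 25, 15))
  expect_equal(dim(cropVolume(g, box)), c(30L, 25L, 15L))
})

test_that("effective resolution reproduces the printed expansion arithmetic", {
  expect_equal(effectiveResolution(5, 4), 1.25)
  expect_equal(effectiveResolution(2, 4), 0.5)
  expect_equal(effectiveResolution(c(2, 2, 5), 1), c(2, 2, 5))
  # homogeneity
  r <- c(2, 2, 5)
  expect_equal(effectiveResolution(3 * r, 4.5), 3 * effectiveResolution(r, 4.5))
  expect_error(effectiveResolution(c(-1, 2), 4), "positive")
})

test_that("resample and crop commute on box-aligned grids", {
  a <- array(runif(24^3), c(24, 24, 24))
  g <- VoxelGrid(a, spacing = 1)
  box <- RegionBox(c(0, 0, 0), c(12, 24, 24))
  rc <- cropVolume(resampleVolume(g, spacing = 2),
                   RegionBox(c(0, 0, 0), c(12, 24, 24)))
  cr <- resampleVolume(cropVolume(g, box), spacing = 2)
  expect_equal(dim(rc), dim(cr))
  expect_lt(max(abs(voxelData(rc) - voxelData(cr))), 1e-6)
})
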