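test_that("binarize thresholds explicitly and via Otsu", {
  a <- array(runif(4000), c(20, 20, 10))
  b <- binarize(VoxelGrid(a), 0.5)
  expect_identical(voxelData(b), a >= 0.5)
  expect_equal(b@meta$threshold, 0.5)

  z <- binarize(VoxelGrid(array(0, c(5, 5, 5))), 0.5)
  expect_false(any(voxelData(z)))

  set.seed(6)
  mix <- c(rnorm(6000, 0.2, 0.05), rnorm(2000, 0.8, 0.05))
  g <- VoxelGrid(array(mix, c(20, 20, 20)))
  expect_message(bo <- binarize(g), "Otsu")
  expect_gt(bo@meta$threshold, 0.35)
  expect_lt(bo@meta$threshold, 0.65)
  expect_error(binarize(VoxelGrid(array(1, c(4, 4, 4)))), "constant")
})

test_that("small-spot removal respects the size boundary convention", {
  m <- array(FALSE, c(20, 20, 20))
  m[2:6, 2, 2] <- TRUE              # 5 voxels
  m[10:19, 10, 10] <- TRUE          # 10 voxels
  g <- VoxelGrid(m)
  out <- voxelData(removeSmallSpots(g, 10))
  expect_false(any(out[2:6, 2, 2]))
  expect_true(all(out[10:19, 10, 10]))   # exactly min_voxels is retained

  count_components <- function(x) {
    attr(voxcensus:::.cpp_label_components(as.logical(x), dim(x), 26L),
         "n_labels")
  }
  set.seed(7)
  r <- array(runif(8000) > 0.7, c(20, 20, 20))
  for (mv in c(1, 3, 9)) {
    expect_lte(count_components(voxelData(removeSmallSpots(VoxelGrid(r), mv))),
               count_components(r))
  }
})

test_that("hole filling fills interior cavities but not border concavities", {
  m <- array(TRUE, c(12, 12, 12))
  m[6, 6, 6:8] <- FALSE              # 3-voxel internal cavity
  filled <- voxelData(fillSmallHoles(VoxelGrid(m), 10))
  expect_true(all(filled))

  m2 <- array(TRUE, c(12, 12, 12))
  m2[1:3, 6, 6] <- FALSE             # border-touching notch
  out2 <- voxelData(fillSmallHoles(VoxelGrid(m2), 10))
  expect_false(any(out2[1:3, 6, 6]))

  sphere <- make_digital_sphere(5)
  expect_identical(voxelData(fillSmallHoles(VoxelGrid(sphere), 50)), sphere)
})

test_that("watershed splits touching spheres near the equidistance plane", {
  n <- c(48, 32, 32)
  co <- expand.grid(z = 0:(n[1] - 1), y = 0:(n[2] - 1), x = 0:(n[3] - 1))
  c1 <- c(16, 16, 16); c2 <- c(28, 16, 16)   # r = 8, centres 12 = 16*0.75
  m <- array((co$z - c1[1])^2 + (co$y - c1[2])^2 + (co$x - c1[3])^2 <= 64 |
             (co$z - c2[1])^2 + (co$y - c2[2])^2 + (co$x - c2[3])^2 <= 64, n)
  lab <- watershedLabel(VoxelGrid(m))
  expect_equal(nLabels(lab), 2L)
  arr <- voxelData(lab)
  expect_true(arr[17, 17, 17] != arr[29, 17, 17])
  # the interface sits within one voxel of the equidistance plane z = 22
  border_z <- range(which(apply(arr == arr[17, 17, 17], 1, any)))
  expect_lte(abs(border_z[2] - 1 - 22), 1)
  # supports partition the foreground
  expect_equal(sum(arr > 0), sum(m))
  expect_equal(sort(unique(as.numeric(arr))), c(0, 1, 2))

  single <- make_digital_sphere(6)
  l1 <- watershedLabel(VoxelGrid(single))
  expect_equal(nLabels(l1), 1L)
  expect_equal(sum(voxelData(l1) > 0), sum(single))
  expect_error(watershedLabel(VoxelGrid(array(FALSE, c(4, 4, 4)))), "empty")
})

test_that("watershed agrees with a brute-force priority-flood oracle", {
  set.seed(8)
  n_agree <- 0
  for (case in 1:100) {
    d <- sample(3:6, 3, replace = TRUE)
    mask <- array(runif(prod(d)) > 0.35, d)
    if (!any(mask) || all(mask)) next
    land <- array(round(runif(prod(d)), 2), d)   # coarse values: exercise ties
    mk <- array(0L, d)
    seeds <- which(mask)
    k <- min(length(seeds), sample(1:3, 1))
    mk[sample(seeds, k)] <- seq_len(k)
    ours <- voxcensus:::.cpp_watershed(as.numeric(land), as.integer(mk),
                                       as.logical(mask), as.integer(d), 6L)
    oracle <- watershed_oracle(land, mk, mask, 6)
    expect_identical(array(as.integer(ours), d), oracle)
    n_agree <- n_agree + 1
  }
  expect_gte(n_agree, 80)   # at least this many non-degenerate cases ran
})

test_that("label censuses assign regions by centroid and sum correctly", {
  ph <- makeNucleiPhantom(n = 30, dim = c(96, 96, 96), snr = Inf, seed = 9)
  res <- countNuclei(ph$grid)
  expect_equal(nrow(res$table), 30)
  expect_equal(sum(res$table$voxels), sum(voxelData(res$labels) > 0))
  expect_equal(res$table$volume_um3, res$table$voxels * 1)

  r1 <- RegionBox(c(0, 0, 0), c(48, 96, 96), "head")
  r2 <- RegionBox(c(48, 0, 0), c(96, 96, 96), "body")
  tab <- countLabels(res$labels, list(r1, r2))
  expect_equal(sum(tab$region == "head") + sum(tab$region == "body"), 30)
  tot <- attr(tab, "region_totals")
  expect_equal(sum(tot$n), 30)

  overlap <- RegionBox(c(0, 0, 0), c(96, 96, 96))
  expect_error(countLabels(res$labels, list(r1, overlap)), "overlap")
  expect_equal(nrow(countLabels(res$labels, list(r1, overlap),
                                priority = TRUE)), 30)

  empty <- new("LabelGrid", data = array(0L, c(4, 4, 4)),
               spacing = c(1, 1, 1), expansion = 1, nLabels = 0L)
  expect_equal(nrow(countLabels(empty)), 0)
})

test_that("counting survives intensity rescaling and rotation of the phantom", {
  ph <- makeNucleiPhantom(n = 15, dim = c(80, 80, 80), snr = 10, seed = 10)
  base <- nrow(countNuclei(ph$grid)$table)
  resc <- VoxelGrid(2.5 * voxelData(ph$grid) + 0.3)
  expect_equal(nrow(countNuclei(resc)$table), base)
  rot <- VoxelGrid(aperm(voxelData(ph$grid)[, , 80:1], c(3, 2, 1)))
  expect_equal(nrow(countNuclei(rot)$table), base)
})
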