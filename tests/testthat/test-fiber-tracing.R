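test_that("orientation sets cover the hemisphere without antipodal pairs", {
  ax90 <- makeOrientationSet(90)
  expect_equal(nrow(ax90), 3)
  expect_true(all(abs(abs(ax90) - diag(3)[, c(1, 2, 3)]) < 1e-9 |
                  abs(ax90) < 1e-9))   # the three coordinate axes

  set.seed(14)
  v <- matrix(rnorm(3000), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  for (step in c(10, 20)) {
    ax <- makeOrientationSet(step)
    worst <- max(vapply(seq_len(nrow(v)), function(i)
      min(acos(pmin(1, abs(ax %*% v[i, ]))) * 180 / pi), numeric(1)))
    expect_lte(worst, step)
    dots <- ax %*% t(ax)
    ang <- acos(pmin(pmax(dots, -1), 1))   # keeps matrix shape
    expect_gt(min(180 - ang[upper.tri(ang)] * 180 / pi), 1)  # no antipodes
  }
  expect_error(makeOrientationSet(0), "degrees")
  expect_error(makeOrientationSet(120), "degrees")
})

test_that("a rendered template self-matches at correlation 1", {
  axset <- makeOrientationSet(5)
  a <- axset[101, ]
  n <- c(40, 40, 40); ctr <- c(20, 20, 20)
  sig <- voxcensus:::.render_capsules(n, c(1, 1, 1),
    list(list(p = ctr - a * 9, q = ctr + a * 9, radius = 2.8)),
    soft_axial = TRUE)
  cf <- cylinderCorrelate(VoxelGrid(sig), CylinderTemplate(18, 2.8, 3, 5),
                          min_intensity = 0.2)
  pk <- which.max(cf@corr)
  expect_gte(max(cf@corr), 0.99)
  expect_equal(as.numeric(arrayInd(pk, n)), ctr + 1)   # peak at the midpoint
  bi <- cf@axisIndex[pk]
  err <- acos(min(1, abs(sum(cf@axes[bi, ] * a)))) * 180 / pi
  expect_lte(err, 5)
})

test_that("orientation recovery stays within 1.5 steps for off-sample axes", {
  set.seed(15)
  step <- 15
  for (rep in 1:3) {
    a <- rnorm(3); a <- a / sqrt(sum(a^2)); if (a[1] < 0) a <- -a
    ctr <- c(20, 20, 20)
    sig <- voxcensus:::.render_capsules(c(40, 40, 40), c(1, 1, 1),
      list(list(p = ctr - a * 9, q = ctr + a * 9, radius = 2.8)),
      soft_axial = TRUE)
    cf <- cylinderCorrelate(VoxelGrid(sig), CylinderTemplate(18, 2.8, 3, step),
                            min_intensity = 0.2)
    pk <- which.max(cf@corr)
    err <- acos(min(1, abs(sum(cf@axes[cf@axisIndex[pk], ] * a)))) * 180 / pi
    expect_lte(err, 1.5 * step)
  }
})

test_that("uniform volumes correlate to zero by convention", {
  g <- VoxelGrid(array(0.7, c(32, 32, 32)))
  cf <- cylinderCorrelate(g, CylinderTemplate(12, 2, 2.5, 30))
  expect_lt(max(abs(cf@corr)), 1e-6)
})

test_that("the paper's template parameters are accepted verbatim", {
  tm <- CylinderTemplate(18, 2.8, 3, 5)
  expect_equal(tm@length, 18)
  expect_equal(tm@outerRadius, 2.8)
  expect_equal(tm@maskRadius, 3)
  expect_equal(tm@angularStep, 5)
  expect_error(CylinderTemplate(4, 2.8, 3, 5), "length")
  expect_error(CylinderTemplate(18, 2.8, 2, 5), "maskRadius")
})

test_that("correlation matches a direct rotated-template oracle", {
  ph <- makeFiberPhantom(
    fibers = data.frame(class = rep(c("circular", "longitudinal", "diagonal"),
                                    2), length = 35, radius = 2),
    dim = c(64, 64, 64), snr = Inf, seed = 5)
  tm <- CylinderTemplate(18, 2.8, 3, 20)
  cf <- cylinderCorrelate(ph$grid, tm, min_intensity = 0.3)
  ax <- makeOrientationSet(20)
  arr <- voxelData(ph$grid)
  reach <- 11
  set.seed(2)
  cand <- which(cf@corr > 0.1, arr.ind = TRUE)
  interior <- cand[apply(cand, 1, function(v)
    all(v - 1 >= reach & v <= dim(arr) - reach)), , drop = FALSE]
  pick <- interior[sample(nrow(interior), 20), , drop = FALSE]
  for (i in seq_len(nrow(pick))) {
    v0 <- pick[i, ] - 1
    expected <- cylinder_corr_oracle(arr, v0, ax, 18, 2.8, 3)
    expect_lt(abs(expected - cf@corr[pick[i, 1], pick[i, 2], pick[i, 3]]),
              1e-4)
  }
})

test_that("tracing recovers isolated and parallel fibers with true lengths", {
  # one straight fiber along x of length 100 voxels
  n <- c(32, 32, 120)
  seg <- list(list(p = c(16, 16, 10), q = c(16, 16, 110), radius = 2))
  sig <- voxcensus:::.render_capsules(n, c(1, 1, 1), seg)
  cf <- cylinderCorrelate(VoxelGrid(sig), CylinderTemplate(14, 2, 3, 15),
                          min_intensity = 0.3)
  fs <- traceCorrelationLines(cf, seed_threshold = 0.6, min_length = 20)
  expect_equal(length(fs@traces), 1L)
  expect_rel_error(fs@lengths[1], 100, 0.1)

  # two parallel fibers separated by 10 > 2 * maskRadius
  seg2 <- list(list(p = c(12, 16, 10), q = c(12, 16, 110), radius = 2),
               list(p = c(22, 16, 10), q = c(22, 16, 110), radius = 2))
  sig2 <- voxcensus:::.render_capsules(n, c(1, 1, 1), seg2)
  cf2 <- cylinderCorrelate(VoxelGrid(sig2), CylinderTemplate(14, 2, 3, 15),
                           min_intensity = 0.3)
  fs2 <- traceCorrelationLines(cf2, seed_threshold = 0.6, min_length = 20)
  expect_equal(length(fs2@traces), 2L)

  # a field entirely below threshold yields nothing
  lowcf <- cylinderCorrelate(VoxelGrid(sig * 0.001 +
      array(rnorm(prod(n), 0, 1e-5), n)),
    CylinderTemplate(14, 2, 3, 30))
  fs3 <- traceCorrelationLines(lowcf, seed_threshold = 0.99)
  expect_equal(length(fs3@traces), 0L)
  expect_equal(nrow(as.data.frame(fs3)), 0L)
  expect_error(traceCorrelationLines(cf, seed_threshold = 2), "\\[-1, 1\\]")
})

test_that("orientation classes follow the 30/60 degree bins and axis flips", {
  frame <- rbind(AP = c(0, 0, 1), ML = c(0, 1, 0), DV = c(1, 0, 0))
  mk_fs <- function(o) {
    tr <- rbind(c(0, 0, 0), o * 50)
    new("FiberSet", traces = list(tr), orientations = rbind(o),
        lengths = 50, classes = factor("unclassified",
          levels = c("circular", "diagonal", "longitudinal", "dorsoventral",
                     "unclassified")),
        params = list())
  }
  cls <- function(o) as.character(classifyOrientation(mk_fs(o), frame)@classes)
  expect_equal(cls(c(0, 0, 1)), "longitudinal")     # along AP
  expect_equal(cls(c(0, 1, 0)), "circular")          # along ML
  expect_equal(cls(c(1, 0, 0)), "dorsoventral")      # along DV
  d45 <- c(0, 1, 1) / sqrt(2)
  expect_equal(cls(d45), "diagonal")                 # 45 deg to AP in-plane
  # relabelling AP -> -AP changes nothing (axes, not directions)
  frame2 <- frame; frame2[1, ] <- -frame2[1, ]
  expect_equal(as.character(classifyOrientation(mk_fs(d45), frame2)@classes),
               "diagonal")
  expect_error(classifyOrientation(mk_fs(d45), matrix(1, 3, 3)),
               "orthonormal")
})

test_that("region censuses count midpoints and normalise proportions", {
  lv <- c("circular", "diagonal", "longitudinal", "dorsoventral",
          "unclassified")
  mk <- function(classes, zs) {
    n <- length(classes)
    traces <- lapply(zs, function(z) rbind(c(z, 10, 0), c(z, 10, 40)))
    new("FiberSet", traces = traces,
        orientations = matrix(rep(c(0, 0, 1), n), ncol = 3, byrow = TRUE),
        lengths = rep(40, n), classes = factor(classes, levels = lv),
        params = list())
  }
  fs <- mk(c(rep("circular", 10), rep("longitudinal", 5)), rep(5, 15))
  st <- fiberRegionStats(fs, RegionBox(c(0, 0, 0), c(50, 50, 50)))
  expect_equal(st$count[st$class == "circular"], 10L)
  expect_equal(st$proportion[st$class == "circular"], 2 / 3)
  expect_equal(st$proportion[st$class == "longitudinal"], 1 / 3)
  expect_equal(sum(st$count), 15L)

  empty <- fiberRegionStats(fs, RegionBox(c(100, 100, 100), c(120, 120, 120)))
  expect_equal(sum(empty$count), 0L)
  expect_true(all(is.na(empty$proportion)))

  # the census box of the anterior study region is expressible directly
  box <- RegionBox(c(0, 0, 0), c(500, 250, 300), "anterior census")
  expect_equal(box@upper - box@lower, c(500, 250, 300))
})
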