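test_that("nuclei phantoms honour counts, pairs, bounds and determinism", {
  ph <- makeNucleiPhantom(n = 60, dim = c(128, 128, 128),
                          touching_fraction = 0.2, seed = 21)
  expect_equal(nrow(ph$truth), 60)
  expect_equal(sum(ph$truth$pair > 0), 12)           # 20% of nuclei paired
  expect_equal(length(unique(ph$truth$pair[ph$truth$pair > 0])), 6)
  expect_true(all(ph$truth[, 1:3] >= 0 & ph$truth[, 1:3] <= 127))

  # designated pairs sit at 1.5 radii; all other gaps are positive
  tr <- ph$truth
  dmat <- as.matrix(dist(tr[, 1:3]))
  for (p in unique(tr$pair[tr$pair > 0])) {
    ix <- which(tr$pair == p)
    expect_equal(dmat[ix[1], ix[2]], 1.5 * tr$radius[ix[1]], tolerance = 1e-9)
  }
  singles <- which(tr$pair == 0)
  gaps <- dmat[singles, ] - outer(tr$radius[singles], tr$radius, `+`)
  diag(gaps[, singles]) <- NA
  gaps[cbind(seq_along(singles), singles)] <- NA
  expect_true(all(gaps > 0, na.rm = TRUE))

  ph2 <- makeNucleiPhantom(n = 60, dim = c(128, 128, 128),
                           touching_fraction = 0.2, seed = 21)
  expect_identical(voxelData(ph$grid), voxelData(ph2$grid))
  expect_identical(ph$truth, ph2$truth)
  expect_error(makeNucleiPhantom(n = 500, dim = c(32, 32, 32), seed = 1),
               "infeasible")
})

test_that("phantom noise realises the declared SNR definition", {
  ph <- makeNucleiPhantom(n = 10, dim = c(96, 96, 96), snr = 10, seed = 22)
  clean <- makeNucleiPhantom(n = 10, dim = c(96, 96, 96), snr = Inf,
                             seed = 22)
  bg <- voxelData(ph$grid)[voxelData(clean$grid) < 1e-6]
  snr_obs <- (1 - mean(bg)) / sd(bg)
  expect_equal(snr_obs, 10, tolerance = 0.1)
})

test_that("fiber phantoms draw axes inside their class bins and stay apart", {
  ph <- makeFiberPhantom(fibers = 20, dim = c(128, 128, 128), snr = Inf,
                         seed = 23, min_separation = 8)
  tr <- ph$truth
  expect_equal(nrow(tr), 20)
  frame <- ph$body_frame
  for (i in seq_len(nrow(tr))) {
    o <- as.numeric(tr[i, c("az", "ay", "ax")])
    th_dv <- acos(min(1, abs(sum(o * frame[3, ])))) * 180 / pi
    if (tr$class[i] == "dorsoventral") {
      expect_lt(th_dv, 30)
    } else {
      phi <- atan2(abs(sum(o * frame[2, ])), abs(sum(o * frame[1, ]))) *
        180 / pi
      truth_bin <- switch(as.character(tr$class[i]),
                          longitudinal = c(0, 30), diagonal = c(30, 60),
                          circular = c(60, 90))
      expect_gte(phi, truth_bin[1])
      expect_lte(phi, truth_bin[2])
    }
  }
  # pairwise segment clearance
  seg_dist_min <- min(vapply(seq_len(nrow(tr) - 1), function(i) {
    min(vapply((i + 1):nrow(tr), function(j) {
      p1 <- as.numeric(tr[i, 1:3]); q1 <- as.numeric(tr[i, 4:6])
      p2 <- as.numeric(tr[j, 1:3]); q2 <- as.numeric(tr[j, 4:6])
      min(vapply(seq(0, 1, 0.05), function(t1)
        min(vapply(seq(0, 1, 0.05), function(t2)
          sqrt(sum((p1 + t1 * (q1 - p1) - p2 - t2 * (q2 - p2))^2)),
          numeric(1))), numeric(1)))
    }, numeric(1)))
  }, numeric(1)))
  expect_gte(seg_dist_min, 8 - 0.5)

  ph2 <- makeFiberPhantom(fibers = 20, dim = c(128, 128, 128), snr = Inf,
                          seed = 23, min_separation = 8)
  expect_identical(voxelData(ph$grid), voxelData(ph2$grid))
})

test_that("rendered masses track analytic truth within anti-aliasing error", {
  bp <- makeBodyPhantom("sphere", 15)
  expect_rel_error(sum(voxelData(bp$grid)), bp$truth$volume, 0.01)
  bc <- makeBodyPhantom("cube", 20)
  expect_rel_error(sum(voxelData(bc$grid)), 20^3, 0.01)
  expect_equal(bc$truth$surface_area, 2400)
  cap <- makeBodyPhantom("capsule", c(10, 60))
  expect_equal(cap$truth$length, 80)
  expect_rel_error(sum(voxelData(cap$grid)), cap$truth$volume, 0.01)

  # oblique, off-lattice axis: the representative case for phantom fibers
  # (axis-aligned on-lattice cylinders are the worst case for the lattice
  # sum and can deviate by ~2%)
  u <- c(0.3, 0.5, 0.81); u <- u / sqrt(sum(u^2))
  p <- c(10.3, 11.7, 6.2); q <- p + 40 * u
  seg <- list(list(p = p, q = q, radius = 2))
  cylmass <- sum(voxcensus:::.render_capsules(c(50, 50, 60), c(1, 1, 1), seg))
  expect_rel_error(cylmass, pi * 4 * 40, 0.01)
})

test_that("allometry tables follow their declared scaling law", {
  exact <- makeAllometryTable(n_samples = 50, slopes = c(0.1, 0.05),
                              breakpoint = 5e5, noise_cv = 0, seed = 24)
  truth <- attr(exact, "truth")
  mu <- ifelse(exact$cells <= 5e5, truth$intercepts[1] + 0.1 * exact$cells,
               truth$intercepts[2] + 0.05 * exact$cells)
  expect_equal(exact$neurons, mu)
  # continuity at the breakpoint
  expect_equal(truth$intercepts[1] + 0.1 * 5e5,
               truth$intercepts[2] + 0.05 * 5e5)

  single <- makeAllometryTable(n_samples = 30, slopes = 0.1,
                               breakpoint = NULL, noise_cv = 0, seed = 25)
  expect_equal(single$neurons, 0.1 * single$cells)
  expect_true(is.na(attr(single, "truth")$breakpoint))

  r1 <- makeAllometryTable(n_samples = 40, seed = 26)
  r2 <- makeAllometryTable(n_samples = 40, seed = 26)
  expect_identical(r1, r2)
})

test_that("phantom truth survives a JSON round trip", {
  ph <- makeNucleiPhantom(n = 12, dim = c(96, 96, 96), seed = 27)
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(ph$truth, f, digits = NA)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$z, ph$truth$z)
  expect_equal(back$radius, ph$truth$radius)
  expect_equal(back$pair, ph$truth$pair)
})
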