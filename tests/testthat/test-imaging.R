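test_that("smoothing leaves constant stacks unchanged and conserves mass", {
  vs <- VoxelStack(array(77, c(8, 8, 8)), c(1, 1, 1))
  sm <- preprocessStack(vs, PreprocessParams("MAP2_RAT"))
  expect_true(all(abs(voxelData(sm) - 77) <= 1))   # up to integer rounding
  # single bright voxel, Gaussian only: symmetric spread, mass conserved
  # before quantization
  a <- array(0, c(9, 9, 9)); a[5, 5, 5] <- 200
  k <- WireScale:::gaussKernel(1, minHalf = 2)
  sm <- WireScale:::conv_sep3d_cpp(as.numeric(a), dim(a), k, k, k)
  expect_equal(sum(sm), 200, tolerance = 1e-12)
  out <- array(sm, dim(a))
  expect_equal(out, out[9:1, , ])                   # symmetry about centre
  expect_equal(out, aperm(out, c(3, 2, 1)))
  expect_error(preprocessStack(VoxelStack(array(0, c(3, 3, 3)), c(1, 1, 1))),
               "kernel larger")
})

test_that("edge-preserving diffusion matches a brute-force oracle and keeps edges", {
  set.seed(42)
  a <- array(runif(5 * 4 * 3, 0, 255), c(5, 4, 3))
  expect_equal(WireScale:::pmDiffuse3d(a, iters = 3), bruteDiffuse(a, 3),
               tolerance = 1e-12)
  # step edge: position preserved within 1 voxel after 10 iterations
  a <- array(0, c(20, 5, 5)); a[11:20, , ] <- 200
  d <- WireScale:::pmDiffuse3d(a, iters = 10)
  profile <- d[, 3, 3]
  crossing <- which(diff(profile > 100) != 0)
  expect_true(abs(crossing - 10) <= 1)
})

test_that("thresholding is idempotent, monotone and exact at the extremes", {
  set.seed(1)
  vs <- VoxelStack(array(sample(0:255, 4 * 4 * 4, TRUE), c(4, 4, 4)),
                   c(1, 1, 1))
  expect_true(all(voxelData(segmentStack(vs, 0)) == 1))
  expect_true(all(voxelData(segmentStack(vs, 256)) == 0))
  b <- segmentStack(vs, 100)
  expect_identical(voxelData(segmentStack(b, 1)), voxelData(b))
  hi <- segmentStack(vs, 150)
  expect_true(all(voxelData(hi) <= voxelData(b)))
})

test_that("segmentation recovers a synthetic tube against its mask", {
  dims <- c(40, 40, 20); voxel <- c(0.25, 0.25, 0.25)
  truthMask <- makeTubeStack(c(5, 5, 2.5), c(5, 5, 2.5 + 15), 0.5,
                             dims, voxel)
  img <- array(10, dims)
  img[voxelData(truthMask) == 1] <- 200
  seg <- segmentStack(VoxelStack(img, voxel), 40)
  inter <- sum(voxelData(seg) * voxelData(truthMask))
  dice <- 2 * inter / (sum(voxelData(seg)) + sum(voxelData(truthMask)))
  expect_gt(dice, 0.9)
})

test_that("penetration window matches the analytic exponential-decay depth", {
  nz <- 30; z0 <- 100
  a <- array(rep(round(255 * exp(-(0:(nz - 1)) / z0)), each = 4),
             c(2, 2, nz))
  w <- penetrationWindow(VoxelStack(a, c(1, 1, 1)))
  expect_equal(w@firstSlice, 1L)
  expect_equal(w@lastSlice - w@firstSlice + 1L,
               floor(-z0 * log(0.954)) + 1L)
  # uniform stack: full range; single bright slice: that slice only
  u <- penetrationWindow(VoxelStack(array(100, c(2, 2, 7)), c(1, 1, 1)))
  expect_equal(c(u@firstSlice, u@lastSlice), c(1L, 7L))
  a <- array(0, c(2, 2, 9)); a[, , 4] <- 200; a[, , c(3, 5)] <- 100
  s <- penetrationWindow(VoxelStack(a, c(1, 1, 1)))
  expect_equal(c(s@firstSlice, s@lastSlice), c(4L, 4L))
  expect_error(penetrationWindow(VoxelStack(array(0, c(2, 2, 2)),
                                            c(1, 1, 1))), "no signal")
})

test_that("penetration window shrinks as the criterion level rises", {
  set.seed(7)
  prof <- round(200 * exp(-(0:19) / 12) + runif(20, 0, 5))
  a <- array(rep(prof, each = 9), c(3, 3, 20))
  vs <- VoxelStack(a, c(1, 1, 1))
  sizes <- vapply(c(0.5, 0.7, 0.9, 0.954, 0.99), function(lv) {
    w <- penetrationWindow(vs, lv)
    w@lastSlice - w@firstSlice + 1L
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("mask subtraction behaves at the extremes and commutes with thresholding", {
  set.seed(3)
  img <- array(sample(0:255, 6^3, TRUE), c(6, 6, 6))
  vs <- VoxelStack(img, c(1, 1, 1))
  bin <- segmentStack(vs, 128)
  expect_identical(voxelData(subtractMasks(bin, array(0, c(6, 6, 6)))),
                   voxelData(bin))
  expect_true(all(voxelData(subtractMasks(bin, array(1, c(6, 6, 6)))) == 0))
  expect_error(subtractMasks(bin, array(0, c(5, 6, 6))), "shape")
  m <- array(0, c(6, 6, 6)); m[1:3, , ] <- 1
  masked <- voxelData(vs); masked[m == 1] <- 0
  expect_identical(
    voxelData(subtractMasks(bin, m)),
    voxelData(segmentStack(VoxelStack(masked, c(1, 1, 1)), 128)))
})

test_that("soma subtraction restores the fiber-only skeleton length", {
  spec <- PhantomSpec(extent = c(30, 30, 15), voxelSize = c(0.25, 0.25, 0.25),
                      lengthDensity = 4, diameterMedian = 1, diameterLogSd = 0.1,
                      somaCount = 2, somaRadiusRange = c(2.5, 3.5), seed = 21)
  ph <- generateFiberStack(spec)
  bin <- segmentStack(ph$stack, 100)
  clean <- subtractMasks(bin, ph$truth@somaMask)
  sk <- reconstructSkeleton(clean)
  relErr <- (totalLength(sk) - totalLength(ph$truth)) / totalLength(ph$truth)
  expect_lt(abs(relErr), 0.07)
})

test_that("sub-threshold audit measures the missing fiber fraction", {
  spec <- recoveryPhantom(seed = 13)
  ph <- generateFiberStack(spec)
  bin <- segmentStack(ph$stack, 100)
  expect_lt(auditSubthreshold(bin, ph$truth), 0.02)   # all above threshold
  expect_equal(auditSubthreshold(segmentStack(ph$stack, 0), ph$truth), 0)
  # erase ~one fiber's voxels to emulate sub-threshold loss
  arcs <- vapply(ph$truth@polylines, WireScale:::polylineLength, numeric(1))
  drop <- which.min(abs(cumsum(arcs) / sum(arcs) - 0.3))
  a <- voxelData(bin)
  dims <- dim(a)
  for (i in seq_len(drop)) {
    dense <- WireScale:::resamplePolyline(ph$truth@polylines[[i]], 0.1)
    m <- WireScale:::paint_balls_cpp(dims, c(0.25, 0.25, 0.25), dense,
                                     ph$truth@radii[[i]][1] + 0.3,
                                     integer(prod(dims)))
    a[m == 1] <- 0
  }
  frac <- auditSubthreshold(VoxelStack(a, c(0.25, 0.25, 0.25), "binary"),
                            ph$truth)
  planted <- sum(arcs[seq_len(drop)]) / sum(arcs)
  expect_equal(frac, planted, tolerance = 0.02)
  expect_error(auditSubthreshold(bin, GroundTruth()), "no ground truth")
})
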