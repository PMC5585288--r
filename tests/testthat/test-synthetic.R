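test_that("zero length density yields an empty stack with zero truth", {
  ph <- generateFiberStack(PhantomSpec(extent = c(10, 10, 5),
                                       lengthDensity = 0, seed = 1))
  expect_equal(totalLength(ph$truth), 0)
  expect_length(ph$truth@polylines, 0)
  expect_true(all(voxelData(ph$stack) ==
                    max(voxelData(ph$stack))))  # background only
})

test_that("true total length equals the density target exactly", {
  spec <- PhantomSpec(extent = c(50, 50, 20), lengthDensity = 5, seed = 7)
  ph <- generateFiberStack(spec)
  # 5 m/mm^3 x 5e4 um^3 = 250 um
  expect_equal(totalLength(ph$truth), 250, tolerance = 1e-9)
  arcs <- vapply(ph$truth@polylines, WireScale:::polylineLength, numeric(1))
  expect_equal(sum(arcs), totalLength(ph$truth), tolerance = 1e-9)
})

test_that("a fixed spec and seed reproduce the stack bit-identically", {
  spec <- PhantomSpec(extent = c(20, 20, 10), lengthDensity = 3,
                      noiseGaussianSd = 10, blurSigma = c(0.2, 0.2, 0.2),
                      somaCount = 1, speckleCount = 5, seed = 11)
  a <- generateFiberStack(spec)
  b <- generateFiberStack(spec)
  expect_identical(voxelData(a$stack), voxelData(b$stack))
  expect_identical(a$truth@polylines, b$truth@polylines)
  c <- generateFiberStack(PhantomSpec(extent = c(20, 20, 10),
                                      lengthDensity = 3, seed = 12))
  expect_false(identical(voxelData(a$stack), voxelData(c$stack)))
})

test_that("mean slice intensity decays monotonically with depth when noise is off", {
  # homogeneous (fiber-free) stack isolates the attenuation profile
  ph <- generateFiberStack(PhantomSpec(extent = c(20, 20, 20),
                                       lengthDensity = 0,
                                       backgroundIntensity = 120,
                                       attenuationDepth = 15, seed = 3))
  m <- apply(voxelData(ph$stack), 3, mean)
  expect_true(all(diff(m) <= 1e-9))
  expect_equal(m, 120 * exp(-((1:80) - 0.5) * 0.25 / 15), tolerance = 0.01)
})

test_that("soma and speckle masks are recorded and lie inside the volume", {
  ph <- generateFiberStack(PhantomSpec(extent = c(20, 20, 10),
                                       lengthDensity = 2, somaCount = 2,
                                       somaRadiusRange = c(2, 3),
                                       speckleCount = 10, seed = 5))
  expect_identical(dim(ph$truth@somaMask), dim(ph$stack))
  expect_gt(sum(ph$truth@somaMask), 0)
  expect_gt(sum(ph$truth@speckleMask), 0)
  # masked structures are rendered at fiber intensity
  expect_true(all(voxelData(ph$stack)[ph$truth@somaMask == 1] > 100))
})

test_that("invalid phantom specs are rejected and sub-voxel medians warn", {
  expect_error(PhantomSpec(extent = c(0, 10, 10)))
  expect_error(PhantomSpec(diameterMedian = -1))
  expect_warning(generateFiberStack(
    PhantomSpec(extent = c(10, 10, 5), voxelSize = c(0.5, 0.5, 0.5),
                lengthDensity = 1, diameterMedian = 0.3, seed = 1)),
    "below one voxel")
})

test_that("point populations are exact, reproducible and seed-sensitive", {
  expect_equal(nrow(generatePointPopulation(c(10, 10, 10), 0)@points), 0)
  a <- generatePointPopulation(c(100, 100, 50), 1000, seed = 4)
  b <- generatePointPopulation(c(100, 100, 50), 1000, seed = 4)
  c <- generatePointPopulation(c(100, 100, 50), 1000, seed = 5)
  expect_equal(nrow(a@points), 1000)
  expect_identical(a@points, b@points)
  expect_false(identical(a@points, c@points))
  expect_true(all(a@points >= 0) &&
                all(sweep(a@points, 2, c(100, 100, 50), "<=")))
  expect_error(generatePointPopulation(c(10, 10, 10), -1))
})

test_that("diameter samples scale as specified", {
  s <- generateDiameterSamples(0.8, 0.35, 1e5, scaleFactor = 1.35, seed = 9)
  expect_equal(median(s$B) / median(s$A), 1.35, tolerance = 0.01)
  s1 <- generateDiameterSamples(0.8, 0.35, 1, seed = 1)
  expect_length(s1$A, 1)
  expect_error(generateDiameterSamples(0.8, 0.35, 10, scaleFactor = 0))
  expect_error(generateDiameterSamples(-1, 0.35, 10))
})

test_that("tip polygons have the requested equivalent diameters", {
  # dispersion 0: every polygon has exactly the mean diameter
  polys <- generateTipPolygons(5, 150, dispersion = 0, seed = 2)
  d <- vapply(polys, function(p) droiFromPolygon(p)$diameter, numeric(1))
  expect_equal(d, rep(150, 5), tolerance = 1e-9)
  # the published monkey preset: n = 54 around 196 um
  polys <- generateTipPolygons(54, 196, dispersion = 0.2, seed = 3)
  d <- vapply(polys, function(p) droiFromPolygon(p)$diameter, numeric(1))
  ci <- t.test(d, mu = 196)
  expect_gt(ci$p.value, 0.01)
  expect_error(generateTipPolygons(3, 100, vertices = 2))
  expect_error(generateTipPolygons(0, 100))
})
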