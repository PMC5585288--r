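test_that("distance map: isolated voxel, slab symmetry, cylinder centreline", {
  vs <- stackFromVoxels(cbind(3, 3, 3), c(5, 5, 5), c(0.4, 0.4, 0.8))
  dm <- distanceMap(vs)
  expect_equal(dm[3, 3, 3], 0.2)            # half the smallest voxel edge
  expect_true(all(dm[-3, , ] == 0))
  # two-voxel slab: both voxels at equal distance
  vs <- stackFromVoxels(rbind(c(3, 3, 3), c(4, 3, 3)), c(7, 5, 5))
  dm <- distanceMap(vs)
  expect_equal(dm[3, 3, 3], dm[4, 3, 3])
  # long cylinder of radius 1.5 um: centreline distance = r within a voxel
  dims <- c(30, 30, 60); voxel <- c(0.25, 0.25, 0.25)
  tube <- makeTubeStack(c(3.875, 3.875, 1), c(3.875, 3.875, 14), 1.5,
                        dims, voxel)
  dm <- distanceMap(tube)
  centre <- dm[16, 16, 30]
  expect_lt(abs(centre - 1.5), 0.25)
})

test_that("thinning preserves components and reduces tubes to single chains", {
  dims <- c(24, 24, 60); voxel <- c(0.25, 0.25, 0.25)
  tube <- makeTubeStack(c(3.05, 3.05, 1.1), c(3.05, 3.05, 14.1), 0.55,
                        dims, voxel)
  th <- thinToSkeleton(tube)
  expect_true(all(voxelData(th) <= voxelData(tube)))  # output subset of input
  sk <- buildGraph(th, distanceMap(tube), extendTips = FALSE)
  expect_equal(length(unique(nodeTable(sk)$component)), 1L)
  expect_equal(totalLength(sk), 13, tolerance = 0.1)
  # empty stack stays empty; a solid sphere leaves a small central cluster
  empty <- VoxelStack(array(0, c(4, 4, 4)), c(1, 1, 1), "binary")
  expect_equal(sum(voxelData(thinToSkeleton(empty))), 0)
  sph <- makeTubeStack(c(10, 10, 10), c(10, 10.01, 10), 6, c(20, 20, 20),
                       c(1, 1, 1))
  expect_lt(sum(voxelData(thinToSkeleton(sph))), 12)
})

test_that("a straight 10-um chain resamples to 21 nodes at 0.5-um spacing", {
  idx <- cbind(1:21, 3, 3)
  vs <- stackFromVoxels(idx, c(21, 5, 5), c(0.5, 0.5, 0.5))
  sk <- buildGraph(vs, distanceMap(vs), extendTips = FALSE)
  expect_equal(nrow(nodeTable(sk)), 21L)
  p <- as.matrix(nodeTable(sk)[, c("x", "y", "z")])
  e <- edgeTable(sk)
  steps <- sqrt(rowSums((p[e[, 1], ] - p[e[, 2], ])^2))
  expect_true(all(abs(steps - 0.5) < 1e-6))
})

test_that("a Y-junction yields exactly one degree-3 vertex", {
  idx <- rbind(cbind(1:10, 10, 3),
               cbind(10 + 1:8, 10, 3),
               cbind(10 + 1:8, 10 + 1:8, 3))
  vs <- stackFromVoxels(idx, c(20, 20, 5), c(0.5, 0.5, 0.5))
  sk <- buildGraph(vs, distanceMap(vs), extendTips = FALSE)
  deg <- tabulate(edgeTable(sk), nbins = nrow(nodeTable(sk)))
  expect_equal(sum(deg == 3), 1L)
  expect_equal(sum(deg > 3), 0L)
})

test_that("node radii recover the tube radius within a voxel", {
  dims <- c(40, 40, 60); voxel <- c(0.25, 0.25, 0.25)
  for (r in c(0.5, 0.75, 1.0)) {
    tube <- makeTubeStack(c(5.125, 5.125, 2), c(5.125, 5.125, 13), r,
                          dims, voxel)
    sk <- reconstructSkeleton(tube)
    nd <- nodeTable(sk)
    inner <- nd[nd$z > 4 & nd$z < 11, ]   # away from the capped ends
    expect_lt(abs(mean(inner$radius) - r), max(0.1, 0.25))
  }
})

test_that("particle filter removes sub-cutoff components inclusively", {
  # one 10-um fiber, one isolated voxel, one exactly-0.25-um pair
  idx <- rbind(cbind(2:41, 5, 5),          # 40 voxels * 0.25 = 9.75 um chain
               cbind(60, 5, 5),            # isolated voxel
               cbind(60, 20, 5), cbind(61, 20, 5))  # 0.25-um pair
  vs <- stackFromVoxels(idx, c(70, 30, 10), c(0.25, 0.25, 0.25))
  sk <- buildGraph(vs, distanceMap(vs), extendTips = FALSE)
  expect_equal(length(unique(nodeTable(sk)$component)), 3L)
  f <- filterParticles(sk, 0.25)
  comps <- unique(nodeTable(f)$component)
  expect_equal(length(comps), 2L)          # isolated voxel dropped
  f2 <- filterParticles(sk, 0.2500001)
  expect_equal(length(unique(nodeTable(f2)$component)), 1L)
  # monotone: raising the cutoff never increases total length
  lens <- vapply(c(0, 0.25, 1, 5, 20), function(m)
    totalLength(filterParticles(sk, m)), numeric(1))
  expect_true(all(diff(lens) <= 1e-9))
})

test_that("shrinkage factor reproduces the published worked numbers", {
  expect_equal(shrinkageFactor(60, 22), 22 / 60)
  expect_equal(shrinkageFactor(60, 60), 1)
  expect_equal(shrinkageFactor(60, 30), 0.5)
  expect_error(shrinkageFactor(0, 22))
  expect_error(shrinkageFactor(60, -1))
})

test_that("length density arithmetic and shrinkage correction", {
  # 250 um of skeleton in a 50 x 50 x 20 um probe -> 5 m/mm^3
  nodes <- data.frame(x = seq(0, 50, by = 0.5), y = 25, z = 10)
  nodes <- do.call(rbind, lapply(0:4, function(k)
    transform(nodes, y = 5 + 5 * k)))
  nodes$radius <- 0.4
  nodes$component <- rep(1:5, each = 101)
  edges <- do.call(rbind, lapply(0:4, function(k)
    cbind(101 * k + 1:100, 101 * k + 2:101)))
  sk <- FiberSkeleton(nodes = nodes,
                      edges = matrix(as.integer(edges), ncol = 2))
  expect_equal(totalLength(sk), 250)
  stack <- VoxelStack(array(0, c(100, 100, 40)), c(0.5, 0.5, 0.5))
  rec <- lengthDensity(sk, stack)
  expect_equal(rec$density, 5)
  rec2 <- lengthDensity(sk, stack, shrinkage = 0.5)
  expect_equal(rec2$correctedDensity, 0.5 * rec2$density)
  empty <- FiberSkeleton()
  expect_equal(lengthDensity(empty, stack)$density, 0)
})

test_that("skeleton length recovery meets the phantom tolerances", {
  for (seed in c(2, 5)) {
    ph <- generateFiberStack(recoveryPhantom(seed))
    sk <- reconstructSkeleton(segmentStack(ph$stack, 100))
    relErr <- (totalLength(sk) - totalLength(ph$truth)) /
      totalLength(ph$truth)
    expect_lt(abs(relErr), 0.05)
  }
  ph <- generateFiberStack(recoveryPhantom(4, noisy = TRUE))
  sm <- preprocessStack(ph$stack, PreprocessParams("MAP2_RAT"))
  sk <- reconstructSkeleton(segmentStack(sm, 40))
  relErr <- (totalLength(sk) - totalLength(ph$truth)) / totalLength(ph$truth)
  expect_lt(abs(relErr), 0.10)
})

test_that("graph length is stable under axis permutation of the stack", {
  ph <- generateFiberStack(recoveryPhantom(6))
  bin <- segmentStack(ph$stack, 100)
  L1 <- totalLength(reconstructSkeleton(bin))
  perm <- VoxelStack(aperm(voxelData(bin), c(3, 1, 2)),
                     voxelSize(bin)[c(3, 1, 2)], "binary")
  L2 <- totalLength(reconstructSkeleton(perm))
  expect_equal(L1, L2, tolerance = 0.02)
})

test_that("SWC and CSV export round-trip the node table", {
  ph <- generateFiberStack(recoveryPhantom(3))
  sk <- reconstructSkeleton(segmentStack(ph$stack, 100))
  swc <- tempfile(fileext = ".swc")
  writeSWC(sk, swc)
  tab <- read.table(swc)
  expect_equal(nrow(tab), nrow(nodeTable(sk)))
  expect_true(all(tab[, 2] == 0))                      # type code 0
  expect_equal(tab[, 6], nodeTable(sk)$radius)
  roots <- sum(tab[, 7] == -1)
  expect_equal(roots, length(unique(nodeTable(sk)$component)))
  csv <- tempfile(fileext = ".csv")
  writeSkeletonCSV(sk, csv)
  nd <- read.csv(csv)
  expect_equal(nd$x, nodeTable(sk)$x)
  ed <- read.csv(sub("\\.csv$", "_edges.csv", csv))
  expect_equal(nrow(ed), nrow(edgeTable(sk)))
})
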