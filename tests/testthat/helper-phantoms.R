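# fixtures built in code: digital tubes, oracle implementations

# binary stack holding a tube of given radius between two points (um)
makeTubeStack <- function(p0, p1, radius, dims, voxel) {
  dense <- WireScale:::resamplePolyline(rbind(p0, p1), min(voxel) / 4)
  mask <- WireScale:::paint_balls_cpp(as.integer(dims), voxel, dense, radius,
                                      integer(prod(dims)))
  VoxelStack(array(as.numeric(mask), dims), voxel, "binary")
}

# binary stack from explicit voxel indices (n x 3 matrix, 1-based)
stackFromVoxels <- function(idx, dims, voxel = c(1, 1, 1)) {
  a <- array(0, dims)
  a[idx] <- 1
  VoxelStack(a, voxel, "binary")
}

# Monte-Carlo polygon area oracle: rejection sampling in the bounding box
# with an even-odd ray-crossing point-in-polygon test (independent of the
# shoelace formula)
mcPolygonArea <- function(v, n = 2e5, seed = 1) {
  set.seed(seed)
  xr <- range(v[, 1]); yr <- range(v[, 2])
  px <- runif(n, xr[1], xr[2])
  py <- runif(n, yr[1], yr[2])
  inside <- rep(FALSE, n)
  nv <- nrow(v)
  j <- nv
  for (i in seq_len(nv)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  mean(inside) * diff(xr) * diff(yr)
}

# brute-force 6-neighbour diffusion oracle (plain loops, replicated border)
bruteDiffuse <- function(a, iters, K = 10, dt = 1 / 7) {
  d <- dim(a)
  for (it in seq_len(iters)) {
    b <- a
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
      s <- 0
      for (off in list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                       c(0, 0, -1), c(0, 0, 1))) {
        xx <- min(max(x + off[1], 1), d[1])
        yy <- min(max(y + off[2], 1), d[2])
        zz <- min(max(z + off[3], 1), d[3])
        df <- a[xx, yy, zz] - a[x, y, z]
        s <- s + exp(-(df / K)^2) * df
      }
      b[x, y, z] <- a[x, y, z] + dt * s
    }
    a <- b
  }
  a
}

# default recovery phantom used across skeleton tests
recoveryPhantom <- function(seed, noisy = FALSE) {
  PhantomSpec(extent = c(30, 30, 15), voxelSize = c(0.25, 0.25, 0.25),
              lengthDensity = 5, diameterMedian = 1.0, diameterLogSd = 0.1,
              blurSigma = if (noisy) c(0.2, 0.2, 0.3) else c(0, 0, 0),
              noiseGaussianSd = if (noisy) 20 else 0,
              seed = seed)
}
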