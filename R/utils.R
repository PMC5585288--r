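#' Natural-log-spaced histogram bin edges
#'
#' Default diameter binning: 32 bins spanning 0.2--4.0 um, equally spaced on
#' the natural-log axis.
#'
#' @param from,to bin range (um).
#' @param nBins number of bins.
#' @return numeric vector of \code{nBins + 1} strictly increasing edges.
#' @examples
#' logBinEdges()[1:4]
#' @export
logBinEdges <- function(from = 0.2, to = 4, nBins = 32) {
  exp(seq(log(from), log(to), length.out = nBins + 1))
}

# shoelace polygon area (absolute), vertices as n x 2 matrix
shoelaceArea <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

# TRUE if the closed polygon has a pair of properly crossing edges
polygonSelfIntersects <- function(v) {
  n <- nrow(v)
  if (n < 4) return(FALSE)
  seg <- cbind(v, v[c(2:n, 1), ])
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in seq(i + 2, jmax)) {
      p <- seg[i, ]; q <- seg[j, ]
      d1 <- cross(p[1], p[2], p[3], p[4], q[1], q[2])
      d2 <- cross(p[1], p[2], p[3], p[4], q[3], q[4])
      d3 <- cross(q[1], q[2], q[3], q[4], p[1], p[2])
      d4 <- cross(q[1], q[2], q[3], q[4], p[3], p[4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
        return(TRUE)
    }
  }
  FALSE
}

# trilinear interpolation of a 3D array at physical positions (um);
# voxel-centre convention, clamped at the array border
trilinearInterp <- function(arr, voxel, pos) {
  d <- dim(arr)
  g <- sweep(pos, 2, voxel, "/") + 0.5       # 1-based continuous index
  g <- pmin(pmax(g, 1), matrix(d, nrow(pos), 3, byrow = TRUE))
  i0 <- pmin(floor(g), matrix(d - 1L, nrow(pos), 3, byrow = TRUE))
  i0 <- pmax(i0, 1)
  f <- g - i0
  val <- 0
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (cx * f[, 1] + (1 - cx) * (1 - f[, 1])) *
         (cy * f[, 2] + (1 - cy) * (1 - f[, 2])) *
         (cz * f[, 3] + (1 - cz) * (1 - f[, 3]))
    idx <- cbind(i0[, 1] + cx, i0[, 2] + cy, i0[, 3] + cz)
    val <- val + w * arr[idx]
  }
  val
}

# resample a polyline (n x 3) at fixed arc spacing, keeping both endpoints
resamplePolyline <- function(p, spacing) {
  if (nrow(p) < 2) return(p)
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (L < .Machine$double.eps) return(p[1, , drop = FALSE])
  t <- seq(0, L, by = spacing)
  if (L - t[length(t)] > 1e-9) t <- c(t, L)
  apply(p, 2, function(col) stats::approx(s, col, xout = t)$y)
}

# moving-average smoothing of a polyline, endpoints fixed
smoothPolyline <- function(p, window = 5L, passes = 2L) {
  n <- nrow(p)
  if (n < 3 || window < 3) return(p)
  half <- window %/% 2L
  for (pass in seq_len(passes)) {
    q <- p
    for (i in 2:(n - 1)) {
      lo <- max(1, i - half); hi <- min(n, i + half)
      q[i, ] <- colMeans(p[lo:hi, , drop = FALSE])
    }
    p <- q
  }
  p
}

# uniformly distributed unit vector(s)
randomUnitVector <- function(n = 1) {
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}

# rotate unit vector u by angle theta towards a uniformly random azimuth
rotateWithinCone <- function(u, theta) {
  a <- randomUnitVector()
  a <- a - sum(a * u) * u
  na <- sqrt(sum(a^2))
  if (na < 1e-12) return(u)
  a <- a / na
  v <- cos(theta) * u + sin(theta) * a
  v / sqrt(sum(v^2))
}
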