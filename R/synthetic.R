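#' Generate a synthetic fiber-stack phantom with exact ground truth
#'
#' Renders a confocal-like probe volume: tubular fibers are grown as
#' persistent random walks with 1-um steps and a capped per-step bend angle
#' (reflected at the volume boundary so the arc length stays exact), given a
#' log-normal diameter, and rasterized as tubes (a voxel is foreground when
#' its centre lies within the local radius of the centreline). Optional soma
#' blobs and lipofuscin-like speckles are rendered at fiber intensity but
#' recorded in masks. Depth attenuation (\code{exp(-z / z0)}), Gaussian blur
#' and detector noise (Gaussian plus signal-proportional variance) are
#' applied in that order, then the stack is clipped and quantized to 8 bit.
#'
#' Fibers are added until the summed centreline length equals the target
#' \code{lengthDensity * volume} exactly (the last fiber is truncated), so
#' \code{totalLength(truth)} is exact by construction.
#'
#' @param spec a \code{\linkS4class{PhantomSpec}}.
#' @return list with elements \code{stack} (a
#'   \code{\linkS4class{VoxelStack}}, 8-bit) and \code{truth} (a
#'   \code{\linkS4class{GroundTruth}}).
#' @examples
#' ph <- generateFiberStack(PhantomSpec(extent = c(20, 20, 10),
#'                                      lengthDensity = 2, seed = 1))
#' totalLength(ph$truth)
#' @export
generateFiberStack <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  set.seed(spec@seed)
  extent <- spec@extent
  voxel <- spec@voxelSize
  dims <- as.integer(round(extent / voxel))
  if (any(dims < 1)) stop("volume extent smaller than one voxel")
  subres <- spec@diameterMedian < min(voxel)
  if (subres)
    warning("median fiber diameter below one voxel; recovery not guaranteed")

  targetLength <- spec@lengthDensity * 1e-3 * prod(extent)  # um of fiber
  polylines <- list()
  radii <- list()
  fiberLen <- 0
  nominal <- max(10, 1.5 * max(extent))
  maxBend <- spec@maxBendAngle * pi / 180
  while (targetLength - fiberLen > 1e-9) {
    L <- min(nominal, targetLength - fiberLen)
    d <- stats::rlnorm(1, log(spec@diameterMedian), spec@diameterLogSd)
    # inset the walk domain by the fiber radius so the whole tube lies
    # inside the volume (no wall-truncated half-tubes)
    margin <- pmin(d / 2, extent / 4)
    inner <- extent - 2 * margin
    poly <- randomWalkFiber(L, inner, maxBend)
    poly <- sweep(poly, 2, margin, "+")
    polylines[[length(polylines) + 1L]] <- poly
    radii[[length(radii) + 1L]] <- rep(d / 2, nrow(poly))
    fiberLen <- fiberLen + polylineLength(poly)
  }

  mask <- integer(prod(dims))
  for (i in seq_along(polylines)) {
    dense <- resamplePolyline(polylines[[i]], min(voxel) / 2)
    mask <- paint_balls_cpp(dims, voxel, dense, radii[[i]][1], mask)
  }

  somaMask <- integer(prod(dims))
  if (spec@somaCount > 0) {
    centres <- matrix(stats::runif(3 * spec@somaCount), ncol = 3) %*%
      diag(extent)
    srad <- stats::runif(spec@somaCount, spec@somaRadiusRange[1],
                         spec@somaRadiusRange[2])
    for (i in seq_len(spec@somaCount))
      somaMask <- paint_balls_cpp(dims, voxel,
                                  centres[i, , drop = FALSE], srad[i],
                                  somaMask)
  }
  speckleMask <- integer(prod(dims))
  if (spec@speckleCount > 0) {
    centres <- matrix(stats::runif(3 * spec@speckleCount), ncol = 3) %*%
      diag(extent)
    speckleMask <- paint_balls_cpp(dims, voxel, centres,
                                   rep(spec@speckleSize / 2,
                                       spec@speckleCount), speckleMask)
  }

  img <- array(spec@backgroundIntensity, dims)
  img[mask == 1 | somaMask == 1 | speckleMask == 1] <- spec@fiberIntensity

  if (is.finite(spec@attenuationDepth)) {
    depth <- ((seq_len(dims[3]) - 0.5) * voxel[3])
    att <- exp(-depth / spec@attenuationDepth)
    img <- sweep(img, 3, att, "*")
  }
  if (any(spec@blurSigma > 0)) {
    kerns <- lapply(1:3, function(a) gaussKernel(spec@blurSigma[a] / voxel[a]))
    img <- array(conv_sep3d_cpp(as.numeric(img), dims, kerns[[1]],
                                kerns[[2]], kerns[[3]]), dims)
  }
  if (spec@noiseGaussianSd > 0 || spec@noisePoissonScale > 0) {
    sdv <- sqrt(spec@noiseGaussianSd^2 +
                spec@noisePoissonScale * pmax(img, 0))
    img <- img + stats::rnorm(length(img), 0, as.numeric(sdv))
  }
  img <- array(pmin(pmax(round(img), 0), 255), dims)

  truth <- GroundTruth(polylines = polylines, radii = radii,
                       totalLength = fiberLen,
                       somaMask = array(as.numeric(somaMask), dims),
                       speckleMask = array(as.numeric(speckleMask), dims))
  stack <- VoxelStack(img, voxel, "raw")
  attr(stack, "subresolution") <- subres
  list(stack = stack, truth = truth)
}

polylineLength <- function(p) {
  if (nrow(p) < 2) return(0)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

# persistent random walk of total arc length L inside [0, extent], step 1 um,
# bend angle per step uniform in [0, maxBend]; boundary reflections insert
# the boundary point so the polyline arc length is exactly L
randomWalkFiber <- function(L, extent, maxBend, step = 1) {
  pos <- stats::runif(3) * extent
  dir <- as.numeric(randomUnitVector())
  pts <- list(pos)
  remaining <- L
  while (remaining > 1e-12) {
    s <- min(step, remaining)
    res <- advanceReflect(pos, dir, s, extent)
    pts <- c(pts, res$points)
    pos <- res$pos
    dir <- res$dir
    remaining <- remaining - s
    dir <- rotateWithinCone(dir, stats::runif(1, 0, maxBend))
  }
  do.call(rbind, pts)
}

# advance len along dir with mirror reflection at the box boundary,
# returning every intermediate boundary point
advanceReflect <- function(pos, dir, len, extent) {
  pts <- list()
  guard <- 0L
  while (len > 1e-12 && guard < 100L) {
    guard <- guard + 1L
    tHit <- Inf
    axHit <- 0L
    for (a in 1:3) {
      if (dir[a] > 1e-12) {
        t <- (extent[a] - pos[a]) / dir[a]
      } else if (dir[a] < -1e-12) {
        t <- -pos[a] / dir[a]
      } else t <- Inf
      if (t < tHit) { tHit <- t; axHit <- a }
    }
    if (len <= tHit) {
      pos <- pos + dir * len
      pts[[length(pts) + 1L]] <- pos
      len <- 0
    } else {
      pos <- pos + dir * tHit
      pos <- pmin(pmax(pos, 0), extent)
      pts[[length(pts) + 1L]] <- pos
      dir[axHit] <- -dir[axHit]
      len <- len - tHit
    }
  }
  list(points = pts, pos = pos, dir = dir)
}

# normalized 1D Gaussian kernel (sigma in voxels), radius 3 sigma, >= 2 taps
# on each side of the centre when sigma > 0
gaussKernel <- function(sigma, minHalf = 2L) {
  if (sigma <= 0) return(1)
  half <- max(minHalf, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Generate a uniform point population for stereology phantoms
#'
#' @param extent numeric(3), volume extent (um).
#' @param count number of points (exact).
#' @param seed RNG seed.
#' @return a \code{\linkS4class{GroundTruth}} whose \code{points} slot holds
#'   the true positions; the true count is \code{nrow} of that matrix.
#' @examples
#' gt <- generatePointPopulation(c(100, 100, 100), 50, seed = 1)
#' nrow(gt@points)
#' @export
generatePointPopulation <- function(extent, count, seed = 1L) {
  if (length(extent) != 3 || any(extent <= 0))
    stop("extent must be 3 positive lengths")
  if (count < 0) stop("count must be >= 0")
  set.seed(seed)
  pts <- matrix(stats::runif(3 * count), ncol = 3) %*% diag(extent)
  colnames(pts) <- c("x", "y", "z")
  GroundTruth(points = pts)
}

#' Generate paired log-normal fiber-diameter samples
#'
#' Draws two independent samples from the same log-normal diameter
#' distribution; the second is multiplied elementwise by
#' \code{scaleFactor}, mimicking a species whose fibers are uniformly
#' thicker by that linear factor.
#'
#' @param median median diameter (um).
#' @param logSd sd of log diameter.
#' @param n sample size (>= 1).
#' @param scaleFactor positive linear scale applied to the second sample.
#' @param seed RNG seed.
#' @return list with numeric vectors \code{A} and \code{B}.
#' @examples
#' s <- generateDiameterSamples(0.8, 0.35, 1000, scaleFactor = 1.35, seed = 1)
#' median(s$B) / median(s$A)
#' @export
generateDiameterSamples <- function(median, logSd, n, scaleFactor = 1,
                                    seed = 1L) {
  if (median <= 0) stop("median must be > 0")
  if (n < 1) stop("n must be >= 1")
  if (scaleFactor <= 0) stop("scaleFactor must be > 0")
  set.seed(seed)
  A <- stats::rlnorm(n, log(median), logSd)
  B <- stats::rlnorm(n, log(median), logSd) * scaleFactor
  list(A = A, B = B)
}

#' Generate synthetic dendritic-tip polygons
#'
#' Emulates 2D outlines connecting the outer tips of dendritic trees:
#' star-shaped simple polygons whose equivalent-circle diameters are drawn
#' around \code{meanDiameter} (log-normal with multiplicative dispersion,
#' mean-corrected so the expected diameter equals \code{meanDiameter};
#' \code{dispersion = 0} gives identical diameters).
#'
#' @param n number of polygons (>= 1).
#' @param meanDiameter mean equivalent-circle diameter (um).
#' @param dispersion sd of log diameter across polygons.
#' @param seed RNG seed.
#' @param vertices integer range of vertex counts to draw from (>= 3).
#' @return list of k x 2 coordinate matrices (um), vertices in order.
#' @examples
#' polys <- generateTipPolygons(5, 196, dispersion = 0.2, seed = 1)
#' droiFromPolygon(polys[[1]])$diameter
#' @export
generateTipPolygons <- function(n, meanDiameter, dispersion = 0.2, seed = 1L,
                                vertices = 6:12) {
  if (n < 1) stop("n must be >= 1")
  if (meanDiameter <= 0) stop("meanDiameter must be > 0")
  if (any(vertices < 3)) stop("polygons need at least 3 vertices")
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    k <- if (length(vertices) > 1) sample(vertices, 1) else vertices
    repeat {
      # stratified angles keep every angular gap below pi (for k >= 4), so
      # the vertex fan around the centroid yields a simple polygon
      ang <- sort(2 * pi * (seq_len(k) - 1 + stats::runif(k)) / k)
      rad <- 1 + stats::runif(k, -0.3, 0.3)
      v <- cbind(rad * cos(ang), rad * sin(ang))
      if (!polygonSelfIntersects(v)) break
    }
    d <- meanDiameter * exp(stats::rnorm(1, -dispersion^2 / 2, dispersion))
    v * sqrt((pi * (d / 2)^2) / shoelaceArea(v))
  })
}
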