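#' Edge-preserving smoothing followed by Gaussian filtering
#'
#' Reproduces the published preprocessing chain: a 3D edge-preserving
#' smoothing step parameterized by a time-stop and step size, followed by
#' Gaussian filtering with a fixed voxel kernel. The edge-preserving step is
#' realized as Perona--Malik-style anisotropic diffusion with
#' \code{timeStop / stepSize} iterations (exponential conductance, stable
#' time increment), which damps noise while keeping fiber edges in place.
#'
#' @param stack a raw \code{\linkS4class{VoxelStack}}.
#' @param params a \code{\linkS4class{PreprocessParams}} (stain preset or
#'   explicit values).
#' @param conductance diffusion conductance K (intensity units); gradients
#'   well above K are preserved as edges.
#' @return the smoothed \code{VoxelStack} (8-bit, provenance
#'   \code{"smoothed"}).
#' @export
preprocessStack <- function(stack, params = PreprocessParams("MAP2_RAT"),
                            conductance = 10) {
  stopifnot(is(stack, "VoxelStack"), is(params, "PreprocessParams"))
  d <- dim(stack)
  if (any(params@kernelSize > d))
    stop("Gaussian kernel larger than the stack")
  a <- stack@data * 1.0
  iters <- max(0L, as.integer(round(params@timeStop / params@stepSize)))
  a <- pmDiffuse3d(a, iters, K = conductance)
  half <- (params@kernelSize - 1L) %/% 2L
  k <- gaussKernel(params@sigma, minHalf = half)
  # fixed kernel size: truncate/normalize to the requested support
  if ((length(k) - 1) / 2 > half) {
    mid <- (length(k) + 1) / 2
    k <- k[(mid - half):(mid + half)]
    k <- k / sum(k)
  }
  a <- array(conv_sep3d_cpp(as.numeric(a), dim(a), k, k, k), dim(a))
  VoxelStack(array(pmin(pmax(round(a), 0), 255), d), stack@voxelSize,
             "smoothed")
}

# Perona-Malik diffusion, 6-neighbour fluxes, zero-flux (replicated)
# boundary, exponential conductance g(d) = exp(-(d/K)^2), dt = 1/7 (stable
# for a 6-neighbour 3D stencil)
pmDiffuse3d <- function(a, iters, K = 10, dt = 1 / 7) {
  if (iters < 1) return(a)
  d <- dim(a)
  shift <- function(x, axis, by) {
    idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    i <- idx[[axis]] + by
    i[i < 1] <- 1
    i[i > d[axis]] <- d[axis]
    idx[[axis]] <- i
    x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  }
  for (it in seq_len(iters)) {
    flux <- 0
    for (axis in 1:3) for (by in c(-1L, 1L)) {
      df <- shift(a, axis, by) - a
      flux <- flux + exp(-(df / K)^2) * df
    }
    a <- a + dt * flux
  }
  a
}

#' Fixed-threshold binarization
#'
#' A voxel is foreground iff its intensity is at least \code{threshold}.
#' Thresholds are fixed constants chosen per stain (25 for MAP2 rat, 40 for
#' MAP2 monkey, 80 for PCP2), not adaptive.
#'
#' @param stack a smoothed (or raw) \code{\linkS4class{VoxelStack}}.
#' @param threshold intensity threshold in [0, 256].
#' @return binary \code{VoxelStack}.
#' @examples
#' vs <- VoxelStack(array(c(10, 200), c(2, 1, 1)), c(1, 1, 1))
#' voxelData(segmentStack(vs, 40))
#' @export
segmentStack <- function(stack, threshold) {
  stopifnot(is(stack, "VoxelStack"))
  VoxelStack(array(as.numeric(stack@data >= threshold), dim(stack)),
             stack@voxelSize, "binary")
}

#' Antibody-penetration window of a probe stack
#'
#' Finds the maximal contiguous range of optical slices, anchored at the
#' brightest slice, in which every slice's maximal intensity reaches at
#' least \code{level} of the whole-probe maximum. Restricting fiber analysis
#' to this window discards the poorly penetrated deep portion of the
#' section.
#'
#' @param stack a \code{\linkS4class{VoxelStack}}.
#' @param level criterion as a fraction of the global maximum (default
#'   0.954).
#' @return a \code{\linkS4class{PenetrationWindow}}.
#' @export
penetrationWindow <- function(stack, level = 0.954) {
  stopifnot(is(stack, "VoxelStack"))
  m <- apply(stack@data, 3, max)
  M <- max(m)
  if (M <= 0) stop("all-zero stack: no signal to window")
  z0 <- which.max(m)
  ok <- m >= level * M
  lo <- z0
  while (lo > 1 && ok[lo - 1]) lo <- lo - 1
  hi <- z0
  while (hi < length(m) && ok[hi + 1]) hi <- hi + 1
  new("PenetrationWindow", firstSlice = as.integer(lo),
      lastSlice = as.integer(hi), level = level)
}

#' Remove masked structures from a binary stack
#'
#' Sets foreground voxels under any supplied mask (somata, lipofuscin
#' speckles) to background, mirroring the manual removal of MAP2-stained
#' somata and lipofuscin particles before fiber quantification.
#'
#' @param binary a binary \code{\linkS4class{VoxelStack}}.
#' @param masks a 0/1 array or list of arrays matching the stack shape.
#' @return binary \code{VoxelStack} with masked voxels cleared.
#' @export
subtractMasks <- function(binary, masks) {
  stopifnot(is(binary, "VoxelStack"))
  if (!is.list(masks)) masks <- list(masks)
  a <- binary@data
  for (m in masks) {
    if (length(m) == 0) next
    if (!identical(dim(m), dim(a))) stop("mask shape mismatch")
    a[m != 0] <- 0
  }
  VoxelStack(a, binary@voxelSize, "binary")
}

#' Audit the fraction of fiber length lost below threshold
#'
#' Thresholds chosen to keep nearby fibers apart push the thinnest fibers
#' below threshold. Given the ground truth (or an annotation) of true
#' centrelines, this measures the fraction of true fiber length absent from
#' the binary stack: centrelines are resampled finely and a sample point
#' counts as missing when its voxel is background.
#'
#' @param binary a binary \code{\linkS4class{VoxelStack}}.
#' @param truth a \code{\linkS4class{GroundTruth}} with centreline
#'   polylines.
#' @param step resampling step along the centrelines (um).
#' @return fraction in [0, 1] of true length not captured.
#' @export
auditSubthreshold <- function(binary, truth, step = 0.25) {
  stopifnot(is(binary, "VoxelStack"), is(truth, "GroundTruth"))
  if (length(truth@polylines) == 0)
    stop("no ground truth centrelines to audit against")
  d <- dim(binary)
  voxel <- binary@voxelSize
  miss <- 0
  tot <- 0
  for (p in truth@polylines) {
    dense <- resamplePolyline(p, step)
    idx <- pmin(pmax(ceiling(sweep(dense, 2, voxel, "/")), 1L),
                matrix(d, nrow(dense), 3, byrow = TRUE))
    fg <- binary@data[idx]
    miss <- miss + sum(fg == 0)
    tot <- tot + length(fg)
  }
  miss / tot
}
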