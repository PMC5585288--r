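#' @import methods
NULL

#' VoxelStack: a 3D grayscale image stack with physical voxel size
#'
#' The unit of image analysis: an 8-bit (0--255) intensity grid with the
#' physical voxel spacing in micrometres for each array axis. The third array
#' axis is the optical-slice (z) axis. Physical positions follow the
#' voxel-centre convention: a voxel with 0-based index \code{i} spans
#' \code{[i, i+1] * voxelSize} and its centre lies at
#' \code{(i + 0.5) * voxelSize}.
#'
#' @slot data numeric 3D array; intensities in [0, 255] (0/1 for binary
#'   stacks).
#' @slot voxelSize numeric(3), micrometres per voxel along the three array
#'   axes (anisotropy allowed; axis 3 = z).
#' @slot provenance character scalar, one of \code{"raw"}, \code{"smoothed"},
#'   \code{"binary"}.
#'
#' @examples
#' vs <- VoxelStack(array(0, c(8, 8, 4)), voxelSize = c(0.2, 0.2, 0.5))
#' dim(vs)
#' voxelSize(vs)
#' @export
setClass("VoxelStack",
  representation(data = "array", voxelSize = "numeric",
                 provenance = "character"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a 3D array")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      msg <- c(msg, "voxelSize must be 3 positive values (um)")
    if (!object@provenance %in% c("raw", "smoothed", "binary"))
      msg <- c(msg, "provenance must be 'raw', 'smoothed' or 'binary'")
    rng <- suppressWarnings(range(object@data))
    if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 255))
      msg <- c(msg, "intensities must lie in [0, 255]")
    if (object@provenance == "binary" &&
        !all(object@data %in% c(0, 1)))
      msg <- c(msg, "binary stacks must contain only 0/1")
    if (length(msg)) msg else TRUE
  })

#' @rdname VoxelStack-class
#' @param data 3D numeric array of intensities.
#' @param voxelSize numeric(3), micrometres per voxel.
#' @param provenance processing stage tag.
#' @export
VoxelStack <- function(data, voxelSize, provenance = "raw") {
  new("VoxelStack", data = data, voxelSize = as.numeric(voxelSize),
      provenance = provenance)
}

#' PhantomSpec: parameters of a synthetic fiber-stack phantom
#'
#' Describes a confocal probe phantom: tubular fluorescent fibers of known
#' total length and log-normal diameter distribution, optional soma blobs and
#' lipofuscin-like speckles, depth-dependent intensity attenuation (emulating
#' limited antibody penetration), Gaussian blur and detector noise.
#'
#' @slot extent numeric(3), physical volume extent in micrometres.
#' @slot voxelSize numeric(3), micrometres per voxel.
#' @slot lengthDensity target fiber length density in m per mm^3.
#' @slot diameterMedian median fiber diameter (um).
#' @slot diameterLogSd standard deviation of log diameter.
#' @slot maxBendAngle maximal bend angle (degrees) per 1-um centreline step;
#'   controls tortuosity.
#' @slot somaCount,somaRadiusRange number of soma blobs and their radius
#'   range (um).
#' @slot speckleCount,speckleSize number and diameter (um) of speckles.
#' @slot attenuationDepth depth constant z0 (um) of the exp(-z/z0) intensity
#'   attenuation; \code{Inf} disables attenuation.
#' @slot blurSigma numeric(3), Gaussian blur sigma in um per axis (0 = none).
#' @slot noiseGaussianSd additive Gaussian noise sd (intensity units).
#' @slot noisePoissonScale scale of the signal-dependent (Poisson-like)
#'   variance component: variance contribution = scale * intensity.
#' @slot fiberIntensity,backgroundIntensity rendered intensities (0--255).
#' @slot seed integer RNG seed; a fixed spec + seed reproduces the stack
#'   bit-identically.
#' @export
setClass("PhantomSpec",
  representation(extent = "numeric", voxelSize = "numeric",
                 lengthDensity = "numeric", diameterMedian = "numeric",
                 diameterLogSd = "numeric", maxBendAngle = "numeric",
                 somaCount = "numeric", somaRadiusRange = "numeric",
                 speckleCount = "numeric", speckleSize = "numeric",
                 attenuationDepth = "numeric", blurSigma = "numeric",
                 noiseGaussianSd = "numeric", noisePoissonScale = "numeric",
                 fiberIntensity = "numeric", backgroundIntensity = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@extent) != 3L || any(object@extent <= 0))
      msg <- c(msg, "extent must be 3 positive lengths (um)")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      msg <- c(msg, "voxelSize must be 3 positive lengths (um)")
    if (object@lengthDensity < 0)
      msg <- c(msg, "lengthDensity must be >= 0")
    if (object@diameterMedian <= 0 || object@diameterLogSd < 0)
      msg <- c(msg, "diameter distribution parameters invalid")
    if (object@attenuationDepth <= 0)
      msg <- c(msg, "attenuationDepth must be > 0 (use Inf to disable)")
    if (length(object@blurSigma) != 3L || any(object@blurSigma < 0))
      msg <- c(msg, "blurSigma must be 3 non-negative values")
    if (object@somaCount < 0 || object@speckleCount < 0)
      msg <- c(msg, "counts must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' @rdname PhantomSpec-class
#' @param extent,voxelSize,lengthDensity,diameterMedian,diameterLogSd see
#'   slots.
#' @param maxBendAngle,somaCount,somaRadiusRange,speckleCount,speckleSize see
#'   slots.
#' @param attenuationDepth,blurSigma,noiseGaussianSd,noisePoissonScale see
#'   slots.
#' @param fiberIntensity,backgroundIntensity,seed see slots.
#' @export
PhantomSpec <- function(extent = c(50, 50, 20), voxelSize = c(0.25, 0.25, 0.25),
                        lengthDensity = 5, diameterMedian = 0.8,
                        diameterLogSd = 0.35, maxBendAngle = 20,
                        somaCount = 0, somaRadiusRange = c(4, 8),
                        speckleCount = 0, speckleSize = 0.8,
                        attenuationDepth = Inf, blurSigma = c(0, 0, 0),
                        noiseGaussianSd = 0, noisePoissonScale = 0,
                        fiberIntensity = 200, backgroundIntensity = 10,
                        seed = 1L) {
  new("PhantomSpec", extent = as.numeric(extent),
      voxelSize = as.numeric(voxelSize),
      lengthDensity = lengthDensity, diameterMedian = diameterMedian,
      diameterLogSd = diameterLogSd, maxBendAngle = maxBendAngle,
      somaCount = somaCount, somaRadiusRange = as.numeric(somaRadiusRange),
      speckleCount = speckleCount, speckleSize = speckleSize,
      attenuationDepth = attenuationDepth,
      blurSigma = rep(as.numeric(blurSigma), length.out = 3),
      noiseGaussianSd = noiseGaussianSd,
      noisePoissonScale = noisePoissonScale,
      fiberIntensity = fiberIntensity,
      backgroundIntensity = backgroundIntensity, seed = as.integer(seed))
}

#' GroundTruth: exact ground truth of a synthetic phantom
#'
#' Oracle object carried alongside generated phantoms: true centreline
#' polylines with per-node radii, the exact total fiber length, soma and
#' speckle masks, and true point positions for stereology phantoms.
#'
#' @slot polylines list of n x 3 matrices of centreline coordinates (um).
#' @slot radii list of per-node radius vectors (um), parallel to
#'   \code{polylines}.
#' @slot totalLength exact total centreline arc length (um).
#' @slot somaMask,speckleMask 0/1 arrays matching the stack, or 0-length
#'   arrays when absent.
#' @slot points n x 3 matrix of true point positions (um) for stereology
#'   phantoms.
#' @export
setClass("GroundTruth",
  representation(polylines = "list", radii = "list", totalLength = "numeric",
                 somaMask = "array", speckleMask = "array",
                 points = "matrix"),
  validity = function(object) {
    msg <- character()
    arc <- vapply(object@polylines, function(p) {
      if (nrow(p) < 2) return(0)
      sum(sqrt(rowSums((p[-1, , drop = FALSE] -
                        p[-nrow(p), , drop = FALSE])^2)))
    }, numeric(1))
    if (length(arc) &&
        abs(sum(arc) - object@totalLength) > 1e-6 * max(1, object@totalLength))
      msg <- c(msg, "totalLength must equal the summed polyline arc lengths")
    if (length(object@radii) != length(object@polylines))
      msg <- c(msg, "radii must parallel polylines")
    if (length(msg)) msg else TRUE
  })

GroundTruth <- function(polylines = list(), radii = list(),
                        totalLength = 0, somaMask = array(0, c(0, 0, 0)),
                        speckleMask = array(0, c(0, 0, 0)),
                        points = matrix(numeric(), ncol = 3)) {
  new("GroundTruth", polylines = polylines, radii = radii,
      totalLength = totalLength, somaMask = somaMask,
      speckleMask = speckleMask, points = points)
}

#' FiberSkeleton: radius-annotated centreline graph of a fiber network
#'
#' Graph of centreline nodes at (approximately) fixed 0.5-um arc spacing.
#' Each node carries its physical position (um) and local fiber radius (um,
#' from the distance map); edges connect consecutive nodes along fibers and
#' meet at branch vertices.
#'
#' @slot nodes data.frame with columns \code{x}, \code{y}, \code{z},
#'   \code{radius}, \code{component}.
#' @slot edges integer 2-column matrix of node indices.
#' @slot spacing nominal node arc spacing (um).
#' @export
setClass("FiberSkeleton",
  representation(nodes = "data.frame", edges = "matrix", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    need <- c("x", "y", "z", "radius", "component")
    if (!all(need %in% names(object@nodes)))
      msg <- c(msg, "nodes must have columns x, y, z, radius, component")
    if (nrow(object@edges) > 0) {
      if (any(object@edges < 1) || any(object@edges > nrow(object@nodes)))
        msg <- c(msg, "edge indices out of range")
      if (any(object@edges[, 1] == object@edges[, 2]))
        msg <- c(msg, "self-loops are not allowed")
    }
    if (nrow(object@nodes) > 0 && any(object@nodes$radius <= 0))
      msg <- c(msg, "node radii must be > 0")
    if (length(object@spacing) != 1L || object@spacing <= 0)
      msg <- c(msg, "spacing must be a positive scalar")
    if (length(msg)) msg else TRUE
  })

FiberSkeleton <- function(nodes = data.frame(x = numeric(), y = numeric(),
                                             z = numeric(),
                                             radius = numeric(),
                                             component = integer()),
                          edges = matrix(integer(), ncol = 2),
                          spacing = 0.5) {
  new("FiberSkeleton", nodes = nodes, edges = edges, spacing = spacing)
}

#' FractionatorDesign: optical-fractionator sampling design
#'
#' Counting-frame geometry and sampling fractions of the optical
#' fractionator: systematic-random frames of size \code{frame} on a grid of
#' spacing \code{grid}, a dissector of height \code{dissectorHeight} offset
#' by symmetric \code{guardZone}s inside sections of measured thickness
#' \code{sectionThickness}, counting every \code{1/ssf}-th section.
#'
#' @slot frame numeric(2), counting-frame size (um).
#' @slot grid numeric(2), frame grid spacing (um).
#' @slot ssf slice sampling fraction (0, 1].
#' @slot dissectorHeight dissector height h (um).
#' @slot guardZone guard-zone height (um), applied top and bottom.
#' @slot sectionThickness measured section thickness t (um).
#' @export
setClass("FractionatorDesign",
  representation(frame = "numeric", grid = "numeric", ssf = "numeric",
                 dissectorHeight = "numeric", guardZone = "numeric",
                 sectionThickness = "numeric"),
  validity = function(object) {
    msg <- character()
    if (any(object@frame > object@grid))
      msg <- c(msg, "frame must not exceed grid spacing")
    if (object@ssf <= 0 || object@ssf > 1)
      msg <- c(msg, "ssf must lie in (0, 1]")
    if (object@dissectorHeight + 2 * object@guardZone >
        object@sectionThickness + 1e-9)
      msg <- c(msg, "dissector height plus guard zones must fit in the section")
    if (any(c(object@frame, object@grid, object@dissectorHeight,
              object@sectionThickness) <= 0) || object@guardZone < 0)
      msg <- c(msg, "geometry must be positive (guard zone >= 0)")
    if (length(msg)) msg else TRUE
  })

#' @rdname FractionatorDesign-class
#' @param frame,grid,ssf,dissectorHeight,guardZone,sectionThickness see
#'   slots. Defaults follow the rat design: 50 x 50 um frames on a
#'   200 x 200 um grid, every 4th section, 14-um dissector with 2-um guards
#'   in 23.4-um sections.
#' @export
FractionatorDesign <- function(frame = c(50, 50), grid = c(200, 200),
                               ssf = 1 / 4, dissectorHeight = 14,
                               guardZone = 2, sectionThickness = 23.4) {
  new("FractionatorDesign", frame = as.numeric(frame), grid = as.numeric(grid),
      ssf = ssf, dissectorHeight = dissectorHeight, guardZone = guardZone,
      sectionThickness = sectionThickness)
}

#' CavalieriDesign: point-counting volume estimation design
#'
#' @slot areaPerPoint area per grid point aF (um^2).
#' @slot blockAdvance microtome block advance T (um).
#' @slot ssf slice sampling fraction.
#' @export
setClass("CavalieriDesign",
  representation(areaPerPoint = "numeric", blockAdvance = "numeric",
                 ssf = "numeric"),
  validity = function(object) {
    if (any(c(object@areaPerPoint, object@blockAdvance, object@ssf) <= 0))
      "areaPerPoint, blockAdvance and ssf must be > 0" else TRUE
  })

#' @rdname CavalieriDesign-class
#' @param areaPerPoint,blockAdvance,ssf see slots.
#' @export
CavalieriDesign <- function(areaPerPoint, blockAdvance, ssf = 1) {
  new("CavalieriDesign", areaPerPoint = areaPerPoint,
      blockAdvance = blockAdvance, ssf = ssf)
}

#' DiameterHistogram: log-binned, normalized fiber-diameter distributions
#'
#' Per-group (typically species x nucleus) diameter distributions on shared
#' natural-log-spaced bins. \code{proportions} are pooled counts normalized
#' by the group's total diameter count; \code{binMean}/\code{binSd}/\code{n}
#' hold the across-probe mean, sd and probe number per bin, used by the
#' bin-wise difference confidence intervals.
#'
#' @slot edges strictly increasing bin edges (um, log-spaced).
#' @slot proportions groups x bins matrix; each row sums to 1.
#' @slot binMean,binSd groups x bins matrices of across-probe per-bin
#'   proportion means and sds.
#' @slot n named numeric, probes per group.
#' @export
setClass("DiameterHistogram",
  representation(edges = "numeric", proportions = "matrix",
                 binMean = "matrix", binSd = "matrix", n = "numeric"),
  validity = function(object) {
    msg <- character()
    if (any(diff(object@edges) <= 0))
      msg <- c(msg, "edges must be strictly increasing")
    if (ncol(object@proportions) != length(object@edges) - 1L)
      msg <- c(msg, "proportions must have one column per bin")
    s <- rowSums(object@proportions)
    if (length(s) && any(abs(s - 1) > 1e-8))
      msg <- c(msg, "each group's proportions must sum to 1")
    if (length(msg)) msg else TRUE
  })

#' PenetrationWindow: z-slice range retained for fiber analysis
#'
#' Contiguous range of optical slices, anchored at the brightest slice, in
#' which each slice's maximal intensity reaches at least \code{level} of the
#' whole-probe maximum (default 0.954). Slice indices are 1-based and
#' inclusive.
#'
#' @slot firstSlice,lastSlice 1-based inclusive slice indices.
#' @slot level criterion level (fraction of the global maximum).
#' @export
setClass("PenetrationWindow",
  representation(firstSlice = "integer", lastSlice = "integer",
                 level = "numeric"),
  validity = function(object) {
    if (object@firstSlice < 1L || object@lastSlice < object@firstSlice)
      "slice range must be non-empty and 1-based" else TRUE
  })

#' PreprocessParams: stain-specific preprocessing parameters
#'
#' Edge-preserving (diffusion) smoothing time-stop and step size, Gaussian
#' kernel size and sigma (in voxels), the fixed segmentation threshold, and
#' the minimum particle extent retained after skeletonization.
#'
#' @slot timeStop,stepSize diffusion time-stop and step size; the number of
#'   diffusion iterations is \code{timeStop / stepSize}.
#' @slot kernelSize,sigma Gaussian kernel size (voxels per axis) and sigma.
#' @slot threshold fixed binarization threshold (0--255).
#' @slot minParticle minimum skeleton component extent retained (um).
#' @export
setClass("PreprocessParams",
  representation(timeStop = "numeric", stepSize = "numeric",
                 kernelSize = "integer", sigma = "numeric",
                 threshold = "numeric", minParticle = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@threshold < 0 || object@threshold > 255)
      msg <- c(msg, "threshold must lie in [0, 255]")
    if (object@sigma <= 0) msg <- c(msg, "sigma must be > 0")
    if (object@stepSize <= 0 || object@timeStop < 0)
      msg <- c(msg, "timeStop/stepSize must be positive")
    if (length(msg)) msg else TRUE
  })

#' @rdname PreprocessParams-class
#' @param stain one of \code{"MAP2_RAT"}, \code{"MAP2_MONKEY"},
#'   \code{"PCP2"}; selects the published time-stop (50 / 50 / 100) and
#'   threshold (25 / 40 / 80) presets.
#' @param timeStop,stepSize,kernelSize,sigma,threshold,minParticle override
#'   any preset value.
#' @export
PreprocessParams <- function(stain = c("MAP2_RAT", "MAP2_MONKEY", "PCP2"),
                             timeStop = NULL, stepSize = 5, kernelSize = 5L,
                             sigma = 1, threshold = NULL,
                             minParticle = 0.25) {
  stain <- match.arg(stain)
  preset <- switch(stain,
    MAP2_RAT = list(timeStop = 50, threshold = 25),
    MAP2_MONKEY = list(timeStop = 50, threshold = 40),
    PCP2 = list(timeStop = 100, threshold = 80))
  new("PreprocessParams",
      timeStop = if (is.null(timeStop)) preset$timeStop else timeStop,
      stepSize = stepSize, kernelSize = as.integer(kernelSize),
      sigma = sigma,
      threshold = if (is.null(threshold)) preset$threshold else threshold,
      minParticle = minParticle)
}
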