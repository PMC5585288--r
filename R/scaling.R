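#' Allometric power-law prediction
#'
#' Predicts a quantity in a larger (or smaller) brain from the volume ratio
#' of the corresponding structures raised to a fixed exponent: lengths and
#' linear sizes scale with exponent 1/3, densities with -1/3.
#'
#' @param base measured value in the reference species.
#' @param volumeRatio structure volume ratio (target / reference).
#' @param exponent scaling exponent (default 1/3).
#' @return one-row data.frame: base, volumeRatio, exponent, predicted.
#' @examples
#' powerLawPredict(7.1, 61)  # 1/3-power upscaling
#' @export
powerLawPredict <- function(base, volumeRatio, exponent = 1 / 3) {
  if (base <= 0 || volumeRatio <= 0)
    stop("base and volumeRatio must be > 0")
  data.frame(base = base, volumeRatio = volumeRatio, exponent = exponent,
             predicted = base * volumeRatio^exponent)
}

#' Rectified-difference optimal scale-factor search
#'
#' For each candidate factor f, the reference diameters are multiplied by
#' f, re-binned onto the target's log bins, and the rectified (absolute)
#' bin-wise difference of the normalized proportions is summed; the optimum
#' is the factor minimizing this sum (ties resolved towards the smaller
#' factor). Factors at which the scaled sample no longer overlaps the bin
#' range are flagged and excluded from the argmin.
#'
#' @param reference numeric vector of reference diameters (um), e.g. the
#'   rat sample.
#' @param target numeric vector of target diameters (um, e.g. the primate
#'   sample) or a single-group \code{\linkS4class{DiameterHistogram}}.
#' @param grid strictly increasing candidate factors (default 0.80--2.00 in
#'   steps of 0.01).
#' @param edges histogram bin edges (um).
#' @return list of class \code{"scaleFactorScan"}: \code{grid},
#'   \code{objective}, \code{optimum}, \code{excluded}.
#' @examples
#' s <- generateDiameterSamples(0.8, 0.35, 5000, scaleFactor = 1.2, seed = 2)
#' scaleFactorScan(s$A, s$B)$optimum
#' @export
scaleFactorScan <- function(reference, target, grid = seq(0.8, 2, by = 0.01),
                            edges = logBinEdges()) {
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (length(reference) == 0) stop("empty reference sample")
  if (is(target, "DiameterHistogram")) {
    if (nrow(target@proportions) != 1)
      stop("target histogram must have a single group")
    if (!isTRUE(all.equal(target@edges, edges)))
      edges <- target@edges
    pT <- target@proportions[1, ]
  } else {
    if (length(target) == 0) stop("empty target sample")
    pT <- binProportions(target, edges)
  }
  nb <- length(edges) - 1
  objective <- vapply(grid, function(f) {
    s <- reference * f
    if (!any(s > edges[1] & s <= edges[length(edges)])) return(NA_real_)
    sum(abs(pT - binProportions(s, edges)))
  }, numeric(1))
  excluded <- is.na(objective)
  if (all(excluded)) stop("no candidate factor overlaps the bin range")
  opt <- grid[which.min(objective)]  # NA ranks last; ties -> smaller factor
  structure(list(grid = grid, objective = objective, optimum = opt,
                 excluded = excluded),
            class = "scaleFactorScan")
}

#' @export
print.scaleFactorScan <- function(x, ...) {
  cat(sprintf("scale-factor scan: %d factors in [%.2f, %.2f], optimum %.2f\n",
              length(x$grid), min(x$grid), max(x$grid), x$optimum))
  invisible(x)
}

#' @export
plot.scaleFactorScan <- function(x, ...) {
  graphics::plot(x$grid, x$objective, type = "l",
                 xlab = "scale factor",
                 ylab = "summed rectified difference", ...)
  graphics::abline(v = x$optimum, lty = 2)
  invisible(x)
}

#' Dendritic region-of-influence from a tip polygon
#'
#' Shoelace area of the polygon connecting the outer dendritic tips,
#' converted to the equivalent-circle diameter
#' \code{2 * sqrt(area / pi)}.
#'
#' @param vertices k x 2 matrix of polygon vertices (um), in order; the
#'   polygon must be simple and non-degenerate.
#' @return data.frame: \code{source}, \code{area} (um^2), \code{diameter}
#'   (um).
#' @examples
#' droiFromPolygon(cbind(c(0, 2, 0), c(0, 0, 2)))
#' @export
droiFromPolygon <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3) stop("need at least 3 vertices")
  if (polygonSelfIntersects(vertices)) stop("self-intersecting polygon")
  area <- shoelaceArea(vertices)
  if (area <= 0) stop("degenerate (collinear) polygon: zero area")
  data.frame(source = "golgi-2D", area = area,
             diameter = 2 * sqrt(area / pi))
}

#' Dendritic region-of-influence from 3D dendritic-tip coordinates
#'
#' Projects the tip cloud onto its principal (best-fit) plane, takes the 2D
#' convex hull of the projection (the projection of the 3D hull), and
#' converts the hull area to the equivalent-circle diameter, making the 3D
#' estimate directly comparable with 2D tip-polygon estimates. Duplicate
#' points are collapsed; (near-)coplanar clouds reduce to the 2D case.
#'
#' @param tips n x 3 matrix of dendritic tip coordinates (um), n >= 4 (>= 3
#'   after deduplication for the planar fallback).
#' @return data.frame: \code{source}, \code{area} (um^2), \code{diameter}
#'   (um).
#' @export
droiFrom3dTips <- function(tips) {
  tips <- unique(as.matrix(tips))
  if (nrow(tips) < 3) stop("need at least 3 distinct tip points")
  ctr <- sweep(tips, 2, colMeans(tips))
  pc <- svd(ctr, nu = 0, nv = 3)
  proj <- ctr %*% pc$v[, 1:2]
  h <- grDevices::chull(proj)
  if (length(h) < 3) stop("degenerate tip cloud: collinear projection")
  area <- shoelaceArea(proj[h, , drop = FALSE])
  data.frame(source = "intracellular-3D", area = area,
             diameter = 2 * sqrt(area / pi))
}

#' Module multiplicity implied by a region-of-influence deficit
#'
#' A dendritic region-of-influence smaller than the allometric prediction
#' by a linear factor \code{predicted / measured} lets
#' \code{(predicted / measured)^3} times more independent modules occupy
#' the same tissue volume. Scale-invariant: multiplying both diameters by a
#' constant leaves both outputs unchanged.
#'
#' @param predictedDiameter allometrically predicted diameter (um).
#' @param measuredDiameter measured diameter (um).
#' @return one-row data.frame: \code{linearFactor},
#'   \code{volumetricMultiplicity}.
#' @examples
#' moduleMultiplicity(850, 190)
#' @export
moduleMultiplicity <- function(predictedDiameter, measuredDiameter) {
  if (predictedDiameter <= 0 || measuredDiameter <= 0)
    stop("diameters must be > 0")
  lin <- predictedDiameter / measuredDiameter
  data.frame(linearFactor = lin, volumetricMultiplicity = lin^3)
}
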