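#' @rdname VoxelStack-class
#' @param object,x a \code{VoxelStack} or \code{FiberSkeleton}.
#' @export
setGeneric("voxelData", function(object) standardGeneric("voxelData"))

#' @rdname VoxelStack-class
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' @rdname VoxelStack-class
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @rdname FiberSkeleton-class
#' @export
setGeneric("nodeTable", function(object) standardGeneric("nodeTable"))

#' @rdname FiberSkeleton-class
#' @export
setGeneric("edgeTable", function(object) standardGeneric("edgeTable"))

#' @rdname FiberSkeleton-class
#' @export
setGeneric("totalLength", function(object, ...) standardGeneric("totalLength"))

#' @exportMethod voxelData
setMethod("voxelData", "VoxelStack", function(object) object@data)

#' @exportMethod voxelSize
setMethod("voxelSize", "VoxelStack", function(object) object@voxelSize)

#' @exportMethod provenance
setMethod("provenance", "VoxelStack", function(object) object@provenance)

#' @exportMethod dim
setMethod("dim", "VoxelStack", function(x) dim(x@data))

#' @exportMethod show
setMethod("show", "VoxelStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("VoxelStack [%s]: %d x %d x %d voxels, %.3g x %.3g x %.3g um\n",
              object@provenance, d[1], d[2], d[3],
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3]))
  if (prod(d) > 0)
    cat(sprintf("  intensity range [%g, %g]\n",
                min(object@data), max(object@data)))
})

#' @exportMethod nodeTable
setMethod("nodeTable", "FiberSkeleton", function(object) object@nodes)

#' @exportMethod edgeTable
setMethod("edgeTable", "FiberSkeleton", function(object) object@edges)

#' @describeIn FiberSkeleton-class total skeleton length (um): sum of all
#'   edge lengths.
#' @param ... unused.
#' @exportMethod totalLength
setMethod("totalLength", "FiberSkeleton", function(object, ...) {
  if (nrow(object@edges) == 0) return(0)
  p <- as.matrix(object@nodes[, c("x", "y", "z")])
  sum(sqrt(rowSums((p[object@edges[, 1], , drop = FALSE] -
                    p[object@edges[, 2], , drop = FALSE])^2)))
})

#' @exportMethod show
setMethod("show", "FiberSkeleton", function(object) {
  cat(sprintf(paste0("FiberSkeleton: %d nodes, %d edges, %d components, ",
                     "total length %.2f um\n"),
              nrow(object@nodes), nrow(object@edges),
              length(unique(object@nodes$component)), totalLength(object)))
})

#' @exportMethod show
setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d polylines, total length %.2f um, %d points\n",
              length(object@polylines), object@totalLength,
              nrow(object@points)))
})

#' @exportMethod show
setMethod("show", "PenetrationWindow", function(object) {
  cat(sprintf("PenetrationWindow: slices %d..%d (level %.3f)\n",
              object@firstSlice, object@lastSlice, object@level))
})

#' @exportMethod show
setMethod("show", "DiameterHistogram", function(object) {
  cat(sprintf("DiameterHistogram: %d groups x %d log bins (%.2f..%.2f um)\n",
              nrow(object@proportions), ncol(object@proportions),
              min(object@edges), max(object@edges)))
})

#' @describeIn GroundTruth-class exact total centreline length (um).
#' @exportMethod totalLength
setMethod("totalLength", "GroundTruth", function(object, ...)
  object@totalLength)
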