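#' Read and write voxel stacks as multi-page TIFF
#'
#' Stacks are stored as multi-page 8-bit grayscale TIFF (one page per
#' optical slice, rows = first array axis) with the physical voxel size
#' recorded in a JSON sidecar (\code{<file>.json}).
#'
#' @param stack a \code{\linkS4class{VoxelStack}}.
#' @param path TIFF file path.
#' @return \code{writeStackTIFF} returns the path invisibly;
#'   \code{readStackTIFF} returns a \code{VoxelStack}.
#' @export
writeStackTIFF <- function(stack, path) {
  stopifnot(is(stack, "VoxelStack"))
  scale <- if (stack@provenance == "binary") 1 else 255
  pages <- lapply(seq_len(dim(stack)[3]),
                  function(k) stack@data[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  jsonlite::write_json(
    list(voxelSizeUm = stack@voxelSize, provenance = stack@provenance),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeStackTIFF
#' @param voxelSize fallback voxel size when no sidecar is present.
#' @export
readStackTIFF <- function(path, voxelSize = c(1, 1, 1)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  sidecar <- paste0(path, ".json")
  provenance <- "raw"
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    voxelSize <- meta$voxelSizeUm
    provenance <- meta$provenance
  }
  scale <- if (provenance == "binary") 1 else 255
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    arr[, , k] <- round(pg * scale)
  }
  VoxelStack(arr, voxelSize, provenance)
}

#' Export a fiber skeleton
#'
#' \code{writeSWC} writes the skeleton in SWC format (type code 0, radius
#' column = node radius, parents from a spanning traversal per component;
#' cycle-closing edges are necessarily dropped, SWC being a tree format).
#' \code{writeSkeletonCSV} writes lossless node and edge tables.
#'
#' @param skeleton a \code{\linkS4class{FiberSkeleton}}.
#' @param path output file path (for \code{writeSkeletonCSV}, the node
#'   table; the edge table gets suffix \code{_edges.csv}).
#' @return the path, invisibly.
#' @export
writeSWC <- function(skeleton, path) {
  stopifnot(is(skeleton, "FiberSkeleton"))
  nd <- skeleton@nodes
  n <- nrow(nd)
  parent <- rep(-1L, n)
  if (nrow(skeleton@edges)) {
    g <- igraph::graph_from_edgelist(skeleton@edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
    for (cc in unique(comp)) {
      root <- min(which(comp == cc))
      b <- igraph::bfs(g, root = root, father = TRUE, unreachable = FALSE)
      f <- suppressWarnings(as.integer(b$father))
      for (v in which(comp == cc))
        if (!is.na(f[v]) && f[v] > 0) parent[v] <- f[v]
    }
  }
  swc <- data.frame(id = seq_len(n), type = 0L,
                    x = nd$x, y = nd$y, z = nd$z, radius = nd$radius,
                    parent = parent)
  utils::write.table(swc, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeSWC
#' @export
writeSkeletonCSV <- function(skeleton, path) {
  stopifnot(is(skeleton, "FiberSkeleton"))
  utils::write.csv(skeleton@nodes, path, row.names = FALSE)
  ed <- as.data.frame(skeleton@edges)
  names(ed) <- c("from", "to")
  utils::write.csv(ed, sub("\\.csv$", "_edges.csv", path), row.names = FALSE)
  invisible(path)
}
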