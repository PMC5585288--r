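#' Euclidean distance map of a binary stack
#'
#' Exact anisotropic Euclidean distance transform: each foreground voxel
#' receives its physical distance (um) to the nearest background voxel
#' centre. On digitized tubes the inclusion rule (voxel centres inside the
#' surface) erodes the digital object by about the same amount as the
#' background-centre overshoot, so the centreline value approximates the
#' tube radius directly. One-voxel-thin structures (distance equal to one
#' voxel spacing) are assigned half the smallest voxel edge, the natural
#' radius of an isolated voxel. Background voxels are 0.
#'
#' @param binary a binary \code{\linkS4class{VoxelStack}}.
#' @return numeric 3D array of distances (um).
#' @export
distanceMap <- function(binary) {
  stopifnot(is(binary, "VoxelStack"))
  d <- dim(binary)
  d2 <- edt_squared_cpp(as.integer(binary@data != 0), d, binary@voxelSize)
  dm <- sqrt(d2)
  half <- min(binary@voxelSize) / 2
  thin <- binary@data != 0 & dm <= min(binary@voxelSize) * 1.0001
  dm[thin] <- half
  dm[binary@data == 0] <- 0
  array(dm, d)
}

#' Topology-preserving 3D thinning to a curve skeleton
#'
#' Iteratively removes simple points (removal preserves both object and
#' background topology; 26-connected object, 6-connected background) in
#' order of increasing distance-map value, so erosion proceeds from the
#' surface inwards and stops on the medial curve. Curve endpoints are
#' preserved. The output is a subset of the input with the same connected
#' components.
#'
#' @param binary a binary \code{\linkS4class{VoxelStack}}.
#' @param dm optional precomputed \code{\link{distanceMap}} array used as
#'   the erosion priority.
#' @return binary \code{VoxelStack} holding the one-voxel-wide skeleton.
#' @export
thinToSkeleton <- function(binary, dm = NULL) {
  stopifnot(is(binary, "VoxelStack"))
  if (is.null(dm)) dm <- distanceMap(binary)
  # deterministic sub-voxel jitter breaks priority ties; without it,
  # plateaus of equal distance (e.g. an axis-aligned tube with an
  # even-width core) are deleted in index order, which can zip through a
  # two-voxel-wide ridge end-to-end
  n <- length(dm)
  jitter <- ((seq_len(n) * 2654435761) %% 1048576) / 1048576
  prio <- as.numeric(dm) + jitter * (min(binary@voxelSize) * 1e-3)
  out <- thin3d_cpp(as.integer(binary@data != 0), dim(binary), prio)
  VoxelStack(array(as.numeric(out), dim(binary)), binary@voxelSize, "binary")
}

#' Convert a thinned stack into a radius-annotated fiber skeleton graph
#'
#' Traces 26-connected skeleton voxel chains into polylines (branch voxels
#' become graph vertices of degree >= 3; cycles are allowed), lightly
#' smooths each chain to suppress voxel-grid zigzag, resamples it at a fixed
#' arc spacing (0.5 um, both chain ends kept), and annotates every node with
#' the local fiber radius obtained by trilinear interpolation of the
#' distance map at the node position.
#'
#' @param skeleton thinned binary \code{\linkS4class{VoxelStack}} (from
#'   \code{\link{thinToSkeleton}}).
#' @param dm distance map array from \code{\link{distanceMap}} (computed on
#'   the pre-thinning binary stack).
#' @param spacing node arc spacing (um).
#' @param smoothWindow,smoothPasses moving-average smoothing of traced
#'   chains before resampling (endpoints fixed).
#' @param extendTips extend every degree-1 chain end outward by its local
#'   radius: the medial axis of a capped tube stops one radius short of the
#'   cap, so uncorrected skeletons systematically under-measure each fiber
#'   end.
#' @param cycleCollapse drop voxel-graph chord edges that close cycles
#'   shorter than this length (um). Where two tubes cross or touch,
#'   thinning leaves ladder-like double connections whose rungs would be
#'   counted as extra fiber length; genuine (long) cycles are kept.
#' @return a \code{\linkS4class{FiberSkeleton}}.
#' @export
buildGraph <- function(skeleton, dm, spacing = 0.5, smoothWindow = 3L,
                       smoothPasses = 1L, extendTips = TRUE,
                       cycleCollapse = 3) {
  stopifnot(is(skeleton, "VoxelStack"))
  d <- dim(skeleton)
  voxel <- skeleton@voxelSize
  ids <- which(skeleton@data != 0)
  if (length(ids) == 0) return(FiberSkeleton(spacing = spacing))
  vox <- arrayInd(ids, d)
  lookup <- array(0L, d)
  lookup[ids] <- seq_along(ids)

  # 26-neighbour voxel adjacency (13 positive half-offsets, deterministic
  # lexicographic order)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
               (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), ,
               drop = FALSE]
  efrom <- integer(0); eto <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(vox, 2, offs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    tid <- integer(length(ids))
    tid[ok] <- lookup[nb[ok, , drop = FALSE]]
    hit <- tid > 0
    efrom <- c(efrom, which(hit))
    eto <- c(eto, tid[hit])
  }

  if (cycleCollapse > 0 && length(efrom)) {
    pr <- pruneShortChords(vox, voxel, efrom, eto, cycleCollapse)
    efrom <- pr$from
    eto <- pr$to
  }

  paths <- traceChains(length(ids), efrom, eto)

  nodes <- list(); edges <- list()
  termNode <- new.env(parent = emptyenv())  # terminal voxel -> node index
  nNodes <- 0L
  addRun <- function(xyz, firstKey, lastKey) {
    n <- nrow(xyz)
    idxs <- integer(n)
    reuseFirst <- !is.null(firstKey) && !is.null(termNode[[firstKey]])
    reuseLast <- !is.null(lastKey) && !is.null(termNode[[lastKey]])
    for (i in seq_len(n)) {
      if (i == 1 && reuseFirst) {
        idxs[1] <- termNode[[firstKey]]
      } else if (i == n && reuseLast) {
        idxs[n] <- termNode[[lastKey]]
      } else {
        nNodes <<- nNodes + 1L
        nodes[[nNodes]] <<- xyz[i, ]
        idxs[i] <- nNodes
        if (i == 1 && !is.null(firstKey)) termNode[[firstKey]] <<- nNodes
        if (i == n && !is.null(lastKey)) termNode[[lastKey]] <<- nNodes
      }
    }
    if (n > 1) {
      e <- cbind(idxs[-n], idxs[-1])
      e <- e[e[, 1] != e[, 2], , drop = FALSE]
      if (nrow(e)) edges[[length(edges) + 1L]] <<- e
    }
    invisible(NULL)
  }

  for (p in paths) {
    xyz <- sweep(vox[p$voxels, , drop = FALSE] - 0.5, 2, voxel, "*")
    if (nrow(xyz) > 2)
      xyz <- smoothPolyline(xyz, window = smoothWindow, passes = smoothPasses)
    xyz <- resamplePolyline(xyz, spacing)
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    addRun(xyz,
           if (p$terminalFirst) as.character(p$voxels[1]) else NULL,
           if (p$terminalLast) as.character(p$voxels[length(p$voxels)])
           else NULL)
  }

  pos <- do.call(rbind, nodes)
  edg <- if (length(edges)) do.call(rbind, edges) else
    matrix(integer(), ncol = 2)
  storage.mode(edg) <- "integer"
  rad <- trilinearInterp(dm, voxel, pos)
  rad <- pmax(rad, min(voxel) / 4)

  if (extendTips && nrow(edg) > 0) {
    deg <- tabulate(edg, nbins = nNodes)
    tips <- which(deg == 1)
    for (tp in tips) {
      e <- which(edg[, 1] == tp | edg[, 2] == tp)[1]
      nbIdx <- setdiff(edg[e, ], tp)
      dirv <- pos[tp, ] - pos[nbIdx, ]
      nv <- sqrt(sum(dirv^2))
      if (nv < 1e-9) next
      nNodes <- nNodes + 1L
      pos <- rbind(pos, pos[tp, ] + dirv / nv * rad[tp])
      rad <- c(rad, rad[tp])
      edg <- rbind(edg, c(tp, nNodes))
    }
    storage.mode(edg) <- "integer"
  }

  g <- igraph::graph_from_edgelist(edg, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nNodes - igraph::vcount(g)))
  comp <- igraph::components(g)$membership

  FiberSkeleton(nodes = data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                                   radius = rad,
                                   component = as.integer(comp)),
                edges = edg, spacing = spacing)
}

# remove non-spanning-tree voxel edges that close short cycles (ladder
# rungs at tube crossings); chords closing cycles longer than `thresh` are
# genuine topology and kept
pruneShortChords <- function(vox, voxel, efrom, eto, thresh) {
  w <- sqrt(rowSums((sweep(vox[efrom, , drop = FALSE], 2, voxel, "*") -
                     sweep(vox[eto, , drop = FALSE], 2, voxel, "*"))^2))
  g <- igraph::graph_from_edgelist(cbind(efrom, eto), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(vox) - igraph::vcount(g)))
  igraph::E(g)$weight <- w
  igraph::E(g)$eid <- seq_along(w)
  tre <- igraph::mst(g)
  treeIds <- igraph::E(tre)$eid
  extras <- setdiff(seq_along(w), treeIds)
  if (length(extras) == 0) return(list(from = efrom, to = eto))
  keep <- igraph::subgraph_from_edges(g, which(igraph::E(g)$eid %in% treeIds),
                                      delete.vertices = FALSE)
  kept <- treeIds
  for (e in extras[order(w[extras])]) {
    dpath <- igraph::distances(keep, v = efrom[e], to = eto[e])[1, 1]
    if (!is.finite(dpath) || dpath + w[e] > thresh) {
      keep <- igraph::add_edges(keep, c(efrom[e], eto[e]),
                                attr = list(weight = w[e]))
      kept <- c(kept, e)
    }
  }
  kept <- sort(kept)
  list(from = efrom[kept], to = eto[kept])
}

# decompose a voxel adjacency graph into maximal chains between terminal
# vertices (degree != 2); pure cycles get an arbitrary but deterministic
# anchor. Returns list of (voxels = vertex index path, terminalFirst/Last).
traceChains <- function(nv, efrom, eto) {
  adj <- vector("list", nv)
  ne <- length(efrom)
  if (ne) {
    for (i in seq_len(ne)) {
      adj[[efrom[i]]] <- c(adj[[efrom[i]]], list(c(eto[i], i)))
      adj[[eto[i]]] <- c(adj[[eto[i]]], list(c(efrom[i], i)))
    }
  }
  deg <- vapply(adj, length, integer(1))
  visited <- logical(ne)
  inChain <- logical(nv)
  paths <- list()

  walk <- function(v0, firstEdge) {
    path <- v0
    e <- firstEdge
    v <- v0
    repeat {
      visited[e[2]] <<- TRUE
      v <- e[1]
      path <- c(path, v)
      inChain[v] <<- TRUE
      if (deg[v] != 2) break
      nxt <- NULL
      for (cand in adj[[v]]) if (!visited[cand[2]]) { nxt <- cand; break }
      if (is.null(nxt)) break
      e <- nxt
    }
    path
  }

  terminals <- which(deg != 2)
  for (v0 in terminals) {
    inChain[v0] <- TRUE
    for (cand in adj[[v0]]) {
      if (visited[cand[2]]) next
      path <- walk(v0, cand)
      vLast <- path[length(path)]
      paths[[length(paths) + 1L]] <-
        list(voxels = path, terminalFirst = TRUE,
             terminalLast = deg[vLast] != 2)
    }
  }
  # remaining unvisited edges belong to pure cycles
  for (i in seq_len(ne)) {
    if (ne == 0 || visited[i]) next
    v0 <- efrom[i]
    path <- walk(v0, c(eto[i], i))
    paths[[length(paths) + 1L]] <-
      list(voxels = path, terminalFirst = TRUE, terminalLast = TRUE)
  }
  # isolated voxels
  for (v in which(deg == 0)) {
    paths[[length(paths) + 1L]] <-
      list(voxels = v, terminalFirst = TRUE, terminalLast = TRUE)
  }
  paths
}

#' Remove spuriously small skeleton particles
#'
#' Drops connected components whose maximal path length (geodesic extent)
#' falls below \code{minExtent}; components of exactly \code{minExtent} are
#' kept (the cutoff excludes strictly smaller particles). Raising the cutoff
#' never increases the surviving total length.
#'
#' @param skeleton a \code{\linkS4class{FiberSkeleton}}.
#' @param minExtent minimum component extent retained (um, default 0.25).
#' @return filtered \code{FiberSkeleton} with re-indexed nodes.
#' @export
filterParticles <- function(skeleton, minExtent = 0.25) {
  stopifnot(is(skeleton, "FiberSkeleton"))
  nd <- skeleton@nodes
  if (nrow(nd) == 0) return(skeleton)
  ed <- skeleton@edges
  p <- as.matrix(nd[, c("x", "y", "z")])
  elen <- if (nrow(ed)) sqrt(rowSums((p[ed[, 1], , drop = FALSE] -
                                      p[ed[, 2], , drop = FALSE])^2)) else
    numeric(0)
  keep <- logical(max(nd$component))
  for (cc in unique(nd$component)) {
    eIn <- which(nd$component[ed[, 1]] == cc)
    tot <- sum(elen[eIn])
    if (tot < minExtent) { keep[cc] <- FALSE; next }
    if (tot >= 4 * minExtent) { keep[cc] <- TRUE; next }
    # small component: extent = weighted geodesic diameter
    vIdx <- which(nd$component == cc)
    g <- igraph::graph_from_edgelist(
      matrix(match(as.integer(ed[eIn, ]), vIdx), ncol = 2), directed = FALSE)
    igraph::E(g)$weight <- elen[eIn]
    dmat <- igraph::distances(g)
    keep[cc] <- max(dmat[is.finite(dmat)]) >= minExtent
  }
  vKeep <- keep[nd$component]
  remap <- cumsum(vKeep)
  edKeep <- ed[vKeep[ed[, 1]] & vKeep[ed[, 2]], , drop = FALSE]
  edNew <- matrix(as.integer(remap[edKeep]), ncol = 2)
  ndNew <- nd[vKeep, , drop = FALSE]
  rownames(ndNew) <- NULL
  ndNew$component <- as.integer(factor(ndNew$component))
  FiberSkeleton(nodes = ndNew, edges = edNew, spacing = skeleton@spacing)
}

#' Tissue shrinkage correction factor
#'
#' Ratio of the measured post-processing section thickness to the microtome
#' block advance; staining and embedding shrink sections substantially
#' (e.g., 60-um block advance mounting at 22 um gives a factor of ~0.37).
#'
#' @param blockAdvance microtome block advance (um).
#' @param measuredThickness post-processing section thickness (um).
#' @return shrinkage fraction (measured / block advance).
#' @examples
#' shrinkageFactor(60, 22)
#' @export
shrinkageFactor <- function(blockAdvance, measuredThickness) {
  if (blockAdvance <= 0 || measuredThickness <= 0)
    stop("thicknesses must be > 0")
  measuredThickness / blockAdvance
}

#' Fiber length density of a probe
#'
#' Sums skeleton length inside the penetration window and divides by the
#' windowed probe volume. The volume is rescaled to pre-shrinkage tissue by
#' dividing the z-extent contribution by the shrinkage factor, so the
#' corrected density equals the uncorrected density multiplied by the
#' shrinkage fraction.
#'
#' @param skeleton a \code{\linkS4class{FiberSkeleton}} (positions in um).
#' @param stack the \code{\linkS4class{VoxelStack}} the skeleton was
#'   measured in (supplies dimensions and voxel size).
#' @param window optional \code{\linkS4class{PenetrationWindow}}; default
#'   uses the full z-range.
#' @param shrinkage shrinkage fraction from \code{\link{shrinkageFactor}}
#'   (1 = no correction).
#' @return one-row data.frame: total length (um), windowed volume (um^3),
#'   pre-shrinkage volume (um^3), uncorrected and corrected density
#'   (m/mm^3).
#' @export
lengthDensity <- function(skeleton, stack, window = NULL, shrinkage = 1) {
  stopifnot(is(skeleton, "FiberSkeleton"), is(stack, "VoxelStack"))
  if (shrinkage <= 0) stop("shrinkage factor must be > 0")
  d <- dim(stack)
  voxel <- stack@voxelSize
  if (is.null(window)) {
    zlim <- c(0, d[3] * voxel[3])
    nz <- d[3]
  } else {
    zlim <- c((window@firstSlice - 1) * voxel[3], window@lastSlice * voxel[3])
    nz <- window@lastSlice - window@firstSlice + 1L
  }
  nd <- skeleton@nodes
  ed <- skeleton@edges
  L <- 0
  if (nrow(ed)) {
    inWin <- nd$z >= zlim[1] & nd$z <= zlim[2]
    use <- inWin[ed[, 1]] & inWin[ed[, 2]]
    p <- as.matrix(nd[, c("x", "y", "z")])
    L <- sum(sqrt(rowSums((p[ed[use, 1], , drop = FALSE] -
                           p[ed[use, 2], , drop = FALSE])^2)))
  }
  vol <- d[1] * voxel[1] * d[2] * voxel[2] * nz * voxel[3]
  if (vol <= 0) stop("probe volume must be > 0")
  volCorr <- vol / shrinkage
  data.frame(totalLength = L, volumeUm3 = vol, correctedVolumeUm3 = volCorr,
             density = L / vol * 1000, correctedDensity = L / volCorr * 1000)
}

#' Full stack-to-skeleton reconstruction
#'
#' Convenience wrapper chaining \code{\link{distanceMap}},
#' \code{\link{thinToSkeleton}}, \code{\link{buildGraph}} and
#' \code{\link{filterParticles}} on a binary stack.
#'
#' @param binary a binary \code{\linkS4class{VoxelStack}}.
#' @param minExtent particle-filter cutoff (um).
#' @param ... passed to \code{\link{buildGraph}}.
#' @return a \code{\linkS4class{FiberSkeleton}}.
#' @export
reconstructSkeleton <- function(binary, minExtent = 0.25, ...) {
  dm <- distanceMap(binary)
  thin <- thinToSkeleton(binary, dm)
  filterParticles(buildGraph(thin, dm, ...), minExtent = minExtent)
}
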