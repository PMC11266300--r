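#' Construct a TriangleMesh
#'
#' @param vertices numeric P x 3 matrix, mm.
#' @param faces integer F x 3 matrix of 1-based vertex indices.
#' @param name optional identifier.
#' @param side optional `"left"`/`"right"` tag.
#' @param metadata named list of auxiliary entries.
#' @return A [TriangleMesh-class].
#' @examples
#' tet <- triangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
#'                     rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4)))
#' nVertices(tet)
#' @export
triangleMesh <- function(vertices, faces, name = NULL, side = NULL,
                         metadata = list()) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  new("TriangleMesh", vertices = vertices, faces = faces, name = name,
      side = side, metadata = metadata)
}

#' @describeIn triangleMesh vertex coordinate matrix (P x 3, mm).
#' @param mesh,object a [TriangleMesh-class].
#' @export
meshVertices <- function(mesh) mesh@vertices

#' @describeIn triangleMesh face index matrix (F x 3, 1-based).
#' @export
meshFaces <- function(mesh) mesh@faces

#' @describeIn triangleMesh number of vertices.
#' @export
nVertices <- function(mesh) nrow(mesh@vertices)

#' @describeIn triangleMesh number of faces.
#' @export
nFaces <- function(mesh) nrow(mesh@faces)

#' @describeIn triangleMesh metadata list.
#' @export
meshMetadata <- function(mesh) mesh@metadata

#' @describeIn triangleMesh replace the metadata list.
#' @param value replacement metadata list.
#' @export
`meshMetadata<-` <- function(mesh, value) {
  mesh@metadata <- value
  mesh
}

setMethod("show", "TriangleMesh", function(object) {
  cat("TriangleMesh", if (!is.null(object@name)) object@name else "",
      if (!is.null(object@side)) sprintf("(%s)", object@side) else "", "\n")
  cat(sprintf("  %d vertices, %d faces\n", nVertices(object), nFaces(object)))
  if (nVertices(object) > 0) {
    bb <- apply(object@vertices, 2, range)
    cat(sprintf("  bbox [%.1f, %.1f] x [%.1f, %.1f] x [%.1f, %.1f] mm\n",
                bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  }
  if (isTRUE(object@metadata$aligned))
    cat("  aligned to anatomical frame\n")
  invisible(NULL)
})

#' Edge lengths of a mesh
#'
#' Unique undirected edges and their Euclidean lengths in mm.
#'
#' @param mesh a [TriangleMesh-class].
#' @return numeric vector of edge lengths.
#' @export
edgeLengths <- function(mesh) {
  e <- meshEdges(mesh)
  v <- mesh@vertices
  sqrt(rowSums((v[e[, 1], , drop = FALSE] - v[e[, 2], , drop = FALSE])^2))
}

# unique undirected edges as a 2-column matrix (smaller index first)
meshEdges <- function(mesh) {
  f <- mesh@faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[!duplicated(e[, 1] * (nVertices(mesh) + 1) + e[, 2]), , drop = FALSE]
}

# directed edge multiplicity bookkeeping for manifoldness checks
edgeUseCounts <- function(mesh) {
  f <- mesh@faces
  P <- as.numeric(nVertices(mesh) + 1)
  und <- c(pmin(f[, 1], f[, 2]) * P + pmax(f[, 1], f[, 2]),
           pmin(f[, 2], f[, 3]) * P + pmax(f[, 2], f[, 3]),
           pmin(f[, 3], f[, 1]) * P + pmax(f[, 3], f[, 1]))
  table(und)
}

#' Surface area, enclosed volume and Euler characteristic
#'
#' `meshArea` sums triangle areas (mm^2); `meshVolume` uses the divergence
#' theorem (signed, positive for outward-oriented closed surfaces, mm^3);
#' `eulerCharacteristic` returns V - E + F (2 for a genus-0 closed surface).
#'
#' @param mesh a [TriangleMesh-class].
#' @export
meshArea <- function(mesh) {
  v <- mesh@vertices
  f <- mesh@faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' @rdname meshArea
#' @export
meshVolume <- function(mesh) {
  v <- mesh@vertices
  f <- mesh@faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) +
      p1[, 2] * (p2[, 3] * p3[, 1] - p2[, 1] * p3[, 3]) +
      p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
}

#' @rdname meshArea
#' @export
eulerCharacteristic <- function(mesh) {
  nVertices(mesh) - nrow(meshEdges(mesh)) + nFaces(mesh)
}

#' Watertightness / manifoldness check
#'
#' A mesh is closed-manifold when every undirected edge is shared by
#' exactly two faces and the two incident faces traverse it in opposite
#' directions (consistent orientation).
#'
#' @param mesh a [TriangleMesh-class].
#' @return logical; attributes `boundaryEdges` and `nonmanifoldEdges` give
#'   the offending counts.
#' @export
isWatertight <- function(mesh) {
  if (nFaces(mesh) == 0) return(structure(FALSE, boundaryEdges = 0L,
                                          nonmanifoldEdges = 0L))
  cnt <- edgeUseCounts(mesh)
  boundary <- sum(cnt == 1)
  nonmanifold <- sum(cnt > 2)
  f <- mesh@faces
  P <- as.numeric(nVertices(mesh) + 1)
  dir_keys <- c(f[, 1] * P + f[, 2], f[, 2] * P + f[, 3], f[, 3] * P + f[, 1])
  oriented <- !any(duplicated(dir_keys))
  structure(boundary == 0 && nonmanifold == 0 && oriented,
            boundaryEdges = as.integer(boundary),
            nonmanifoldEdges = as.integer(nonmanifold))
}

#' Connected components of a mesh
#'
#' Components over the face-adjacency graph (faces sharing an edge).
#'
#' @param mesh a [TriangleMesh-class].
#' @param largestOnly return only the component with the largest face count.
#' @return list of [TriangleMesh-class] (or a single mesh when
#'   `largestOnly = TRUE`), ordered by decreasing face count.
#' @export
connectedComponents <- function(mesh, largestOnly = FALSE) {
  f <- mesh@faces
  nf <- nrow(f)
  if (nf == 0) stop("mesh has no faces")
  P <- as.numeric(nVertices(mesh) + 1)
  keys <- c(pmin(f[, 1], f[, 2]) * P + pmax(f[, 1], f[, 2]),
            pmin(f[, 2], f[, 3]) * P + pmax(f[, 2], f[, 3]),
            pmin(f[, 3], f[, 1]) * P + pmax(f[, 3], f[, 1]))
  fidx <- rep(seq_len(nf), 3)
  ord <- order(keys)
  keys <- keys[ord]
  fidx <- fidx[ord]
  same <- which(keys[-1] == keys[-length(keys)])
  el <- cbind(fidx[same], fidx[same + 1])
  g <- igraph::graph_from_edgelist(unique(el), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nf - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  comps <- split(seq_len(nf), memb)
  comps <- comps[order(-vapply(comps, length, 1L))]
  result <- lapply(comps, function(idx) subsetMeshFaces(mesh, idx))
  if (largestOnly) result[[1]] else result
}

# keep a subset of faces and drop unreferenced vertices
subsetMeshFaces <- function(mesh, face_idx) {
  f <- mesh@faces[face_idx, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(nVertices(mesh))
  remap[used] <- seq_along(used)
  triangleMesh(mesh@vertices[used, , drop = FALSE],
               matrix(remap[f], ncol = 3),
               name = mesh@name, side = mesh@side, metadata = mesh@metadata)
}

# keep a subset of vertices (and faces fully inside the subset)
subsetMeshVertices <- function(mesh, keep) {
  keep_idx <- which(keep)
  remap <- integer(nVertices(mesh))
  remap[keep_idx] <- seq_along(keep_idx)
  f <- mesh@faces
  fk <- keep[f[, 1]] & keep[f[, 2]] & keep[f[, 3]]
  triangleMesh(mesh@vertices[keep_idx, , drop = FALSE],
               matrix(remap[f[fk, , drop = FALSE]], ncol = 3),
               name = mesh@name, side = mesh@side, metadata = mesh@metadata)
}

#' Centroid size of a mesh
#'
#' Root-mean-square distance of the vertices from their centroid; the scale
#' measure used to pick the median template specimen.
#'
#' @param mesh a [TriangleMesh-class] or a P x 3 coordinate matrix.
#' @return positive scalar (mm).
#' @export
centroidSize <- function(mesh) {
  v <- if (is(mesh, "TriangleMesh")) mesh@vertices else as.matrix(mesh)
  cen <- colMeans(v)
  sqrt(mean(rowSums(sweep(v, 2, cen)^2)))
}

#' Distances from points to a mesh surface
#'
#' Exact closest-point distances from a set of query points to a triangle
#' soup, used for remeshing deviation checks and Hausdorff-type metrics.
#'
#' @param points N x 3 matrix of query points (mm).
#' @param mesh a [TriangleMesh-class].
#' @return list with `distance` (N), `points` (N x 3 closest points) and
#'   `face` (N, 1-based face index).
#' @export
surfaceDistance <- function(points, mesh) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  .closestOnSurface(points, mesh@vertices, mesh@faces)
}
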