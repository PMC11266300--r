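#' Select the template specimen
#'
#' Returns the index of the mesh whose centroid size is the population
#' median (lower median for an even count).  Scale dominates variation in
#' bone populations, which makes centroid size the natural order statistic
#' for picking a "median" specimen; the selected mesh is subsequently
#' remeshed to the standard 2 mm resolution when the corresponded set is
#' built.
#'
#' @param meshes non-empty list of [TriangleMesh-class].
#' @return integer index into `meshes`.
#' @export
selectTemplate <- function(meshes) {
  if (length(meshes) == 0) stop("cannot select a template from an empty list")
  sizes <- vapply(meshes, centroidSize, numeric(1))
  order(sizes)[floor((length(sizes) + 1) / 2)]
}

#' Register a target shape onto the template connectivity
#'
#' For every template vertex, takes the nearest target vertex
#' (`mode = "vertex"`, the default) or the closest point on the target
#' surface (`mode = "surface"`); the output adopts the template's vertex
#' count and connectivity.  Queries use a uniform spatial grid but are
#' exact: results equal an exhaustive nearest-neighbour search, with ties
#' broken towards the lowest target vertex index.
#'
#' @param template a [TriangleMesh-class] (the connectivity owner).
#' @param target a [TriangleMesh-class] in the same anatomical frame.
#' @param mode `"vertex"` or `"surface"`.
#' @return P x 3 matrix of corresponded coordinates (P = template vertex
#'   count) with attribute `meanDistance` (mean correspondence distance,
#'   a quality-control metric).
#' @export
registerNearestNeighbor <- function(template, target,
                                    mode = c("vertex", "surface")) {
  stopifnot(is(template, "TriangleMesh"), is(target, "TriangleMesh"))
  mode <- match.arg(mode)
  if (nVertices(target) == 0) stop("target mesh is empty")
  q <- template@vertices
  if (mode == "vertex") {
    idx <- .nearestVertex(q, target@vertices)
    out <- target@vertices[idx, , drop = FALSE]
  } else {
    cp <- .closestOnSurface(q, target@vertices, target@faces)
    out <- cp$points
  }
  attr(out, "meanDistance") <- mean(sqrt(rowSums((out - q)^2)))
  out
}

#' Build a corresponded set from aligned meshes
#'
#' Remeshes the chosen template to the target edge length and registers
#' every training mesh onto its connectivity by nearest-neighbour
#' resampling; the template itself enters the set as its own (remeshed)
#' vertices.  Per-shape mean correspondence distance is recorded as a QC
#' metric.
#'
#' @param meshes list of aligned [TriangleMesh-class] (K >= 2 for model
#'   building).
#' @param template_index index of the template mesh; `NULL` selects the
#'   median-size specimen via [selectTemplate()].
#' @param target_edge template remeshing edge length in mm.
#' @param mode correspondence mode, see [registerNearestNeighbor()].
#' @param remesh_template remesh the template before registration
#'   (disable for meshes already at the target resolution).
#' @param ids specimen labels (default `names(meshes)` or `shape_<k>`).
#' @param require_aligned insist that every mesh carries the
#'   aligned-to-frame metadata flag.
#' @param size_normalize initialise each registration with a similarity
#'   normalisation: the target is scaled to the template's centroid size
#'   about the anatomical origin before nearest-neighbour resampling and
#'   the corresponded vertices are scaled back afterwards (they therefore
#'   still lie exactly on the target geometry).  Without this, plain
#'   closest-point matching cannot express large size offsets at the bone
#'   extremities -- template vertices fall inside the head of a larger
#'   specimen and the map folds -- and the resulting model leaks scale
#'   variance into spurious modes.  Default on.
#' @return A [CorrespondedSet-class].
#' @export
buildCorrespondedSet <- function(meshes, template_index = NULL,
                                 target_edge = 2.0,
                                 mode = c("vertex", "surface"),
                                 remesh_template = TRUE, ids = NULL,
                                 require_aligned = TRUE,
                                 size_normalize = TRUE) {
  mode <- match.arg(mode)
  K <- length(meshes)
  if (K < 1) stop("no meshes supplied")
  if (is.null(ids)) {
    ids <- names(meshes)
    if (is.null(ids)) ids <- sprintf("shape_%02d", seq_len(K))
  }
  if (require_aligned) {
    ok <- vapply(meshes, function(m) isTRUE(m@metadata$aligned), logical(1))
    if (!all(ok))
      stop("meshes not aligned to an anatomical frame: ",
           paste(ids[!ok], collapse = ", "),
           " (run alignToFrame() first, or set require_aligned = FALSE)")
  }
  if (is.null(template_index)) template_index <- selectTemplate(meshes)
  template <- meshes[[template_index]]
  if (remesh_template) template <- remeshUniform(template, target_edge)
  P <- nVertices(template)
  shapes <- array(NA_real_, c(K, P, 3))
  qc <- data.frame(id = ids, meanDistance = NA_real_, stringsAsFactors = FALSE)
  ts <- centroidSize(template)
  for (k in seq_len(K)) {
    if (k == template_index) {
      shapes[k, , ] <- template@vertices
      qc$meanDistance[k] <- 0
      next
    }
    target <- meshes[[k]]
    s_k <- 1
    if (size_normalize) {
      s_k <- centroidSize(target) / ts
      target <- triangleMesh(target@vertices / s_k, target@faces)
    }
    reg <- tryCatch(registerNearestNeighbor(template, target, mode),
                    error = function(e)
                      stop("registration failed for shape '", ids[k], "': ",
                           conditionMessage(e)))
    shapes[k, , ] <- reg * s_k
    qc$meanDistance[k] <- attr(reg, "meanDistance") * s_k
  }
  new("CorrespondedSet", template = template, shapes = shapes, ids = ids,
      qc = qc)
}

setMethod("show", "CorrespondedSet", function(object) {
  d <- dim(object@shapes)
  cat(sprintf("CorrespondedSet: %d shapes x %d vertices\n", d[1], d[2]))
  md <- object@qc$meanDistance
  if (any(is.finite(md)))
    cat(sprintf("  mean NN correspondence distance %.3f mm (max %.3f)\n",
                mean(md, na.rm = TRUE), max(md, na.rm = TRUE)))
  invisible(NULL)
})

#' @describeIn buildCorrespondedSet number of shapes in a set.
#' @param set a [CorrespondedSet-class].
#' @export
nShapes <- function(set) dim(set@shapes)[1]

#' @describeIn buildCorrespondedSet extract one shape as a mesh.
#' @param k shape index.
#' @export
shapeMesh <- function(set, k) {
  triangleMesh(set@shapes[k, , ], set@template@faces, name = set@ids[k])
}
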