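#' @import methods
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' TriangleMesh: a triangulated surface in millimetres
#'
#' The universal currency of the shape-modelling pipeline: a vertex matrix
#' (P x 3, mm) and a face index matrix (F x 3, 1-based).  The `metadata`
#' list carries provenance flags such as whether the mesh has been aligned
#' to an anatomical frame, its side tag, and quality-control records.
#'
#' @slot vertices numeric P x 3 matrix of coordinates in mm.
#' @slot faces integer F x 3 matrix of 1-based vertex indices.
#' @slot name optional identifier.
#' @slot side optional side tag, `"left"` or `"right"`.
#' @slot metadata named list of auxiliary information.
#' @export
setClass("TriangleMesh",
  representation(vertices = "matrix", faces = "matrix",
                 name = "characterOrNULL", side = "characterOrNULL",
                 metadata = "list"),
  prototype(name = NULL, side = NULL, metadata = list()))

setValidity("TriangleMesh", function(object) {
  v <- object@vertices
  f <- object@faces
  msgs <- character()
  if (!is.numeric(v) || ncol(v) != 3)
    msgs <- c(msgs, "vertices must be a numeric P x 3 matrix")
  if (!all(is.finite(v)))
    msgs <- c(msgs, "vertex coordinates must be finite")
  if (ncol(f) != 3)
    msgs <- c(msgs, "faces must be an F x 3 index matrix")
  if (nrow(f) > 0) {
    if (min(f) < 1 || max(f) > nrow(v))
      msgs <- c(msgs, "face indices out of range")
    degen <- f[, 1] == f[, 2] | f[, 1] == f[, 3] | f[, 2] == f[, 3]
    if (any(degen))
      msgs <- c(msgs, sprintf("%d degenerate face(s) with repeated vertex indices",
                              sum(degen)))
  }
  if (!is.null(object@side) && !object@side %in% c("left", "right"))
    msgs <- c(msgs, "side must be 'left' or 'right'")
  if (length(msgs)) msgs else TRUE
})

#' VoxelVolume: a scalar 3-D image grid
#'
#' CT-like scalar volume with anisotropic spacing (mm per voxel along each
#' axis) and a world-space origin (mm, position of the first voxel).
#'
#' @slot data 3-D numeric array of intensities.
#' @slot spacing numeric length-3, mm per voxel, all > 0.
#' @slot origin numeric length-3, mm.
#' @export
setClass("VoxelVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0)))

setValidity("VoxelVolume", function(object) {
  msgs <- character()
  d <- dim(object@data)
  if (length(d) != 3)
    msgs <- c(msgs, "data must be a 3-D array")
  else if (any(d < 2))
    msgs <- c(msgs, "grid must have at least 2 voxels per axis")
  if (length(object@spacing) != 3 || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msgs <- c(msgs, "spacing must be 3 positive finite values (mm/voxel)")
  if (length(object@origin) != 3 || any(!is.finite(object@origin)))
    msgs <- c(msgs, "origin must be 3 finite values (mm)")
  if (is.numeric(object@data) && !all(is.finite(object@data)))
    msgs <- c(msgs, "intensities must be finite")
  if (length(msgs)) msgs else TRUE
})

#' BinaryMask: a segmented 3-D grid
#'
#' Same grid geometry as [VoxelVolume-class] but logical data; the
#' intermediate between threshold segmentation and surface extraction.
#'
#' @slot data 3-D logical array.
#' @slot spacing,origin as in [VoxelVolume-class].
#' @export
setClass("BinaryMask",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0)))

setValidity("BinaryMask", function(object) {
  msgs <- character()
  if (length(dim(object@data)) != 3 || !is.logical(object@data))
    msgs <- c(msgs, "data must be a 3-D logical array")
  if (length(object@spacing) != 3 || any(object@spacing <= 0))
    msgs <- c(msgs, "spacing must be 3 positive values")
  if (length(object@origin) != 3 || any(!is.finite(object@origin)))
    msgs <- c(msgs, "origin must be 3 finite values")
  if (length(msgs)) msgs else TRUE
})

#' Sphere: centre and radius in millimetres
#'
#' Used for the condylar and femoral-head articular surfaces, whose fitted
#' spheres define the anatomical frame origin and the partial-bone length
#' unit.
#'
#' @slot center numeric length-3, mm.
#' @slot radius positive scalar, mm.
#' @slot rms root-mean-square fit residual, mm (0 for exact data).
#' @export
setClass("Sphere",
  representation(center = "numeric", radius = "numeric", rms = "numeric"),
  prototype(rms = 0))

setValidity("Sphere", function(object) {
  msgs <- character()
  if (length(object@center) != 3 || any(!is.finite(object@center)))
    msgs <- c(msgs, "center must be 3 finite values")
  if (length(object@radius) != 1 || !is.finite(object@radius) ||
      object@radius <= 0)
    msgs <- c(msgs, "radius must be a positive finite scalar")
  if (length(msgs)) msgs else TRUE
})

#' AnatomicalFrame: origin plus right-handed orthonormal axes
#'
#' X, Y, Z are unit vectors; Y points proximally along the anatomical axis,
#' Z latero-medially (positive towards the medial condyle) and X completes
#' the right-handed triple, so its anatomical direction (cranial/caudal)
#' flips between left and right bones.
#'
#' @slot origin numeric length-3, mm.
#' @slot x,y,z unit axis vectors.
#' @slot side optional side tag.
#' @export
setClass("AnatomicalFrame",
  representation(origin = "numeric", x = "numeric", y = "numeric",
                 z = "numeric", side = "characterOrNULL"),
  prototype(side = NULL))

setValidity("AnatomicalFrame", function(object) {
  msgs <- character()
  axes <- list(x = object@x, y = object@y, z = object@z)
  for (nm in names(axes)) {
    a <- axes[[nm]]
    if (length(a) != 3 || any(!is.finite(a)))
      msgs <- c(msgs, sprintf("%s axis must be 3 finite values", nm))
    else if (abs(sqrt(sum(a^2)) - 1) > 1e-9)
      msgs <- c(msgs, sprintf("%s axis must have unit norm (within 1e-9)", nm))
  }
  if (!length(msgs)) {
    R <- cbind(object@x, object@y, object@z)
    ortho <- crossprod(R) - diag(3)
    if (max(abs(ortho)) > 1e-9)
      msgs <- c(msgs, "axes must be pairwise orthogonal within 1e-9")
    if (det(R) < 0)
      msgs <- c(msgs, "axes must form a right-handed triple (det +1)")
  }
  if (length(object@origin) != 3 || any(!is.finite(object@origin)))
    msgs <- c(msgs, "origin must be 3 finite values")
  if (length(msgs)) msgs else TRUE
})

#' CorrespondedSet: shapes sharing one connectivity
#'
#' K shapes with exactly P vertices each, all adopting the template's
#' connectivity; the direct input of PCA model building.
#'
#' @slot template the template [TriangleMesh-class] (connectivity owner).
#' @slot shapes numeric array K x P x 3 of corresponded vertex coordinates.
#' @slot ids character length-K specimen labels.
#' @slot qc data.frame of per-shape quality metrics (mean/max nearest-
#'   neighbour correspondence distance in mm).
#' @export
setClass("CorrespondedSet",
  representation(template = "TriangleMesh", shapes = "array",
                 ids = "character", qc = "data.frame"))

setValidity("CorrespondedSet", function(object) {
  msgs <- character()
  d <- dim(object@shapes)
  if (length(d) != 3 || d[3] != 3)
    msgs <- c(msgs, "shapes must be a K x P x 3 array")
  else {
    if (d[2] != nrow(object@template@vertices))
      msgs <- c(msgs, "every shape must have exactly the template's vertex count")
    if (length(object@ids) != d[1])
      msgs <- c(msgs, "ids must have one entry per shape")
    if (!all(is.finite(object@shapes)))
      msgs <- c(msgs, "shape coordinates must be finite")
  }
  if (length(msgs)) msgs else TRUE
})

#' ShapeModel: a PCA point-distribution model
#'
#' Mean shape plus orthonormal modes of variation; a Mode is the
#' deformation of the mean along one principal component, and mode shapes
#' are synthesised as mean + k * sqrt(eigenvalue) * mode.
#'
#' @slot meanVector numeric length 3P, vertex-major (x1,y1,z1,x2,...), mm.
#' @slot modes 3P x M matrix with orthonormal columns.
#' @slot eigenvalues length-M non-increasing non-negative variances (mm^2).
#' @slot nTraining number of training shapes K.
#' @slot template the template [TriangleMesh-class] providing connectivity.
#' @export
setClass("ShapeModel",
  representation(meanVector = "numeric", modes = "matrix",
                 eigenvalues = "numeric", nTraining = "integer",
                 template = "TriangleMesh"))

setValidity("ShapeModel", function(object) {
  msgs <- character()
  M <- ncol(object@modes)
  if (length(object@eigenvalues) != M)
    msgs <- c(msgs, "one eigenvalue per mode required")
  if (any(object@eigenvalues < -1e-12))
    msgs <- c(msgs, "eigenvalues must be non-negative")
  if (length(object@eigenvalues) > 1 &&
      any(diff(object@eigenvalues) >
          1e-8 * max(object@eigenvalues[1], 1e-300)))
    msgs <- c(msgs, "eigenvalues must be non-increasing")
  if (M > object@nTraining - 1L)
    msgs <- c(msgs, "at most K - 1 modes are identifiable from K shapes")
  if (nrow(object@modes) != length(object@meanVector))
    msgs <- c(msgs, "modes and meanVector dimension mismatch")
  if (length(object@meanVector) != 3 * nrow(object@template@vertices))
    msgs <- c(msgs, "meanVector length must be 3 x template vertex count")
  if (M > 0) {
    g <- crossprod(object@modes)
    if (max(abs(g - diag(M))) > 1e-8)
      msgs <- c(msgs, "mode columns must be orthonormal within 1e-8")
  }
  if (length(msgs)) msgs else TRUE
})

#' VarianceTable: per-mode and cumulative percent variance
#'
#' Column A is the percentage of total variance explained by each mode and
#' column B its running sum, the layout used to report shape-model
#' compactness per group and side.
#'
#' @slot percent numeric, per-mode percentages (exact, unrounded).
#' @slot cumulative numeric, cumulative percentages (exact, unrounded).
#' @export
setClass("VarianceTable",
  representation(percent = "numeric", cumulative = "numeric"))

setValidity("VarianceTable", function(object) {
  msgs <- character()
  if (length(object@percent) != length(object@cumulative))
    msgs <- c(msgs, "percent and cumulative must have equal length")
  if (any(object@percent < -1e-9))
    msgs <- c(msgs, "percentages must be non-negative")
  if (max(abs(cumsum(object@percent) - object@cumulative)) > 1e-6)
    msgs <- c(msgs, "cumulative must be the running sum of percent")
  if (is.unsorted(object@cumulative))
    msgs <- c(msgs, "cumulative column must be non-decreasing")
  if (length(msgs)) msgs else TRUE
})

#' BonePopulationSpec: latent factors of a synthetic bone population
#'
#' Defines the generative conditions for a synthetic femur-like (or tibia/
#' patella-like) population: the number of specimens and the standard
#' deviations of the latent factors -- global log-scale, varus/valgus
#' (frontal bend, degrees), procurvation (sagittal bend, degrees), torsion
#' (axial twist, degrees) and condylar width (fractional).
#'
#' @slot n number of specimens (>= 2).
#' @slot scaleSD log-scale standard deviation (dimensionless).
#' @slot varusSD,procurvSD,torsionSD degrees.
#' @slot condyleWidthSD fractional SD of condylar separation.
#' @slot seed integer RNG seed.
#' @slot bone one of "femur", "tibia", "patella".
#' @slot baseDimensions named list of base sizes in mm.
#' @slot meshSpacing iso-surfacing grid spacing in mm.
#' @export
setClass("BonePopulationSpec",
  representation(n = "integer", scaleSD = "numeric", varusSD = "numeric",
                 procurvSD = "numeric", torsionSD = "numeric",
                 condyleWidthSD = "numeric", seed = "integer",
                 bone = "character", baseDimensions = "list",
                 meshSpacing = "numeric"))

setValidity("BonePopulationSpec", function(object) {
  msgs <- character()
  if (object@n < 2) msgs <- c(msgs, "n must be >= 2")
  sds <- c(object@scaleSD, object@varusSD, object@procurvSD,
           object@torsionSD, object@condyleWidthSD)
  if (any(!is.finite(sds)) || any(sds < 0))
    msgs <- c(msgs, "all factor SDs must be finite and >= 0")
  if (!object@bone %in% c("femur", "tibia", "patella"))
    msgs <- c(msgs, "bone must be 'femur', 'tibia' or 'patella'")
  dims <- unlist(object@baseDimensions)
  if (any(!is.finite(dims)) || any(dims <= 0))
    msgs <- c(msgs, "base dimensions must be positive")
  if (object@meshSpacing <= 0)
    msgs <- c(msgs, "meshSpacing must be positive")
  if (length(msgs)) msgs else TRUE
})

#' GroupSpec: a declarative analysis group
#'
#' Mirrors the grouping used for canine hind-limb shape models: groups are
#' defined by bone (complete femur, femur condyles, femoral head, tibia,
#' tibia plateau, patella), side, and optionally a body-weight band (kg) or
#' breed list.
#'
#' @slot name group label.
#' @slot bone one of the supported bone/region codes.
#' @slot side "left" or "right".
#' @slot weightBand optional numeric length-2 (kg, lower/upper).
#' @slot breeds optional character vector.
#' @export
setClass("GroupSpec",
  representation(name = "character", bone = "character", side = "character",
                 weightBand = "numeric", breeds = "character"),
  prototype(weightBand = numeric(0), breeds = character(0)))

setValidity("GroupSpec", function(object) {
  msgs <- character()
  bones <- c("complete_femur", "femur_condyles", "femoral_head",
             "tibia", "tibia_plateau", "patella")
  if (!object@bone %in% bones)
    msgs <- c(msgs, paste("bone must be one of:", paste(bones, collapse = ", ")))
  if (!object@side %in% c("left", "right"))
    msgs <- c(msgs, "side must be 'left' or 'right'")
  if (length(object@weightBand) %in% c(0, 2) == FALSE)
    msgs <- c(msgs, "weightBand must be empty or length 2")
  if (length(msgs)) msgs else TRUE
})
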