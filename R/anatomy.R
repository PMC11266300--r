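#' Least-squares sphere fit
#'
#' Fits a sphere to 3-D points by the linearised algebraic least-squares
#' system (solving for centre and radius from \eqn{|p|^2 = 2 c \cdot p + k}),
#' optionally refined by geometric Gauss-Newton least squares on the radial
#' residuals.  Used to locate the condylar and femoral-head articular
#' surfaces whose centres anchor the anatomical frame.
#'
#' @param points N x 3 matrix of coordinates, mm; N >= 4, not coplanar.
#' @param refine run the geometric refinement (default TRUE).
#' @return A [Sphere-class]; the `rms` slot holds the root-mean-square
#'   radial residual in mm.
#' @examples
#' pts <- rbind(c(6, 2, 3), c(-4, 2, 3), c(1, 7, 3), c(1, -3, 3),
#'              c(1, 2, 8), c(1, 2, -2))
#' fitSphere(pts)  # centre (1, 2, 3), radius 5
#' @export
fitSphere <- function(points, refine = TRUE) {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("'points' must be an N x 3 matrix")
  if (nrow(points) < 4) stop("sphere fitting needs at least 4 points")
  if (any(!is.finite(points))) stop("points must be finite")
  cen0 <- colMeans(points)
  sv <- svd(sweep(points, 2, cen0))
  if (sv$d[3] < 1e-9 * max(sv$d[1], 1))
    stop("degenerate sphere fit: points are (nearly) coplanar or collinear")
  A <- cbind(2 * points, 1)
  b <- rowSums(points^2)
  sol <- qr.solve(A, b)
  center <- sol[1:3]
  radius <- sqrt(sol[4] + sum(center^2))
  if (refine) {
    for (iter in seq_len(25)) {
      d <- sweep(points, 2, center)
      r <- sqrt(rowSums(d^2))
      res <- r - radius
      J <- cbind(-d / pmax(r, 1e-300), -1)
      step <- tryCatch(qr.solve(J, -res), error = function(e) rep(0, 4))
      center <- center + step[1:3]
      radius <- radius + step[4]
      if (sqrt(sum(step^2)) < 1e-12 * max(radius, 1)) break
    }
  }
  d <- sweep(points, 2, center)
  rms <- sqrt(mean((sqrt(rowSums(d^2)) - radius)^2))
  new("Sphere", center = as.numeric(center), radius = as.numeric(radius),
      rms = rms)
}

setMethod("show", "Sphere", function(object) {
  cat(sprintf("Sphere: centre (%.3f, %.3f, %.3f) mm, radius %.3f mm, RMS %.2g mm\n",
              object@center[1], object@center[2], object@center[3],
              object@radius, object@rms))
  invisible(NULL)
})

#' @describeIn fitSphere accessor for the centre.
#' @param sphere a [Sphere-class].
#' @export
sphereCenter <- function(sphere) sphere@center

#' @describeIn fitSphere accessor for the radius.
#' @export
sphereRadius <- function(sphere) sphere@radius

#' Estimate the anatomical (long) axis of a bone
#'
#' The anatomical axis is the total-least-squares line through the
#' centroids of cross-sections sampled along the bone's dominant
#' elongation direction, restricted to a central shaft fraction (the
#' middle 50\% by default) so the epiphyses do not bias the fit.
#'
#' @param mesh a [TriangleMesh-class] with a dominant elongation.
#' @param shaft_fraction length-2 fractions of the bone length delimiting
#'   the shaft window, default `c(0.25, 0.75)`.
#' @param nSlices number of cross-section bins.
#' @param proximal_hint direction whose positive half-space is proximal;
#'   the returned axis has positive dot product with it.
#' @return Unit 3-vector pointing proximally.
#' @export
estimateAnatomicalAxis <- function(mesh, shaft_fraction = c(0.25, 0.75),
                                   nSlices = 15L, proximal_hint = c(0, 1, 0)) {
  stopifnot(is(mesh, "TriangleMesh"))
  if (length(shaft_fraction) != 2 || any(shaft_fraction < 0) ||
      any(shaft_fraction > 1) || diff(shaft_fraction) <= 0)
    stop("'shaft_fraction' must be an increasing pair in [0, 1]")
  v <- mesh@vertices
  cen <- colMeans(v)
  sv <- svd(sweep(v, 2, cen))
  if (sv$d[1] < 1.5 * sv$d[2])
    stop("mesh has no dominant elongation direction; cannot estimate an ",
         "anatomical axis")
  dir0 <- sv$v[, 1]
  t <- as.numeric(sweep(v, 2, cen) %*% dir0)
  lo <- min(t) + shaft_fraction[1] * diff(range(t))
  hi <- min(t) + shaft_fraction[2] * diff(range(t))
  breaks <- seq(lo, hi, length.out = nSlices + 1)
  bin <- findInterval(t, breaks, rightmost.closed = TRUE)
  inside <- bin >= 1 & bin <= nSlices
  cents <- t(vapply(seq_len(nSlices), function(b) {
    idx <- which(inside & bin == b)
    if (length(idx) == 0) return(c(NA_real_, NA_real_, NA_real_))
    colMeans(v[idx, , drop = FALSE])
  }, numeric(3)))
  cents <- cents[stats::complete.cases(cents), , drop = FALSE]
  if (nrow(cents) < 3)
    stop("fewer than 3 non-empty cross-sections in the shaft window")
  csv <- svd(sweep(cents, 2, colMeans(cents)))
  axis <- csv$v[, 1]
  if (sum(axis * proximal_hint) < 0) axis <- -axis
  axis / sqrt(sum(axis^2))
}

# orthonormal right-handed frame from a privileged y axis and a z hint:
# y is kept exact, z orthogonalized against y, x = y x z
makeFrame <- function(origin, y_axis, z_hint, side = NULL) {
  y <- y_axis / sqrt(sum(y_axis^2))
  z <- z_hint - sum(z_hint * y) * y
  nz <- sqrt(sum(z^2))
  if (nz < 1e-12) stop("z direction is parallel to the y axis")
  z <- z / nz
  x <- c(y[2] * z[3] - y[3] * z[2],
         y[3] * z[1] - y[1] * z[3],
         y[1] * z[2] - y[2] * z[1])
  new("AnatomicalFrame", origin = as.numeric(origin), x = x, y = y, z = z,
      side = side)
}

#' Build the femoral anatomical frame
#'
#' The origin is the point equidistant from the two condylar sphere
#' centres (their midpoint); Y is the anatomical axis, positive proximal;
#' Z is the latero-medial inter-condylar direction orthogonalised against
#' Y, positive towards the medial condyle; X = Y x Z completes the
#' right-handed triple.  Because Y is privileged and Z re-orthogonalised,
#' the frame is exactly orthonormal even when the raw inter-condylar
#' direction is not perpendicular to the anatomical axis.
#'
#' @param condyle_med,condyle_lat fitted condylar [Sphere-class]s (medial
#'   and lateral).
#' @param anatomical_axis unit 3-vector, positive proximal.
#' @param side `"left"` or `"right"`; recorded in the frame so the
#'   anatomical meaning of X (cranial/caudal) can be resolved downstream.
#' @return An [AnatomicalFrame-class].
#' @export
buildFemoralFrame <- function(condyle_med, condyle_lat, anatomical_axis,
                              side = c("left", "right")) {
  stopifnot(is(condyle_med, "Sphere"), is(condyle_lat, "Sphere"))
  side <- match.arg(side)
  cm <- condyle_med@center
  cl <- condyle_lat@center
  d <- cm - cl
  nd <- sqrt(sum(d^2))
  if (nd < 1e-9) stop("condyle centres coincide; frame is undefined")
  y <- anatomical_axis / sqrt(sum(anatomical_axis^2))
  cosang <- abs(sum(d / nd * y))
  if (cosang > cos(5 * pi / 180))
    stop("ill-conditioned frame: anatomical axis within 5 degrees of the ",
         "inter-condylar line")
  makeFrame(origin = (cm + cl) / 2, y_axis = y, z_hint = d, side = side)
}

setMethod("show", "AnatomicalFrame", function(object) {
  cat("AnatomicalFrame",
      if (!is.null(object@side)) sprintf("(%s)", object@side) else "", "\n")
  cat(sprintf("  origin (%.2f, %.2f, %.2f) mm\n", object@origin[1],
              object@origin[2], object@origin[3]))
  for (nm in c("x", "y", "z")) {
    a <- slot(object, nm)
    cat(sprintf("  %s (%.4f, %.4f, %.4f)\n", toupper(nm), a[1], a[2], a[3]))
  }
  invisible(NULL)
})

#' Align a mesh to an anatomical frame
#'
#' Applies the rigid transform mapping the frame origin to (0,0,0) and its
#' axes to the world axes; inter-vertex distances are preserved exactly.
#' The result is flagged as aligned in its metadata, a precondition of the
#' partial-bone cuts and of correspondence building.
#'
#' @param mesh a [TriangleMesh-class].
#' @param frame an [AnatomicalFrame-class].
#' @return The aligned [TriangleMesh-class].
#' @export
alignToFrame <- function(mesh, frame) {
  stopifnot(is(mesh, "TriangleMesh"), is(frame, "AnatomicalFrame"))
  R <- rbind(frame@x, frame@y, frame@z)
  v <- sweep(mesh@vertices, 2, frame@origin) %*% t(R)
  out <- triangleMesh(v, mesh@faces, name = mesh@name,
                      side = if (!is.null(frame@side)) frame@side else mesh@side,
                      metadata = mesh@metadata)
  out@metadata$aligned <- TRUE
  out
}

#' @describeIn alignToFrame transform arbitrary points into frame
#'   coordinates (or back with `inverse = TRUE`).
#' @param points N x 3 matrix.
#' @param inverse map frame coordinates back to world coordinates.
#' @export
transformPoints <- function(points, frame, inverse = FALSE) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  R <- rbind(frame@x, frame@y, frame@z)
  if (inverse)
    sweep(points %*% R, 2, -frame@origin)
  else
    sweep(points, 2, frame@origin) %*% t(R)
}

#' Cut a partial femur model
#'
#' Retains the distal (or proximal) sub-mesh up to two condylar (or head)
#' sphere diameters from the bone's extreme vertex along Y, normalising
#' partial-model length across specimens of very different sizes.  The cut
#' plane is perpendicular to Y and the open boundary is left as-is.
#'
#' @param mesh an aligned [TriangleMesh-class] (Y proximal-positive).
#' @param region `"distal"` or `"proximal"`.
#' @param reference_sphere the condylar (distal) or femoral-head
#'   (proximal) [Sphere-class] providing the length unit.
#' @return The cut [TriangleMesh-class]; if the cut length exceeds the
#'   bone length, the whole mesh is returned with a warning.
#' @export
cutPartialFemur <- function(mesh, region = c("distal", "proximal"),
                            reference_sphere) {
  stopifnot(is(mesh, "TriangleMesh"), is(reference_sphere, "Sphere"))
  region <- match.arg(region)
  if (!isTRUE(mesh@metadata$aligned))
    stop("mesh must be aligned to an anatomical frame before cutting")
  len <- 2 * (2 * reference_sphere@radius)  # two sphere diameters
  y <- mesh@vertices[, 2]
  span <- diff(range(y))
  if (len >= span) {
    warning("cut length (", len, " mm) exceeds bone length (",
            round(span, 1), " mm); returning the whole mesh")
    return(mesh)
  }
  keep <- if (region == "distal") y <= min(y) + len else y >= max(y) - len
  out <- subsetMeshVertices(mesh, keep)
  out@metadata$partial_region <- region
  out
}

#' Cut a partial proximal tibia model
#'
#' Retains the proximal part of the tibia above the most distal point of
#' the tibial tuberosity (a manually annotated landmark); the cut plane is
#' perpendicular to Y.
#'
#' @param mesh an aligned [TriangleMesh-class].
#' @param tuberosity_distal_point 3-vector landmark, same frame as `mesh`.
#' @return The cut [TriangleMesh-class].
#' @export
cutPartialTibia <- function(mesh, tuberosity_distal_point) {
  stopifnot(is(mesh, "TriangleMesh"))
  if (!isTRUE(mesh@metadata$aligned))
    stop("mesh must be aligned to an anatomical frame before cutting")
  yc <- tuberosity_distal_point[2]
  y <- mesh@vertices[, 2]
  if (yc <= min(y)) return(mesh)
  keep <- y >= yc
  if (!any(keep))
    stop("tuberosity landmark lies above the proximal end: empty cut")
  out <- subsetMeshVertices(mesh, keep)
  out@metadata$partial_region <- "proximal"
  out
}

#' Rigid regional realignment (iterative closest point)
#'
#' Finds the rigid transform (rotation + translation, no scaling) that
#' minimises the RMS distance between a region of the source mesh and the
#' closest points on the target surface, by closest-point iterations with
#' a Kabsch update, initialised at the identity.  Realigning on a bone's
#' extremities is how curvature-type modes are localised when interpreting
#' a model.
#'
#' @param source,target [TriangleMesh-class]es in the same frame.
#' @param region_indices vertex indices of the source region (default: all
#'   vertices); at least 3 non-collinear points.
#' @param max_iter,tol iteration control.
#' @return list with `rotation` (3 x 3), `translation` (3), `mesh` (the
#'   transformed source), `rms` (mm) and `converged`.
#' @export
rigidAlignRegions <- function(source, target, region_indices = NULL,
                              max_iter = 200L, tol = 1e-8) {
  stopifnot(is(source, "TriangleMesh"), is(target, "TriangleMesh"))
  if (is.null(region_indices)) region_indices <- seq_len(nVertices(source))
  pts <- source@vertices[region_indices, , drop = FALSE]
  if (nrow(pts) < 3) stop("region must contain at least 3 points")
  sv <- svd(sweep(pts, 2, colMeans(pts)))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("region points are collinear; rigid alignment is underdetermined")
  R <- diag(3)
  tr <- c(0, 0, 0)
  rms <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    cur <- sweep(pts %*% t(R), 2, tr, `+`)
    cp <- .closestOnSurface(cur, target@vertices, target@faces)
    new_rms <- sqrt(mean(cp$distance^2))
    if (is.finite(rms) && abs(rms - new_rms) < tol * max(1, rms)) {
      rms <- new_rms
      converged <- TRUE
      break
    }
    rms <- new_rms
    # Kabsch: best rigid map of original pts onto current correspondences
    mu_s <- colMeans(pts)
    mu_t <- colMeans(cp$points)
    H <- crossprod(sweep(pts, 2, mu_s), sweep(cp$points, 2, mu_t))
    dec <- svd(H)
    S <- diag(c(1, 1, sign(det(dec$v %*% t(dec$u)))))
    R_new <- dec$v %*% S %*% t(dec$u)
    tr_new <- mu_t - as.numeric(R_new %*% mu_s)
    delta <- max(abs(R_new - R), abs(tr_new - tr))
    R <- R_new
    tr <- tr_new
    if (delta < 1e-12) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("rigid alignment did not converge in ", max_iter,
            " iterations; returning the best transform found")
  v <- sweep(source@vertices %*% t(R), 2, tr, `+`)
  out <- triangleMesh(v, source@faces, name = source@name,
                      side = source@side, metadata = source@metadata)
  list(rotation = R, translation = as.numeric(tr), mesh = out, rms = rms,
       converged = converged)
}
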