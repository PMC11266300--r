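# shape <-> flat-vector conversions (vertex-major: x1,y1,z1,x2,...)
flattenShape <- function(v) as.numeric(t(v))
unflattenShape <- function(x) matrix(x, ncol = 3, byrow = TRUE)

#' Build a PCA statistical shape model
#'
#' Principal component analysis of the corresponded vertex coordinates:
#' the mean shape is the arithmetic mean over shapes and the modes are the
#' eigenvectors of the (1/(K-1))-normalised covariance of the centred
#' K x 3P data matrix, computed by singular value decomposition of the
#' centred data (forming the 3P x 3P covariance would be wasteful since
#' K << 3P).  Modes are sorted by descending eigenvalue and their sign is
#' fixed so each mode's largest-magnitude component is positive (PCA signs
#' are otherwise arbitrary).  No size normalisation or Procrustes scaling
#' is applied: scale is deliberately retained as a shape factor, and it is
#' expected to dominate Mode 1 in bone populations.
#'
#' @param set a [CorrespondedSet-class] with K >= 2 shapes.
#' @param center_scale divide out centroid size before PCA (exploratory
#'   option; off by default).
#' @return A [ShapeModel-class] with M = K - 1 modes.
#' @export
buildSSM <- function(set, center_scale = FALSE) {
  stopifnot(is(set, "CorrespondedSet"))
  K <- nShapes(set)
  if (K < 2) stop("model building needs at least 2 shapes")
  P <- dim(set@shapes)[2]
  X <- matrix(NA_real_, K, 3 * P)
  for (k in seq_len(K)) {
    v <- set@shapes[k, , ]
    if (center_scale) v <- v / centroidSize(v)
    X[k, ] <- flattenShape(v)
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0, nv = min(K - 1, 3 * P))
  M <- min(K - 1, 3 * P)
  eig <- (sv$d[seq_len(M)]^2) / (K - 1)
  modes <- sv$v[, seq_len(M), drop = FALSE]
  # deterministic ordering for numerically tied eigenvalues
  if (M > 1) {
    ord <- seq_len(M)
    i <- 1
    while (i < M) {
      j <- i
      while (j < M && abs(eig[j + 1] - eig[i]) <= 1e-12 * max(eig[1], 1e-300))
        j <- j + 1
      if (j > i) {
        block <- ord[i:j]
        cmp <- apply(modes[, block, drop = FALSE], 2, paste, collapse = ",")
        ord[i:j] <- block[order(cmp)]
      }
      i <- j + 1
    }
    modes <- modes[, ord, drop = FALSE]
    eig <- eig[ord]
  }
  # sign convention: largest-magnitude component positive
  for (m in seq_len(M)) {
    imax <- which.max(abs(modes[, m]))
    if (modes[imax, m] < 0) modes[, m] <- -modes[, m]
  }
  new("ShapeModel", meanVector = mu, modes = modes, eigenvalues = eig,
      nTraining = as.integer(K), template = set@template)
}

setMethod("show", "ShapeModel", function(object) {
  M <- length(object@eigenvalues)
  cat(sprintf("ShapeModel: %d training shapes, %d vertices, %d modes\n",
              object@nTraining, length(object@meanVector) / 3, M))
  if (M > 0 && sum(object@eigenvalues) > 0) {
    pct <- 100 * object@eigenvalues / sum(object@eigenvalues)
    show_n <- min(5, M)
    cat("  variance explained:",
        paste(sprintf("%.3g%%", pct[seq_len(show_n)]), collapse = ", "),
        if (M > show_n) "..." else "", "\n")
  }
  invisible(NULL)
})

#' @describeIn buildSSM eigenvalues accessor (mm^2, descending).
#' @param model a [ShapeModel-class].
#' @export
modelEigenvalues <- function(model) model@eigenvalues

#' @describeIn buildSSM mode matrix accessor (3P x M, orthonormal columns).
#' @export
modelModes <- function(model) model@modes

#' @describeIn buildSSM mean shape as a [TriangleMesh-class].
#' @export
meanShape <- function(model) {
  triangleMesh(unflattenShape(model@meanVector), model@template@faces,
               name = "mean")
}

#' Per-mode and cumulative variance table
#'
#' Column A is the percentage of total variance explained by each mode
#' (100 * eigenvalue / total) and column B its running sum; values are
#' reported at 3 significant figures via [formatVarianceTable()], the
#' precision conventionally used for such tables.
#'
#' @param model a [ShapeModel-class] with a non-zero spectrum.
#' @param n_modes number of modes to tabulate (default 5).
#' @return A [VarianceTable-class] holding exact (unrounded) values.
#' @export
varianceTable <- function(model, n_modes = 5) {
  stopifnot(is(model, "ShapeModel"))
  tot <- sum(model@eigenvalues)
  if (tot <= 0)
    stop("all eigenvalues are zero: variance percentages are undefined")
  n <- min(n_modes, length(model@eigenvalues))
  pct <- 100 * model@eigenvalues / tot
  new("VarianceTable", percent = pct[seq_len(n)],
      cumulative = cumsum(pct)[seq_len(n)])
}

#' @describeIn varianceTable render as a data.frame with columns `Mode`,
#'   `A`, `B` at 3 significant figures.
#' @param table a [VarianceTable-class].
#' @export
formatVarianceTable <- function(table) {
  stopifnot(is(table, "VarianceTable"))
  data.frame(Mode = seq_along(table@percent),
             A = signif(table@percent, 3),
             B = signif(table@cumulative, 3))
}

setMethod("show", "VarianceTable", function(object) {
  print(formatVarianceTable(object), row.names = FALSE)
  invisible(NULL)
})

#' Synthesise a mode shape
#'
#' A Mode shape is the mean model displaced along a single principal
#' component: vertices = mean + k_sd * sqrt(eigenvalue) * mode.  The
#' conventional visualisation set is the mean plus the +/-3 SD shapes of
#' the first five modes.
#'
#' @param model a [ShapeModel-class].
#' @param mode_index mode number (1-based).
#' @param k_sd displacement in standard-deviation units, typically in
#'   `[-3, 3]`.
#' @return A [TriangleMesh-class] on the template connectivity.
#' @export
sampleMode <- function(model, mode_index, k_sd) {
  stopifnot(is(model, "ShapeModel"))
  M <- length(model@eigenvalues)
  if (mode_index < 1 || mode_index > M)
    stop("mode_index must be in 1..", M)
  x <- model@meanVector +
    k_sd * sqrt(model@eigenvalues[mode_index]) * model@modes[, mode_index]
  triangleMesh(unflattenShape(x), model@template@faces,
               name = sprintf("mode%d_%+.1fsd", mode_index, k_sd))
}

#' Project a shape onto the model
#'
#' Returns per-mode coefficients in standard-deviation units:
#' b_i = mode_i . (x - mean) / sqrt(eigenvalue_i) for modes with positive
#' eigenvalue (coefficients of zero-variance modes are reported as 0).
#'
#' @param model a [ShapeModel-class].
#' @param shape P x 3 coordinate matrix or [TriangleMesh-class] on the
#'   template connectivity.
#' @return numeric vector of length M.
#' @export
projectShape <- function(model, shape) {
  stopifnot(is(model, "ShapeModel"))
  v <- if (is(shape, "TriangleMesh")) shape@vertices else as.matrix(shape)
  x <- flattenShape(v)
  if (length(x) != length(model@meanVector))
    stop("shape size does not match the model")
  raw <- as.numeric(crossprod(model@modes, x - model@meanVector))
  sd <- sqrt(model@eigenvalues)
  pos <- sd > 1e-12 * max(sd, 1e-300)
  b <- numeric(length(raw))
  b[pos] <- raw[pos] / sd[pos]
  b
}

#' Reconstruct a shape from mode coefficients
#'
#' vertices = mean + sum_i b_i * sqrt(eigenvalue_i) * mode_i; with the full
#' coefficient vector of a training shape this inverts [projectShape()].
#'
#' @param model a [ShapeModel-class].
#' @param coefficients per-mode coefficients in SD units (shorter vectors
#'   are zero-padded: truncated reconstruction).
#' @return A [TriangleMesh-class].
#' @export
reconstructShape <- function(model, coefficients) {
  stopifnot(is(model, "ShapeModel"))
  M <- length(model@eigenvalues)
  b <- rep(0, M)
  b[seq_along(coefficients)] <- coefficients
  x <- model@meanVector +
    as.numeric(model@modes %*% (b * sqrt(model@eigenvalues)))
  triangleMesh(unflattenShape(x), model@template@faces)
}
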