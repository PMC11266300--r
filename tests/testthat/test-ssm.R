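# corresponded set built directly from coordinate arrays
setFromArrays <- function(shapes3d, template_vertices = NULL) {
  K <- dim(shapes3d)[1]
  P <- dim(shapes3d)[2]
  if (is.null(template_vertices)) template_vertices <- shapes3d[1, , ]
  tmpl <- triangleMesh(template_vertices,
                       if (P >= 3) matrix(c(1L, 2L, 3L), 1)
                       else matrix(integer(0), 0, 3))
  new("CorrespondedSet", template = tmpl, shapes = shapes3d,
      ids = sprintf("s%d", seq_len(K)),
      qc = data.frame(id = sprintf("s%d", seq_len(K)),
                      meanDistance = 0))
}

modelFromEigenvalues <- function(eig) {
  M <- length(eig)
  P <- ceiling(M / 3) + 1
  modes <- diag(3 * P)[, seq_len(M), drop = FALSE]
  tmpl <- triangleMesh(matrix(0, P, 3), matrix(integer(0), 0, 3))
  new("ShapeModel", meanVector = numeric(3 * P), modes = modes,
      eigenvalues = sort(eig, decreasing = TRUE),
      nTraining = as.integer(M + 1), template = tmpl)
}

test_that("PCA handles degenerate and two-shape training sets exactly", {
  set.seed(2)
  base <- matrix(rnorm(60), 20, 3)
  shapes <- array(0, c(4, 20, 3))
  for (k in 1:4) shapes[k, , ] <- base
  model <- buildSSM(setFromArrays(shapes))
  expect_lt(max(modelEigenvalues(model)), 1e-18)
  expect_equal(matrix(model@meanVector, ncol = 3, byrow = TRUE), base)

  # K = 2: one mode, eigenvalue = ||x1 - x2||^2 / 2
  s2 <- array(0, c(2, 4, 3))
  s2[1, , ] <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1), 4, 3, byrow = TRUE)
  s2[2, , ] <- s2[1, , ] + matrix(c(0.3, -0.1, 0.2), 4, 3, byrow = TRUE)
  model2 <- buildSSM(setFromArrays(s2))
  d2 <- sum((s2[1, , ] - s2[2, , ])^2)
  expect_equal(modelEigenvalues(model2)[1], d2 / 2, tolerance = 1e-12)
  expect_equal(length(modelEigenvalues(model2)), 1L)

  expect_error(buildSSM(setFromArrays(array(0, c(1, 4, 3)))), "at least 2")
})

test_that("the SVD path matches an explicit covariance eigendecomposition", {
  set.seed(11)
  K <- 10; P <- 20
  shapes <- array(rnorm(K * P * 3), c(K, P, 3))
  model <- buildSSM(setFromArrays(shapes))
  X <- t(apply(shapes, 1, function(v) as.numeric(t(v))))
  C <- stats::cov(X)  # 1/(K-1) covariance
  eg <- eigen(C, symmetric = TRUE)
  M <- length(modelEigenvalues(model))
  expect_equal(modelEigenvalues(model), eg$values[seq_len(M)],
               tolerance = 1e-8)
  for (m in seq_len(M)) {
    # modes agree up to sign
    expect_gt(abs(sum(model@modes[, m] * eg$vectors[, m])), 1 - 1e-8)
  }
  # orthonormality and the sign convention
  expect_lt(max(abs(crossprod(model@modes) - diag(M))), 1e-8)
  for (m in seq_len(M)) {
    imax <- which.max(abs(model@modes[, m]))
    expect_gt(model@modes[imax, m], 0)
  }
})

test_that("variance tables reproduce per-mode and cumulative percentages", {
  # spectrum proportional to a published femur group (remainder 0.26
  # spread beyond the tabulated five modes)
  model <- modelFromEigenvalues(c(93.5, 5.62, 0.34, 0.17, 0.11,
                                  rep(0.26 / 4, 4)))
  tab <- formatVarianceTable(varianceTable(model, 5))
  expect_equal(tab$A, c(93.5, 5.62, 0.34, 0.17, 0.11))
  expect_equal(tab$B, c(93.5, 99.1, 99.5, 99.6, 99.7))

  tab4 <- formatVarianceTable(varianceTable(modelFromEigenvalues(rep(2, 4))))
  expect_equal(tab4$A, rep(25, 4))
  expect_equal(tab4$B, c(25, 50, 75, 100))

  tab1 <- formatVarianceTable(varianceTable(modelFromEigenvalues(c(3, 0, 0))))
  expect_equal(tab1$A[1], 100)
  expect_equal(tab1$B[1], 100)

  expect_error(varianceTable(modelFromEigenvalues(c(0, 0))), "zero")
})

test_that("the variance table accounts for the whole spectrum", {
  set.seed(4)
  shapes <- array(rnorm(8 * 10 * 3), c(8, 10, 3))
  model <- buildSSM(setFromArrays(shapes))
  tab <- varianceTable(model, n_modes = length(modelEigenvalues(model)))
  expect_lt(abs(sum(tab@percent) - 100), 1e-6)
  expect_false(is.unsorted(tab@cumulative))
  expect_lt(abs(tab@cumulative[length(tab@cumulative)] - 100), 1e-6)
})

test_that("mode sampling is linear and symmetric about the mean", {
  set.seed(6)
  shapes <- array(rnorm(6 * 12 * 3), c(6, 12, 3))
  model <- buildSSM(setFromArrays(shapes))
  expect_equal(meshVertices(sampleMode(model, 1, 0)),
               meshVertices(meanShape(model)))
  plus <- meshVertices(sampleMode(model, 2, 3))
  minus <- meshVertices(sampleMode(model, 2, -3))
  expect_lt(max(abs((plus + minus) / 2 - meshVertices(meanShape(model)))),
            1e-9)
  expect_error(sampleMode(model, 99, 1), "mode_index")
})

test_that("projection and reconstruction invert each other", {
  set.seed(7)
  K <- 8; P <- 15
  shapes <- array(rnorm(K * P * 3), c(K, P, 3))
  set <- setFromArrays(shapes)
  model <- buildSSM(set)
  # mean projects to zero
  expect_lt(max(abs(projectShape(model, meanShape(model)))), 1e-10)
  # full-mode reconstruction of a training shape
  b <- projectShape(model, shapes[3, , ])
  rec <- reconstructShape(model, b)
  expect_lt(max(abs(meshVertices(rec) - shapes[3, , ])), 1e-8)
  # sampled mode shapes project to a unit coordinate vector
  sm <- sampleMode(model, 2, 1.7)
  bsm <- projectShape(model, sm)
  expect_equal(bsm[2], 1.7, tolerance = 1e-8)
  expect_lt(max(abs(bsm[-2])), 1e-8)
  # truncated reconstruction error is non-increasing in the mode count
  errs <- vapply(seq_along(b), function(m)
    sqrt(mean((meshVertices(reconstructShape(model, b[seq_len(m)])) -
               shapes[3, , ])^2)), numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("scale-dominated populations order and recover their factors", {
  fx <- referencePopulationModel()
  lam <- modelEigenvalues(fx$model)
  # mode-1 +3 SD shape is larger than the -3 SD shape
  expect_gt(centroidSize(sampleMode(fx$model, 1, 3)),
            centroidSize(sampleMode(fx$model, 1, -3)))
  # two leading modes reconstruct training shapes well
  k <- 7
  b <- projectShape(fx$model, shapeMesh(fx$set, k))
  rec2 <- meshVertices(reconstructShape(fx$model, b[1:2]))
  x <- fx$set@shapes[k, , ]
  shape_sd <- sqrt(sum(lam))
  expect_lt(sqrt(sum((rec2 - x)^2)), 0.1 * shape_sd)
})
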