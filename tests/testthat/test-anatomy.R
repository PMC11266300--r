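test_that("sphere fitting is exact on noiseless data", {
  pts <- rbind(c(6, 2, 3), c(-4, 2, 3), c(1, 7, 3), c(1, -3, 3),
               c(1, 2, 8), c(1, 2, -2))
  s <- fitSphere(pts)
  expect_lt(max(abs(sphereCenter(s) - c(1, 2, 3))), 1e-9)
  expect_lt(abs(sphereRadius(s) - 5), 1e-9)
  expect_lt(s@rms, 1e-9)
})

test_that("sphere fitting matches a nonlinear least-squares oracle on noisy data", {
  set.seed(10)
  u <- matrix(rnorm(1500), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pts <- u + matrix(rnorm(1500, 0, 0.01), ncol = 3)
  s <- fitSphere(pts)
  expect_lt(sqrt(sum(sphereCenter(s)^2)), 0.005)
  # independent oracle: direct numeric minimisation of radial residuals
  obj <- function(p) sum((sqrt(rowSums(sweep(pts, 2, p[1:3])^2)) - p[4])^2)
  op <- stats::optim(c(0.1, -0.1, 0.05, 1.2), obj, method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-14))
  expect_lt(max(abs(sphereCenter(s) - op$par[1:3])), 1e-5)
  expect_lt(abs(sphereRadius(s) - op$par[4]), 1e-5)
})

test_that("degenerate sphere inputs error", {
  expect_error(fitSphere(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                               c(1, 1, 0))), "coplanar|degenerate")
  expect_error(fitSphere(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))),
               "at least 4")
})

test_that("sphere fitting is rigid-invariant", {
  set.seed(3)
  u <- matrix(rnorm(300), ncol = 3)
  pts <- 4 * u / sqrt(rowSums(u^2)) + matrix(rnorm(300, 0, 0.05), ncol = 3)
  s0 <- fitSphere(pts)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tr <- c(5, -2, 9)
  s1 <- fitSphere(sweep(pts %*% t(R), 2, tr, `+`))
  expect_lt(max(abs(sphereCenter(s1) - (as.numeric(R %*% sphereCenter(s0)) + tr))),
            1e-9)
  expect_lt(abs(sphereRadius(s1) - sphereRadius(s0)), 1e-9)
})

test_that("the anatomical axis of a straight cylinder is exact", {
  cyl <- cylinderMesh(radius = 5, length = 80)
  ax <- estimateAnatomicalAxis(cyl)
  expect_lt(max(abs(ax - c(0, 1, 0))), 1e-6)
})

test_that("a bent shaft yields the total-least-squares axis of its centroids", {
  cyl <- cylinderMesh(radius = 5, length = 80, nTheta = 36, nRings = 81)
  v <- meshVertices(cyl)
  bend <- v[, 2] > 0
  th <- 10 * pi / 180
  v[bend, ] <- cbind(cos(th) * v[bend, 1] - sin(th) * v[bend, 2],
                     sin(th) * v[bend, 1] + cos(th) * v[bend, 2],
                     v[bend, 3])
  bent <- triangleMesh(v, meshFaces(cyl))
  ax <- estimateAnatomicalAxis(bent, shaft_fraction = c(0.25, 0.75))
  # oracle: TLS line through cross-section centroids, recomputed directly
  cen <- colMeans(v)
  d0 <- svd(sweep(v, 2, cen))$v[, 1]
  t <- as.numeric(sweep(v, 2, cen) %*% d0)
  lo <- min(t) + 0.25 * diff(range(t))
  hi <- min(t) + 0.75 * diff(range(t))
  br <- seq(lo, hi, length.out = 16)
  bin <- findInterval(t, br, rightmost.closed = TRUE)
  cents <- do.call(rbind, lapply(1:15, function(b) {
    idx <- which(bin == b & t >= lo & t <= hi)
    if (!length(idx)) return(NULL)
    colMeans(v[idx, , drop = FALSE])
  }))
  tls <- svd(sweep(cents, 2, colMeans(cents)))$v[, 1]
  ang <- acos(min(1, abs(sum(ax * tls)))) * 180 / pi
  expect_lt(ang, 1)
})

test_that("meshes without dominant elongation are rejected", {
  disc <- icosphereMesh(10, 2)
  v <- meshVertices(disc)
  v[, 2] <- v[, 2] * 0.05  # flat disc
  expect_error(estimateAnatomicalAxis(triangleMesh(v, meshFaces(disc)),
                                      proximal_hint = c(0, 0, 1)),
               "elongation")
})

test_that("the femoral frame follows the condylar construction", {
  med <- new("Sphere", center = c(0, 0, 10), radius = 8)
  lat <- new("Sphere", center = c(0, 0, -10), radius = 8)
  fr <- buildFemoralFrame(med, lat, c(0, 1, 0), "left")
  expect_equal(fr@origin, c(0, 0, 0))
  expect_equal(fr@y, c(0, 1, 0))
  expect_equal(fr@z, c(0, 0, 1))
  expect_equal(fr@x, c(1, 0, 0))

  # tilted axis: Y kept exact, Z re-orthogonalised (Gram-Schmidt oracle)
  ax <- c(0, 0.9806, 0.1961)
  ax <- ax / sqrt(sum(ax^2))
  fr2 <- buildFemoralFrame(med, lat, ax, "left")
  expect_equal(fr2@y, ax, tolerance = 1e-12)
  zg <- c(0, 0, 1) - sum(c(0, 0, 1) * ax) * ax
  zg <- zg / sqrt(sum(zg^2))
  expect_equal(fr2@z, zg, tolerance = 1e-12)
  R <- cbind(fr2@x, fr2@y, fr2@z)
  expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
  expect_equal(det(R), 1, tolerance = 1e-9)

  expect_error(buildFemoralFrame(med, med, c(0, 1, 0), "left"), "coincide")
  expect_error(buildFemoralFrame(med, lat, c(0, 0.05, 0.999), "left"),
               "5 degrees")
})

test_that("frames are right-handed orthonormal for both sides", {
  med <- new("Sphere", center = c(1, 2, 12), radius = 8)
  lat <- new("Sphere", center = c(-1, 1, -9), radius = 9)
  for (side in c("left", "right")) {
    fr <- buildFemoralFrame(med, lat, c(0.05, 0.99, 0.1), side)
    R <- cbind(fr@x, fr@y, fr@z)
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
  }
})

test_that("alignment is rigid and invertible", {
  s <- icosphereMesh(7, 2)
  idf <- new("AnatomicalFrame", origin = c(0, 0, 0), x = c(1, 0, 0),
             y = c(0, 1, 0), z = c(0, 0, 1))
  expect_equal(meshVertices(alignToFrame(s, idf)), meshVertices(s))

  fr <- buildFemoralFrame(new("Sphere", center = c(3, -40, 12), radius = 8),
                          new("Sphere", center = c(2, -41, -10), radius = 8),
                          c(0.1, 0.98, 0.05) / sqrt(sum(c(0.1, 0.98, 0.05)^2)),
                          "left")
  al <- alignToFrame(s, fr)
  # inter-vertex distances preserved exactly
  d0 <- as.matrix(stats::dist(meshVertices(s)[1:20, ]))
  d1 <- as.matrix(stats::dist(meshVertices(al)[1:20, ]))
  expect_lt(max(abs(d0 - d1)), 1e-9)
  # round trip
  back <- transformPoints(meshVertices(al), fr, inverse = TRUE)
  expect_lt(max(abs(back - meshVertices(s))), 1e-9)
  # frame origin maps to the world origin
  expect_lt(max(abs(transformPoints(fr@origin, fr))), 1e-12)
})

test_that("aligned condylar spheres are centred about the origin", {
  pop <- smallPopulation()
  al <- alignSpecimen(pop$pop$meshes[[2]], pop$pop$landmarks[[2]],
                      "complete_femur", "left")
  mid <- (sphereCenter(al$spheres$condyle_med) +
          sphereCenter(al$spheres$condyle_lat)) / 2
  expect_lt(max(abs(mid)), 1e-9)
  expect_true(isTRUE(meshMetadata(al$mesh)$aligned))
})

test_that("partial femur cuts retain two sphere diameters", {
  cyl <- markAligned(cylinderMesh(radius = 6, length = 100))
  sph <- new("Sphere", center = c(0, -40, 0), radius = 10)
  cut <- cutPartialFemur(cyl, "distal", sph)
  v <- meshVertices(cyl)
  expect_setequal(meshVertices(cut)[, 2], v[v[, 2] <= -50 + 40, 2])
  expect_equal(range(meshVertices(cut)[, 2]), c(-50, -10))

  cutp <- cutPartialFemur(cyl, "proximal", sph)
  expect_equal(range(meshVertices(cutp)[, 2]), c(10, 50))

  expect_warning(full <- cutPartialFemur(cyl, "distal",
                                         new("Sphere", center = c(0, 0, 0),
                                             radius = 30)),
                 "exceeds")
  expect_identical(nVertices(full), nVertices(cyl))
  expect_error(cutPartialFemur(cylinderMesh(), "distal", sph), "aligned")
})

test_that("partial tibia cuts retain the proximal part above the landmark", {
  cyl <- markAligned(cylinderMesh(radius = 6, length = 100))
  v <- meshVertices(cyl)
  v[, 2] <- v[, 2] - 50  # span [-100, 0]
  tib <- markAligned(triangleMesh(v, meshFaces(cyl)))
  cut <- cutPartialTibia(tib, c(5, -20, 0))
  expect_equal(range(meshVertices(cut)[, 2]), c(-20, 0))
  # landmark below the distal end: whole mesh
  expect_identical(nVertices(cutPartialTibia(tib, c(0, -150, 0))),
                   nVertices(tib))
  # landmark above the proximal end: empty result
  expect_error(cutPartialTibia(tib, c(0, 10, 0)), "empty")
  expect_error(cutPartialTibia(triangleMesh(v, meshFaces(cyl)), c(0, -20, 0)),
               "aligned")
})

test_that("rigid regional realignment recovers a known rotation", {
  v <- meshVertices(icosphereMesh(10, 3))
  v <- cbind(v[, 1] * 1.6, v[, 2] * 0.8, v[, 3])  # ellipsoid: no symmetry
  src <- triangleMesh(v, meshFaces(icosphereMesh(10, 3)))
  th <- 5 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tgt <- triangleMesh(v %*% t(R), meshFaces(src))
  res <- rigidAlignRegions(src, tgt)
  err <- res$rotation %*% t(R)
  ang <- acos(min(1, (sum(diag(err)) - 1) / 2)) * 180 / pi
  expect_lt(ang, 0.1)
  expect_lt(res$rms, 0.05)

  # source == target: identity
  res0 <- rigidAlignRegions(src, src)
  expect_lt(max(abs(res0$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(res0$translation)), 1e-9)

  expect_error(rigidAlignRegions(src, tgt, region_indices = c(1, 1, 1)),
               "collinear|3 points")
})
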