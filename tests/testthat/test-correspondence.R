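test_that("the median-size specimen is selected as template", {
  s <- icosphereMesh(10, 1)
  scaled <- function(f) triangleMesh(meshVertices(s) * f, meshFaces(s))
  expect_identical(selectTemplate(list(scaled(1), scaled(2), scaled(3))), 2L)
  expect_identical(selectTemplate(list(scaled(3), scaled(1), scaled(2))), 3L)
  # even count: lower median
  expect_identical(selectTemplate(list(scaled(1), scaled(2), scaled(3),
                                       scaled(4))), 2L)
  expect_identical(selectTemplate(list(scaled(1))), 1L)
  expect_error(selectTemplate(list()), "empty")
})

test_that("nearest-neighbour registration is exact", {
  s <- icosphereMesh(8, 2)
  # identity
  out <- registerNearestNeighbor(s, s)
  expect_identical(out[seq_len(nVertices(s)), ], meshVertices(s))
  expect_equal(attr(out, "meanDistance"), 0)

  # ties break to the lowest target index
  tmpl <- triangleMesh(rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0)),
                       matrix(c(1L, 2L, 3L), 1))
  tgt <- triangleMesh(rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0)),
                      matrix(c(1L, 2L, 3L), 1))
  out <- registerNearestNeighbor(tmpl, tgt)
  expect_equal(out[1, ], c(1, 0, 0))

  # random case against an exhaustive search
  set.seed(5)
  A <- matrix(rnorm(150), 50, 3)
  B <- matrix(rnorm(600), 200, 3)
  tA <- triangleMesh(A, matrix(c(1L, 2L, 3L), 1))
  tB <- triangleMesh(B, matrix(c(1L, 2L, 3L), 1))
  out <- registerNearestNeighbor(tA, tB)
  brute <- t(vapply(seq_len(50), function(i)
    B[which.min(colSums((t(B) - A[i, ])^2)), ], numeric(3)))
  expect_identical(unclass(out)[seq_len(50), ], brute)
})

test_that("surface-mode registration lands exactly on the target surface", {
  set.seed(8)
  tmpl <- icosphereMesh(9, 2)
  tgt <- icosphereMesh(10, 2)
  out <- registerNearestNeighbor(tmpl, tgt, mode = "surface")
  d <- surfaceDistance(out[seq_len(nrow(out)), ], tgt)$distance
  expect_lt(max(d), 1e-9)
})

test_that("corresponded sets resample the target geometry", {
  # K identical meshes -> identical arrays
  s <- markAligned(icosphereMesh(10, 2))
  set <- buildCorrespondedSet(list(a = s, b = s, c = s),
                              remesh_template = FALSE)
  expect_equal(set@shapes[1, , ], set@shapes[2, , ])
  expect_equal(set@shapes[2, , ], set@shapes[3, , ])

  # spheres of radii 9, 10, 11 with the radius-10 template: every
  # corresponded vertex lies on its source sphere
  meshes <- lapply(c(9, 10, 11), function(r) markAligned(icosphereMesh(r, 3)))
  set <- buildCorrespondedSet(meshes, template_index = 2L,
                              remesh_template = FALSE)
  for (k in 1:3) {
    radii <- sqrt(rowSums(set@shapes[k, , ]^2))
    expect_lt(max(abs(radii - c(9, 10, 11)[k])), 1e-6)
  }
  # vertex-mode outputs are a subset of target vertices (exact)
  for (k in c(1, 3)) {
    idx <- ossm:::.nearestVertex(set@shapes[k, , ], meshVertices(meshes[[k]]))
    snap <- meshVertices(meshes[[k]])[idx, ]
    expect_lt(max(abs(snap - set@shapes[k, , ])), 1e-9)
  }

  # unaligned input is rejected with the offending ids
  expect_error(buildCorrespondedSet(list(x = icosphereMesh(9, 1),
                                         y = markAligned(icosphereMesh(10, 1))),
                                    remesh_template = FALSE),
               "not aligned.*x")
})

test_that("registration is deterministic for fixed input ordering", {
  pop <- smallPopulation()
  set1 <- buildCorrespondedSet(pop$aligned)
  set2 <- buildCorrespondedSet(pop$aligned)
  expect_identical(set1@shapes, set2@shapes)
  expect_identical(set1@qc$meanDistance, set2@qc$meanDistance)
})
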