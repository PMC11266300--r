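test_that("meshes round-trip through STL, PLY and OBJ", {
  tet <- tetrahedronMesh()
  for (fmt in c("stl", "ply", "obj")) {
    for (binary in if (fmt == "obj") FALSE else c(TRUE, FALSE)) {
      path <- tempfile(fileext = paste0(".", fmt))
      writeMesh(tet, path, binary = binary)
      back <- readMesh(path)
      expect_equal(nVertices(back), 4L)
      expect_equal(nFaces(back), 4L)
      if (fmt == "stl") {
        # STL stores per-facet float32 vertices; match after merging
        perm <- ossm:::.nearestVertex(meshVertices(back), meshVertices(tet))
        expect_equal(meshVertices(back), meshVertices(tet)[perm, ],
                     tolerance = 1e-6)
      } else {
        expect_equal(meshVertices(back), meshVertices(tet),
                     tolerance = 1e-6)
        expect_identical(meshFaces(back), meshFaces(tet))
      }
    }
  }
})

test_that("binary and ascii PLY of the same mesh agree", {
  s <- icosphereMesh(5, 1)
  pb <- tempfile(fileext = ".ply")
  pa <- tempfile(fileext = ".ply")
  writeMesh(s, pb, binary = TRUE)
  writeMesh(s, pa, binary = FALSE)
  mb <- readMesh(pb)
  ma <- readMesh(pa)
  expect_identical(meshFaces(mb), meshFaces(ma))
  expect_lt(max(abs(meshVertices(mb) - meshVertices(ma))), 1e-6)
})

test_that("duplicated STL facet vertices are merged with tolerance", {
  s <- icosphereMesh(5, 1)
  path <- tempfile(fileext = ".stl")
  writeMesh(s, path, binary = TRUE)  # STL has no connectivity: soup on disk
  back <- readMesh(path)
  expect_identical(nVertices(back), nVertices(s))
  expect_identical(nFaces(back), nFaces(s))
  expect_true(isWatertight(back))
})

test_that("corrupt meshes are rejected", {
  # out-of-range face index
  path <- tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 3",
               "property float x", "property float y", "property float z",
               "element face 1", "property list uchar int vertex_indices",
               "end_header", "0 0 0", "1 0 0", "0 1 0", "3 0 1 7"), path)
  expect_error(readMesh(path), "out of range|indices")
  # unknown format
  expect_error(readMesh(tempfile(fileext = ".xyz")), "not found|unknown")
  # empty mesh refuses to serialize
  empty <- triangleMesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3))
  expect_error(writeMesh(empty, tempfile(fileext = ".ply")), "empty")
})

test_that("remeshing reaches the target resolution without losing shape", {
  s <- icosphereMesh(10, 4)  # fine input, median edge ~0.76 mm
  r <- remeshUniform(s, 2)
  el <- edgeLengths(r)
  expect_gt(median(el), 1.5)
  expect_lt(median(el), 2.5)
  expect_lt(abs(meshArea(r) - meshArea(s)) / meshArea(s), 0.03)
  expect_lt(abs(meshVolume(r) - meshVolume(s)) / meshVolume(s), 0.02)
  expect_true(isWatertight(r))
  expect_identical(eulerCharacteristic(r), 2L)
  # unimodal edge distribution around the target
  expect_lt(stats::sd(el) / mean(el), 0.35)
  # one-sided surface deviation below half the target edge
  expect_lt(max(surfaceDistance(meshVertices(r), s)$distance), 1)
  # orientation preserved (positive enclosed volume)
  expect_gt(meshVolume(r), 0)
})

test_that("remeshing an already-uniform mesh is near a fixed point", {
  r <- remeshUniform(icosphereMesh(10, 4), 2)
  r2 <- remeshUniform(r, 2)
  expect_lt(abs(nVertices(r2) - nVertices(r)) / nVertices(r), 0.2)
})

test_that("degenerate remeshing inputs are rejected cleanly", {
  s <- icosphereMesh(10, 2)
  expect_error(remeshUniform(s, -1), "positive")
  expect_error(remeshUniform(s, 100), "bounding-box")
  holey <- triangleMesh(meshVertices(s), meshFaces(s)[-1, ])
  expect_error(remeshUniform(holey, 2), "manifold")
})
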