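test_that("threshold segmentation follows the inclusive >= convention", {
  vol <- voxelVolume(array(1000, c(4, 4, 4)))
  expect_true(all(thresholdSegment(vol, 350)@data))

  vals <- array(0, c(3, 3, 3))
  vals[2, 2, 2] <- 350
  m <- thresholdSegment(voxelVolume(vals), 350)
  expect_identical(sum(m@data), 1L)
  expect_true(m@data[2, 2, 2])

  expect_error(thresholdSegment(vol, NaN), "finite")
  expect_error(thresholdSegment(vol, Inf), "finite")
})

test_that("threshold segmentation matches the analytic voxelized ball", {
  # intensity 1000 inside a radius-10 ball at 1 mm spacing
  g <- seq(-14, 14, by = 1)
  coords <- expand.grid(x = g, y = g, z = g)
  inside <- with(coords, x^2 + y^2 + z^2) <= 10^2
  vol <- voxelVolume(array(ifelse(inside, 1000, 0), c(29, 29, 29)),
                     origin = c(-14, -14, -14))
  mask <- thresholdSegment(vol, 350)
  # oracle: brute-force count of voxel centers inside the ball
  expect_identical(sum(mask@data), sum(inside))
  expect_lt(abs(sum(mask@data) - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000),
            0.02)
})

test_that("raising the threshold never adds foreground voxels", {
  set.seed(1)
  vol <- voxelVolume(array(runif(8^3, 0, 1000), c(8, 8, 8)))
  counts <- vapply(c(100, 300, 350, 500, 900),
                   function(t) sum(thresholdSegment(vol, t)@data), 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("morphological closing fills cavities and is idempotent", {
  # ball mask with a single interior 1-voxel cavity
  g <- seq(-12, 12, by = 1)
  coords <- expand.grid(x = g, y = g, z = g)
  inside <- with(coords, x^2 + y^2 + z^2) <= 8^2
  arr <- array(inside, c(25, 25, 25))
  arr[13, 13, 13] <- FALSE
  mask <- binaryMask(arr, origin = c(-12, -12, -12))
  closed <- morphologicalClose(mask, 3.0)
  expect_true(closed@data[13, 13, 13])

  # brute-force dilate/erode oracle with an explicit ball structuring
  # element (radius 1.5 voxels)
  off <- as.matrix(expand.grid(i = -1:1, j = -1:1, k = -1:1))
  off <- off[rowSums(off^2) <= 1.5^2, ]
  d <- dim(arr)
  shift_or <- function(a) {
    out <- array(FALSE, d)
    for (r in seq_len(nrow(off))) {
      src <- list(seq_len(d[1]) - off[r, 1], seq_len(d[2]) - off[r, 2],
                  seq_len(d[3]) - off[r, 3])
      ok <- lapply(seq_len(3), function(ax) src[[ax]] >= 1 & src[[ax]] <= d[ax])
      dst <- lapply(seq_len(3), function(ax) seq_len(d[ax])[ok[[ax]]])
      out[dst[[1]], dst[[2]], dst[[3]]] <-
        out[dst[[1]], dst[[2]], dst[[3]]] |
        a[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
    }
    out
  }
  shift_and <- function(a) {
    out <- array(TRUE, d)
    for (r in seq_len(nrow(off))) {
      src <- list(seq_len(d[1]) - off[r, 1], seq_len(d[2]) - off[r, 2],
                  seq_len(d[3]) - off[r, 3])
      ok <- lapply(seq_len(3), function(ax) src[[ax]] >= 1 & src[[ax]] <= d[ax])
      dst <- lapply(seq_len(3), function(ax) seq_len(d[ax])[ok[[ax]]])
      contrib <- array(FALSE, d)  # out-of-range treated as background
      contrib[dst[[1]], dst[[2]], dst[[3]]] <-
        a[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
      out <- out & contrib
    }
    out
  }
  oracle <- shift_and(shift_or(arr))
  # interior agreement (the implementation pads, the oracle clips at the
  # array border; the mask here does not touch the border)
  expect_identical(closed@data, oracle)

  # idempotence
  closed2 <- morphologicalClose(closed, 3.0)
  expect_identical(closed2@data, closed@data)

  # closing of the empty set
  empty <- binaryMask(array(FALSE, c(5, 5, 5)))
  expect_false(any(morphologicalClose(empty, 3.0)@data))
})

test_that("a sub-voxel kernel warns and returns the mask unchanged", {
  mask <- binaryMask(array(TRUE, c(4, 4, 4)), spacing = c(5, 5, 5))
  expect_warning(out <- morphologicalClose(mask, 3.0), "unchanged")
  expect_identical(out@data, mask@data)
})

test_that("surface extraction recovers a voxelized ball", {
  ball <- voxelizeMesh(icosphereMesh(10, 3), spacing = 1)
  mask <- thresholdSegment(ball, 350)
  surf <- extractSurface(mask)
  expect_lt(abs(meshArea(surf) - 4 * pi * 100) / (4 * pi * 100), 0.05)
  expect_identical(eulerCharacteristic(surf), 2L)
  expect_true(isWatertight(surf))
  # outward orientation: enclosed volume is positive
  expect_gt(meshVolume(surf), 0)
  # radius recovery within one voxel spacing
  sp <- fitSphere(meshVertices(surf))
  expect_lt(abs(sphereRadius(sp) - 10), 1)

  expect_error(extractSurface(binaryMask(array(FALSE, c(4, 4, 4)))),
               "empty segmentation")
})

test_that("disjoint components are separable", {
  s1 <- icosphereMesh(6, 2)
  v2 <- meshVertices(s1)
  v2[, 1] <- v2[, 1] + 25
  s2 <- triangleMesh(v2, meshFaces(s1))
  vol <- voxelizeMesh(triangleMesh(rbind(meshVertices(s1), v2),
                                   rbind(meshFaces(s1),
                                         meshFaces(s2) + nVertices(s1))),
                      spacing = 1)
  mask <- thresholdSegment(vol, 350)
  surf <- extractSurface(mask)
  comps <- connectedComponents(surf)
  expect_length(comps, 2)
  largest <- extractSurface(mask, largestComponent = TRUE)
  expect_lt(nFaces(largest), nFaces(surf))
  expect_true(isWatertight(largest))
})

test_that("the full chain stays within two voxels of the source surface", {
  pop <- smallPopulation()
  src <- pop$pop$meshes[[1]]
  vol <- voxelizeMesh(src, spacing = 1)
  mesh <- extractSurface(morphologicalClose(thresholdSegment(vol, 350), 3.0))
  d1 <- max(surfaceDistance(meshVertices(mesh), src)$distance)
  d2 <- max(surfaceDistance(meshVertices(src), mesh)$distance)
  expect_lt(max(d1, d2), 2 * max(vol@spacing))
})
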