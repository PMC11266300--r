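# geometric fixtures built in code, plus lazily cached heavy populations
# shared across test files (testthat sources helpers once per run)

tetrahedronMesh <- function() {
  triangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
               rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4)))
}

icosphereMesh <- function(r = 10, n = 3) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (i in seq_len(n)) {
    nf <- nrow(f)
    newf <- matrix(0L, 0, 3)
    key <- new.env()
    mid <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      if (!is.null(key[[k]])) return(key[[k]])
      v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
      key[[k]] <- nrow(v)
      nrow(v)
    }
    for (j in seq_len(nf)) {
      a <- f[j, 1]; b <- f[j, 2]; cc <- f[j, 3]
      ab <- mid(a, b); bc <- mid(b, cc); ca <- mid(cc, a)
      newf <- rbind(newf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc),
                    c(ab, bc, ca))
    }
    f <- newf
  }
  v <- v / sqrt(rowSums(v^2)) * r
  triangleMesh(v, f)
}

# closed cylinder along +Y, rings symmetric about the axis
cylinderMesh <- function(radius = 5, length = 60, nTheta = 24, nRings = 31) {
  th <- seq(0, 2 * pi, length.out = nTheta + 1)[-(nTheta + 1)]
  ys <- seq(-length / 2, length / 2, length.out = nRings)
  v <- do.call(rbind, lapply(ys, function(y)
    cbind(radius * cos(th), y, radius * sin(th))))
  f <- matrix(0L, 0, 3)
  idx <- function(ring, k) (ring - 1L) * nTheta + ((k - 1L) %% nTheta) + 1L
  for (ring in seq_len(nRings - 1)) {
    for (k in seq_len(nTheta)) {
      a <- idx(ring, k); b <- idx(ring, k + 1)
      c2 <- idx(ring + 1, k); d <- idx(ring + 1, k + 1)
      f <- rbind(f, c(a, b, d), c(a, d, c2))
    }
  }
  bot <- nrow(v) + 1L
  v <- rbind(v, c(0, -length / 2, 0))
  top <- nrow(v) + 1L
  v <- rbind(v, c(0, length / 2, 0))
  for (k in seq_len(nTheta)) {
    f <- rbind(f, c(bot, idx(1, k + 1), idx(1, k)),
               c(top, idx(nRings, k), idx(nRings, k + 1)))
  }
  triangleMesh(v, f)
}

markAligned <- function(mesh) {
  mesh@metadata$aligned <- TRUE
  mesh
}

alignPopulation <- function(pop, bone = "complete_femur", side = "left") {
  out <- lapply(seq_along(pop$meshes), function(i)
    alignSpecimen(pop$meshes[[i]], pop$landmarks[[i]], bone, side)$mesh)
  names(out) <- names(pop$meshes)
  out
}

# ---- cached heavy fixtures --------------------------------------------

.fixture_cache <- new.env(parent = emptyenv())

cachedFixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# the reference study condition: 30 femora, scale-dominated with small
# secondary factors, pushed through alignment, correspondence and PCA
referencePopulationModel <- function() {
  cachedFixture("pop30", function() {
    pop <- generateBonePopulation(bonePopulationSpec(n = 30, seed = 1))
    aligned <- alignPopulation(pop)
    set <- buildCorrespondedSet(aligned)
    model <- buildSSM(set)
    scores <- t(vapply(seq_len(nShapes(set)), function(k)
      projectShape(model, shapeMesh(set, k)),
      numeric(length(modelEigenvalues(model)))))
    list(pop = pop, set = set, model = model, scores = scores)
  })
}

# small coarse population for cheap structural tests
smallPopulation <- function() {
  cachedFixture("pop5", function() {
    pop <- generateBonePopulation(
      bonePopulationSpec(n = 5, seed = 42, mesh_spacing = 2))
    aligned <- alignPopulation(pop)
    list(pop = pop, aligned = aligned)
  })
}
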