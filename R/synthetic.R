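# ---- implicit-surface bone construction -------------------------------
#
# Synthetic bones are built as smooth unions (log-sum-exp smooth minimum)
# of capsule and sphere signed-distance fields, iso-surfaced on a regular
# grid, then deformed by smooth latent-factor warps (global scale, distal
# frontal bend = varus/valgus, distal sagittal bend = procurvation, distal
# axial twist = torsion).  Canonical pose: +Y proximal, +Z medial,
# +X cranial, origin at mid-shaft.

sdfSphere <- function(p, center, r) {
  sqrt((p[, 1] - center[1])^2 + (p[, 2] - center[2])^2 +
       (p[, 3] - center[3])^2) - r
}

sdfCapsule <- function(p, a, b, r) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- ((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2] +
        (p[, 3] - a[3]) * ab[3]) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((p[, 1] - a[1] - t * ab[1])^2 + (p[, 2] - a[2] - t * ab[2])^2 +
       (p[, 3] - a[3] - t * ab[3])^2) - r
}

sdfEllipsoid <- function(p, center, semi) {
  # scaled-sphere approximation, adequate for mildly eccentric shapes
  q <- cbind((p[, 1] - center[1]) / semi[1], (p[, 2] - center[2]) / semi[2],
             (p[, 3] - center[3]) / semi[3])
  (sqrt(rowSums(q^2)) - 1) * min(semi)
}

smin2 <- function(a, b, k) {
  m <- pmin(a, b)
  m - k * log(exp(-(a - m) / k) + exp(-(b - m) / k))
}

sminAll <- function(parts, k) Reduce(function(a, b) smin2(a, b, k), parts)

# default base dimensions (mm) for a medium-to-large dog
femurBaseDimensions <- function(shaft_length = 180) {
  s <- shaft_length / 180
  list(shaft_length = shaft_length, shaft_radius = 11 * s,
       condyle_radius = 13 * s, condyle_offset = 11 * s,
       head_radius = 12 * s, neck_radius = 6.5 * s,
       trochanter_radius = 8.5 * s, blend = 4 * s)
}

tibiaBaseDimensions <- function(shaft_length = 160) {
  s <- shaft_length / 160
  list(shaft_length = shaft_length, shaft_radius = 9 * s,
       plateau_semi = c(15, 7, 19) * s, tuberosity_radius = 6 * s,
       malleolus_radius = 8 * s, blend = 4 * s)
}

patellaBaseDimensions <- function(length = 28) {
  s <- length / 28
  list(length = length, semi = c(8, 13, 9) * s, apex_radius = 4.5 * s,
       blend = 3 * s)
}

# component list for a canonical bone; width_factor scales the condylar
# separation (femur only)
boneComponents <- function(bone, base, width_factor = 1) {
  if (bone == "femur") {
    h <- base$shaft_length / 2
    rc <- base$condyle_radius
    off <- base$condyle_offset * width_factor
    list(
      shaft = list(type = "capsule", a = c(0, -h + 6, 0), b = c(0, h - 10, 0),
                   r = base$shaft_radius),
      condyle_med = list(type = "sphere",
                         center = c(-2, -h + 0.6 * rc, off), r = rc),
      condyle_lat = list(type = "sphere",
                         center = c(-2, -h + 0.6 * rc, -off), r = rc),
      neck = list(type = "capsule", a = c(0, h - 14, 2),
                  b = c(0, h - 2, 0.9 * base$head_radius + 2),
                  r = base$neck_radius),
      head = list(type = "sphere",
                  center = c(0, h - 2, 0.9 * base$head_radius + 4),
                  r = base$head_radius),
      trochanter = list(type = "sphere", center = c(0, h - 2, -10),
                        r = base$trochanter_radius))
  } else if (bone == "tibia") {
    h <- base$shaft_length / 2
    list(
      shaft = list(type = "capsule", a = c(0, -h + 6, 0), b = c(0, h - 6, 0),
                   r = base$shaft_radius),
      plateau = list(type = "ellipsoid", center = c(0, h - 4, 0),
                     semi = base$plateau_semi),
      tuberosity = list(type = "sphere",
                        center = c(base$shaft_radius + 3, h - 18, 0),
                        r = base$tuberosity_radius),
      malleolus = list(type = "sphere", center = c(0, -h + 2, 3),
                       r = base$malleolus_radius))
  } else {  # patella
    list(
      body = list(type = "ellipsoid", center = c(0, 0, 0), semi = base$semi),
      apex = list(type = "sphere", center = c(0, -base$semi[2] - 1, 0),
                  r = base$apex_radius))
  }
}

evalComponents <- function(comps, p, blend) {
  parts <- lapply(comps, function(cp) switch(cp$type,
    sphere = sdfSphere(p, cp$center, cp$r),
    capsule = sdfCapsule(p, cp$a, cp$b, cp$r),
    ellipsoid = sdfEllipsoid(p, cp$center, cp$semi)))
  sminAll(parts, blend)
}

componentBBox <- function(comps) {
  lo <- rep(Inf, 3)
  hi <- rep(-Inf, 3)
  for (cp in comps) {
    ext <- switch(cp$type,
      sphere = rbind(cp$center - cp$r, cp$center + cp$r),
      capsule = rbind(pmin(cp$a, cp$b) - cp$r, pmax(cp$a, cp$b) + cp$r),
      ellipsoid = rbind(cp$center - cp$semi, cp$center + cp$semi))
    lo <- pmin(lo, ext[1, ])
    hi <- pmax(hi, ext[2, ])
  }
  rbind(lo, hi)
}

# mesh the zero level set of the component union on a regular grid
meshComponents <- function(comps, blend, spacing) {
  bb <- componentBBox(comps)
  margin <- blend + 2 * spacing
  lo <- bb[1, ] - margin
  hi <- bb[2, ] + margin
  dims <- pmax(4L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  gx <- lo[1] + (seq_len(dims[1]) - 1) * spacing
  gy <- lo[2] + (seq_len(dims[2]) - 1) * spacing
  gz <- lo[3] + (seq_len(dims[3]) - 1) * spacing
  p <- cbind(rep(gx, times = dims[2] * dims[3]),
             rep(rep(gy, each = dims[1]), times = dims[3]),
             rep(gz, each = dims[1] * dims[2]))
  vals <- -evalComponents(comps, p, blend)  # inside = positive
  res <- .mtSurface(vals, dims, rep(spacing, 3), lo, 0)
  triangleMesh(res$vertices, res$faces)
}

# ---- latent-factor warps ----------------------------------------------

smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

# distal weight: 1 well below the hinge band, 0 well above
distalWeight <- function(y, band) smoothstep((band - y) / (2 * band))

rotateAbout <- function(p, axis, angle_rad) {
  # per-point angles; axis is one of "x", "y", "z"
  ca <- cos(angle_rad)
  sa <- sin(angle_rad)
  out <- p
  if (axis == "x") {
    out[, 2] <- ca * p[, 2] - sa * p[, 3]
    out[, 3] <- sa * p[, 2] + ca * p[, 3]
  } else if (axis == "y") {
    out[, 1] <- ca * p[, 1] + sa * p[, 3]
    out[, 3] <- -sa * p[, 1] + ca * p[, 3]
  } else {
    out[, 1] <- ca * p[, 1] - sa * p[, 2]
    out[, 2] <- sa * p[, 1] + ca * p[, 2]
  }
  out
}

# apply the latent factors to points; order: scale -> varus -> procurvation
# -> torsion (fixed so latent records stay interpretable)
applyLatentWarp <- function(p, latent, band) {
  p <- p * exp(latent$scale)
  b <- band * exp(latent$scale)
  w <- distalWeight(p[, 2], b)
  p <- rotateAbout(p, "x", latent$varus * pi / 180 * w)
  w <- distalWeight(p[, 2], b)
  p <- rotateAbout(p, "z", latent$procurv * pi / 180 * w)
  w <- distalWeight(p[, 2], b)
  p <- rotateAbout(p, "y", latent$torsion * pi / 180 * w)
  p
}

# ---- population specification and generation --------------------------

#' Specify a synthetic bone population
#'
#' The defaults describe the reference study condition for pipeline
#' validation: 30 femur-like specimens whose dominant latent factor is
#' global scale (log-scale SD 0.1, i.e. roughly +/-10\% size) with small
#' secondary varus/valgus, procurvation, torsion and condylar-width
#' factors, mirroring the factor ordering expected in real canine femora
#' where size dominates and frontal-plane bend is the second factor.
#'
#' @param n number of specimens.
#' @param scale_sd SD of the log of the global scale factor.
#' @param varus_sd SD of the frontal-plane distal bend, degrees.
#' @param procurv_sd SD of the sagittal-plane distal bend, degrees.
#' @param torsion_sd SD of the distal axial twist, degrees.
#' @param condyle_width_sd fractional SD of the condylar separation.
#' @param seed RNG seed; generation is fully deterministic given the spec.
#' @param bone `"femur"`, `"tibia"` or `"patella"`.
#' @param base_dimensions named list of base sizes in mm; defaults to the
#'   bone's standard dimensions (180 mm femoral shaft for a medium-to-
#'   large dog).
#' @param mesh_spacing iso-surfacing grid spacing in mm; controls mesh
#'   resolution.
#' @return A [BonePopulationSpec-class].
#' @export
bonePopulationSpec <- function(n = 30, scale_sd = 0.1, varus_sd = 1.5,
                               procurv_sd = 1.0, torsion_sd = 1.5,
                               condyle_width_sd = 0.03, seed = 1,
                               bone = "femur", base_dimensions = NULL,
                               mesh_spacing = 1.25) {
  if (is.null(base_dimensions))
    base_dimensions <- switch(bone,
      femur = femurBaseDimensions(),
      tibia = tibiaBaseDimensions(),
      patella = patellaBaseDimensions())
  new("BonePopulationSpec", n = as.integer(n), scaleSD = scale_sd,
      varusSD = varus_sd, procurvSD = procurv_sd, torsionSD = torsion_sd,
      condyleWidthSD = condyle_width_sd, seed = as.integer(seed),
      bone = bone, baseDimensions = base_dimensions,
      meshSpacing = mesh_spacing)
}

setMethod("show", "BonePopulationSpec", function(object) {
  cat(sprintf("BonePopulationSpec: %d %s specimens (seed %d)\n", object@n,
              object@bone, object@seed))
  cat(sprintf("  scale SD %.3g (log), varus %.3g deg, procurvation %.3g deg,\n",
              object@scaleSD, object@varusSD, object@procurvSD))
  cat(sprintf("  torsion %.3g deg, condyle width %.3g (fraction)\n",
              object@torsionSD, object@condyleWidthSD))
  invisible(NULL)
})

# build one bone mesh + landmarks from realized latent factors (no RNG)
generateBone <- function(bone, base, latent, mesh_spacing, side = "left",
                         id = "specimen") {
  width_factor <- if (bone == "femur") 1 + latent$condyle_width else 1
  comps <- boneComponents(bone, base, width_factor)
  mesh <- meshComponents(comps, base$blend, mesh_spacing)
  band <- 0.06 * if (bone == "patella") base$length else base$shaft_length
  v0 <- mesh@vertices

  landmarks <- list()
  if (bone == "femur") {
    rc <- base$condyle_radius
    for (nm in c("condyle_med", "condyle_lat")) {
      cen <- comps[[nm]]$center
      d <- sqrt(rowSums(sweep(v0, 2, cen)^2))
      patch <- which(abs(d - rc) < 0.15 * rc & v0[, 2] < cen[2] + 0.8 * rc)
      landmarks[[sub("condyle_med", "condyle_medial_patch",
                     sub("condyle_lat", "condyle_lateral_patch", nm))]] <- patch
    }
    hc <- comps$head$center
    dh <- sqrt(rowSums(sweep(v0, 2, hc)^2))
    landmarks$head_patch <-
      which(abs(dh - base$head_radius) < 0.15 * base$head_radius &
            v0[, 3] > hc[3] - 0.8 * base$head_radius)
    h <- base$shaft_length / 2
    pts <- rbind(shaft_proximal_point = c(0, 0.7 * h, 0),
                 shaft_distal_point = c(0, -0.7 * h, 0))
  } else if (bone == "tibia") {
    h <- base$shaft_length / 2
    tub <- comps$tuberosity$center
    pts <- rbind(shaft_proximal_point = c(0, 0.7 * h, 0),
                 shaft_distal_point = c(0, -0.7 * h, 0),
                 tuberosity_distal_point = tub + c(2, -base$tuberosity_radius, 0))
  } else {
    pts <- rbind(apex_point = c(0, -base$semi[2] - base$apex_radius, 0))
  }

  warped <- applyLatentWarp(mesh@vertices, latent, band)
  ptsw <- applyLatentWarp(pts, latent, band)
  for (i in seq_len(nrow(pts))) landmarks[[rownames(pts)[i]]] <- ptsw[i, ]
  if (bone == "femur") {
    cm <- applyLatentWarp(rbind(comps$condyle_med$center,
                                comps$condyle_lat$center,
                                comps$head$center), latent, band)
    landmarks$condyle_medial_center <- cm[1, ]
    landmarks$condyle_lateral_center <- cm[2, ]
    landmarks$head_center <- cm[3, ]
  }

  out <- triangleMesh(warped, mesh@faces, name = id, side = side)
  list(mesh = out, landmarks = landmarks)
}

#' Generate a synthetic bone population
#'
#' Builds `n` closed femur-like (or tibia/patella-like) surfaces with
#' known latent factors: a curved-tube shaft with two condylar sphere
#' bulges distally and a head sphere plus trochanter bump proximally, each
#' specimen scaled by exp(N(0, scale_sd)) and deformed by its realized
#' varus/valgus, procurvation and torsion angles.  Deterministic for a
#' fixed spec (the seed is consumed in an isolated RNG scope).  Per-
#' specimen landmarks (condylar and head articular patches, axis
#' endpoints) are emitted consistently with the generated geometry,
#' enabling the anatomical-frame stage to run unsupervised.
#'
#' @param spec a [BonePopulationSpec-class].
#' @param side side tag attached to every mesh.
#' @param dir optional directory: writes `<id>.ply`, `<id>_landmarks.json`
#'   and `latent.csv`.
#' @return list with `meshes` (list of [TriangleMesh-class]), `landmarks`
#'   (per-specimen named lists of points / vertex-index patches), `latent`
#'   (data.frame of realized factors, one row per specimen) and `spec`.
#' @export
generateBonePopulation <- function(spec, side = "left", dir = NULL) {
  stopifnot(is(spec, "BonePopulationSpec"))
  validObject(spec)
  latent <- withLocalSeed(spec@seed, {
    data.frame(
      id = sprintf("%s_%03d", spec@bone, seq_len(spec@n)),
      scale = stats::rnorm(spec@n, 0, spec@scaleSD),
      varus = stats::rnorm(spec@n, 0, spec@varusSD),
      procurv = stats::rnorm(spec@n, 0, spec@procurvSD),
      torsion = stats::rnorm(spec@n, 0, spec@torsionSD),
      condyle_width = stats::rnorm(spec@n, 0, spec@condyleWidthSD),
      stringsAsFactors = FALSE)
  })
  meshes <- vector("list", spec@n)
  landmarks <- vector("list", spec@n)
  for (i in seq_len(spec@n)) {
    g <- generateBone(spec@bone, spec@baseDimensions, latent[i, ],
                      spec@meshSpacing, side = side, id = latent$id[i])
    meshes[[i]] <- g$mesh
    landmarks[[i]] <- g$landmarks
  }
  names(meshes) <- names(landmarks) <- latent$id
  out <- list(meshes = meshes, landmarks = landmarks, latent = latent,
              spec = spec)
  if (!is.null(dir)) writePopulation(out, dir)
  out
}

withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

writePopulation <- function(pop, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(pop$meshes)) {
    writeMesh(pop$meshes[[id]], file.path(dir, paste0(id, ".ply")))
    writeLandmarks(pop$landmarks[[id]],
                   file.path(dir, paste0(id, "_landmarks.json")))
  }
  utils::write.csv(pop$latent, file.path(dir, "latent.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read / write a landmark document
#'
#' Landmarks are stored as a JSON object mapping names to either a 3-D
#' point (length-3 numeric, mm, same space as the mesh) or a patch
#' (vector of 1-based vertex indices).  The schema is validated on read.
#'
#' @param landmarks named list of points and index patches.
#' @param path JSON file path.
#' @export
writeLandmarks <- function(landmarks, path) {
  jsonlite::write_json(landmarks, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname writeLandmarks
#' @export
readLandmarks <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path)
  lm <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(lm) || is.null(names(lm)) || any(names(lm) == ""))
    stop("landmark file must be a JSON object of named entries: ", path)
  for (nm in names(lm)) {
    v <- lm[[nm]]
    if (!is.numeric(v) || length(v) < 1 || any(!is.finite(v)))
      stop("landmark '", nm, "' must be numeric (a 3-D point or an index",
           " patch): ", path)
    if (grepl("patch$", nm)) lm[[nm]] <- as.integer(v)
  }
  lm
}

#' Voxelize a mesh into a CT-like volume
#'
#' Marks voxels whose centre lies inside the closed surface (vertical-ray
#' parity test) with the `inside` intensity, others with `outside`.  The
#' default 1000/0 intensities make the standard bone threshold of 350
#' meaningful on synthetic volumes.
#'
#' @param mesh a watertight [TriangleMesh-class].
#' @param spacing voxel size, mm (scalar or length-3).
#' @param pad margin, in voxels, around the mesh bounding box.
#' @param inside,outside intensities.
#' @return A [VoxelVolume-class].
#' @export
voxelizeMesh <- function(mesh, spacing = 1, pad = 3L, inside = 1000,
                         outside = 0) {
  stopifnot(is(mesh, "TriangleMesh"))
  if (any(spacing <= 0) || any(!is.finite(spacing)))
    stop("'spacing' must be positive and finite")
  spacing <- rep(as.numeric(spacing), length.out = 3)
  pad <- as.integer(pad)
  bb <- apply(mesh@vertices, 2, range)
  origin <- bb[1, ] - pad * spacing
  dims <- as.integer(ceiling((bb[2, ] - origin) / spacing)) + pad + 1L
  insideMask <- .voxelizeParity(mesh@vertices, mesh@faces, dims, spacing,
                                origin)
  arr <- array(ifelse(insideMask, inside, outside), dims)
  voxelVolume(arr, spacing = spacing, origin = origin)
}

# ---- declarative group fixtures ---------------------------------------

groupFixtureTable <- function() {
  data.frame(
    name = c("complete_femur_group_1", "complete_femur_group_2",
             "complete_femur_group_3", "complete_femur_group_4",
             "complete_femur_group_5", "complete_femur_group_6",
             "femur_condyles", "femoral_head", "tibia", "tibia_plateau",
             "patella"),
    n = c(61L, 21L, 18L, 22L, 18L, 13L, 61L, 61L, 30L, 72L, 85L),
    bone = c(rep("complete_femur", 6), "femur_condyles", "femoral_head",
             "tibia", "tibia_plateau", "patella"),
    bands = c("mixed", "small", "medium", "large", "chondro", "retriever",
              "mixed", "mixed", "mixed", "mixed", "mixed"),
    stringsAsFactors = FALSE)
}

# weight band -> base shaft length (mm); a fixture convention, not a
# biological claim
bandBaseLength <- function(band, bone) {
  len <- switch(band, small = 110, medium = 150, large = 190,
                chondro = 120, retriever = 185)
  if (bone %in% c("tibia", "tibia_plateau")) len * 0.85 else len
}

#' Generate a study-group-sized synthetic population
#'
#' Emulates the composition of the canine hind-limb study groups: the
#' complete-femur groups partition 61 femora into weight bands of 21
#' (0-10 kg), 18 (10-25 kg) and 22 (>25 kg) cases plus chondrodystrophic
#' (18) and retriever (13) breed groups; partial-femur groups reuse the
#' 61-femur composition, and the tibia, tibia-plateau and patella groups
#' hold 30, 72 and 85 cases.  Weight bands map to base bone lengths
#' (110/150/190 mm shaft for small/medium/large) and every specimen draws
#' its latent factors within-band.
#'
#' @param group group name, one of
#'   `complete_femur_group_1` ... `complete_femur_group_6`,
#'   `femur_condyles`, `femoral_head`, `tibia`, `tibia_plateau`,
#'   `patella`.
#' @param seed RNG seed.
#' @param side side tag.
#' @param mesh_spacing iso-surfacing grid spacing, mm.
#' @return As [generateBonePopulation()], plus a `group` ([GroupSpec-class])
#'   element.
#' @export
makeGroupFixture <- function(group, seed = 1, side = "left",
                             mesh_spacing = 1.5) {
  tab <- groupFixtureTable()
  row <- tab[tab$name == group, ]
  if (nrow(row) == 0)
    stop("unknown group '", group, "'; available: ",
         paste(tab$name, collapse = ", "))
  bone_kind <- switch(row$bone,
    complete_femur = "femur", femur_condyles = "femur",
    femoral_head = "femur", tibia = "tibia", tibia_plateau = "tibia",
    patella = "patella")
  n <- row$n
  res <- withLocalSeed(seed, {
    bands <- if (row$bands == "mixed") {
      sample(rep(c("small", "medium", "large"),
                 times = c(21, 18, 22)), n, replace = n > 61)
    } else rep(row$bands, n)
    lat <- data.frame(
      id = sprintf("%s_%03d", group, seq_len(n)),
      band = bands,
      scale = stats::rnorm(n, 0, 0.05),
      varus = stats::rnorm(n, 0, 1.5),
      procurv = stats::rnorm(n, 0, if (row$bands == "chondro") 2.5 else 1.0),
      torsion = stats::rnorm(n, 0, 1.5),
      condyle_width = stats::rnorm(n, 0, 0.03),
      stringsAsFactors = FALSE)
    lat
  })
  meshes <- vector("list", n)
  landmarks <- vector("list", n)
  for (i in seq_len(n)) {
    len <- bandBaseLength(res$band[i], row$bone)
    base <- switch(bone_kind,
      femur = femurBaseDimensions(len),
      tibia = tibiaBaseDimensions(len),
      patella = patellaBaseDimensions(28 * len / 180))
    g <- generateBone(bone_kind, base, res[i, ], mesh_spacing, side = side,
                      id = res$id[i])
    meshes[[i]] <- g$mesh
    landmarks[[i]] <- g$landmarks
  }
  names(meshes) <- names(landmarks) <- res$id
  gs <- new("GroupSpec", name = group, bone = row$bone, side = side)
  list(meshes = meshes, landmarks = landmarks, latent = res, group = gs)
}
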