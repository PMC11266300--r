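# ---- anatomical alignment helpers -------------------------------------

#' Align a specimen using its landmark document
#'
#' Dispatches on bone kind: femora get the condylar-sphere frame
#' ([buildFemoralFrame()]); tibiae a frame from the anatomical axis and the
#' cranial tuberosity direction; patellae (no elongation, no reliable
#' landmarks) an inertial frame from the principal axes of their vertices.
#'
#' @param mesh a [TriangleMesh-class].
#' @param landmarks named list of landmark points / patches (see
#'   [readLandmarks()]).
#' @param bone bone kind (`"femur"`, `"tibia"`, `"patella"` or one of the
#'   group bone codes).
#' @param side `"left"` or `"right"`.
#' @return list with `mesh` (aligned), `frame`, and for femora `spheres`
#'   (medial/lateral/union condylar and head [Sphere-class] fits, in
#'   aligned coordinates).
#' @export
alignSpecimen <- function(mesh, landmarks, bone, side = "left") {
  kind <- switch(bone,
    complete_femur = , femur_condyles = , femoral_head = , femur = "femur",
    tibia_plateau = , tibia = "tibia",
    patella = "patella",
    stop("unknown bone '", bone, "'"))
  v <- mesh@vertices
  if (kind == "femur") {
    need <- c("condyle_medial_patch", "condyle_lateral_patch",
              "shaft_proximal_point", "shaft_distal_point")
    miss <- setdiff(need, names(landmarks))
    if (length(miss))
      stop("missing landmarks for femoral frame: ", paste(miss, collapse = ", "))
    med <- fitSphere(v[landmarks$condyle_medial_patch, , drop = FALSE])
    lat <- fitSphere(v[landmarks$condyle_lateral_patch, , drop = FALSE])
    hint <- landmarks$shaft_proximal_point - landmarks$shaft_distal_point
    axis <- estimateAnatomicalAxis(mesh, proximal_hint = hint)
    frame <- buildFemoralFrame(med, lat, axis, side)
    aligned <- alignToFrame(mesh, frame)
    va <- aligned@vertices
    tp <- function(s) new("Sphere",
                          center = as.numeric(transformPoints(s@center, frame)),
                          radius = s@radius, rms = s@rms)
    spheres <- list(condyle_med = tp(med), condyle_lat = tp(lat))
    both <- c(landmarks$condyle_medial_patch, landmarks$condyle_lateral_patch)
    spheres$condyle_union <- fitSphere(va[both, , drop = FALSE])
    if (!is.null(landmarks$head_patch))
      spheres$head <- fitSphere(va[landmarks$head_patch, , drop = FALSE])
    list(mesh = aligned, frame = frame, spheres = spheres)
  } else if (kind == "tibia") {
    need <- c("shaft_proximal_point", "shaft_distal_point",
              "tuberosity_distal_point")
    miss <- setdiff(need, names(landmarks))
    if (length(miss))
      stop("missing landmarks for tibial frame: ", paste(miss, collapse = ", "))
    hint <- landmarks$shaft_proximal_point - landmarks$shaft_distal_point
    axis <- estimateAnatomicalAxis(mesh, proximal_hint = hint)
    cen <- colMeans(v)
    x_raw <- landmarks$tuberosity_distal_point - cen
    z_hint <- c(x_raw[2] * axis[3] - x_raw[3] * axis[2],
                x_raw[3] * axis[1] - x_raw[1] * axis[3],
                x_raw[1] * axis[2] - x_raw[2] * axis[1])
    frame <- makeFrame(cen, axis, z_hint, side = side)
    aligned <- alignToFrame(mesh, frame)
    list(mesh = aligned, frame = frame,
         tuberosity = as.numeric(transformPoints(
           landmarks$tuberosity_distal_point, frame)))
  } else {
    frame <- buildInertialFrame(mesh, side = side)
    list(mesh = alignToFrame(mesh, frame), frame = frame)
  }
}

#' Inertial (principal-axes) frame
#'
#' Frame from the eigenvectors of the vertex covariance: Y along the
#' largest principal axis, Z along the second.  Axis signs are fixed
#' deterministically by the third central moment of the vertex projections
#' (falling back to the largest-magnitude component when the distribution
#' is symmetric), and the triple is completed right-handed.
#'
#' @param mesh a [TriangleMesh-class].
#' @param side optional side tag.
#' @return An [AnatomicalFrame-class].
#' @export
buildInertialFrame <- function(mesh, side = NULL) {
  v <- mesh@vertices
  cen <- colMeans(v)
  vc <- sweep(v, 2, cen)
  eg <- eigen(crossprod(vc) / nrow(vc), symmetric = TRUE)
  fixSign <- function(a) {
    proj <- as.numeric(vc %*% a)
    skew <- mean(proj^3)
    if (abs(skew) > 1e-8 * max(abs(proj))^3) {
      if (skew < 0) a <- -a
    } else if (a[which.max(abs(a))] < 0) a <- -a
    a
  }
  y <- fixSign(eg$vectors[, 1])
  z <- fixSign(eg$vectors[, 2])
  makeFrame(cen, y, z, side = side)
}

# ---- pipeline configuration -------------------------------------------

#' Validate a pipeline configuration
#'
#' Configurations are named lists (or JSON files) with keys `seed`,
#' `output_dir`, `parameters` (threshold, kernel_mm, target_edge, nn_mode,
#' n_modes, mesh_spacing), `groups` (each with `name` and `side`) and an
#' optional `manifest` of specimen records (`id`, `mesh`, `landmarks`,
#' `group`, `side`).  Unknown keys are rejected and every referenced path
#' must exist.
#'
#' @param config named list or path to a JSON configuration.
#' @return the validated config (with defaults filled in), invisibly
#'   usable by [runPipeline()].
#' @export
validatePipelineConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE,
                                  simplifyMatrix = FALSE)
  }
  known <- c("seed", "output_dir", "parameters", "groups", "manifest")
  extra <- setdiff(names(config), known)
  if (length(extra))
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "))
  if (is.null(config$groups) || !length(config$groups))
    stop("configuration must list at least one group")
  par_known <- c("threshold", "kernel_mm", "target_edge", "nn_mode",
                 "n_modes", "mesh_spacing")
  par <- config$parameters
  if (!is.null(par)) {
    extra <- setdiff(names(par), par_known)
    if (length(extra))
      stop("unknown parameter key(s): ", paste(extra, collapse = ", "))
  }
  defaults <- list(threshold = 350, kernel_mm = 3.0, target_edge = 2.0,
                   nn_mode = "vertex", n_modes = 5, mesh_spacing = 1.5)
  config$parameters <- utils::modifyList(defaults, as.list(par))
  if (is.null(config$seed)) config$seed <- 1L
  for (g in config$groups) {
    if (is.null(g$name) || is.null(g$side))
      stop("every group needs 'name' and 'side'")
    if (!g$side %in% c("left", "right"))
      stop("group side must be 'left' or 'right'")
  }
  if (!is.null(config$manifest)) {
    for (rec in config$manifest) {
      for (key in c("id", "mesh", "landmarks", "group", "side"))
        if (is.null(rec[[key]]))
          stop("manifest records need id, mesh, landmarks, group, side")
      for (p in c(rec$mesh, rec$landmarks))
        if (!file.exists(p)) stop("manifest path does not exist: ", p)
    }
  }
  invisible(config)
}

# ---- pipeline ----------------------------------------------------------

#' Run the shape-modelling pipeline
#'
#' For every configured (group, side): load or synthesise the specimens,
#' align each to its anatomical frame, cut partial-bone regions where the
#' group calls for one, select and remesh the median template, build the
#' corresponded set by nearest-neighbour registration, fit the PCA shape
#' model, and write the variance table (CSV), the mean and +/-3 SD mode
#' meshes for the first `n_modes` modes (PLY), and a per-specimen QC log.
#' Deterministic for a fixed configuration and seed.
#'
#' @param config configuration list or JSON path, see
#'   [validatePipelineConfig()].
#' @param output_dir overrides the config's `output_dir`.
#' @return invisibly, a named list per group with elements `model`,
#'   `set`, `table` and `dir`.
#' @export
runPipeline <- function(config, output_dir = NULL) {
  config <- validatePipelineConfig(config)
  if (!is.null(output_dir)) config$output_dir <- output_dir
  if (is.null(config$output_dir))
    stop("an output directory is required (config$output_dir or output_dir)")
  par <- config$parameters
  results <- list()
  for (gi in seq_along(config$groups)) {
    g <- config$groups[[gi]]
    label <- paste0(g$name, "_", g$side)
    gdir <- file.path(config$output_dir, label)
    dir.create(gdir, recursive = TRUE, showWarnings = FALSE)

    if (!is.null(config$manifest)) {
      recs <- Filter(function(r) r$group == g$name && r$side == g$side,
                     config$manifest)
      if (!length(recs)) stop("no manifest records for group ", label)
      meshes <- lapply(recs, function(r) readMesh(r$mesh))
      landmarks <- lapply(recs, function(r) readLandmarks(r$landmarks))
      ids <- vapply(recs, `[[`, "", "id")
      names(meshes) <- names(landmarks) <- ids
      bone <- g$name
      fix <- list(meshes = meshes, landmarks = landmarks)
      bone_code <- if (!is.null(g$bone)) g$bone else g$name
    } else {
      fix <- makeGroupFixture(g$name, seed = config$seed + gi,
                              side = g$side, mesh_spacing = par$mesh_spacing)
      bone_code <- fix$group@bone
    }
    if (length(fix$meshes) < 2)
      stop("group ", label, " has fewer than 2 specimens; a shape model ",
           "needs K >= 2")

    aligned <- vector("list", length(fix$meshes))
    cutinfo <- vector("list", length(fix$meshes))
    for (i in seq_along(fix$meshes)) {
      al <- alignSpecimen(fix$meshes[[i]], fix$landmarks[[i]], bone_code,
                          side = g$side)
      aligned[[i]] <- al$mesh
      cutinfo[[i]] <- al
    }
    names(aligned) <- names(fix$meshes)

    cutFun <- switch(bone_code,
      femur_condyles = function(m, info)
        cutPartialFemur(m, "distal", info$spheres$condyle_union),
      femoral_head = function(m, info)
        cutPartialFemur(m, "proximal", info$spheres$head),
      tibia_plateau = function(m, info)
        cutPartialTibia(m, info$tuberosity),
      NULL)

    if (is.null(cutFun)) {
      shapes <- aligned
      tmpl_idx <- selectTemplate(shapes)
      set <- buildCorrespondedSet(shapes, template_index = tmpl_idx,
                                  target_edge = par$target_edge,
                                  mode = par$nn_mode)
    } else {
      shapes <- Map(cutFun, aligned, cutinfo)
      tmpl_idx <- selectTemplate(shapes)
      # remesh the template's complete bone, then cut, so the remesher
      # only ever sees a closed surface
      tmpl_full <- remeshUniform(aligned[[tmpl_idx]], par$target_edge)
      tmpl <- cutFun(tmpl_full, cutinfo[[tmpl_idx]])
      shapes[[tmpl_idx]] <- tmpl
      set <- buildCorrespondedSet(shapes, template_index = tmpl_idx,
                                  target_edge = par$target_edge,
                                  mode = par$nn_mode,
                                  remesh_template = FALSE)
    }

    model <- buildSSM(set)
    tab <- varianceTable(model, n_modes = par$n_modes)
    exportVarianceTable(stats::setNames(list(tab), label),
                        file.path(gdir, "variance.csv"))
    writeMesh(meanShape(model), file.path(gdir, "mean.ply"))
    for (m in seq_len(min(par$n_modes, length(model@eigenvalues)))) {
      writeMesh(sampleMode(model, m, 3),
                file.path(gdir, sprintf("mode%d_plus3sd.ply", m)))
      writeMesh(sampleMode(model, m, -3),
                file.path(gdir, sprintf("mode%d_minus3sd.ply", m)))
    }
    qc <- set@qc
    qc$stage <- "correspondence"
    utils::write.csv(qc, file.path(gdir, "qc.csv"), row.names = FALSE)
    saveShapeModel(model, file.path(gdir, "model"),
                   metadata = list(group = g$name, side = g$side,
                                   bone = bone_code,
                                   K = nShapes(set),
                                   P = nVertices(set@template)))
    results[[label]] <- list(model = model, set = set, table = tab,
                             dir = gdir)
  }
  invisible(results)
}

#' Export variance tables as CSV
#'
#' One row per mode with paired A (per-mode percent) and B (cumulative
#' percent) columns per table, at 3 significant figures and in stable
#' column order; the layout used to report model compactness per group
#' and side.
#'
#' @param tables named list of [VarianceTable-class] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
exportVarianceTable <- function(tables, path) {
  if (!length(tables)) {
    utils::write.csv(data.frame(Mode = integer(0)), path, row.names = FALSE)
    return(invisible(path))
  }
  if (is.null(names(tables)) || any(names(tables) == ""))
    stop("'tables' must be a named list")
  nmax <- max(vapply(tables, function(t) length(t@percent), 1L))
  out <- data.frame(Mode = seq_len(nmax))
  for (nm in names(tables)) {
    t <- tables[[nm]]
    A <- B <- rep(NA_real_, nmax)
    A[seq_along(t@percent)] <- signif(t@percent, 3)
    B[seq_along(t@cumulative)] <- signif(t@cumulative, 3)
    out[[paste0(nm, "_A")]] <- A
    out[[paste0(nm, "_B")]] <- B
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Save / load a shape model archive
#'
#' A portable plain-text archive: `mean.ply` (mean mesh on the template
#' connectivity), `eigenvalues.csv`, `modes.csv` (3P x M) and
#' `metadata.json`.
#'
#' @param model a [ShapeModel-class].
#' @param dir archive directory (created).
#' @param metadata named list stored alongside (group, side, bone, ...).
#' @return `dir` (or the restored [ShapeModel-class] for
#'   `readShapeModel`).
#' @export
saveShapeModel <- function(model, dir, metadata = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeMesh(meanShape(model), file.path(dir, "mean.ply"))
  utils::write.csv(data.frame(eigenvalue = model@eigenvalues),
                   file.path(dir, "eigenvalues.csv"), row.names = FALSE)
  utils::write.table(model@modes, file.path(dir, "modes.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  metadata$n_training <- model@nTraining
  jsonlite::write_json(metadata, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname saveShapeModel
#' @export
readShapeModel <- function(dir) {
  mean_mesh <- readMesh(file.path(dir, "mean.ply"))
  eig <- utils::read.csv(file.path(dir, "eigenvalues.csv"))$eigenvalue
  modes <- as.matrix(utils::read.csv(file.path(dir, "modes.csv"),
                                     header = FALSE))
  dimnames(modes) <- NULL
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  new("ShapeModel", meanVector = flattenShape(mean_mesh@vertices),
      modes = modes, eigenvalues = eig,
      nTraining = as.integer(meta$n_training), template = mean_mesh)
}

# ---- reference variance tables ----------------------------------------

#' Reference variance-explained tables
#'
#' The published per-mode (A) and cumulative (B) percentages for the
#' canine hind-limb shape-model groups (complete femur groups 1-6, femur
#' condyles, femoral head, tibia, tibia plateau and patella, each side
#' separately), shipped as printed -- i.e. rounded to 3 significant
#' figures -- for arithmetic consistency checking.  Values are kept as
#' strings so the printed precision of each cell is preserved.
#'
#' @return data.frame with columns `table`, `group`, `side`, `mode`,
#'   `A`, `B` (A and B as printed strings).
#' @export
referenceVarianceTables <- function() {
  path <- system.file("extdata", "reference_variance_tables.csv",
                      package = "ossm", mustWork = TRUE)
  utils::read.csv(path, colClasses = c(mode = "integer", A = "character",
                                       B = "character"))
}

decimalsOf <- function(s) {
  ifelse(grepl("\\.", s), nchar(sub("^[^.]*\\.", "", s)), 0L)
}

#' Cumulative-column consistency of the reference tables
#'
#' Recomputes the cumulative column B from the printed per-mode column A
#' and compares with the printed B at each cell's printed precision.
#' Because the printed A values are themselves rounded, the recomputed
#' cumulative can differ from the printed cell by up to the accumulated
#' rounding slack; the per-cell `bound` column gives that propagated
#' half-ulp budget.
#'
#' @return data.frame with one row per cell: recomputed B, printed B,
#'   absolute deviation, ulp of the printed cell and the propagated
#'   rounding bound.
#' @export
checkCumulativeConsistency <- function() {
  tab <- referenceVarianceTables()
  out <- do.call(rbind, lapply(
    split(tab, list(tab$group, tab$side), drop = TRUE), function(d) {
      d <- d[order(d$mode), ]
      A <- as.numeric(d$A)
      B_printed <- as.numeric(d$B)
      B_recomputed <- cumsum(A)
      ulpA <- 10^(-decimalsOf(d$A))
      ulpB <- 10^(-decimalsOf(d$B))
      data.frame(group = d$group, side = d$side, mode = d$mode,
                 B_recomputed = B_recomputed, B_printed = B_printed,
                 deviation = abs(B_recomputed - B_printed),
                 ulp = ulpB,
                 bound = cumsum(ulpA) / 2 + ulpB / 2)
    }))
  rownames(out) <- NULL
  out
}
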