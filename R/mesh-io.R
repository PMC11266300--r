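#' Read a triangle mesh from STL, PLY or OBJ
#'
#' Binary and ascii STL and PLY are auto-detected.  Duplicate vertices are
#' merged within a 1e-6 mm tolerance (STL stores per-facet vertices, so
#' merging reconstructs connectivity).  Face indices are validated against
#' the vertex count and degenerate faces rejected.
#'
#' @param path file path.
#' @param format `"stl"`, `"ply"`, `"obj"` or `"auto"` (from the extension).
#' @param mergeTolerance vertex merge tolerance in mm.
#' @return A [TriangleMesh-class].
#' @export
readMesh <- function(path, format = c("auto", "stl", "ply", "obj"),
                     mergeTolerance = 1e-6) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("stl", "ply", "obj"))
      stop("unknown mesh format '", ext, "' for ", path)
    format <- ext
  }
  mesh <- switch(format,
    stl = readSTL(path, mergeTolerance),
    ply = readPLY(path),
    obj = readOBJ(path))
  validObject(mesh)
  mesh@name <- sub("\\.[^.]*$", "", basename(path))
  mesh
}

#' Write a triangle mesh to STL, PLY or OBJ
#'
#' Output is deterministic for a fixed input.  PLY and STL can be written
#' in `binary` (default) or `ascii` flavours; OBJ is always ascii.
#'
#' @param mesh a [TriangleMesh-class] with at least one face.
#' @param path output file path.
#' @param format `"stl"`, `"ply"`, `"obj"` or `"auto"` (from the extension).
#' @param binary write the binary flavour where the format has one.
#' @return `path`, invisibly.
#' @export
writeMesh <- function(mesh, path, format = c("auto", "stl", "ply", "obj"),
                      binary = TRUE) {
  stopifnot(is(mesh, "TriangleMesh"))
  if (nVertices(mesh) == 0 || nFaces(mesh) == 0)
    stop("refusing to write an empty mesh")
  validObject(mesh)
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("stl", "ply", "obj"))
      stop("unknown mesh format '", ext, "' for ", path)
    format <- ext
  }
  switch(format,
    stl = writeSTL(mesh, path, binary),
    ply = writePLY(mesh, path, binary),
    obj = writeOBJ(mesh, path))
  invisible(path)
}

# ---- STL ----

readSTL <- function(path, tol) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 80)
  sz <- file.info(path)$size
  ntri_guess <- readBin(con, "integer", 1, size = 4, endian = "little")
  is_binary <- !is.na(ntri_guess) && sz == 84 + 50 * as.numeric(ntri_guess)
  if (is_binary) {
    tri <- matrix(0, ntri_guess * 3, 3)
    for (i in seq_len(ntri_guess)) {
      rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
      readBin(con, "raw", 2)
      tri[(i - 1) * 3 + 1:3, ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    }
  } else {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (!length(vl)) stop("corrupt STL: no vertex records in ", path)
    nums <- lapply(strsplit(trimws(vl), "\\s+"), function(x) as.numeric(x[2:4]))
    tri <- do.call(rbind, nums)
    if (nrow(tri) %% 3 != 0)
      stop("corrupt STL: vertex count not a multiple of 3 in ", path)
    if (any(!is.finite(tri))) stop("corrupt STL: non-numeric vertex in ", path)
  }
  mergeVertexSoup(tri, tol)
}

mergeVertexSoup <- function(tri, tol) {
  key <- apply(round(tri / tol), 1, paste, collapse = "_")
  uid <- !duplicated(key)
  verts <- tri[uid, , drop = FALSE]
  remap <- match(key, key[uid])
  faces <- matrix(remap, ncol = 3, byrow = TRUE)
  degen <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
    faces[, 1] == faces[, 3]
  triangleMesh(verts, faces[!degen, , drop = FALSE])
}

writeSTL <- function(mesh, path, binary) {
  v <- mesh@vertices
  f <- mesh@faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(n^2))
  n <- n / pmax(len, 1e-300)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      rec <- c(n[i, ], t(v[f[i, ], ]))
      writeBin(as.numeric(rec), con, size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mesh", con)
    for (i in seq_len(nrow(f))) {
      writeLines(sprintf("facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2],
                         n[i, 3]), con)
      writeLines("  outer loop", con)
      for (k in 1:3)
        writeLines(sprintf("    vertex %.9g %.9g %.9g", v[f[i, k], 1],
                           v[f[i, k], 2], v[f[i, k], 3]), con)
      writeLines("  endloop", con)
      writeLines("endfacet", con)
    }
    writeLines("endsolid mesh", con)
  }
}

# ---- PLY ----

readPLY <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header is ascii whatever the body encoding
  header <- character()
  repeat {
    line <- readAsciiLine(con)
    if (is.null(line)) stop("corrupt PLY: unterminated header in ", path)
    header <- c(header, line)
    if (line == "end_header") break
  }
  if (!grepl("^ply", header[1])) stop("corrupt PLY: missing magic in ", path)
  fmt_line <- grep("^format ", header, value = TRUE)[1]
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format '", fmt, "' in ", path)
  elements <- list()
  cur <- NULL
  for (line in header) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list")
        cur$props[[length(cur$props) + 1]] <-
          list(name = tok[5], list = TRUE, count_type = tok[3], type = tok[4])
      else
        cur$props[[length(cur$props) + 1]] <-
          list(name = tok[3], list = FALSE, type = tok[2])
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex) || is.null(elements$face))
    stop("corrupt PLY: vertex/face elements missing in ", path)

  if (fmt == "ascii") {
    body <- readLines(con, warn = FALSE)
    body <- body[nzchar(trimws(body))]
    nv <- elements$vertex$count
    nf <- elements$face$count
    if (length(body) < nv + nf) stop("corrupt PLY: truncated body in ", path)
    vprops <- vapply(elements$vertex$props, `[[`, "", "name")
    vtab <- do.call(rbind,
      lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"), as.numeric))
    xyz <- match(c("x", "y", "z"), vprops)
    if (any(is.na(xyz))) stop("corrupt PLY: vertex x/y/z properties missing")
    verts <- vtab[, xyz, drop = FALSE]
    faces <- lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"),
                    function(x) {
      n <- as.integer(x[1])
      if (n != 3) stop("only triangular PLY faces are supported")
      as.integer(x[2:4]) + 1L
    })
    faces <- do.call(rbind, faces)
  } else {
    sizes <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1, short = 2,
               ushort = 2, int16 = 2, uint16 = 2, int = 4, uint = 4,
               int32 = 4, uint32 = 4, float = 4, float32 = 4, double = 8,
               float64 = 8)
    readScalar <- function(type) {
      sz <- sizes[[type]]
      if (type %in% c("float", "float32", "double", "float64"))
        readBin(con, "numeric", 1, size = sz, endian = "little")
      else
        readBin(con, "integer", 1, size = sz, endian = "little",
                signed = !(sz < 4 && grepl("^u", type)))
    }
    nv <- elements$vertex$count
    verts <- matrix(0, nv, 3)
    vprops <- elements$vertex$props
    pn <- vapply(vprops, `[[`, "", "name")
    for (i in seq_len(nv)) {
      for (p in seq_along(vprops)) {
        val <- readScalar(vprops[[p]]$type)
        j <- match(pn[p], c("x", "y", "z"))
        if (!is.na(j)) verts[i, j] <- val
      }
    }
    nf <- elements$face$count
    faces <- matrix(0L, nf, 3)
    fprop <- elements$face$props[[1]]
    for (i in seq_len(nf)) {
      cnt <- readScalar(fprop$count_type)
      if (cnt != 3) stop("only triangular PLY faces are supported")
      faces[i, ] <- c(readScalar(fprop$type), readScalar(fprop$type),
                      readScalar(fprop$type)) + 1L
    }
  }
  triangleMesh(verts, faces)
}

readAsciiLine <- function(con) {
  chars <- character()
  repeat {
    b <- readBin(con, "raw", 1)
    if (length(b) == 0) return(NULL)
    if (b == as.raw(10)) break
    if (b != as.raw(13)) chars <- c(chars, rawToChar(b))
  }
  paste(chars, collapse = "")
}

writePLY <- function(mesh, path, binary) {
  v <- mesh@vertices
  f <- mesh@faces - 1L
  fmt <- if (binary) "binary_little_endian" else "ascii"
  header <- c("ply", paste("format", fmt, "1.0"),
              paste("element vertex", nrow(v)),
              "property float x", "property float y", "property float z",
              paste("element face", nrow(f)),
              "property list uchar int vertex_indices", "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(paste0(paste(header, collapse = "\n"), "\n")), con)
    writeBin(as.numeric(t(v)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.raw(3), con)
      writeBin(as.integer(f[i, ]), con, size = 4, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  }
}

# ---- OBJ ----

readOBJ <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- txt[startsWith(txt, "v ")]
  fl <- txt[startsWith(txt, "f ")]
  if (!length(vl) || !length(fl))
    stop("corrupt OBJ: missing vertex or face records in ", path)
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                 function(x) as.numeric(x[2:4])))
  faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(x) {
    idx <- vapply(x[-1], function(tok)
      as.integer(strsplit(tok, "/")[[1]][1]), 1L)
    if (length(idx) != 3) stop("only triangular OBJ faces are supported")
    idx
  }))
  triangleMesh(verts, faces)
}

writeOBJ <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh@vertices
  f <- mesh@faces
  writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
}
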