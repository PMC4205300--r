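#' Triangulated surface mesh
#'
#' Construct a `surface_mesh`: a triangulated 3D surface with vertex
#' coordinates in millimetres. Faces are stored as 1-based vertex-index
#' triples. This is the container used for templates, synthetic face
#' populations and dense-correspondence meshes throughout the package.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates (mm).
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @param normals optional numeric matrix, n x 3, per-vertex outward normals.
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, normals = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range (1-based)")
  }
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    storage.mode(normals) <- "double"
    if (!all(dim(normals) == dim(vertices)))
      stop("normals must match vertices in dimension")
  }
  structure(list(vertices = vertices, faces = faces, normals = normals),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (is.null(x$normals)) "" else ", with normals"))
  invisible(x)
}

#' Number of vertices / faces of a mesh
#' @param mesh a `surface_mesh`.
#' @return integer count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

# area-weighted per-vertex normals from face winding
#' Per-vertex outward normals
#'
#' Area-weighted average of incident face normals, normalised to unit length.
#' Orientation follows the face winding (counter-clockwise seen from outside).
#'
#' @param mesh a `surface_mesh`.
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  e1 <- p2 - p1; e2 <- p3 - p1
  # cross product rows; magnitude = 2 * face area, so summing weights by area
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nv <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    idx <- f[, k]
    nv[, 1] <- nv[, 1] + tapply_add(fn[, 1], idx, nrow(v))
    nv[, 2] <- nv[, 2] + tapply_add(fn[, 2], idx, nrow(v))
    nv[, 3] <- nv[, 3] + tapply_add(fn[, 3], idx, nrow(v))
  }
  len <- sqrt(rowSums(nv^2))
  len[len == 0] <- 1
  nv / len
}

tapply_add <- function(values, idx, n) {
  out <- numeric(n)
  s <- rowsum(values, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' Unique undirected edges of a mesh
#' @param mesh a `surface_mesh`.
#' @return integer matrix, e x 2, with `edge[,1] < edge[,2]`.
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  storage.mode(e) <- "integer"
  e
}

#' Mean edge length of a mesh (mm)
#' @param mesh a `surface_mesh`.
#' @return scalar mean length over unique edges.
#' @export
mean_edge_length <- function(mesh) {
  e <- mesh_edges(mesh)
  d <- mesh$vertices[e[, 1], , drop = FALSE] - mesh$vertices[e[, 2], , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

#' Read a surface mesh from PLY (ASCII) or OBJ
#'
#' Formats are recognised by file extension. Face indices are converted to
#' the package's 1-based internal convention regardless of the on-disk
#' dialect (OBJ is 1-based, PLY 0-based).
#'
#' @param path file path ending in `.ply` or `.obj`.
#' @return a `surface_mesh`.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = read_ply(path),
         obj = read_obj(path),
         stop("unsupported mesh format '.", ext, "' (use .ply or .obj)"))
}

#' Write a surface mesh to PLY (ASCII) or OBJ
#' @param mesh a `surface_mesh`.
#' @param path output path ending in `.ply` or `.obj`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = write_ply(mesh, path),
         obj = write_obj(mesh, path),
         stop("unsupported mesh format '.", ext, "' (use .ply or .obj)"))
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("parse error in ", path, ": empty file")
  vlines <- grep("^v([[:space:]])", lines, value = TRUE)
  flines <- grep("^f([[:space:]])", lines, value = TRUE)
  if (length(vlines) == 0) stop("parse error in ", path, ": no vertex lines")
  vs <- t(vapply(strsplit(trimws(sub("^v", "", vlines)), "[[:space:]]+"),
                 function(x) as.numeric(x[1:3]), numeric(3)))
  if (anyNA(vs)) stop("parse error in ", path, ": non-numeric vertex coordinate")
  fs <- t(vapply(strsplit(trimws(sub("^f", "", flines)), "[[:space:]]+"),
                 function(x) as.integer(sub("/.*$", "", x[1:3])), integer(3)))
  if (anyNA(fs)) stop("parse error in ", path, ": malformed face line")
  surface_mesh(vs, fs)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  if (nrow(mesh$faces) > 0)
    writeLines(sprintf("f %d %d %d",
                       mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
  invisible(path)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("parse error in ", path, ": empty file")
  if (trimws(lines[1]) != "ply")
    stop("parse error in ", path, " line 1: missing 'ply' magic")
  hdr_end <- match("end_header", trimws(lines))
  if (is.na(hdr_end)) stop("parse error in ", path, ": no end_header")
  hdr <- trimws(lines[seq_len(hdr_end)])
  fmt <- grep("^format", hdr, value = TRUE)
  if (length(fmt) == 0 || !grepl("ascii", fmt[1]))
    stop("parse error in ", path, ": only ASCII PLY is supported")
  nv <- as.integer(sub("^element vertex ", "", grep("^element vertex ", hdr, value = TRUE)[1]))
  nf <- as.integer(sub("^element face ", "", grep("^element face ", hdr, value = TRUE)[1]))
  if (is.na(nv)) stop("parse error in ", path, ": no vertex element")
  if (is.na(nf)) nf <- 0L
  body <- lines[(hdr_end + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf)
    stop("parse error in ", path, ": expected ", nv + nf, " data rows, found ", length(body))
  vs <- t(vapply(strsplit(trimws(body[seq_len(nv)]), "[[:space:]]+"),
                 function(x) as.numeric(x[1:3]), numeric(3)))
  if (anyNA(vs)) stop("parse error in ", path, ": non-numeric vertex coordinate")
  if (nf > 0) {
    fs <- t(vapply(strsplit(trimws(body[nv + seq_len(nf)]), "[[:space:]]+"),
                   function(x) {
                     if (as.integer(x[1]) != 3L) stop("only triangular faces supported")
                     as.integer(x[2:4])
                   }, integer(3))) + 1L  # PLY is 0-based on disk
  } else {
    fs <- matrix(integer(0), 0, 3)
  }
  surface_mesh(vs, fs)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  if (nrow(mesh$faces) > 0)
    writeLines(sprintf("3 %d %d %d",
                       mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  invisible(path)
}
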