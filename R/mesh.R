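#' Triangle surface mesh
#'
#' Vertices in physical um coordinates and triangular faces as 1-based
#' vertex-index triples (the R-native convention; Wavefront OBJ is also
#' 1-based so indices pass through unchanged on write).
#'
#' @param vertices n x 3 numeric matrix `(x, y, z)` um.
#' @param faces m x 3 integer matrix of vertex indices.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- rbind_matrix3(vertices)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face references vertex outside 1..", nrow(vertices))
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces, enclosed volume %.4g um^3\n",
              nrow(x$vertices), nrow(x$faces), mesh_volume(x)))
  invisible(x)
}

#' Enclosed volume of a closed mesh
#'
#' Signed volume by the divergence theorem (sum of signed tetrahedra against
#' the origin); positive for consistently outward-wound watertight meshes.
#'
#' @param mesh a `surface_mesh`.
#' @return volume in um^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  cross <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
                 b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
                 b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(rowSums(a * cross)) / 6
}

#' Check that every edge is shared by exactly two faces
#' @param mesh a `surface_mesh`.
#' @return `TRUE` if watertight (2-manifold closed), else `FALSE`.
#' @export
mesh_is_watertight <- function(mesh) {
  f <- mesh$faces
  if (!nrow(f)) return(FALSE)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Write a mesh as Wavefront OBJ
#'
#' `v x y z` lines followed by `f i j k` lines with 1-based indices.
#'
#' @param mesh a `surface_mesh`.
#' @param path output path.
#' @export
write_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (nrow(mesh$faces) && max(mesh$faces) > nrow(mesh$vertices))
    stop("face references missing vertex")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.10g %.10g %.10g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d",
                     mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
  invisible(path)
}

#' Read a Wavefront OBJ mesh (v/f subset)
#'
#' Parses `v` and triangular `f` statements; `f` entries of the form
#' `i/j/k` keep only the vertex index. Other statements are ignored.
#'
#' @param path OBJ file path.
#' @return a `surface_mesh`.
#' @export
read_obj <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (!length(vl)) stop("OBJ file has no vertices")
  vparts <- strsplit(trimws(sub("^v", "", vl)), "\\s+")
  verts <- matrix(as.numeric(unlist(lapply(vparts, `[`, 1:3))), ncol = 3, byrow = TRUE)
  faces <- matrix(integer(0), ncol = 3)
  if (length(fl)) {
    fparts <- strsplit(trimws(sub("^f", "", fl)), "\\s+")
    if (any(lengths(fparts) != 3L)) stop("only triangular faces are supported")
    fidx <- vapply(fparts, function(p) as.integer(sub("/.*$", "", p)), integer(3))
    faces <- t(fidx)
  }
  surface_mesh(verts, faces)
}
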