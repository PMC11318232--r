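#' Construct a triangle mesh
#'
#' The container used for the reconstructed stimulus surface: vertex
#' coordinates in model units plus 1-based triangular face indices, with
#' optional per-vertex RGB colour (0-255 integers, as PLY stores it).
#'
#' @param vertices Nx3 numeric matrix of vertex coordinates.
#' @param faces Mx3 integer matrix of 1-based vertex indices.
#' @param color Optional Nx3 integer matrix, per-vertex RGB in 0..255.
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, color = NULL) {
  vertices <- matrix(as.numeric(vertices), ncol = 3,
                     dimnames = list(NULL, c("x", "y", "z")))
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0) {
    if (min(faces) < 1 || max(faces) > nrow(vertices)) {
      stop("face index out of range [1, ", nrow(vertices), "]")
    }
    distinct <- faces[, 1] != faces[, 2] & faces[, 1] != faces[, 3] &
      faces[, 2] != faces[, 3]
    if (!all(distinct)) {
      stop(sum(!distinct), " face(s) reference fewer than 3 distinct vertices")
    }
  }
  if (!is.null(color)) {
    color <- matrix(as.integer(color), ncol = 3)
    stopifnot(nrow(color) == nrow(vertices),
              all(color >= 0), all(color <= 255))
  }
  structure(list(vertices = vertices, faces = faces, color = color),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (is.null(x$color)) "" else ", per-vertex colour"))
  invisible(x)
}

#' @rdname triangle_mesh
#' @param x A `triangle_mesh`.
#' @param ... Unused.
#' @export
n_vertices <- function(x) nrow(x$vertices)

#' @rdname triangle_mesh
#' @export
n_faces <- function(x) nrow(x$faces)

#' Tidy a mesh into a long vertex table
#'
#' @param x A `triangle_mesh`.
#' @param ... Unused.
#' @return A tibble with one row per vertex: `vertex`, `x`, `y`, `z`
#'   (and `r`, `g`, `b` when the mesh carries colour).
#' @method tidy triangle_mesh
#' @export
tidy.triangle_mesh <- function(x, ...) {
  out <- tibble::as_tibble(x$vertices)
  out <- dplyr::mutate(out, vertex = dplyr::row_number(), .before = 1)
  if (!is.null(x$color)) {
    out$r <- x$color[, 1]; out$g <- x$color[, 2]; out$b <- x$color[, 3]
  }
  out
}

# per-face corner coordinate matrices, reused by the intersectors
.face_corners <- function(mesh) {
  list(v0 = mesh$vertices[mesh$faces[, 1], , drop = FALSE],
       v1 = mesh$vertices[mesh$faces[, 2], , drop = FALSE],
       v2 = mesh$vertices[mesh$faces[, 3], , drop = FALSE])
}

# rowwise cross product of Nx3 matrices
.cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}
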