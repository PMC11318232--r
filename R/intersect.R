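# Ray-mesh intersection: Moeller-Trumbore, vectorised over faces, with an
# exhaustive path and an AABB-culled accelerated path that must agree exactly.

# Core Moeller-Trumbore over a subset of faces. geo holds precomputed v0, e1,
# e2 (Mx3). Returns the nearest hit among `idx` or NULL. Ties in t break to
# the lowest face index (idx is always increasing, which.min takes the first).
.mt_hits <- function(origin, direction, geo, idx, t_epsilon, backface_cull) {
  if (length(idx) == 0) return(NULL)
  v0 <- geo$v0[idx, , drop = FALSE]
  e1 <- geo$e1[idx, , drop = FALSE]
  e2 <- geo$e2[idx, , drop = FALSE]
  dmat <- matrix(direction, nrow = length(idx), ncol = 3, byrow = TRUE)
  pvec <- .cross_rows(dmat, e2)
  det <- rowSums(e1 * pvec)
  ok <- if (backface_cull) det > 1e-12 else abs(det) > 1e-12
  if (!any(ok)) return(NULL)
  tvec <- -sweep(v0, 2, origin)          # origin - v0
  bu <- rowSums(tvec * pvec) / det
  qvec <- .cross_rows(tvec, e1)
  bv <- rowSums(dmat * qvec) / det
  tt <- rowSums(e2 * qvec) / det
  bc_eps <- 1e-9
  ok <- ok & bu >= -bc_eps & bv >= -bc_eps & (bu + bv) <= 1 + bc_eps &
    tt > t_epsilon
  if (!any(ok)) return(NULL)
  w <- which(ok)
  best <- w[which.min(tt[w])]
  t_best <- unname(tt[best])
  list(t = t_best,
       point = unname(origin + t_best * direction),
       face_index = idx[best],
       barycentric = unname(c(1 - bu[best] - bv[best], bu[best], bv[best])))
}

.ray_geo <- function(mesh) {
  fc <- .face_corners(mesh)
  list(v0 = fc$v0, e1 = fc$v1 - fc$v0, e2 = fc$v2 - fc$v0)
}

#' Intersect a ray with a single triangle
#'
#' Moeller-Trumbore test against the closed triangle region. Intersections
#' closer than `t_epsilon` along the ray (including behind the origin) are
#' rejected, which suppresses self-hits when a beam starts on a surface.
#'
#' @param ray A `gaze_ray` (see [ray_from_fixation()]) or a list with
#'   `origin` and unit `direction`.
#' @param v0,v1,v2 Triangle corner 3-vectors.
#' @param t_epsilon Minimum accepted ray parameter (model units).
#' @return `NULL` on a miss, otherwise a list with `t`, `point`,
#'   `barycentric` (`b0` at `v0`; components sum to 1).
#' @examples
#' ray <- structure(list(origin = c(0, 0, -1), direction = c(0, 0, 1)),
#'                  class = "gaze_ray")
#' intersect_ray_triangle(ray, c(-1, -1, 0), c(1, -1, 0), c(0, 1, 0))
#' @export
intersect_ray_triangle <- function(ray, v0, v1, v2, t_epsilon = 1e-9) {
  geo <- list(v0 = rbind(v0), e1 = rbind(v1 - v0), e2 = rbind(v2 - v0))
  h <- .mt_hits(ray$origin, ray$direction, geo, 1L, t_epsilon, FALSE)
  if (is.null(h)) return(NULL)
  h$face_index <- NULL
  h
}

#' Intersect a ray with a triangle mesh (nearest hit)
#'
#' Returns the intersection with the smallest ray parameter among all faces,
#' or `NULL` when no face is hit. When `accelerator` is supplied the search
#' is restricted to faces whose bounding boxes the ray crosses; the result is
#' identical to the exhaustive scan by construction. Both triangle sides are
#' hittable by default since gaze can land on any rendered surface.
#'
#' @param ray A `gaze_ray`.
#' @param mesh A [triangle_mesh()].
#' @param accelerator Optional index from [build_accelerator()].
#' @param t_epsilon Minimum accepted ray parameter (model units).
#' @param backface_cull Only count front-facing (counter-clockwise) hits.
#' @return `NULL`, or a list with `t`, `point`, `face_index`, `barycentric`.
#' @export
intersect_ray_mesh <- function(ray, mesh, accelerator = NULL,
                               t_epsilon = 1e-9, backface_cull = FALSE) {
  if (n_faces(mesh) == 0) {
    warning("empty mesh: no faces to intersect")
    return(NULL)
  }
  if (is.null(accelerator)) {
    geo <- .ray_geo(mesh)
    return(.mt_hits(ray$origin, ray$direction, geo, seq_len(n_faces(mesh)),
                    t_epsilon, backface_cull))
  }
  idx <- .aabb_candidates(accelerator, ray$origin, ray$direction, t_epsilon)
  .mt_hits(ray$origin, ray$direction, accelerator$geo, idx,
           t_epsilon, backface_cull)
}

#' Build a spatial index over a mesh for accelerated ray queries
#'
#' Precomputes per-face edge vectors and axis-aligned bounding boxes; queries
#' cull faces by a vectorised slab test before the exact triangle test, so
#' answers are exactly those of the exhaustive scan. Construction is
#' deterministic for a fixed mesh. Degenerate (zero-area) faces are counted
#' once here; they can never be hit.
#'
#' @param mesh A [triangle_mesh()].
#' @return An opaque object of class `mesh_accelerator`.
#' @export
build_accelerator <- function(mesh) {
  geo <- .ray_geo(mesh)
  n <- .cross_rows(geo$e1, geo$e2)
  degen <- sum(rowSums(n^2) == 0)
  if (degen > 0) {
    message(degen, " degenerate (zero-area) face(s) in mesh; they cannot be hit")
  }
  fc <- .face_corners(mesh)
  structure(list(
    geo = geo,
    n_faces = n_faces(mesh),
    lo = pmin(fc$v0, fc$v1, fc$v2),
    hi = pmax(fc$v0, fc$v1, fc$v2)
  ), class = "mesh_accelerator")
}

#' @export
print.mesh_accelerator <- function(x, ...) {
  cat(sprintf("<mesh_accelerator> AABB slab index over %d faces\n", x$n_faces))
  invisible(x)
}

# faces whose AABB the ray [t_epsilon, Inf) crosses
.aabb_candidates <- function(acc, origin, direction, t_epsilon) {
  m <- acc$n_faces
  if (m == 0) return(integer(0))
  tmin <- rep(t_epsilon, m)
  tmax <- rep(Inf, m)
  alive <- rep(TRUE, m)
  for (j in 1:3) {
    o <- origin[j]; d <- direction[j]
    lo <- acc$lo[, j]; hi <- acc$hi[, j]
    if (abs(d) < 1e-300) {
      alive <- alive & o >= lo & o <= hi
    } else {
      t1 <- (lo - o) / d
      t2 <- (hi - o) / d
      tmin <- pmax(tmin, pmin(t1, t2))
      tmax <- pmin(tmax, pmax(t1, t2))
    }
  }
  which(alive & tmin <= tmax)
}
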