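#' Convert a unit quaternion to a rotation matrix
#'
#' Quaternions follow the Hamilton convention in WXYZ component order, as
#' stored in VisualSFM NVM files, and encode the world-to-camera rotation.
#'
#' @param q Numeric vector of length 4, `(w, x, y, z)`. Renormalised if its
#'   norm deviates from 1 by up to `1e-6`; larger deviations warn first.
#' @return A 3x3 orthonormal rotation matrix with determinant +1.
#' @examples
#' quat_to_rotmat(c(1, 0, 0, 0))        # identity
#' quat_to_rotmat(c(0, 0, 0, 1))        # half turn about z
#' @export
quat_to_rotmat <- function(q) {
  stopifnot(is.numeric(q), length(q) == 4, all(is.finite(q)))
  n <- sqrt(sum(q^2))
  if (n == 0) stop("zero quaternion has no associated rotation")
  if (abs(n - 1) > 1e-3) {
    warning(sprintf("quaternion norm %.6f deviates from 1; renormalising", n))
  }
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Convert a rotation matrix to a unit quaternion (WXYZ)
#'
#' Inverse of [quat_to_rotmat()], used when writing camera poses back to NVM.
#' The sign is fixed so that `w >= 0`.
#'
#' @param R A 3x3 rotation matrix.
#' @return Numeric vector `(w, x, y, z)` with unit norm.
#' @export
rotmat_to_quat <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) q <- -q
  q
}

#' Convert normalised gaze coordinates to pixel coordinates
#'
#' Pupil Labs exports gaze positions in `[0, 1]` normalised image coordinates
#' with the origin at the bottom-left; image pixels have the origin at the
#' top-left with v growing downward. The default therefore flips the vertical
#' axis: `u = norm_x * width`, `v = (1 - norm_y) * height`. Set
#' `flip_y = FALSE` for exports already in top-left convention.
#'
#' Out-of-range inputs pass through unchanged (gaze may leave the frame); a
#' message notes them.
#'
#' @param norm_x,norm_y Numeric vectors, normalised gaze coordinates.
#' @param image_size Integer vector `(width_px, height_px)`.
#' @param flip_y Flip the vertical axis (default `TRUE`).
#' @return A tibble with columns `u`, `v` (pixels, top-left origin).
#' @export
pixel_from_norm <- function(norm_x, norm_y, image_size, flip_y = TRUE) {
  stopifnot(length(image_size) == 2, all(image_size > 0))
  if (any(norm_x < 0 | norm_x > 1 | norm_y < 0 | norm_y > 1, na.rm = TRUE)) {
    message("gaze position outside [0,1]^2 passed through unchanged")
  }
  v <- if (flip_y) (1 - norm_y) * image_size[2] else norm_y * image_size[2]
  tibble::tibble(u = norm_x * image_size[1], v = v)
}

#' Convert pixel coordinates back to normalised gaze coordinates
#'
#' Exact inverse of [pixel_from_norm()] under the same flip convention.
#'
#' @inheritParams pixel_from_norm
#' @param u,v Pixel coordinates (top-left origin).
#' @return A tibble with columns `norm_x`, `norm_y`.
#' @export
norm_from_pixel <- function(u, v, image_size, flip_y = TRUE) {
  stopifnot(length(image_size) == 2, all(image_size > 0))
  ny <- v / image_size[2]
  if (flip_y) ny <- 1 - ny
  tibble::tibble(norm_x = u / image_size[1], norm_y = ny)
}

# focal-normalised camera coordinates of a pixel about the principal point;
# principal point is the image centre (NVM stores none)
.pix_to_fn <- function(u, v, cam) {
  cx <- cam$width_px / 2
  cy <- cam$height_px / 2
  list(x = (u - cx) / cam$focal_px, y = (v - cy) / cam$focal_px)
}

.fn_to_pix <- function(x, y, cam) {
  list(u = x * cam$focal_px + cam$width_px / 2,
       v = y * cam$focal_px + cam$height_px / 2)
}

#' Apply forward radial distortion to an ideal (pinhole) pixel
#'
#' Single-coefficient radial model in focal-normalised coordinates about the
#' principal point: `r_d = r_u * (1 + k * r_u^2)`.
#'
#' @param u,v Undistorted pixel coordinates (vectors of equal length).
#' @param cam A one-row camera pose (see [read_nvm()]): uses `focal_px`,
#'   `k_radial`, `width_px`, `height_px`.
#' @return A tibble with distorted `u`, `v`.
#' @export
distort_pixel <- function(u, v, cam) {
  k <- cam$k_radial
  fn <- .pix_to_fn(u, v, cam)
  s <- 1 + k * (fn$x^2 + fn$y^2)
  p <- .fn_to_pix(fn$x * s, fn$y * s, cam)
  tibble::tibble(u = p$u, v = p$v)
}

#' Invert radial distortion on an observed pixel
#'
#' Solves `r_d = r_u (1 + k r_u^2)` for `r_u` by fixed-point iteration
#' (`r_u <- r_d / (1 + k r_u^2)`, tolerance `1e-10`, at most 50 iterations).
#' With `k = 0` this is the identity; the principal point is always a fixed
#' point.
#'
#' @inheritParams distort_pixel
#' @param u,v Observed (distorted) pixel coordinates.
#' @return A tibble with undistorted `u`, `v`.
#' @export
undistort_pixel <- function(u, v, cam) {
  stopifnot(cam$focal_px > 0)
  k <- cam$k_radial
  if (k == 0) return(tibble::tibble(u = u, v = v))
  fn <- .pix_to_fn(u, v, cam)
  rd <- sqrt(fn$x^2 + fn$y^2)
  ru <- rd
  for (i in seq_len(50)) {
    ru_new <- rd / (1 + k * ru^2)
    if (all(abs(ru_new - ru) < 1e-10)) {
      ru <- ru_new
      break
    }
    ru <- ru_new
  }
  if (any(abs(rd - ru * (1 + k * ru^2)) > 1e-8)) {
    stop(sprintf("undistortion did not converge for pixel (%g, %g) with k = %g",
                 u[which.max(abs(rd - ru * (1 + k * ru^2)))][1],
                 v[which.max(abs(rd - ru * (1 + k * ru^2)))][1], k))
  }
  scale <- ifelse(rd > 0, ru / rd, 1)
  p <- .fn_to_pix(fn$x * scale, fn$y * scale, cam)
  tibble::tibble(u = p$u, v = p$v)
}

#' Build the visual beam for a gaze pixel from a registered camera pose
#'
#' The camera frame follows the computer-vision convention (x right, y down,
#' z forward); the NVM quaternion rotates world to camera, so camera-frame
#' directions are lifted to the model frame by its transpose. The beam's
#' origin is the camera centre — the position of the world camera when the
#' fixation was detected — and its direction passes through the (undistorted)
#' gaze pixel.
#'
#' @param cam A one-row camera pose tibble (columns `qw..qz`, `cx..cz`,
#'   `focal_px`, `width_px`, `height_px`).
#' @param u,v Undistorted gaze pixel (scalars).
#' @param world_to_camera Interpret the stored quaternion as world-to-camera
#'   (VisualSFM convention, default). Set `FALSE` for foreign files storing
#'   camera-to-world.
#' @return A list with `origin` (3-vector) and `direction` (unit 3-vector),
#'   class `gaze_ray`.
#' @export
ray_from_fixation <- function(cam, u, v, world_to_camera = TRUE) {
  stopifnot(nrow(cam) == 1, is.finite(u), is.finite(v))
  R <- quat_to_rotmat(c(cam$qw, cam$qx, cam$qy, cam$qz))
  if (!world_to_camera) R <- t(R)
  centre <- c(cam$cx, cam$cy, cam$cz)
  if (!all(is.finite(centre)) || !is.finite(cam$focal_px)) {
    stop("degenerate camera pose: non-finite centre or focal length")
  }
  fn <- .pix_to_fn(u, v, cam)
  d_cam <- c(fn$x, fn$y, 1)
  d_world <- as.numeric(t(R) %*% d_cam)
  d_world <- d_world / sqrt(sum(d_world^2))
  structure(list(origin = centre, direction = d_world), class = "gaze_ray")
}

#' Project a model-space point into a camera's image
#'
#' Exact inverse of [ray_from_fixation()]'s direction construction, followed
#' by forward radial distortion (when `distortion = TRUE` and `k_radial != 0`).
#' Points at or behind the camera plane (camera-frame `z <= 0`) yield `NA`
#' pixels with `behind = TRUE`.
#'
#' @param cam A one-row camera pose tibble.
#' @param points Nx3 matrix (or 3-vector) of model-space points.
#' @param distortion Apply the forward radial model (default `TRUE`).
#' @param world_to_camera See [ray_from_fixation()].
#' @return A tibble with columns `u`, `v`, `behind`.
#' @export
project_point_to_pixel <- function(cam, points, distortion = TRUE,
                                   world_to_camera = TRUE) {
  stopifnot(nrow(cam) == 1)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  R <- quat_to_rotmat(c(cam$qw, cam$qx, cam$qy, cam$qz))
  if (!world_to_camera) R <- t(R)
  centre <- c(cam$cx, cam$cy, cam$cz)
  pc <- t(R %*% (t(points) - centre))  # camera-frame coordinates
  behind <- pc[, 3] <= 0
  x <- pc[, 1] / pc[, 3]
  y <- pc[, 2] / pc[, 3]
  p <- .fn_to_pix(x, y, cam)
  u <- p$u; v <- p$v
  if (distortion && cam$k_radial != 0) {
    d <- distort_pixel(u, v, cam)
    u <- d$u; v <- d$v
  }
  u[behind] <- NA_real_
  v[behind] <- NA_real_
  tibble::tibble(u = u, v = v, behind = behind)
}

#' @export
print.gaze_ray <- function(x, ...) {
  cat(sprintf("<gaze_ray> origin (%.4g, %.4g, %.4g), direction (%.4g, %.4g, %.4g)\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}
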