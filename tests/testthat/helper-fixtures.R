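# Fixtures and independent oracles shared across the suite.

# regular tetrahedron as an ascii PLY string
tetra_ply_lines <- function() {
  c("ply", "format ascii 1.0",
    "element vertex 4",
    "property float x", "property float y", "property float z",
    "element face 4",
    "property list uchar int vertex_indices",
    "end_header",
    "1 1 1", "1 -1 -1", "-1 1 -1", "-1 -1 1",
    "3 0 1 2", "3 0 3 1", "3 0 2 3", "3 1 3 2")
}

make_ray <- function(origin, direction) {
  direction <- direction / sqrt(sum(direction^2))
  structure(list(origin = origin, direction = direction), class = "gaze_ray")
}

# random pose with asymmetric image size; k = 0 unless given
random_camera <- function(k_radial = 0) {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  tibble::tibble(
    image_name = "random.png",
    focal_px = stats::runif(1, 700, 1600),
    qw = q[1], qx = q[2], qy = q[3], qz = q[4],
    cx = stats::rnorm(1), cy = stats::rnorm(1), cz = stats::rnorm(1),
    k_radial = k_radial,
    width_px = sample(600:1600, 1), height_px = sample(300:1200, 1))
}

# points guaranteed visible from a camera: sampled in-frame, then lifted
visible_points <- function(cam, n) {
  u <- stats::runif(n, 0.05, 0.95) * cam$width_px
  v <- stats::runif(n, 0.05, 0.95) * cam$height_px
  z <- stats::runif(n, 0.5, 5)
  x <- (u - cam$width_px / 2) / cam$focal_px * z
  y <- (v - cam$height_px / 2) / cam$focal_px * z
  R <- quat_to_rotmat(c(cam$qw, cam$qx, cam$qy, cam$qz))
  t(t(cbind(x, y, z) %*% R) + c(cam$cx, cam$cy, cam$cz))  # R^T p + C
}

# distance from a point to the closest point of a ray
ray_point_distance <- function(ray, p) {
  w <- p - ray$origin
  t0 <- sum(w * ray$direction)
  sqrt(sum((ray$origin + t0 * ray$direction - p)^2))
}

# independent ray/triangle oracle: plane intersection + barycentric signs,
# same t/epsilon conventions as the implementation but a different algorithm
oracle_ray_triangle <- function(ray, v0, v1, v2, t_epsilon = 1e-9) {
  e1 <- v1 - v0; e2 <- v2 - v0
  n <- c(e1[2] * e2[3] - e1[3] * e2[2],
         e1[3] * e2[1] - e1[1] * e2[3],
         e1[1] * e2[2] - e1[2] * e2[1])
  denom <- sum(n * ray$direction)
  if (abs(denom) < 1e-12) return(NULL)
  t <- sum(n * (v0 - ray$origin)) / denom
  if (t <= t_epsilon) return(NULL)
  p <- ray$origin + t * ray$direction
  # barycentric via normal projections of sub-triangle areas
  w <- p - v0
  d11 <- sum(e1 * e1); d12 <- sum(e1 * e2); d22 <- sum(e2 * e2)
  dw1 <- sum(w * e1); dw2 <- sum(w * e2)
  det <- d11 * d22 - d12^2
  b1 <- (d22 * dw1 - d12 * dw2) / det
  b2 <- (d11 * dw2 - d12 * dw1) / det
  if (b1 < -1e-9 || b2 < -1e-9 || b1 + b2 > 1 + 1e-9) return(NULL)
  list(t = t, point = p, barycentric = c(1 - b1 - b2, b1, b2))
}

# random scene for round-trip properties
random_scene <- function(n_cameras) {
  rows <- lapply(seq_len(n_cameras), function(i) {
    cam <- random_camera()
    cam$image_name <- sprintf("img_%03d.jpg", i)
    cam$k_radial <- stats::runif(1, -1e-7, 1e-7)
    cam
  })
  sfm_scene(dplyr::bind_rows(rows))
}

scene_fields_equal <- function(a, b, tol) {
  cols <- c("focal_px", "qw", "qx", "qy", "qz", "cx", "cy", "cz", "k_radial")
  identical(a$image_name, b$image_name) &&
    max(abs(as.matrix(a[cols]) - as.matrix(b[cols]))) < tol
}

# a tiny synthetic mapping setup reused by pipeline tests: n fixations on a
# sphere, one observer pose each, optional noise
small_mapping_setup <- function(n = 6, noise_deg = 0, seed = 11,
                                resolution = 16) {
  mesh <- make_stimulus_mesh("sphere", resolution)
  dirs <- withr::with_seed(seed, matrix(stats::rnorm(3 * n), ncol = 3))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  targets <- dirs * 0.18
  standpoints <- dirs * (0.18 + 1)
  sim <- simulate_observer_fixations(mesh, targets, standpoints,
                                     noise_deg = noise_deg, seed = seed)
  assignments <- extract_fixation_frames(sim$fixations, sim$frames)
  list(mesh = mesh, sim = sim, assignments = assignments,
       targets = targets)
}
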