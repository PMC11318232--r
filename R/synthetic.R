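# Synthetic-scene harness: generates every input the pipeline consumes
# (stimulus mesh, reference camera ring, observer poses, fixation table)
# with known ground truth, so the whole chain is testable without a
# recording or a photogrammetric reconstruction.
#
# Convention for synthetic scenes: 1 model unit = 1 metre, so centimetre
# figures (36 cm stimulus, 2.5 cm dots) are directly usable. Real SfM scenes
# have arbitrary scale; nothing outside this module assumes units.

#' Generate a closed stimulus-scale mesh
#'
#' A UV sphere or ellipsoid standing in for a reconstructed stimulus,
#' centred at the origin and scaled so its bounding-box height (z extent)
#' equals `height_units` — default 0.36, a 36 cm statuette in metres.
#'
#' @param kind `"sphere"` or `"ellipsoid"` (UV grids, semi-axis ratio
#'   0.6 : 0.4 : 1 for the ellipsoid), or `"icosphere"` (subdivided
#'   icosahedron, `20 * 4^resolution` faces — level 3 gives 1280).
#' @param resolution Latitude band count for the UV grids (>= 8;
#'   longitudes are `2 * resolution`), subdivision level for the icosphere.
#' @param height_units Bounding-box height in model units.
#' @return A closed, consistently wound [triangle_mesh()].
#' @export
make_stimulus_mesh <- function(kind = c("sphere", "ellipsoid", "icosphere"),
                               resolution = 24, height_units = 0.36) {
  kind <- match.arg(kind)
  if (kind == "icosphere") {
    return(.icosphere(resolution, height_units / 2))
  }
  stopifnot(resolution >= 8)
  n_lat <- as.integer(resolution)
  n_lon <- 2L * n_lat
  semi <- if (kind == "sphere") c(1, 1, 1) / 2 else c(0.3, 0.2, 0.5)
  semi <- semi * height_units / (2 * semi[3])
  lat <- seq(0, pi, length.out = n_lat + 1)[-c(1, n_lat + 1)]
  lon <- seq(0, 2 * pi, length.out = n_lon + 1)[-(n_lon + 1)]
  grid <- expand.grid(lon = lon, lat = lat)
  verts <- rbind(
    c(0, 0, semi[3]),
    cbind(semi[1] * sin(grid$lat) * cos(grid$lon),
          semi[2] * sin(grid$lat) * sin(grid$lon),
          semi[3] * cos(grid$lat)),
    c(0, 0, -semi[3])
  )
  vid <- function(i, j) 1L + (i - 1L) * n_lon + ((j - 1L) %% n_lon) + 1L
  south <- nrow(verts)
  faces <- list()
  # top fan (outward = counter-clockwise seen from outside)
  faces[[1]] <- cbind(1L, vid(1, 1:n_lon), vid(1, 2:(n_lon + 1)))
  # quad bands
  for (i in seq_len(n_lat - 2)) {
    a <- vid(i, 1:n_lon); b <- vid(i, 2:(n_lon + 1))
    c2 <- vid(i + 1, 1:n_lon); d <- vid(i + 1, 2:(n_lon + 1))
    faces[[length(faces) + 1]] <- rbind(cbind(a, c2, d), cbind(a, d, b))
  }
  # bottom fan
  faces[[length(faces) + 1]] <- cbind(south, vid(n_lat - 1, 2:(n_lon + 1)),
                                      vid(n_lat - 1, 1:n_lon))
  triangle_mesh(verts, do.call(rbind, faces))
}

# subdivided icosahedron projected onto a sphere of the given radius
.icosphere <- function(level, radius) {
  stopifnot(level >= 0)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(level)) {
    mid_cache <- new.env(hash = TRUE)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      got <- mid_cache[[key]]
      if (!is.null(got)) return(got)
      v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c3 <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      nf[(i - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                       c(c3, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  triangle_mesh(v, f)
}

# world-to-camera rotation for a camera at `centre` looking at `target`
# (camera z forward, y down); world up is +z
.look_at_quat <- function(centre, target) {
  f <- target - centre
  f <- f / sqrt(sum(f^2))
  up <- if (abs(f[3]) > 0.999) c(0, 1, 0) else c(0, 0, 1)
  right <- c(f[2] * up[3] - f[3] * up[2],
             f[3] * up[1] - f[1] * up[3],
             f[1] * up[2] - f[2] * up[1])
  right <- right / sqrt(sum(right^2))
  down <- c(f[2] * right[3] - f[3] * right[2],
            f[3] * right[1] - f[1] * right[3],
            f[1] * right[2] - f[2] * right[1])
  rotmat_to_quat(rbind(right, down, f))
}

.default_focal <- function(image_size, fov_deg = 60) {
  # horizontal field of view -> focal length in pixels
  image_size[1] / (2 * tan(fov_deg / 2 * pi / 180))
}

#' Generate a two-height reference camera ring
#'
#' Emulates the reference photographs taken around a stimulus at two
#' heights for photogrammetry: `2 * n_per_ring` poses evenly spaced in
#' azimuth, each oriented so `look_at` projects exactly to the image
#' centre. The default 43 per ring yields 86 cameras.
#'
#' @param n_per_ring Cameras per ring (>= 3).
#' @param heights Two z values for the rings (model units).
#' @param radius Ring radius (model units).
#' @param look_at 3-vector the cameras aim at (stimulus centroid).
#' @param image_size `(width, height)` in pixels.
#' @param focal_px Focal length in pixels (default: 60 degree horizontal
#'   field of view, the usual world-camera lens).
#' @param mesh Optional [triangle_mesh()]; when given, `radius` must exceed
#'   the mesh's extent about `look_at`.
#' @param name_prefix Image-name prefix.
#' @return An [sfm_scene()] with `2 * n_per_ring` cameras.
#' @export
make_reference_ring <- function(n_per_ring = 43, heights = c(-0.08, 0.10),
                                radius = 1, look_at = c(0, 0, 0),
                                image_size = c(1280, 720), focal_px = NULL,
                                mesh = NULL, name_prefix = "ref") {
  stopifnot(n_per_ring >= 3, length(heights) == 2)
  focal_px <- focal_px %||% .default_focal(image_size)
  if (!is.null(mesh)) {
    extent <- max(sqrt(rowSums(sweep(mesh$vertices, 2, look_at)^2)))
    if (radius <= extent) {
      stop("ring radius ", radius, " is inside the mesh extent ",
           signif(extent, 4))
    }
  }
  az <- seq(0, 2 * pi, length.out = n_per_ring + 1)[-(n_per_ring + 1)]
  rows <- list()
  for (hi in seq_along(heights)) {
    for (ai in seq_along(az)) {
      centre <- c(look_at[1] + radius * cos(az[ai]),
                  look_at[2] + radius * sin(az[ai]),
                  heights[hi])
      q <- .look_at_quat(centre, look_at)
      rows[[length(rows) + 1]] <- tibble::tibble(
        image_name = sprintf("%s_h%d_%03d.jpg", name_prefix, hi, ai),
        focal_px = focal_px, qw = q[1], qx = q[2], qy = q[3], qz = q[4],
        cx = centre[1], cy = centre[2], cz = centre[3], k_radial = 0,
        width_px = as.integer(image_size[1]),
        height_px = as.integer(image_size[2]))
    }
  }
  sfm_scene(dplyr::bind_rows(rows))
}

#' Simulate an observer fixating known surface targets
#'
#' For each target: an observer (world-camera) pose at the corresponding
#' standpoint, aimed at `look_at` (the stimulus centroid by default); the
#' exact gaze pixel is the target's projection, perturbed by an isotropic
#' angular error — two independent normal components of standard deviation
#' `noise_deg / sqrt(2)` each, so the total angular standard deviation is
#' `noise_deg` (the gaze-accuracy figure of a calibrated mobile tracker,
#' default 0.6 degrees). Fixations get timestamps on the world-frame clock
#' (`fps`), durations above the 30 ms detector floor, and zero dispersion,
#' so an upstream fixation detector (3 degree dispersion cap) would accept
#' them. Targets occluded from their standpoint are an error.
#'
#' @param mesh The stimulus [triangle_mesh()].
#' @param targets Kx3 matrix of intended surface points.
#' @param standpoints Kx3 matrix (or one 3-vector, recycled) of observer
#'   positions.
#' @param noise_deg Total angular gaze error, degrees (0 = perfect gaze).
#' @param seed Integer; the same seed reproduces the same scene exactly.
#' @param image_size,focal_px World-camera intrinsics.
#' @param fps World-video frame rate (frame timestamps, seconds).
#' @param duration_ms Fixation duration written to the table.
#' @param frame_stride Frames between consecutive fixation frames.
#' @param look_at Aim point of the observer poses (default mesh centroid).
#' @param flip_y Normalised-coordinate convention, see [pixel_from_norm()].
#' @param visibility_tol Slack, in model units, allowed between the
#'   first-hit distance and the standpoint-target distance before a target
#'   counts as occluded. Default: half the median mesh edge length, which
#'   absorbs the gap between a faceted mesh and the smooth surface its
#'   targets may lie on.
#' @return A list: `scene` (observer [sfm_scene()], one pose per fixation),
#'   `fixations` (`fixation_table`), `frames` (frame-timestamp tibble
#'   covering the whole synthetic video), `ground_truth` (tibble with the
#'   intended surface point and exact gaze pixel per fixation).
#' @export
simulate_observer_fixations <- function(mesh, targets, standpoints,
                                        noise_deg = 0.6, seed = 1,
                                        image_size = c(1280, 720),
                                        focal_px = NULL, fps = 30,
                                        duration_ms = 150, frame_stride = 10,
                                        look_at = NULL, flip_y = TRUE,
                                        visibility_tol = NULL) {
  if (is.null(dim(targets))) targets <- matrix(targets, ncol = 3)
  if (is.null(dim(standpoints))) standpoints <- matrix(standpoints, ncol = 3)
  if (nrow(standpoints) == 1) {
    standpoints <- standpoints[rep(1, nrow(targets)), , drop = FALSE]
  }
  stopifnot(nrow(standpoints) == nrow(targets))
  focal_px <- focal_px %||% .default_focal(image_size)
  look_at <- look_at %||% colMeans(mesh$vertices)
  k <- nrow(targets)
  acc <- build_accelerator(mesh)
  if (is.null(visibility_tol)) {
    fc <- .face_corners(mesh)
    visibility_tol <- max(1e-6, 0.5 * stats::median(
      sqrt(rowSums((fc$v1 - fc$v0)^2))))
  }
  sigma <- noise_deg * pi / 180 / sqrt(2)
  withr::with_seed(seed, {
    noise <- matrix(stats::rnorm(2 * k, sd = sigma), ncol = 2)
    pupil <- stats::rnorm(k, mean = 3.5, sd = 0.25)
  })
  if (noise_deg == 0) noise[] <- 0
  cams <- list(); fix <- list(); gt <- list()
  for (i in seq_len(k)) {
    C <- standpoints[i, ]; Tg <- targets[i, ]
    # visibility: the first mesh hit along the sight line must be the target
    d0 <- Tg - C; dist <- sqrt(sum(d0^2)); d0 <- d0 / dist
    hit <- intersect_ray_mesh(structure(list(origin = C, direction = d0),
                                        class = "gaze_ray"), mesh,
                              accelerator = acc)
    if (is.null(hit) || abs(hit$t - dist) > visibility_tol) {
      stop("target ", i, " is occluded from its standpoint")
    }
    q <- .look_at_quat(C, look_at)
    frame_index <- (i - 1L) * frame_stride
    cam <- tibble::tibble(
      image_name = sprintf("frame_%06d.png", frame_index),
      focal_px = focal_px, qw = q[1], qx = q[2], qy = q[3], qz = q[4],
      cx = C[1], cy = C[2], cz = C[3], k_radial = 0,
      width_px = as.integer(image_size[1]),
      height_px = as.integer(image_size[2]))
    # exact pinhole gaze direction to the target, then angular perturbation
    # in the camera frame
    R <- quat_to_rotmat(q)
    pc <- as.numeric(R %*% (Tg - C))
    if (pc[3] <= 0) stop("target ", i, " is behind its observer camera")
    d <- pc / sqrt(sum(pc^2))
    e1 <- c(-d[3], 0, d[1]); e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(d[2] * e1[3] - d[3] * e1[2],
            d[3] * e1[1] - d[1] * e1[3],
            d[1] * e1[2] - d[2] * e1[1])
    dp <- d + noise[i, 1] * e1 + noise[i, 2] * e2
    u <- dp[1] / dp[3] * focal_px + image_size[1] / 2
    v <- dp[2] / dp[3] * focal_px + image_size[2] / 2
    nm <- norm_from_pixel(u, v, image_size, flip_y = flip_y)
    cams[[i]] <- cam
    fix[[i]] <- tibble::tibble(
      fixation_id = i, start_timestamp = frame_index / fps,
      duration_ms = duration_ms, norm_x = nm$norm_x, norm_y = nm$norm_y,
      dispersion = 0, avg_pupil_size = pupil[i])
    gt[[i]] <- tibble::tibble(
      fixation_id = i, target_x = Tg[1], target_y = Tg[2], target_z = Tg[3],
      standpoint_x = C[1], standpoint_y = C[2], standpoint_z = C[3],
      gaze_u = u, gaze_v = v, frame_file = cam$image_name)
  }
  n_frames <- (k - 1L) * frame_stride + frame_stride
  frames <- tibble::tibble(
    frame_index = 0:(n_frames - 1),
    frame_file = sprintf("frame_%06d.png", 0:(n_frames - 1)),
    timestamp = (0:(n_frames - 1)) / fps)
  fixations <- dplyr::bind_rows(fix)
  class(fixations) <- c("fixation_table", class(fixations))
  list(scene = sfm_scene(dplyr::bind_rows(cams)), fixations = fixations,
       frames = frames, ground_truth = dplyr::bind_rows(gt))
}

#' Place circular dot targets on a mesh surface
#'
#' Emulates physical dot markers attached to a stimulus for accuracy
#' checking: the default is four dots of radius 0.0125 model units —
#' 2.5 cm diameter at the metre scale of the synthetic scenes. Centres are
#' sampled uniformly over the surface (area-weighted faces, uniform
#' barycentric) and resampled until mutually non-overlapping; a copy of the
#' mesh with the dot vertices coloured red is returned alongside.
#'
#' @param mesh A [triangle_mesh()].
#' @param n_dots Number of dots (>= 1).
#' @param radius Dot radius, model units.
#' @param seed Integer seed; same seed, same centres.
#' @param max_tries Candidate budget before giving up.
#' @return A list: `dots` (tibble `dot`, `x`, `y`, `z`, `radius`) and
#'   `mesh` (vertex-coloured copy).
#' @export
place_dots <- function(mesh, n_dots = 4, radius = 0.0125, seed = 1,
                       max_tries = 500) {
  stopifnot(n_dots >= 1)
  fc <- .face_corners(mesh)
  area <- 0.5 * sqrt(rowSums(.cross_rows(fc$v1 - fc$v0, fc$v2 - fc$v0)^2))
  centres <- matrix(NA_real_, nrow = 0, ncol = 3)
  withr::with_seed(seed, {
    tries <- 0
    while (nrow(centres) < n_dots) {
      tries <- tries + 1
      if (tries > max_tries) {
        stop("could not place ", n_dots, " non-overlapping dots in ",
             max_tries, " tries")
      }
      f <- sample.int(length(area), 1, prob = area)
      r1 <- sqrt(stats::runif(1)); r2 <- stats::runif(1)
      b <- c(1 - r1, r1 * (1 - r2), r1 * r2)
      p <- b[1] * fc$v0[f, ] + b[2] * fc$v1[f, ] + b[3] * fc$v2[f, ]
      if (nrow(centres) == 0 ||
          min(sqrt(rowSums(sweep(centres, 2, p)^2))) > 2 * radius) {
        centres <- rbind(centres, p)
      }
    }
  })
  color <- matrix(180L, nrow = n_vertices(mesh), ncol = 3)
  for (i in seq_len(n_dots)) {
    near <- sqrt(rowSums(sweep(mesh$vertices, 2, centres[i, ])^2)) <= radius
    color[near, ] <- rep(c(255L, 0L, 0L), each = sum(near))
  }
  dotted <- triangle_mesh(mesh$vertices, mesh$faces, color)
  list(dots = tibble::tibble(dot = seq_len(n_dots), x = centres[, 1],
                             y = centres[, 2], z = centres[, 3],
                             radius = radius),
       mesh = dotted)
}

#' Score projected fixations against dot targets
#'
#' A mapped fixation counts as on-dot when its intersection point lies
#' within the dot radius (Euclidean distance) of a dot centre; at the
#' default scales the dot radius is far below the surface curvature radius,
#' so Euclidean and geodesic distance agree to well within the radius.
#'
#' @param projections A projection table from [project_fixations()].
#' @param dots Dot tibble from [place_dots()].
#' @return A list of class `dot_evaluation`: `fixations` (per-fixation
#'   nearest dot, distance, `on_dot`), `dots` (per-dot hit counts),
#'   `summary` (one-row totals: on, off, unmapped).
#' @export
evaluate_dot_hits <- function(projections, dots) {
  mapped <- projections[projections$status == "mapped", , drop = FALSE]
  centres <- as.matrix(dots[, c("x", "y", "z")])
  per_fix <- purrr::map_dfr(seq_len(nrow(mapped)), function(i) {
    p <- c(mapped$intersection_x[i], mapped$intersection_y[i],
           mapped$intersection_z[i])
    dist <- sqrt(rowSums(sweep(centres, 2, p)^2))
    j <- which.min(dist)
    tibble::tibble(fixation_id = mapped$fixation_id[i],
                   nearest_dot = dots$dot[j], distance = dist[j],
                   on_dot = dist[j] <= dots$radius[j])
  })
  per_dot <- dplyr::count(dplyr::filter(per_fix, .data$on_dot),
                          .data$nearest_dot, name = "hits")
  per_dot <- dplyr::left_join(dots["dot"], per_dot,
                              by = c(dot = "nearest_dot"))
  per_dot$hits[is.na(per_dot$hits)] <- 0L
  summary <- tibble::tibble(
    n_fixations = nrow(projections),
    n_mapped = nrow(mapped),
    on_dot = sum(per_fix$on_dot),
    off_dot = sum(!per_fix$on_dot),
    dots_hit = sum(per_dot$hits > 0))
  structure(list(fixations = per_fix, dots = per_dot, summary = summary),
            class = "dot_evaluation")
}

#' @export
print.dot_evaluation <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<dot_evaluation> %d fixation(s): %d mapped, %d on-dot, %d off-dot; %d/%d dots hit\n",
              s$n_fixations, s$n_mapped, s$on_dot, s$off_dot, s$dots_hit,
              nrow(x$dots)))
  invisible(x)
}

#' Mean and spread of pixel deviations between paired gaze positions
#'
#' Per-pair Euclidean distance between mapped and reference pixel
#' positions; reports the population mean and the sample standard
#' deviation. Used to compare automatic frame-based mapping against
#' independent (e.g. manual) mappings of the same fixations.
#'
#' @param mapped_pixels,reference_pixels Data frames (or matrices) with
#'   paired `u`, `v` pixel coordinates, equal length.
#' @return A one-row tibble: `n`, `mean_px`, `sd_px`.
#' @export
deviation_statistics <- function(mapped_pixels, reference_pixels) {
  a <- as.data.frame(mapped_pixels); b <- as.data.frame(reference_pixels)
  if (is.null(a$u)) names(a)[1:2] <- c("u", "v")
  if (is.null(b$u)) names(b)[1:2] <- c("u", "v")
  if (nrow(a) == 0) stop("no pixel pairs supplied")
  stopifnot(nrow(a) == nrow(b))
  d <- sqrt((a$u - b$u)^2 + (a$v - b$v)^2)
  tibble::tibble(n = length(d), mean_px = mean(d), sd_px = stats::sd(d))
}

#' Emit a complete synthetic input bundle to disk
#'
#' Writes everything the end-to-end run consumes — dotted stimulus mesh
#' (PLY), merged reference + observer scene (NVM), fixation table (CSV),
#' frame-timestamp table, dot manifest, ground-truth table and a ready
#' pipeline configuration file — so `run_gaze_mapping(file.path(dir,
#' "pipeline.cfg"))` reproduces the whole chain.
#'
#' @param out_dir Output directory (created).
#' @param n_dots,dot_radius,noise_deg,seed Scene parameters, see
#'   [place_dots()] and [simulate_observer_fixations()].
#' @param kind,resolution,height_units Mesh parameters, see
#'   [make_stimulus_mesh()].
#' @param n_per_ring,ring_radius Reference-ring parameters.
#' @param standpoint_distance Observer distance from the surface targets.
#' @param image_size World-camera image size.
#' @param write_frames Also write flat frame PNGs for the fixation frames
#'   (needed only by overlay marking).
#' @return Invisibly, a list with the generated objects and file `paths`.
#' @export
make_synthetic_bundle <- function(out_dir, n_dots = 4, dot_radius = 0.0125,
                                  noise_deg = 0.6, seed = 1,
                                  kind = "ellipsoid", resolution = 24,
                                  height_units = 0.36, n_per_ring = 43,
                                  ring_radius = 1, standpoint_distance = 1,
                                  image_size = c(1280, 720),
                                  write_frames = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mesh0 <- make_stimulus_mesh(kind, resolution = resolution,
                              height_units = height_units)
  dotted <- place_dots(mesh0, n_dots = n_dots, radius = dot_radius,
                       seed = seed)
  centres <- as.matrix(dotted$dots[, c("x", "y", "z")])
  centroid <- colMeans(mesh0$vertices)
  # standpoints along the outward surface normal direction from the centroid
  out_dirs <- sweep(centres, 2, centroid)
  out_dirs <- out_dirs / sqrt(rowSums(out_dirs^2))
  standpoints <- centres + standpoint_distance * out_dirs
  sim <- simulate_observer_fixations(dotted$mesh, centres, standpoints,
                                     noise_deg = noise_deg, seed = seed,
                                     image_size = image_size)
  ring <- make_reference_ring(n_per_ring = n_per_ring, radius = ring_radius,
                              look_at = centroid, image_size = image_size,
                              mesh = mesh0)
  scene <- sfm_scene(dplyr::bind_rows(ring, sim$scene))
  paths <- list(
    mesh = file.path(out_dir, "stimulus_synthetic.ply"),
    scene = file.path(out_dir, "scene_synthetic.nvm"),
    fixations = file.path(out_dir, "fixations_synthetic.csv"),
    timestamps = file.path(out_dir, "frame_timestamps.csv"),
    dots = file.path(out_dir, "dots_synthetic.csv"),
    ground_truth = file.path(out_dir, "ground_truth.csv"),
    config = file.path(out_dir, "pipeline.cfg"),
    frames = file.path(out_dir, "frames")
  )
  write_ply_mesh(dotted$mesh, paths$mesh)
  write_nvm(scene, paths$scene)
  write_fixation_csv(sim$fixations, paths$fixations)
  readr::write_csv(sim$frames, paths$timestamps, progress = FALSE)
  readr::write_csv(dotted$dots, paths$dots, progress = FALSE)
  readr::write_csv(sim$ground_truth, paths$ground_truth, progress = FALSE)
  cfg <- c(
    paste("scene =", paths$scene),
    paste("mesh =", paths$mesh),
    paste("fixations =", paths$fixations),
    paste("timestamps =", paths$timestamps),
    paste("out =", file.path(out_dir, "output")),
    paste("image_width =", image_size[1]),
    paste("image_height =", image_size[2]),
    if (write_frames) paste("frames =", paths$frames)
  )
  writeLines(cfg, paths$config)
  if (write_frames) {
    dir.create(paths$frames, showWarnings = FALSE)
    flat <- array(0.5, dim = c(image_size[2], image_size[1], 3))
    for (f in unique(sim$scene$image_name)) {
      png::writePNG(flat, file.path(paths$frames, f))
    }
  }
  invisible(list(mesh = dotted$mesh, dots = dotted$dots, scene = scene,
                 fixations = sim$fixations, frames = sim$frames,
                 ground_truth = sim$ground_truth, paths = paths))
}
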