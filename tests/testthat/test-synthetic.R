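# The synthetic harness: stimulus meshes, reference rings, simulated
# observers, dot targets and the evaluation statistics.

test_that("stimulus meshes are closed, correctly scaled and deterministic", {
  for (kind in c("sphere", "ellipsoid")) {
    m <- make_stimulus_mesh(kind, 16)
    v <- n_vertices(m); f <- n_faces(m)
    e <- 3 * f / 2                         # closed: every edge shared twice
    expect_equal(v - e + f, 2)             # Euler characteristic
    expect_equal(diff(range(m$vertices[, 3])), 0.36, tolerance = 1e-9)
  }
  ico <- make_stimulus_mesh("icosphere", 3)
  expect_equal(n_faces(ico), 1280)
  expect_equal(n_vertices(ico) - 3 * n_faces(ico) / 2 + n_faces(ico), 2)
  # seedless generator: identical vertex arrays on repeat calls
  expect_identical(make_stimulus_mesh("ellipsoid", 12)$vertices,
                   make_stimulus_mesh("ellipsoid", 12)$vertices)
  # consistent outward winding: face normals point away from the centre
  m <- make_stimulus_mesh("sphere", 12)
  fc <- m$vertices[m$faces[, 1], ]
  e1 <- m$vertices[m$faces[, 2], ] - fc
  e2 <- m$vertices[m$faces[, 3], ] - fc
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  expect_true(all(rowSums(nrm * fc) > 0))
})

test_that("the reference ring has 86 centred cameras at two heights", {
  mesh <- make_stimulus_mesh("ellipsoid", 12)
  ring <- make_reference_ring(43, mesh = mesh)
  expect_equal(nrow(ring), 86)
  expect_equal(length(unique(ring$cz)), 2)
  centroid <- colMeans(mesh$vertices)
  for (i in c(1, 20, 44, 86)) {
    px <- project_point_to_pixel(ring[i, ], centroid)
    expect_lt(abs(px$u - ring$width_px[i] / 2), 1e-6)
    expect_lt(abs(px$v - ring$height_px[i] / 2), 1e-6)
  }
  expect_error(make_reference_ring(43, radius = 0.1, mesh = mesh),
               "inside the mesh extent")
  expect_error(make_reference_ring(2), "n_per_ring")
})

test_that("zero-noise observers fixate their targets exactly; seeds reproduce", {
  setup <- small_mapping_setup(n = 5, noise_deg = 0, seed = 51)
  proj <- project_fixations(setup$sim$scene, setup$mesh, setup$sim$fixations,
                            setup$assignments)
  expect_true(all(proj$status == "mapped"))
  edge <- stats::median(sqrt(rowSums((
    setup$mesh$vertices[setup$mesh$faces[, 2], ] -
    setup$mesh$vertices[setup$mesh$faces[, 1], ])^2)))
  dev <- sqrt((proj$intersection_x - setup$targets[, 1])^2 +
              (proj$intersection_y - setup$targets[, 2])^2 +
              (proj$intersection_z - setup$targets[, 3])^2)
  expect_lt(max(dev), 2 * edge)
  # identical seed, identical tables; different seed differs (noise > 0)
  a <- small_mapping_setup(n = 5, noise_deg = 0.6, seed = 52)
  b <- small_mapping_setup(n = 5, noise_deg = 0.6, seed = 52)
  expect_identical(a$sim$fixations, b$sim$fixations)
  c3 <- small_mapping_setup(n = 5, noise_deg = 0.6, seed = 53)
  expect_false(identical(a$sim$fixations$norm_x, c3$sim$fixations$norm_x))
  # occluded target: aiming at the far side errors with the index
  mesh <- setup$mesh
  expect_error(
    simulate_observer_fixations(mesh, -setup$targets[1, , drop = FALSE],
                                setup$targets[1, , drop = FALSE] * 6,
                                noise_deg = 0, seed = 1),
    "target 1 is occluded")
})

test_that("mapped deviation follows the small-angle tan law and scales linearly", {
  mesh <- make_stimulus_mesh("sphere", 20)
  set.seed(54)
  n <- 150
  dirs <- matrix(stats::rnorm(3 * n), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  targets <- dirs * 0.18
  run_at <- function(noise, dist) {
    sim <- simulate_observer_fixations(mesh, targets, dirs * (0.18 + dist),
                                       noise_deg = noise, seed = 55)
    assign <- extract_fixation_frames(sim$fixations, sim$frames)
    proj <- project_fixations(sim$scene, mesh, sim$fixations, assign)
    dev <- sqrt((proj$intersection_x - targets[, 1])^2 +
                (proj$intersection_y - targets[, 2])^2 +
                (proj$intersection_z - targets[, 3])^2)
    mean(dev, na.rm = TRUE)
  }
  m1 <- run_at(0.6, 1)
  # isotropic two-component noise of total SD sigma gives a Rayleigh miss
  # distance with mean sigma * sqrt(pi) / 2 at unit distance
  sigma <- 0.6 * pi / 180
  expect_lt(abs(m1 - sigma * sqrt(pi) / 2) / (sigma * sqrt(pi) / 2), 0.2)
  expect_lt(abs(m1 - tan(0.6 * pi / 180)) / tan(0.6 * pi / 180), 0.15)
  # linear in noise and in standpoint distance
  m03 <- run_at(0.3, 1); m12 <- run_at(1.2, 1)
  expect_lt(abs(m12 / m03 - 4) / 4, 0.25)
  m_half <- run_at(0.6, 0.5)
  expect_lt(abs(m1 / m_half - 2) / 2, 0.25)
})

test_that("dots are placed on the surface, non-overlapping and reproducibly", {
  mesh <- make_stimulus_mesh("ellipsoid", 20)
  d <- place_dots(mesh, n_dots = 4, radius = 0.0125, seed = 61)
  expect_equal(nrow(d$dots), 4)
  centres <- as.matrix(d$dots[, c("x", "y", "z")])
  pd <- as.matrix(stats::dist(centres))
  expect_gt(min(pd[upper.tri(pd)]), 2 * 0.0125)
  # same seed, same centres
  d2 <- place_dots(mesh, n_dots = 4, radius = 0.0125, seed = 61)
  expect_identical(d$dots, d2$dots)
  # a single dot on a sphere lies on the sphere
  sph <- make_stimulus_mesh("sphere", 24)
  d1 <- place_dots(sph, n_dots = 1, seed = 62)
  r <- sqrt(sum(as.matrix(d1$dots[, c("x", "y", "z")])^2))
  expect_lt(abs(r - 0.18), 2e-3)   # on a facet of the sphere
  # the coloured copy marks only vertices inside dots red
  red <- d$mesh$color[, 1] == 255 & d$mesh$color[, 2] == 0
  vd <- apply(as.matrix(stats::dist(rbind(centres, mesh$vertices)))[
    -(1:4), 1:4, drop = FALSE], 1, min)
  expect_identical(unname(red), unname(vd <= 0.0125))
  # an impossible packing errors out
  expect_error(place_dots(mesh, n_dots = 100, radius = 0.2, seed = 1,
                          max_tries = 50), "non-overlapping")
})

test_that("dot-hit scoring matches geometry and the analytic miss rate", {
  dir <- withr::local_tempdir()
  b <- make_synthetic_bundle(dir, noise_deg = 0, seed = 7, n_per_ring = 5,
                             resolution = 16)
  res <- suppressMessages(run_gaze_mapping(file.path(dir, "pipeline.cfg")))
  ev <- evaluate_dot_hits(res$projections, b$dots)
  expect_equal(glance(ev)$on_dot, 4)
  expect_equal(glance(ev)$off_dot, 0)
  expect_equal(glance(ev)$dots_hit, 4)
  expect_equal(sum(ev$dots$hits), 4)

  # a fixation aimed midway between two dots scores off-dot
  fake <- res$projections[1, ]
  fake$intersection_x <- mean(b$dots$x[1:2])
  fake$intersection_y <- mean(b$dots$y[1:2])
  fake$intersection_z <- mean(b$dots$z[1:2])
  ev2 <- evaluate_dot_hits(fake, b$dots)
  expect_false(ev2$fixations$on_dot)

  # Rayleigh miss-distance model: with sigma the angular SD, distance L and
  # dot radius rho, P(on-dot) = 1 - exp(-rho^2 / (2 (sigma L / sqrt(2))^2));
  # the empirical rate must sit inside the 99% binomial band
  mesh <- make_stimulus_mesh("sphere", 20)
  set.seed(63)
  n <- 200
  dirs <- matrix(stats::rnorm(3 * n), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  targets <- dirs * 0.18
  L <- 0.5
  sim <- simulate_observer_fixations(mesh, targets, dirs * (0.18 + L),
                                     noise_deg = 0.6, seed = 64)
  assign <- extract_fixation_frames(sim$fixations, sim$frames)
  proj <- project_fixations(sim$scene, mesh, sim$fixations, assign)
  rho <- 0.0125
  dev <- sqrt((proj$intersection_x - targets[, 1])^2 +
              (proj$intersection_y - targets[, 2])^2 +
              (proj$intersection_z - targets[, 3])^2)
  hit_rate <- mean(dev <= rho, na.rm = TRUE)
  scale <- 0.6 * pi / 180 * L / sqrt(2)
  p_hit <- 1 - exp(-rho^2 / (2 * scale^2))
  band <- stats::qbinom(c(0.005, 0.995), n, p_hit) / n
  expect_gte(hit_rate, band[1])
  expect_lte(hit_rate, band[2])
})

test_that("pixel deviation statistics match hand values and the Rayleigh mean", {
  same <- tibble::tibble(u = c(1, 2, 3), v = c(4, 5, 6))
  expect_equal(deviation_statistics(same, same),
               tibble::tibble(n = 3L, mean_px = 0, sd_px = 0))
  off <- dplyr::mutate(same, u = u + 3, v = v + 4)
  expect_equal(deviation_statistics(off, same),
               tibble::tibble(n = 3L, mean_px = 5, sd_px = 0))
  expect_error(deviation_statistics(same[0, ], same[0, ]), "no pixel pairs")
  # isotropic 2D error of scale sigma: mean distance sigma * sqrt(pi / 2)
  set.seed(65)
  sigma <- 4
  n <- 1e5
  ref <- tibble::tibble(u = stats::runif(n, 0, 1000),
                        v = stats::runif(n, 0, 1000))
  mapped <- dplyr::mutate(ref, u = u + stats::rnorm(n, sd = sigma),
                          v = v + stats::rnorm(n, sd = sigma))
  st <- deviation_statistics(mapped, ref)
  expect_equal(st$mean_px, sigma * sqrt(pi / 2), tolerance = 0.02)
})

test_that("the emitted bundle is complete and consumed unchanged by the runner", {
  dir <- withr::local_tempdir()
  b <- make_synthetic_bundle(dir, noise_deg = 0.6, seed = 9, n_per_ring = 4,
                             resolution = 14, write_frames = TRUE)
  for (p in b$paths[c("mesh", "scene", "fixations", "timestamps", "dots",
                      "ground_truth", "config")]) {
    expect_true(file.exists(p))
  }
  # frame images exist for every fixation frame
  expect_true(all(file.exists(file.path(b$paths$frames,
                                        unique(b$ground_truth$frame_file)))))
  # the scene merges ring and observer cameras
  expect_equal(nrow(b$scene), 2 * 4 + nrow(b$fixations))
  res <- suppressMessages(run_gaze_mapping(file.path(dir, "pipeline.cfg")))
  expect_equal(nrow(res$projections), nrow(b$fixations))
})
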