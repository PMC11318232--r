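# Projective core: quaternion algebra, gaze-pixel conversions, distortion,
# beam construction and back-projection.

test_that("quaternion-to-rotation matches fixed cases and the Hamilton-product oracle", {
  expect_equal(quat_to_rotmat(c(1, 0, 0, 0)), diag(3))
  expect_equal(quat_to_rotmat(c(0, 0, 0, 1)), diag(c(-1, -1, 1)))
  expect_error(quat_to_rotmat(c(0, 0, 0, 0)), "zero quaternion")

  # oracle: rotate each basis vector by quaternion conjugation q v q*
  hprod <- function(a, b) {
    c(a[1] * b[1] - sum(a[2:4] * b[2:4]),
      a[1] * b[2:4] + b[1] * a[2:4] +
        c(a[3] * b[4] - a[4] * b[3],
          a[4] * b[2] - a[2] * b[4],
          a[2] * b[3] - a[3] * b[2]))
  }
  set.seed(41)
  for (i in 1:20) {
    q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
    R <- quat_to_rotmat(q)
    qc <- c(q[1], -q[2:4])
    # columns of R are the world images of the camera basis under q . q*
    oracle <- sapply(1:3, function(j) {
      e <- c(0, as.numeric(1:3 == j))
      hprod(hprod(q, e), qc)[2:4]
    })
    expect_equal(R, oracle, tolerance = 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-9)
    expect_equal(crossprod(R), diag(3), tolerance = 1e-12,
                 ignore_attr = TRUE)
    # inverse conversion closes the loop (up to sign, fixed to w >= 0)
    qq <- rotmat_to_quat(R)
    if (q[1] < 0) q <- -q
    expect_equal(qq, q, tolerance = 1e-9)
  }
})

test_that("normalised gaze positions map to pixels with the bottom-left flip", {
  expect_equal(pixel_from_norm(0.5, 0.5, c(1280, 720)),
               tibble::tibble(u = 640, v = 360))
  expect_equal(pixel_from_norm(0, 0, c(100, 200)),
               tibble::tibble(u = 0, v = 200))
  expect_equal(pixel_from_norm(0.25, 0.75, c(100, 100)),
               tibble::tibble(u = 25, v = 25))
  expect_equal(pixel_from_norm(0.25, 0.75, c(100, 100), flip_y = FALSE),
               tibble::tibble(u = 25, v = 75))
  # out-of-frame gaze passes through with a notice, not an error
  expect_message(out <- pixel_from_norm(1.2, 0.5, c(100, 100)), "outside")
  expect_equal(out$u, 120)
  # exact inverse
  set.seed(5)
  nx <- runif(20); ny <- runif(20)
  px <- pixel_from_norm(nx, ny, c(1286, 731))
  back <- norm_from_pixel(px$u, px$v, c(1286, 731))
  expect_equal(back$norm_x, nx)
  expect_equal(back$norm_y, ny)
})

test_that("radial undistortion inverts the forward model and fixes k = 0", {
  cam <- tibble::tibble(image_name = "a", focal_px = 1000,
                        qw = 1, qx = 0, qy = 0, qz = 0,
                        cx = 0, cy = 0, cz = 0, k_radial = 0,
                        width_px = 1280L, height_px = 720L)
  expect_identical(undistort_pixel(123.4, 567.8, cam),
                   tibble::tibble(u = 123.4, v = 567.8))
  set.seed(6)
  for (k in c(1e-8, -1e-8, 5e-8)) {
    camk <- cam; camk$k_radial <- k
    u <- runif(50, 0, 1280); v <- runif(50, 0, 720)
    d <- distort_pixel(u, v, camk)
    back <- undistort_pixel(d$u, d$v, camk)
    expect_lt(max(abs(back$u - u), abs(back$v - v)), 1e-6)
    # principal point is a fixed point for any k
    pp <- undistort_pixel(640, 360, camk)
    expect_equal(c(pp$u, pp$v), c(640, 360))
  }
})

test_that("beam construction reproduces the principal ray and known view angles", {
  cam <- tibble::tibble(image_name = "a", focal_px = 1000,
                        qw = 1, qx = 0, qy = 0, qz = 0,
                        cx = 0, cy = 0, cz = 0, k_radial = 0,
                        width_px = 1000L, height_px = 1000L)
  r <- ray_from_fixation(cam, 500, 500)
  expect_equal(r$origin, c(0, 0, 0))
  expect_equal(r$direction, c(0, 0, 1))
  # one focal length off-centre horizontally: 45 degrees
  r45 <- ray_from_fixation(cam, 1500, 500)
  expect_equal(r45$direction, c(1, 0, 1) / sqrt(2))
  # closed-form view angle for random poses and pixels
  set.seed(7)
  for (i in 1:25) {
    camr <- random_camera()
    u <- runif(1, 0, camr$width_px); v <- runif(1, 0, camr$height_px)
    ray <- ray_from_fixation(camr, u, v)
    expect_equal(sqrt(sum(ray$direction^2)), 1, tolerance = 1e-12)
    principal <- ray_from_fixation(camr, camr$width_px / 2,
                                   camr$height_px / 2)
    ang <- acos(min(1, sum(ray$direction * principal$direction)))
    expected <- atan(sqrt((u - camr$width_px / 2)^2 +
                          (v - camr$height_px / 2)^2) / camr$focal_px)
    expect_equal(ang, expected, tolerance = 1e-9)
  }
})

test_that("project-then-raycast recovers points; behind-camera points are flagged", {
  cam <- tibble::tibble(image_name = "a", focal_px = 900,
                        qw = 1, qx = 0, qy = 0, qz = 0,
                        cx = 0, cy = 0, cz = 0, k_radial = 0,
                        width_px = 1280L, height_px = 720L)
  expect_equal(project_point_to_pixel(cam, c(0, 0, 2))[, c("u", "v")],
               tibble::tibble(u = 640, v = 360))
  behind <- project_point_to_pixel(cam, c(0, 0, -1))
  expect_true(behind$behind)
  expect_true(is.na(behind$u))

  set.seed(8)
  for (i in 1:10) {
    camr <- random_camera()
    pts <- visible_points(camr, 100)
    px <- project_point_to_pixel(camr, pts)
    expect_false(any(px$behind))
    worst <- max(vapply(seq_len(nrow(pts)), function(j) {
      ray <- ray_from_fixation(camr, px$u[j], px$v[j])
      ray_point_distance(ray, pts[j, ])
    }, 0))
    expect_lt(worst, 1e-6)
  }
  # small distortion: same loop at looser tolerance
  for (i in 1:3) {
    camr <- random_camera(k_radial = 2e-8)
    pts <- visible_points(camr, 50)
    px <- project_point_to_pixel(camr, pts)
    worst <- max(vapply(seq_len(nrow(pts)), function(j) {
      und <- undistort_pixel(px$u[j], px$v[j], camr)
      ray <- ray_from_fixation(camr, und$u, und$v)
      ray_point_distance(ray, pts[j, ])
    }, 0))
    expect_lt(worst, 1e-4)
  }
})

test_that("rotating a pose rotates all beam directions identically (equivariance)", {
  set.seed(9)
  cam <- random_camera()
  qg <- stats::rnorm(4); qg <- qg / sqrt(sum(qg^2))
  G <- quat_to_rotmat(qg)   # fixed world rotation
  # rotated pose: world-to-camera rotation becomes R G^T, centre G c
  R <- quat_to_rotmat(c(cam$qw, cam$qx, cam$qy, cam$qz))
  q2 <- rotmat_to_quat(R %*% t(G))
  cam2 <- cam
  cam2$qw <- q2[1]; cam2$qx <- q2[2]; cam2$qy <- q2[3]; cam2$qz <- q2[4]
  ctr2 <- as.numeric(G %*% c(cam$cx, cam$cy, cam$cz))
  cam2$cx <- ctr2[1]; cam2$cy <- ctr2[2]; cam2$cz <- ctr2[3]
  for (i in 1:10) {
    u <- runif(1, 0, cam$width_px); v <- runif(1, 0, cam$height_px)
    d1 <- ray_from_fixation(cam, u, v)$direction
    d2 <- ray_from_fixation(cam2, u, v)$direction
    expect_equal(d2, as.numeric(G %*% d1), tolerance = 1e-9)
  }
})
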