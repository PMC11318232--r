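#' Assign each fixation to its world-video frame and extract the images
#'
#' For every fixation, selects the frame whose timestamp is nearest the
#' fixation's reference time — its start by default, or its midpoint with
#' `timestamp_mode = "mid"` — with ties resolved to the earlier frame. When
#' `frame_dir` and `out_dir` are given, the selected images are copied under
#' names embedding the fixation id and the assignment table is written
#' alongside them.
#'
#' @param fixations A `fixation_table` (see [read_fixation_csv()]).
#' @param frame_timestamps Tibble with `frame_index`, `frame_file`,
#'   `timestamp` (seconds, monotone non-decreasing, one row per frame file).
#' @param frame_dir Directory holding the frame image files (optional).
#' @param out_dir Directory to copy extracted frames into (optional).
#' @param timestamp_mode `"start"` or `"mid"`.
#' @return A tibble of class `frame_assignment`: `fixation_id`,
#'   `frame_index`, `frame_file`, `frame_timestamp`, `out_of_span`.
#' @export
extract_fixation_frames <- function(fixations, frame_timestamps,
                                    frame_dir = NULL, out_dir = NULL,
                                    timestamp_mode = c("start", "mid")) {
  timestamp_mode <- match.arg(timestamp_mode)
  ts <- frame_timestamps$timestamp
  stopifnot(nrow(frame_timestamps) > 0, !is.unsorted(ts))
  ref <- fixations$start_timestamp
  if (timestamp_mode == "mid") ref <- ref + fixations$duration_ms / 2000
  # nearest frame; numerically tied distances resolve to the earlier frame
  idx <- vapply(ref, function(r) {
    d <- abs(ts - r)
    which(d <= min(d) + 1e-9 * max(1, abs(r)))[1]
  }, 1L)
  interval <- if (length(ts) > 1) stats::median(diff(ts)) else Inf
  out_of_span <- ref < ts[1] - interval | ref > ts[length(ts)] + interval
  if (any(out_of_span)) {
    message(sum(out_of_span),
            " fixation(s) fall outside the video span by more than one frame interval")
  }
  assign <- tibble::tibble(
    fixation_id = fixations$fixation_id,
    frame_index = frame_timestamps$frame_index[idx],
    frame_file = frame_timestamps$frame_file[idx],
    frame_timestamp = ts[idx],
    out_of_span = out_of_span
  )
  if (!is.null(frame_dir) && !is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(assign))) {
      src <- file.path(frame_dir, assign$frame_file[i])
      dst <- file.path(out_dir, sprintf("fixation_%04d_%s",
                                        assign$fixation_id[i],
                                        assign$frame_file[i]))
      if (file.exists(src)) file.copy(src, dst, overwrite = TRUE)
      else message("frame file missing, not copied: ", src)
    }
    readr::write_csv(assign, file.path(out_dir, "frame_assignments.csv"),
                     progress = FALSE)
  }
  class(assign) <- c("frame_assignment", class(assign))
  assign
}

#' Mark a fixation on a frame image
#'
#' Draws a circle (yellow by default, matching the usual world-video
#' visualisation) centred on the gaze pixel, plus the fixation id rendered
#' with a small built-in digit font next to it. Pixels outside circle and
#' label are untouched. Marks that extend past the image border are clipped
#' with a warning.
#'
#' @param image HxWx3 numeric array in `[0, 1]` (as from [png::readPNG()]).
#' @param u,v Gaze pixel (top-left origin; pixel centres at half-integers).
#' @param fixation_id Integer id drawn next to the circle.
#' @param radius Circle radius in pixels.
#' @param color Circle RGB in `[0, 1]`.
#' @param label_color Label RGB in `[0, 1]`.
#' @return The annotated image array.
#' @export
mark_fixation <- function(image, u, v, fixation_id, radius = 8,
                          color = c(1, 1, 0), label_color = c(1, 1, 1)) {
  stopifnot(length(dim(image)) == 3, is.finite(u), is.finite(v))
  h <- dim(image)[1]; w <- dim(image)[2]
  if (u - radius < 0 || u + radius > w || v - radius < 0 || v + radius > h) {
    warning(sprintf("marker at (%.1f, %.1f) extends past the %dx%d frame; clipped",
                    u, v, w, h))
  }
  cols <- pmax(1L, ceiling(u - radius - 1)):pmin(w, ceiling(u + radius + 1))
  rows <- pmax(1L, ceiling(v - radius - 1)):pmin(h, ceiling(v + radius + 1))
  # pixel (r, c) has centre (c - 0.5, r - 0.5)
  cu <- cols - 0.5; rv <- rows - 0.5
  d <- sqrt(outer((rv - v)^2, (cu - u)^2, `+`))
  ring <- abs(d - radius) <= 0.6
  for (ch in 1:3) {
    plane <- image[rows, cols, ch]
    plane[ring] <- color[ch]
    image[rows, cols, ch] <- plane
  }
  image <- .draw_label(image, as.character(fixation_id),
                       u + radius + 3, v - radius - 1, label_color)
  image
}

# 3x5 digit glyphs, rows top to bottom, "1" = lit
.digit_font <- list(
  "0" = c("111","101","101","101","111"), "1" = c("010","110","010","010","111"),
  "2" = c("111","001","111","100","111"), "3" = c("111","001","111","001","111"),
  "4" = c("101","101","111","001","001"), "5" = c("111","100","111","001","111"),
  "6" = c("111","100","111","101","111"), "7" = c("111","001","010","010","010"),
  "8" = c("111","101","111","101","111"), "9" = c("111","101","111","001","111")
)

.draw_label <- function(image, text, u, v, color) {
  h <- dim(image)[1]; w <- dim(image)[2]
  x0 <- round(u)
  for (chr in strsplit(text, "")[[1]]) {
    g <- .digit_font[[chr]]
    if (!is.null(g)) {
      for (r in 1:5) {
        bits <- strsplit(g[r], "")[[1]] == "1"
        for (c3 in 1:3) {
          if (bits[c3]) {
            rr <- round(v) + r; cc <- x0 + c3
            if (rr >= 1 && rr <= h && cc >= 1 && cc <= w) {
              image[rr, cc, ] <- color
            }
          }
        }
      }
    }
    x0 <- x0 + 4
  }
  image
}

#' Locate a marker circle's centroid in an annotated frame
#'
#' Finds pixels matching the marker colour and returns the centroid of
#' their centres — the evaluation counterpart of [mark_fixation()], used to
#' confirm that drawn markers and projective geometry agree.
#'
#' @param image HxWx3 array.
#' @param color Marker RGB to match (default yellow).
#' @param tol Per-channel match tolerance.
#' @return A tibble with `u`, `v` of the centroid and `n_pixels` matched.
#' @export
detect_marker_centroid <- function(image, color = c(1, 1, 0), tol = 0.02) {
  match_px <- abs(image[, , 1] - color[1]) <= tol &
    abs(image[, , 2] - color[2]) <= tol &
    abs(image[, , 3] - color[3]) <= tol
  w <- which(match_px, arr.ind = TRUE)
  if (nrow(w) == 0) stop("no pixels matching the marker colour")
  tibble::tibble(u = mean(w[, 2] - 0.5), v = mean(w[, 1] - 0.5),
                 n_pixels = nrow(w))
}

#' Project fixations onto the model: the core mapping step
#'
#' For each fixation, in table order: look up the pose of its assigned frame
#' in the scene (status `frame_not_registered` when absent), convert the
#' normalised gaze position to a pixel, undo radial distortion when the pose
#' carries a coefficient, cast the visual beam from the camera centre
#' through the gaze pixel, and intersect it with the mesh. A hit yields
#' status `mapped` with the intersection point; a miss yields
#' `no_intersection`. No fixation is ever dropped — every anomaly is a
#' status — and all eye-tracker columns pass through.
#'
#' @param scene An [sfm_scene()] whose poses cover the fixation frames.
#' @param mesh A [triangle_mesh()].
#' @param fixations A `fixation_table`.
#' @param assignments A `frame_assignment` table covering all fixations.
#' @param flip_y,distortion,world_to_camera,backface_cull,t_epsilon
#'   Geometry switches, see [pixel_from_norm()], [undistort_pixel()],
#'   [ray_from_fixation()] and [intersect_ray_mesh()].
#' @param image_size Fallback `(width, height)` for cameras without one.
#' @param accelerator Optional index from [build_accelerator()]; built
#'   internally when `NULL`.
#' @return A tibble of class `projection_table`: `fixation_id`,
#'   `intersection_x/y/z`, `fixation_start_x/y/z`,
#'   `fixation_direction_x/y/z`, `status`, `ray_t`, then the passthrough
#'   eye-tracker columns.
#' @export
project_fixations <- function(scene, mesh, fixations, assignments,
                              flip_y = TRUE, distortion = TRUE,
                              world_to_camera = TRUE, backface_cull = FALSE,
                              t_epsilon = 1e-9, image_size = c(1280, 720),
                              accelerator = NULL) {
  stopifnot(all(fixations$fixation_id %in% assignments$fixation_id))
  if (is.null(accelerator) && n_faces(mesh) > 0) {
    accelerator <- build_accelerator(mesh)
  }
  amap <- match(fixations$fixation_id, assignments$fixation_id)
  rows <- vector("list", nrow(fixations))
  for (i in seq_len(nrow(fixations))) {
    fx <- fixations[i, ]
    frame_file <- assignments$frame_file[amap[i]]
    cam <- scene_camera(scene, frame_file)
    rec <- tibble::tibble(
      fixation_id = fx$fixation_id,
      intersection_x = NA_real_, intersection_y = NA_real_,
      intersection_z = NA_real_,
      fixation_start_x = NA_real_, fixation_start_y = NA_real_,
      fixation_start_z = NA_real_,
      fixation_direction_x = NA_real_, fixation_direction_y = NA_real_,
      fixation_direction_z = NA_real_,
      status = "frame_not_registered", ray_t = NA_real_
    )
    if (!is.null(cam)) {
      if (is.na(cam$width_px)) {
        cam$width_px <- as.integer(image_size[1])
        cam$height_px <- as.integer(image_size[2])
      }
      px <- pixel_from_norm(fx$norm_x, fx$norm_y,
                            c(cam$width_px, cam$height_px), flip_y = flip_y)
      if (distortion && cam$k_radial != 0) {
        px <- undistort_pixel(px$u, px$v, cam)
      }
      ray <- ray_from_fixation(cam, px$u, px$v,
                               world_to_camera = world_to_camera)
      hit <- intersect_ray_mesh(ray, mesh, accelerator = accelerator,
                                t_epsilon = t_epsilon,
                                backface_cull = backface_cull)
      rec$fixation_start_x <- ray$origin[1]
      rec$fixation_start_y <- ray$origin[2]
      rec$fixation_start_z <- ray$origin[3]
      rec$fixation_direction_x <- ray$direction[1]
      rec$fixation_direction_y <- ray$direction[2]
      rec$fixation_direction_z <- ray$direction[3]
      if (is.null(hit)) {
        rec$status <- "no_intersection"
      } else {
        rec$status <- "mapped"
        rec$intersection_x <- hit$point[1]
        rec$intersection_y <- hit$point[2]
        rec$intersection_z <- hit$point[3]
        rec$ray_t <- hit$t
      }
    }
    rows[[i]] <- rec
  }
  out <- dplyr::bind_rows(rows)
  passthrough <- fixations[setdiff(names(fixations), "fixation_id")]
  out <- dplyr::bind_cols(out, passthrough)
  class(out) <- c("projection_table", class(out))
  out
}

#' Run the full mapping pipeline from a configuration
#'
#' Reads the scene (NVM), model (PLY), fixation table (CSV) and
#' frame-timestamp table, assigns fixations to frames, projects every
#' fixation onto the model, and writes the output bundle into `out`:
#' `projections.csv`, `fixations.ply`, `project.mlp` and `run_log.txt`.
#' Deterministic given inputs and configuration; reruns are byte-identical.
#'
#' @param config Named list, or path to a flat `key = value` configuration
#'   file (see [read_pipeline_config()]). Required keys: `scene`, `mesh`,
#'   `fixations`, `timestamps`, `out`. Optional: `frames` (image dir),
#'   `flip_y`, `distortion`, `world_to_camera`, `backface_cull`,
#'   `timestamp_mode`, `image_width`, `image_height`, `ply_format`.
#' @return Invisibly, a list with `projections`, `assignments`, `scene`,
#'   `mesh` and the output `paths`.
#' @export
run_gaze_mapping <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  required <- c("scene", "mesh", "fixations", "timestamps", "out")
  problems <- character()
  for (key in required) {
    if (is.null(config[[key]])) {
      problems <- c(problems, paste0("missing config key: ", key))
    } else if (key != "out" && !file.exists(config[[key]])) {
      problems <- c(problems, paste0("config key '", key,
                                     "' points to a missing file: ",
                                     config[[key]]))
    }
  }
  if (!is.null(config$frames) && !dir.exists(config$frames)) {
    problems <- c(problems, paste0("config key 'frames' points to a missing directory: ",
                                   config$frames))
  }
  if (length(problems) > 0) {
    stop("configuration invalid:\n  ", paste(problems, collapse = "\n  "))
  }
  get_flag <- function(key, default) {
    v <- config[[key]]
    if (is.null(v)) default else as.logical(v)
  }
  image_size <- c(as.numeric(config$image_width %||% 1280),
                  as.numeric(config$image_height %||% 720))
  scene <- read_nvm(config$scene, image_size = image_size)
  mesh <- read_ply_mesh(config$mesh)
  fixations <- read_fixation_csv(config$fixations)
  timestamps <- readr::read_csv(config$timestamps, show_col_types = FALSE,
                                progress = FALSE)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  assignments <- extract_fixation_frames(
    fixations, timestamps, frame_dir = config$frames,
    out_dir = if (is.null(config$frames)) NULL else
      file.path(config$out, "frames"),
    timestamp_mode = config$timestamp_mode %||% "start")
  projections <- project_fixations(
    scene, mesh, fixations, assignments,
    flip_y = get_flag("flip_y", TRUE),
    distortion = get_flag("distortion", TRUE),
    world_to_camera = get_flag("world_to_camera", TRUE),
    backface_cull = get_flag("backface_cull", FALSE),
    image_size = image_size)
  paths <- list(
    projections = file.path(config$out, "projections.csv"),
    fixation_ply = file.path(config$out, "fixations.ply"),
    meshlab = file.path(config$out, "project.mlp"),
    log = file.path(config$out, "run_log.txt")
  )
  write_projection_csv(projections, paths$projections)
  write_fixation_ply(projections, paths$fixation_ply,
                     format = config$ply_format %||% "binary_little_endian")
  write_meshlab_project(config$mesh, paths$fixation_ply, scene,
                        paths$meshlab, default_image_size = image_size)
  log_lines <- c(
    sprintf("fixation %s: frame %s status %s t %s",
            projections$fixation_id,
            assignments$frame_file[match(projections$fixation_id,
                                         assignments$fixation_id)],
            projections$status,
            ifelse(is.na(projections$ray_t), "-",
                   sprintf("%.6f", projections$ray_t))),
    "summary:",
    sprintf("  %s: %d", names(table(projections$status)),
            as.integer(table(projections$status)))
  )
  writeLines(log_lines, paths$log)
  message("mapped ", sum(projections$status == "mapped"), " of ",
          nrow(projections), " fixation(s); outputs in ", config$out)
  invisible(list(projections = projections, assignments = assignments,
                 scene = scene, mesh = mesh, paths = paths))
}

#' Read a flat key = value pipeline configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment; keys mirror the
#' CLI flags. Values are kept as strings and coerced where used.
#'
#' @param path Path to the configuration file.
#' @return A named list.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line(s): ",
                     paste(lines[bad], collapse = "; "))
  stats::setNames(lapply(kv, `[[`, 2), vapply(kv, `[[`, "", 1))
}
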