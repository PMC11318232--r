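#' Construct an SfM scene (camera-pose table)
#'
#' A scene is a tibble with one row per registered image: `image_name`,
#' `focal_px`, quaternion `qw, qx, qy, qz` (world-to-camera, WXYZ),
#' camera centre `cx, cy, cz` (model units), `k_radial` (single radial
#' distortion coefficient) and the image size `width_px`, `height_px`
#' (may be `NA` until the frame files are read; NVM stores no size).
#'
#' @param cameras A data frame with the columns above (sizes optional).
#' @return A tibble of class `sfm_scene`. Quaternions are renormalised;
#'   duplicate image names are an error.
#' @export
sfm_scene <- function(cameras) {
  cameras <- tibble::as_tibble(cameras)
  needed <- c("image_name", "focal_px", "qw", "qx", "qy", "qz",
              "cx", "cy", "cz", "k_radial")
  missing <- setdiff(needed, names(cameras))
  if (length(missing) > 0) {
    stop("scene is missing columns: ", paste(missing, collapse = ", "))
  }
  if (!"width_px" %in% names(cameras)) cameras$width_px <- NA_integer_
  if (!"height_px" %in% names(cameras)) cameras$height_px <- NA_integer_
  if (anyDuplicated(cameras$image_name)) {
    stop("duplicate image_name in scene: ",
         paste(unique(cameras$image_name[duplicated(cameras$image_name)]),
               collapse = ", "))
  }
  if (nrow(cameras) > 0) {
    stopifnot(all(cameras$focal_px > 0))
    qn <- sqrt(cameras$qw^2 + cameras$qx^2 + cameras$qy^2 + cameras$qz^2)
    if (any(abs(qn - 1) > 1e-3)) {
      warning(sum(abs(qn - 1) > 1e-3),
              " camera quaternion(s) deviate from unit norm by > 1e-3; renormalising")
    }
    cameras$qw <- cameras$qw / qn; cameras$qx <- cameras$qx / qn
    cameras$qy <- cameras$qy / qn; cameras$qz <- cameras$qz / qn
  }
  class(cameras) <- c("sfm_scene", class(tibble::tibble()))
  cameras
}

#' Look up a camera pose by image name
#'
#' The join key between fixation frames and reconstructed poses is the image
#' file name; a frame whose name (exact, or ignoring the file extension) has
#' no pose is unregistered.
#'
#' @param scene An [sfm_scene()].
#' @param image_name Frame file name.
#' @return A one-row tibble, or `NULL` when the frame is not registered.
#' @export
scene_camera <- function(scene, image_name) {
  i <- match(image_name, scene$image_name)
  if (is.na(i)) {
    # tolerate extension mismatch between video frames and reconstruction
    strip <- function(x) sub("\\.[A-Za-z0-9]+$", "", x)
    i <- match(strip(image_name), strip(scene$image_name))
  }
  if (is.na(i)) return(NULL)
  scene[i, ]
}

#' Read a VisualSFM NVM scene file
#'
#' Supports the `NVM_V3` dialect: after the magic line and camera count, one
#' line per camera with `name focal qw qx qy qz cx cy cz k 0` — focal length
#' in pixels, WXYZ orientation quaternion (world-to-camera), camera *centre*
#' (not translation), one radial-distortion coefficient and a trailing zero.
#' Feature points after the camera block are ignored. NVM stores no image
#' size; supply one via `image_size`, or leave `NA` until frames are read.
#'
#' @param path Path to an `.nvm` file (or a character vector of lines).
#' @param image_size Either `NULL`, a single `(width, height)` applied to all
#'   cameras, or a data frame with `image_name`, `width_px`, `height_px`.
#' @return An [sfm_scene()] with cameras in file order.
#' @export
read_nvm <- function(path, image_size = NULL) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  lines <- trimws(lines)
  nonempty <- which(nzchar(lines))
  if (length(nonempty) == 0 || !startsWith(lines[nonempty[1]], "NVM_V3")) {
    stop("not an NVM file: missing NVM_V3 magic line")
  }
  body <- nonempty[-1]
  if (length(body) == 0) stop("NVM file truncated: no camera count")
  n_cam <- suppressWarnings(as.integer(lines[body[1]]))
  if (is.na(n_cam) || n_cam < 0) {
    stop("invalid camera count on line ", body[1], ": '", lines[body[1]], "'")
  }
  cam_lines <- body[-1][seq_len(n_cam)]
  if (n_cam > 0 && (length(cam_lines) < n_cam || anyNA(cam_lines))) {
    stop("NVM file declares ", n_cam, " cameras but fewer lines are present")
  }
  rows <- lapply(cam_lines, function(i) {
    tok <- strsplit(lines[i], "[ \t]+")[[1]]
    if (length(tok) != 11) {
      stop("NVM camera line ", i, ": expected 11 tokens (name + 10 numbers), got ",
           length(tok))
    }
    num <- suppressWarnings(as.numeric(tok[-1]))
    if (anyNA(num)) stop("NVM camera line ", i, ": non-numeric field")
    tibble::tibble(image_name = tok[1], focal_px = num[1],
                   qw = num[2], qx = num[3], qy = num[4], qz = num[5],
                   cx = num[6], cy = num[7], cz = num[8], k_radial = num[9])
  })
  cams <- if (n_cam == 0) {
    tibble::tibble(image_name = character(), focal_px = numeric(),
                   qw = numeric(), qx = numeric(), qy = numeric(),
                   qz = numeric(), cx = numeric(), cy = numeric(),
                   cz = numeric(), k_radial = numeric())
  } else {
    dplyr::bind_rows(rows)
  }
  scene <- sfm_scene(cams)
  if (!is.null(image_size)) {
    if (is.numeric(image_size) && length(image_size) == 2) {
      scene$width_px <- as.integer(image_size[1])
      scene$height_px <- as.integer(image_size[2])
    } else {
      sz <- tibble::as_tibble(image_size)
      i <- match(scene$image_name, sz$image_name)
      scene$width_px <- as.integer(sz$width_px[i])
      scene$height_px <- as.integer(sz$height_px[i])
    }
  }
  scene
}

#' Write a scene to a VisualSFM NVM file
#'
#' Emits the `NVM_V3` dialect read by [read_nvm()]; the output reparses to a
#' field-wise identical scene (within 1e-9; fields are printed with 17
#' significant digits). Image sizes are not representable in NVM and are
#' dropped.
#'
#' @param scene An [sfm_scene()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nvm <- function(scene, path) {
  num_cols <- c("focal_px", "qw", "qx", "qy", "qz", "cx", "cy", "cz", "k_radial")
  if (nrow(scene) > 0 && !all(vapply(scene[num_cols], function(x) all(is.finite(x)), TRUE))) {
    stop("refusing to write scene with non-finite camera fields")
  }
  fmt <- function(x) sprintf("%.17g", x)
  lines <- c("NVM_V3", "", as.character(nrow(scene)))
  if (nrow(scene) > 0) {
    lines <- c(lines, purrr::pmap_chr(scene[c("image_name", num_cols)],
      function(image_name, focal_px, qw, qx, qy, qz, cx, cy, cz, k_radial) {
        paste(image_name, fmt(focal_px), fmt(qw), fmt(qx), fmt(qy), fmt(qz),
              fmt(cx), fmt(cy), fmt(cz), fmt(k_radial), "0")
      }))
  }
  lines <- c(lines, "", "0", "")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.sfm_scene <- function(x, ...) {
  cat(sprintf("<sfm_scene> %d registered camera(s)\n", nrow(x)))
  NextMethod()
}
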