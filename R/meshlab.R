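#' Write a MeshLab project (.mlp) bundling model, fixations and cameras
#'
#' Produces a MeshLab project XML with two mesh layers — the stimulus model
#' and the fixation point cloud — and one raster entry per registered camera
#' carrying its pose (rotation matrix and centre) and intrinsics, so the
#' camera views can be superimposed semi-transparently over the model for
#' visual checking of mapped fixations.
#'
#' @param mesh_path Path to the model PLY (must exist).
#' @param fixation_ply_path Path to the fixation point-cloud PLY (must exist).
#' @param cameras An [sfm_scene()]; cameras without a stored image size fall
#'   back to `default_image_size`.
#' @param path Output `.mlp` path.
#' @param default_image_size `(width, height)` used when a camera has none.
#' @return `path`, invisibly.
#' @export
write_meshlab_project <- function(mesh_path, fixation_ply_path, cameras, path,
                                  default_image_size = c(1280, 720)) {
  for (p in c(mesh_path, fixation_ply_path)) {
    if (!file.exists(p)) stop("referenced file does not exist: ", p)
  }
  doc <- xml2::xml_new_root("MeshLabProject")
  grp <- xml2::xml_add_child(doc, "MeshGroup")
  for (p in c(mesh_path, fixation_ply_path)) {
    m <- xml2::xml_add_child(grp, "MLMesh",
                             label = basename(p), filename = p)
    xml2::xml_add_child(m, "RenderingOption", "000000000000")
  }
  rgrp <- xml2::xml_add_child(doc, "RasterGroup")
  for (i in seq_len(nrow(cameras))) {
    cam <- cameras[i, ]
    w <- cam$width_px; h <- cam$height_px
    if (is.na(w) || is.na(h)) {
      w <- default_image_size[1]; h <- default_image_size[2]
    }
    R <- quat_to_rotmat(c(cam$qw, cam$qx, cam$qy, cam$qz))
    M <- diag(4)
    M[1:3, 1:3] <- R
    r <- xml2::xml_add_child(rgrp, "MLRaster", label = cam$image_name)
    # VCG convention: 35mm-equivalent sensor, focal scaled accordingly
    pix_mm <- 36 / w
    xml2::xml_add_child(r, "VCGCamera",
      TranslationVector = paste(c(-cam$cx, -cam$cy, -cam$cz, 1), collapse = " "),
      RotationMatrix = paste(sprintf("%.12g", t(M)), collapse = " "),
      ViewportPx = paste(c(w, h), collapse = " "),
      CenterPx = paste(c(w / 2, h / 2), collapse = " "),
      PixelSizeMm = paste(rep(sprintf("%.9g", pix_mm), 2), collapse = " "),
      FocalMm = sprintf("%.9g", cam$focal_px * pix_mm),
      LensDistortion = paste(c(cam$k_radial, 0), collapse = " "),
      BinaryData = "0")
    xml2::xml_add_child(r, "Plane", semantic = "1", fileName = cam$image_name)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
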